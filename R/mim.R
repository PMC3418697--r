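# Hemorrhage matching by mutual information maximization. The detected
# seed C_d bounds a sweep of candidate minimum gray levels G_mi in
# [g_min, g_max]; each candidate region B_i (ROI pixels in [G_mi, g_max],
# morphologically cleaned) is compared with C_d by mutual information, and
# the maximizing cut-off becomes the optimum minimum hemorrhage gray G_opt.

#' MIM-stage configuration
#'
#' @param roi_size side `q` of the square region of interest centered on
#'   the seed centroid. 100 px suits 512 px slices: large enough to hold
#'   the whole hemorrhage, small enough to exclude unrelated tissue.
#' @param min_component_area candidate-region components smaller than this
#'   are removed before MI scoring.
#' @param morph_radius closing radius applied to each candidate.
#' @param binary_mi compare binary membership images (default) or the
#'   gray-level region images.
#' @return object of class `mim_config`.
#' @export
mim_config <- function(roi_size = 100L, min_component_area = 9L,
                       morph_radius = 1L, binary_mi = TRUE) {
  if (roi_size < 3L) stop("roi_size must be >= 3")
  structure(list(roi_size = as.integer(roi_size),
                 min_component_area = as.integer(min_component_area),
                 morph_radius = as.integer(morph_radius),
                 binary_mi = isTRUE(binary_mi)),
            class = "mim_config")
}

#' Shannon entropy of an image's gray-level histogram
#'
#' `H = -sum p(c) log2 p(c)` over the empirical distribution of values,
#' with `0 log 0 := 0`. Binary masks are treated as two-symbol images.
#'
#' @param img numeric/integer matrix or vector, or a `region_mask`
#'   (member/non-member as the two symbols).
#' @return entropy in bits.
#' @export
img_entropy <- function(img) {
  v <- as.vector(as_values(img))
  if (!length(v)) stop("cannot compute the entropy of an empty pixel set")
  p <- table(v) / length(v)
  -sum(p * log2(p))
}

as_values <- function(img) {
  if (inherits(img, "region_mask")) return(img$mask * 1L)
  if (inherits(img, "ct_slice")) return(img$pixels)
  img
}

#' Mutual information between two same-shape images
#'
#' `MI(a, b) = H(a) + H(b) - H(a, b)` from the marginal and joint
#' gray-level histograms; symmetric and non-negative up to numerical
#' tolerance.
#'
#' @param a,b matrices (or `region_mask`s) of identical shape.
#' @return mutual information in bits.
#' @export
mutual_information <- function(a, b) {
  va <- as_values(a); vb <- as_values(b)
  if (!identical(dim(va), dim(vb)) || length(va) != length(vb)) {
    stop("mutual_information needs identically shaped images")
  }
  ha <- img_entropy(va)
  hb <- img_entropy(vb)
  joint <- paste(as.vector(va), as.vector(vb), sep = ",")
  hab <- img_entropy(joint)
  ha + hb - hab
}

roi_bounds <- function(centroid, q, h, w) {
  half <- q %/% 2L
  r1 <- round(centroid[1]) - half
  c1 <- round(centroid[2]) - half
  r1 <- max(1L, min(r1, h - q + 1L)); r2 <- min(h, r1 + q - 1L)
  c1 <- max(1L, min(c1, w - q + 1L)); c2 <- min(w, c1 + q - 1L)
  c(r1 = max(1L, r1), r2 = r2, c1 = max(1L, c1), c2 = c2)
}

clean_candidate <- function(cand, cfg) {
  if (!any(cand)) return(cand)
  lab <- label_components(cand)
  areas <- component_areas(lab)
  keep <- which(areas >= cfg$min_component_area)
  cand <- matrix(lab %in% keep, nrow(cand), ncol(cand))
  if (any(cand) && cfg$morph_radius > 0L) {
    cand <- EBImage::closing(cand * 1L, box_brush(cfg$morph_radius)) > 0
  }
  cand
}

#' Find the optimum minimum hemorrhage gray level by MIM
#'
#' Sweeps every candidate cut-off `G_mi` in `[g_min, g_max]` (step 1). For
#' each, the candidate region `B_i` is the set of ROI pixels with gray in
#' `[G_mi, g_max]`, cleaned by small-component removal and closing; its
#' mutual information with the detected seed (both rendered over the ROI)
#' is recorded, and the maximizing cut-off is returned as `G_opt` with its
#' region `B_opt`. Ties take the lowest `G_mi`, which keeps faint boundary
#' pixels. If the seed's gray range is a single level the result
#' degenerates to `G_opt = g_min` with the plain thresholded ROI.
#'
#' @param slice bone- and artery-masked `ct_slice`.
#' @param seed `hemorrhage_seed` with `found = TRUE`.
#' @param cfg `mim_config`.
#' @return object of class `mim_result`: `g_opt`, `b_opt` (`region_mask`
#'   in full-slice coordinates), `mi_curve` (data.frame `g`, `mi`), `roi`
#'   (row/col bounds of the ROI window).
#' @export
mim_search <- function(slice, seed, cfg = mim_config()) {
  if (!isTRUE(seed$found)) stop("mim_search needs a found hemorrhage seed")
  h <- slice$height; w <- slice$width
  b <- roi_bounds(seed$centroid, min(cfg$roi_size, h, w), h, w)
  roi_px <- slice$pixels[b["r1"]:b["r2"], b["c1"]:b["c2"], drop = FALSE]
  cd_roi <- as_mask_matrix(seed$mask)[b["r1"]:b["r2"], b["c1"]:b["c2"],
                                      drop = FALSE]
  to_full <- function(roi_mask) {
    full <- matrix(FALSE, h, w)
    full[b["r1"]:b["r2"], b["c1"]:b["c2"]] <- roi_mask
    full
  }
  if (seed$g_min == seed$g_max) {
    cand <- roi_px >= seed$g_min & roi_px <= seed$g_max & roi_px > 0L
    return(structure(list(
      g_opt = seed$g_min,
      b_opt = region_mask(to_full(cand), "segmented_hemorrhage", slice$id),
      mi_curve = data.frame(g = seed$g_min,
                            mi = mutual_information(cd_roi * 1L, cand * 1L)),
      roi = b, degenerate = TRUE), class = "mim_result"))
  }
  gs <- seq.int(seed$g_min, seed$g_max)
  mi <- numeric(length(gs))
  best <- -Inf; best_mask <- NULL; g_opt <- gs[1]
  cd_img <- if (cfg$binary_mi) cd_roi * 1L else roi_px * cd_roi
  for (k in seq_along(gs)) {
    cand <- roi_px >= gs[k] & roi_px <= seed$g_max & roi_px > 0L
    cand <- clean_candidate(cand, cfg)
    bi_img <- if (cfg$binary_mi) cand * 1L else roi_px * cand
    mi[k] <- mutual_information(cd_img, bi_img)
    if (mi[k] > best + 1e-12) {
      best <- mi[k]; best_mask <- cand; g_opt <- gs[k]
    }
  }
  if (is.null(best_mask) || !any(best_mask)) {
    best_mask <- roi_px >= g_opt & roi_px <= seed$g_max & roi_px > 0L
  }
  structure(list(
    g_opt = g_opt,
    b_opt = region_mask(to_full(best_mask), "segmented_hemorrhage",
                        slice$id),
    mi_curve = data.frame(g = gs, mi = mi),
    roi = b, degenerate = FALSE), class = "mim_result")
}

#' @export
print.mim_result <- function(x, ...) {
  cat(sprintf("<mim_result: G_opt = %d, |B_opt| = %d, %d candidates>\n",
              x$g_opt, mask_area(x$b_opt), nrow(x$mi_curve)))
  invisible(x)
}

#' Write the MI sweep curve as CSV
#' @param result `mim_result`.
#' @param path output CSV path.
#' @export
write_mi_curve <- function(result, path) {
  utils::write.csv(result$mi_curve, path, row.names = FALSE)
  invisible(path)
}
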