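# Synthetic pelvic-CT-like phantoms: a soft-tissue ellipse at mid gray,
# high-gray bone blobs, small bright artery dots, and hemorrhage blobs that
# are brightest at the center and fade toward the edge, plus additive noise.
# Every structure comes with its exact ground-truth mask.

#' Specification for a synthetic pelvic-CT phantom
#'
#' Defaults describe an arterial-phase slice: soft tissue at mean gray 100
#' (sd-5 Gaussian noise), bone at gray 235-250, three 2-px artery dots with
#' per-pixel grays in 170-230, and one hemorrhage blob of radius 10 px whose
#' gray decays from a 220 peak as `peak * exp(-decay * (r/radius)^2)` so the
#' edge fades to ~155. In the veinal phase the blob-minus-tissue contrast is
#' multiplied by `veinal_contrast_scale` (< 1), emulating the loss of
#' hemorrhage conspicuity after the soft tissue absorbs the contrast agent.
#'
#' @param size image height/width in pixels (length-2 integer).
#' @param seed RNG seed; identical spec + seed give bit-identical phantoms.
#' @param tissue list: `center`, `axes` (ellipse semi-axes in px),
#'   `mean_gray`, `noise_sd`.
#' @param bone list: `count`, `gray_range`, `axes_range` (semi-axis range
#'   for the elliptical bone blobs).
#' @param artery list: `count`, `radius`, `gray_range`. The artery gray
#'   range must overlap the hemorrhage gray range: arteries and active
#'   bleeding carry similar contrast-enhanced gray levels, which is what
#'   makes the artery range usable as the hemorrhage search range.
#' @param hemorrhage list: `count`, `center` (NULL = random placement inside
#'   the tissue ellipse), `peak_gray`, `radius`, `decay` (edge-fade rate).
#' @param contrast_phase `"arterial"` or `"veinal"`.
#' @param veinal_contrast_scale contrast multiplier applied in veinal phase.
#' @param table_artifact add a thin bright horizontal band (a scanner table)
#'   outside the body ellipse, to exercise artifact removal.
#' @param gray_depth working gray depth.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(160L, 160L),
                         seed = 1L,
                         tissue = list(),
                         bone = list(),
                         artery = list(),
                         hemorrhage = list(),
                         contrast_phase = c("arterial", "veinal"),
                         veinal_contrast_scale = 0.45,
                         table_artifact = FALSE,
                         gray_depth = 255L) {
  contrast_phase <- match.arg(contrast_phase)
  tissue <- modifyList(list(center = size / 2, axes = c(0.44, 0.38) * size,
                            mean_gray = 100L, noise_sd = 5), tissue)
  bone <- modifyList(list(count = 2L, gray_range = c(235L, 250L),
                          axes_range = c(5, 11)), bone)
  artery <- modifyList(list(count = 3L, radius = 2L,
                            gray_range = c(160L, 230L)), artery)
  hemorrhage <- modifyList(list(count = 1L, center = NULL, peak_gray = 220L,
                                radius = 10, decay = 0.35), hemorrhage)
  spec <- structure(
    list(size = as.integer(size), seed = as.integer(seed), tissue = tissue,
         bone = bone, artery = artery, hemorrhage = hemorrhage,
         contrast_phase = contrast_phase,
         veinal_contrast_scale = veinal_contrast_scale,
         table_artifact = isTRUE(table_artifact),
         gray_depth = as.integer(gray_depth)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

effective_peak <- function(spec) {
  p <- spec$hemorrhage$peak_gray
  if (spec$contrast_phase == "veinal") {
    p <- spec$tissue$mean_gray +
      (p - spec$tissue$mean_gray) * spec$veinal_contrast_scale
  }
  p
}

validate_phantom_spec <- function(spec) {
  if (length(spec$size) != 2L || any(spec$size < 16L)) {
    stop("phantom size must be two values >= 16")
  }
  peak <- effective_peak(spec)
  if (peak <= spec$tissue$mean_gray) {
    stop("hemorrhage peak gray must exceed the soft-tissue mean gray")
  }
  edge <- peak * exp(-spec$hemorrhage$decay)
  a <- spec$artery$gray_range
  if (a[1] > peak || a[2] < edge) {
    stop("artery gray range must overlap the hemorrhage gray range [",
         round(edge), ", ", round(peak), "]")
  }
  if (spec$hemorrhage$decay <= 0) stop("decay must be > 0")
  invisible(spec)
}

ellipse_mask <- function(h, w, center, axes) {
  r <- matrix(seq_len(h), h, w)
  c <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((r - center[1]) / axes[1])^2 + ((c - center[2]) / axes[2])^2 <= 1
}

disk_mask <- function(h, w, center, radius) {
  r <- matrix(seq_len(h), h, w)
  c <- matrix(seq_len(w), h, w, byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

# sample a point uniformly inside the tissue ellipse scaled by `shrink`,
# rejecting points whose `clearance`-disk touches `avoid`
sample_inside <- function(spec, shrink, avoid, clearance, max_tries = 200L) {
  h <- spec$size[1]; w <- spec$size[2]
  ctr <- spec$tissue$center; ax <- spec$tissue$axes * shrink
  for (i in seq_len(max_tries)) {
    u <- runif(1, -1, 1); v <- runif(1, -1, 1)
    if (u^2 + v^2 > 1) next
    p <- c(ctr[1] + u * ax[1], ctr[2] + v * ax[2])
    d <- disk_mask(h, w, p, clearance)
    if (!any(d & avoid)) return(p)
  }
  stop("could not place a phantom structure; spec too crowded")
}

#' Generate a synthetic phantom
#'
#' Structures are painted in order tissue, bone, artery, hemorrhage; the
#' hemorrhage profile is radially monotone non-increasing before noise, and
#' the ground-truth masks are the exact painted supports. Gaussian noise
#' (sd `tissue$noise_sd`) is added to all anatomy pixels and clipped to
#' `[1, gray_depth]`; background pixels stay exactly 0.
#'
#' @param spec `phantom_spec`.
#' @return list with `slice` (`ct_slice`), `truth` (list of `region_mask`:
#'   `bone`, `artery`, `hemorrhage`), `noiseless` (integer matrix before
#'   noise), and `spec`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  h <- spec$size[1]; w <- spec$size[2]
  with_rng(spec$seed, {
    img <- matrix(0, h, w)
    tis <- ellipse_mask(h, w, spec$tissue$center, spec$tissue$axes)
    img[tis] <- spec$tissue$mean_gray

    bone_m <- matrix(FALSE, h, w)
    for (i in seq_len(spec$bone$count)) {
      ctr <- sample_inside(spec, 0.72, bone_m, max(spec$bone$axes_range) + 2)
      ax <- runif(2, spec$bone$axes_range[1], spec$bone$axes_range[2])
      g <- round(runif(1, spec$bone$gray_range[1], spec$bone$gray_range[2]))
      e <- ellipse_mask(h, w, ctr, ax) & tis
      img[e] <- g
      bone_m <- bone_m | e
    }

    art_m <- matrix(FALSE, h, w)
    for (i in seq_len(spec$artery$count)) {
      ctr <- sample_inside(spec, 0.7, bone_m | art_m,
                           spec$artery$radius + 4)
      d <- disk_mask(h, w, ctr, spec$artery$radius) & tis
      # bright lumen center fading linearly to the range low at the dot
      # edge (partial-volume fade), so artery pixels span the whole range
      rr <- matrix(seq_len(h), h, w)
      cc <- matrix(seq_len(w), h, w, byrow = TRUE)
      rad <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2)
      lo <- spec$artery$gray_range[1]; hi <- spec$artery$gray_range[2]
      prof <- hi - (hi - lo) * pmin(rad / spec$artery$radius, 1)
      img[d] <- round(prof[d])
      art_m <- art_m | d
    }

    hem_m <- matrix(FALSE, h, w)
    peak <- effective_peak(spec)
    for (i in seq_len(spec$hemorrhage$count)) {
      R <- spec$hemorrhage$radius
      if (!is.null(spec$hemorrhage$center)) {
        ctr <- spec$hemorrhage$center
        inside <- ((ctr[1] - spec$tissue$center[1]) / spec$tissue$axes[1])^2 +
          ((ctr[2] - spec$tissue$center[2]) / spec$tissue$axes[2])^2 <= 1
        if (!inside) stop("hemorrhage center lies outside the soft-tissue ellipse")
      } else {
        ctr <- sample_inside(spec, 0.55, bone_m | art_m, R + 4)
      }
      d <- disk_mask(h, w, ctr, R)
      rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
      rad2 <- (rr - ctr[1])^2 + (cc - ctr[2])^2
      prof <- peak * exp(-spec$hemorrhage$decay * rad2 / R^2)
      img[d] <- pmax(img[d], prof[d])
      hem_m <- hem_m | d
    }

    if (spec$table_artifact) {
      band <- matrix(FALSE, h, w)
      band[(h - 6L):(h - 4L), ] <- TRUE
      band <- band & !tis
      img[band] <- 200
    }

    noiseless <- matrix(as.integer(round(pmin(img, spec$gray_depth))), h, w)
    anat <- noiseless > 0L
    noisy <- noiseless
    if (spec$tissue$noise_sd > 0) {
      noisy[anat] <- noisy[anat] + rnorm(sum(anat), 0, spec$tissue$noise_sd)
    }
    noisy <- matrix(as.integer(round(pmax(pmin(noisy, spec$gray_depth),
                                          ifelse(anat, 1, 0)))), h, w)

    id <- sprintf("phantom-%d", spec$seed)
    list(
      slice = ct_slice(noisy, gray_depth = spec$gray_depth, id = id),
      truth = list(
        bone = region_mask(bone_m, "bone", id),
        artery = region_mask(art_m, "artery", id),
        hemorrhage = region_mask(hem_m, "ground_truth", id)
      ),
      noiseless = noiseless,
      spec = spec
    )
  })
}
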