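# Initial hemorrhage detection: extract the pelvic region, mask bone and
# arteries to zero so they cannot be mistaken for bleeding, then take the
# remaining pixels whose gray levels fall in the artery range as the
# detected hemorrhage seed C_d. The seed need not be the complete
# hemorrhage; later stages recover the faded boundary.

#' Detection-stage configuration
#'
#' @param bone_threshold gray level above which pixels are bone candidates.
#' @param artery_gray_range length-2 vector `[low, high]`; pixels in this
#'   range (after masking) are hemorrhage candidates. `NULL` means "estimate
#'   from a supplied artery mask at run time".
#' @param min_object_area connected components smaller than this are
#'   discarded as unwanted objects (residual bright specks).
#' @param morph_radius radius of the box brush used for morphological
#'   closing of the bone mask.
#' @return object of class `detection_config`.
#' @export
detection_config <- function(bone_threshold = 232L,
                             artery_gray_range = NULL,
                             min_object_area = 20L,
                             morph_radius = 1L) {
  if (bone_threshold <= 0) stop("bone_threshold must be positive")
  if (!is.null(artery_gray_range)) {
    if (length(artery_gray_range) != 2L ||
        artery_gray_range[1] > artery_gray_range[2]) {
      stop("artery_gray_range must be [low, high] with low <= high")
    }
  }
  structure(list(bone_threshold = bone_threshold,
                 artery_gray_range = artery_gray_range,
                 min_object_area = as.integer(min_object_area),
                 morph_radius = as.integer(morph_radius)),
            class = "detection_config")
}

box_brush <- function(radius) {
  EBImage::makeBrush(2L * radius + 1L, shape = "box")
}

#' Remove scanner artifacts, keeping the pelvic region
#'
#' Keeps only the largest 8-connected non-zero component (the body) and
#' zeroes everything else — tables, cables, and detached bright bands.
#'
#' @param slice `ct_slice`.
#' @return artifact-free `ct_slice`.
#' @export
remove_artifacts <- function(slice) {
  nz <- slice$pixels > 0L
  if (!any(nz)) stop("image is entirely background; nothing to segment")
  lab <- label_components(nz)
  areas <- component_areas(lab)
  keep <- which.max(areas)
  px <- slice$pixels
  px[lab != keep] <- 0L
  ct_slice(px, gray_depth = slice$gray_depth, spacing = slice$spacing,
           id = slice$id)
}

#' Segment bone by thresholding and mask it to zero
#'
#' Bone candidates are pixels above `bone_threshold`; the candidate mask is
#' morphologically closed and components below `min_object_area` are
#' dropped. The surviving bone pixels are set to gray 0 in the returned
#' slice so they cannot enter the hemorrhage search.
#'
#' @param slice artifact-removed `ct_slice`.
#' @param cfg `detection_config`.
#' @return list with `bone` (`region_mask`) and `masked` (`ct_slice`).
#' @export
segment_and_mask_bone <- function(slice, cfg = detection_config()) {
  if (cfg$bone_threshold > slice$gray_depth) {
    stop("bone_threshold exceeds the slice gray depth")
  }
  cand <- slice$pixels >= cfg$bone_threshold
  if (any(cand)) {
    closed <- EBImage::closing(cand * 1L, box_brush(cfg$morph_radius)) > 0
    lab <- label_components(closed)
    areas <- component_areas(lab)
    keep <- which(areas >= cfg$min_object_area)
    bone <- matrix(lab %in% keep, nrow(lab), ncol(lab))
  } else {
    bone <- cand
  }
  px <- slice$pixels
  px[bone] <- 0L
  list(bone = region_mask(bone, "bone", slice$id),
       masked = ct_slice(px, gray_depth = slice$gray_depth,
                         spacing = slice$spacing, id = slice$id))
}

#' Mask artery pixels to zero
#'
#' Arteries carry the same contrast-enhanced gray levels as active bleeding
#' and must be removed before the gray-range search, or they would be
#' detected as false hemorrhage.
#'
#' @param slice `ct_slice`.
#' @param arteries `region_mask` of artery pixels (from configuration ROIs
#'   or phantom ground truth).
#' @return `ct_slice` with artery pixels at gray 0.
#' @export
mask_arteries <- function(slice, arteries) {
  m <- as_mask_matrix(arteries)
  if (!identical(dim(m), dim(slice$pixels))) {
    stop("artery mask dimensions do not match the slice")
  }
  px <- slice$pixels
  px[m] <- 0L
  ct_slice(px, gray_depth = slice$gray_depth, spacing = slice$spacing,
           id = slice$id)
}

#' Estimate the artery gray-level range from an artery mask
#'
#' The plain min/max over the artery pixels of the (un-masked) slice.
#'
#' @param slice `ct_slice` before artery masking.
#' @param arteries `region_mask`.
#' @return integer vector `c(low, high)`.
#' @export
estimate_gray_range <- function(slice, arteries) {
  m <- as_mask_matrix(arteries)
  g <- slice$pixels[m]
  g <- g[g > 0L]
  if (!length(g)) stop("artery mask covers no non-background pixels")
  c(min(g), max(g))
}

#' Detect the hemorrhage seed C_d
#'
#' On the bone- and artery-masked slice, pixels whose gray level falls in
#' the artery range are hemorrhage candidates; connected candidate
#' components smaller than `min_object_area` are removed as unwanted
#' objects. The remaining pixels form the detected hemorrhage `C_d`, whose
#' area centroid and observed gray range `[g_min, g_max]` seed the
#' matching stage.
#'
#' @param masked `ct_slice` with bone and arteries already at gray 0.
#' @param cfg `detection_config` with a non-NULL `artery_gray_range`.
#' @return `hemorrhage_seed`; `found = FALSE` if no pixel qualifies.
#' @export
detect_hemorrhage <- function(masked, cfg) {
  rng <- cfg$artery_gray_range
  if (is.null(rng)) stop("detect_hemorrhage needs cfg$artery_gray_range")
  cand <- masked$pixels >= rng[1] & masked$pixels <= rng[2] &
    masked$pixels > 0L
  if (any(cand)) {
    lab <- label_components(cand)
    areas <- component_areas(lab)
    keep <- which(areas >= cfg$min_object_area)
    cand <- matrix(lab %in% keep, nrow(lab), ncol(lab))
  }
  if (!any(cand)) return(no_hemorrhage())
  hemorrhage_seed(region_mask(cand, "detected_hemorrhage", masked$id), masked)
}
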