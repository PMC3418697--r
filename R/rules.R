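# Three-case heuristic rule engine. Around every boundary pixel of the
# MIM region B_opt an m x m window is classified by its gray-level census
# against G_opt:
#   Case 1 - every window pixel >= G_opt: all in-range pixels join R.
#   Case 2 - a majority (>50%, not all) >= G_opt: a pixel joins R when
#            w1*gray + w2*D + b > 0 (D = distance to the hemorrhage foci).
#   Case 3 - a majority < G_opt: the rule adds the gray-variation and
#            gradient-magnitude features, w3*gray + w4*D + w5*V +
#            w6*|grad f| + b1 > 0, making recruitment more restrictive.
# Weights come from the per-image SVM optimization (svm module).

#' Locate the hemorrhage foci
#'
#' The foci is the maximum-gray pixel of the region; ties are broken by
#' row-major order (first occurrence).
#'
#' @param region non-empty `region_mask`.
#' @param slice `ct_slice`.
#' @return integer `c(row, col)`.
#' @export
locate_foci <- function(region, slice) {
  m <- as_mask_matrix(region)
  if (!any(m)) stop("cannot locate the foci of an empty region")
  idx <- which(m, arr.ind = TRUE)
  g <- slice$pixels[idx]
  cand <- idx[g == max(g), , drop = FALSE]
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  c(row = cand[1, 1], col = cand[1, 2])
}

#' Classify a rule window against G_opt
#'
#' @param window numeric matrix or vector of window gray levels (clipped
#'   windows at the image edge pass only their present pixels).
#' @param g_opt optimum minimum hemorrhage gray level.
#' @return integer case label: 1 (all `>= g_opt`), 2 (majority but not
#'   all), or 3 (at least half below `g_opt`).
#' @export
classify_window <- function(window, g_opt) {
  v <- as.vector(window)
  if (!length(v)) stop("empty window")
  ge <- v >= g_opt
  if (all(ge)) return(1L)
  if (mean(ge) > 0.5) return(2L)
  3L
}

#' Gradient magnitude image
#'
#' Central differences in both axes (one-sided at the image edges),
#' combined as the Euclidean norm.
#'
#' @param slice `ct_slice` or numeric matrix.
#' @return numeric matrix of `|grad f|` values.
#' @export
gradient_magnitude <- function(slice) {
  f <- if (inherits(slice, "ct_slice")) slice$pixels else slice
  f <- matrix(as.numeric(f), nrow(f), ncol(f))
  h <- nrow(f); w <- ncol(f)
  dr <- f
  if (h > 1L) {
    dr[2:(h - 1), ] <- (f[3:h, , drop = FALSE] - f[1:(h - 2), , drop = FALSE]) / 2
    dr[1, ] <- f[2, ] - f[1, ]
    dr[h, ] <- f[h, ] - f[h - 1, ]
  } else dr[] <- 0
  dc <- f
  if (w > 1L) {
    dc[, 2:(w - 1)] <- (f[, 3:w, drop = FALSE] - f[, 1:(w - 2), drop = FALSE]) / 2
    dc[, 1] <- f[, 2] - f[, 1]
    dc[, w] <- f[, w] - f[, w - 1]
  } else dc[] <- 0
  sqrt(dr^2 + dc^2)
}

#' Per-pixel rule features
#'
#' For a pixel inside a window centered at a boundary pixel: its gray
#' level, Euclidean distance `D` to the hemorrhage foci, gray variation
#' `V` (window-center gray minus pixel gray), and gradient magnitude.
#'
#' @param pixel integer `c(row, col)` of the pixel.
#' @param center integer `c(row, col)` of the window center (a boundary
#'   pixel).
#' @param foci integer `c(row, col)` of the hemorrhage foci.
#' @param slice `ct_slice`.
#' @param grad optional precomputed [gradient_magnitude()] matrix.
#' @return named numeric vector `gray`, `dist`, `var`, `grad`.
#' @export
pixel_features <- function(pixel, center, foci, slice, grad = NULL) {
  if (is.null(grad)) grad <- gradient_magnitude(slice)
  g <- slice$pixels[pixel[1], pixel[2]]
  c(gray = as.numeric(g),
    dist = sqrt(sum((as.numeric(foci) - as.numeric(pixel))^2)),
    var = as.numeric(slice$pixels[center[1], center[2]]) - as.numeric(g),
    grad = grad[pixel[1], pixel[2]])
}

window_range <- function(r, c, half, h, w) {
  list(rows = max(1L, r - half):min(h, r + half),
       cols = max(1L, c - half):min(w, c + half))
}

#' Expand the MIM region with the optimized case rules
#'
#' One pass over the boundary of `b_opt`: each boundary pixel's m x m
#' window is classified and its case rule is evaluated on every window
#' pixel; pixels passing in any window are unioned into the region
#' (rules only ever add, so the result always contains `b_opt`).
#' Background (gray-0, i.e. masked) pixels are never recruited.
#'
#' @param b_opt `region_mask` from [mim_search()].
#' @param slice masked `ct_slice`.
#' @param g_opt,g_max working hemorrhage gray range (from the MIM stage
#'   and the seed).
#' @param weights `rule_weights` from [optimize_rule_weights()].
#' @param m odd window side (default 3).
#' @return `region_mask` of the expanded region `R`.
#' @export
apply_rules <- function(b_opt, slice, g_opt, g_max, weights, m = 3L) {
  if (m %% 2L == 0L) stop("rule window size m must be odd")
  bm <- as_mask_matrix(b_opt)
  if (!any(bm)) stop("cannot apply rules to an empty region")
  half <- m %/% 2L
  h <- slice$height; w <- slice$width
  tb <- extract_boundary(bm)
  foci <- locate_foci(b_opt, slice)
  grad <- gradient_magnitude(slice)
  px <- slice$pixels
  add <- matrix(FALSE, h, w)
  w2 <- weights$case2; w3 <- weights$case3
  for (k in seq_len(nrow(tb))) {
    r <- tb[k, 1]; c <- tb[k, 2]
    win <- window_range(r, c, half, h, w)
    grays <- px[win$rows, win$cols, drop = FALSE]
    cs <- classify_window(grays, g_opt)
    rr <- matrix(win$rows, length(win$rows), length(win$cols))
    cc <- matrix(win$cols, length(win$rows), length(win$cols), byrow = TRUE)
    if (cs == 1L) {
      pass <- grays >= g_opt & grays <= g_max
    } else {
      d <- sqrt((rr - foci[1])^2 + (cc - foci[2])^2)
      if (cs == 2L) {
        pass <- w2[1] * grays + w2[2] * d + w2[3] > 0
      } else {
        v <- as.numeric(px[r, c]) - grays
        gm <- grad[win$rows, win$cols, drop = FALSE]
        pass <- w3[1] * grays + w3[2] * d + w3[3] * v + w3[4] * gm + w3[5] > 0
      }
      pass <- pass & grays > 0L
    }
    if (any(pass)) add[cbind(rr[pass], cc[pass])] <- TRUE
  }
  region_mask(bm | add, "segmented_hemorrhage", slice$id)
}
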