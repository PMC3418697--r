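# Soft-margin linear SVM trained in the dual:
#   maximize  L_d(a) = sum_i a_i - 1/2 sum_ij y_i y_j a_i a_j <x_i, x_j>
#   subject to  sum_i y_i a_i = 0,  0 <= a_i <= C.
# Solved by pairwise coordinate ascent on a maximal-KKT-violating pair
# (working set of two, which preserves the equality constraint exactly).
# The hyperplane w0 = sum a_i y_i x_i is read off the support vectors and
# the bias b0 is averaged over the free support vectors (0 < a_i < C).
# Per-image penalty C is selected by stratified 10-fold cross-validation
# over the grid {0.1, 0.01, 0.001}.

#' SVM training configuration
#'
#' @param band_width width in pixels of the sampling bands inside/outside
#'   the region boundary.
#' @param cap maximum number of training pixels per class.
#' @param penalty_grid candidate soft-margin penalties `C`.
#' @param folds cross-validation fold count (lowered automatically when a
#'   class has fewer rows than folds).
#' @param seed RNG seed for band sampling and fold assignment.
#' @return object of class `svm_config`.
#' @export
svm_config <- function(band_width = 2L, cap = 100L,
                       penalty_grid = c(0.1, 0.01, 0.001), folds = 10L,
                       seed = 0L) {
  if (any(penalty_grid <= 0)) stop("penalties must be > 0")
  structure(list(band_width = as.integer(band_width), cap = as.integer(cap),
                 penalty_grid = penalty_grid, folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "svm_config")
}

#' Solve the soft-margin SVM dual
#'
#' Maximizes `sum(a) - 0.5 a' H a` with `H_ij = y_i y_j x_i . x_j` subject
#' to `y'a = 0`, `0 <= a <= C`, by coordinate ascent on the maximal
#' KKT-violating pair. When no free support vector exists the bias falls
#' back to the midpoint between the innermost decision values of the two
#' classes, and the solution is flagged.
#'
#' @param x numeric feature matrix (rows = training points).
#' @param y labels in `{-1, +1}`.
#' @param c_penalty box constraint `C > 0`.
#' @param tol KKT stopping tolerance on the maximal violating pair.
#' @param max_iter iteration safeguard.
#' @return object of class `svm_dual`: `alphas`, `w0`, `b0`, `n_sv`,
#'   `n_fsv`, `objective` (dual value), `iterations`, `converged`,
#'   `kkt_gap`, `c_penalty`, `bias_fallback`.
#' @export
solve_svm_dual <- function(x, y, c_penalty, tol = 1e-6, max_iter = 100000L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (length(y) != n) stop("length(y) must match nrow(x)")
  if (!all(y %in% c(-1, 1))) stop("labels must be -1 or +1")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (c_penalty <= 0) stop("C must be > 0")
  K <- tcrossprod(x)
  alpha <- numeric(n)
  grad <- rep(-1, n)  # gradient of the minimized form 1/2 a'Qa - 1'a
  it <- 0L
  gap <- Inf
  eps_a <- 1e-12 * max(1, c_penalty)
  repeat {
    up <- (y > 0 & alpha < c_penalty - eps_a) | (y < 0 & alpha > eps_a)
    lo <- (y < 0 & alpha < c_penalty - eps_a) | (y > 0 & alpha > eps_a)
    yg <- -y * grad
    m_up <- if (any(up)) max(yg[up]) else -Inf
    m_lo <- if (any(lo)) min(yg[lo]) else Inf
    gap <- m_up - m_lo
    if (gap < tol || it >= max_iter) break
    i <- which(up)[which.max(yg[up])]
    j <- which(lo)[which.min(yg[lo])]
    quad <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (quad <= 1e-12) quad <- 1e-12
    # feasible direction: da_i = +y_i t, da_j = -y_j t keeps y'a constant
    t_step <- min((yg[i] - yg[j]) / quad,
                  if (y[i] > 0) c_penalty - alpha[i] else alpha[i],
                  if (y[j] > 0) alpha[j] else c_penalty - alpha[j])
    alpha[i] <- alpha[i] + y[i] * t_step
    alpha[j] <- alpha[j] - y[j] * t_step
    grad <- grad + t_step * y * (K[, i] - K[, j])
    it <- it + 1L
  }
  alpha <- pmin(pmax(alpha, 0), c_penalty)
  sv_tol <- 1e-8 + 1e-6 * c_penalty
  sv <- alpha > sv_tol
  fsv <- alpha > sv_tol & alpha < c_penalty - sv_tol
  w0 <- drop(crossprod(x, alpha * y))
  dec_raw <- drop(x %*% w0)
  bias_fallback <- FALSE
  if (any(fsv)) {
    b0 <- mean(y[fsv] - dec_raw[fsv])
  } else {
    pos_min <- min(dec_raw[y > 0])
    neg_max <- max(dec_raw[y < 0])
    b0 <- -(pos_min + neg_max) / 2
    bias_fallback <- TRUE
  }
  obj <- sum(alpha) - 0.5 * drop(crossprod(alpha * y, K %*% (alpha * y)))
  structure(list(alphas = alpha, w0 = w0, b0 = b0,
                 n_sv = sum(sv), n_fsv = sum(fsv),
                 objective = obj, iterations = it,
                 converged = gap < tol, kkt_gap = gap,
                 c_penalty = c_penalty, bias_fallback = bias_fallback),
            class = "svm_dual")
}

#' @export
print.svm_dual <- function(x, ...) {
  cat(sprintf(
    "<svm_dual: C = %g, %d SV (%d free), objective %.6g, KKT gap %.2g>\n",
    x$c_penalty, x$n_sv, x$n_fsv, x$objective, x$kkt_gap))
  invisible(x)
}

#' Classify a feature row with a trained machine
#'
#' Sign of the linear decision value `w0 . x + b0`; an exactly-zero
#' decision value resolves to `+1`.
#'
#' @param x numeric feature vector or matrix of rows.
#' @param sol `svm_dual`.
#' @return `+1`/`-1` per row.
#' @export
svm_decide <- function(x, sol) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != length(sol$w0)) {
    stop("feature dimension (", ncol(x), ") does not match the machine (",
         length(sol$w0), ")")
  }
  d <- drop(x %*% sol$w0) + sol$b0
  ifelse(d >= 0, 1, -1)
}

stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Select the soft-margin penalty by cross-validation
#'
#' Stratified k-fold cross-validated classification accuracy for every
#' grid value; ties resolve to the larger `C` (fewer training
#' misclassifications, narrower margin). The fold count drops to the
#' smaller class size when a class has fewer rows than `folds`.
#'
#' @param x feature matrix.
#' @param y labels in `{-1, +1}`.
#' @param grid candidate penalties.
#' @param folds requested fold count.
#' @param seed RNG seed for fold assignment.
#' @return list: `best_c`, `best_accuracy`, `accuracy` (named per grid
#'   value), `folds_used`.
#' @export
select_penalty <- function(x, y, grid = c(0.1, 0.01, 0.001), folds = 10L,
                           seed = 0L) {
  x <- as.matrix(x)
  n_min <- min(table(y))
  k <- max(2L, min(as.integer(folds), n_min))
  acc <- with_rng(seed, {
    assign <- stratified_folds(y, k)
    vapply(grid, function(cc) {
      correct <- 0L
      for (f in seq_len(k)) {
        tr <- assign != f; te <- !tr
        if (length(unique(y[tr])) < 2L) { # degenerate fold; re-stratify
          tr <- rep(TRUE, length(y)); te <- assign == f
        }
        sol <- solve_svm_dual(x[tr, , drop = FALSE], y[tr], cc)
        correct <- correct + sum(svm_decide(x[te, , drop = FALSE], sol) ==
                                   y[te])
      }
      correct / length(y)
    }, numeric(1))
  })
  names(acc) <- as.character(grid)
  best <- grid[acc >= max(acc) - 1e-12]
  best_c <- max(best)
  list(best_c = best_c, best_accuracy = max(acc), accuracy = acc,
       folds_used = k)
}

erode_mask <- function(m, radius) {
  if (radius <= 0L) return(m)
  EBImage::erode(m * 1L, box_brush(radius)) > 0
}

dilate_mask <- function(m, radius) {
  if (radius <= 0L) return(m)
  EBImage::dilate(m * 1L, box_brush(radius)) > 0
}

#' Sample boundary-band training pixels
#'
#' Hemorrhage-class pixels come from a band of `band_width` px just inside
#' the boundary of `b_opt`; soft-tissue pixels from the band just outside.
#' Masked (gray-0) pixels are excluded, both classes are capped to equal
#' size, and the sample is deterministic under `seed`.
#'
#' @param b_opt `region_mask` whose boundary defines the bands.
#' @param slice masked `ct_slice`.
#' @param cfg `svm_config`.
#' @return object of class `svm_training_set`: `coords` (n x 2), `y`
#'   labels, `provenance` factor (inside/outside).
#' @export
sample_training_data <- function(b_opt, slice, cfg = svm_config()) {
  bm <- as_mask_matrix(b_opt)
  if (!any(bm)) stop("cannot sample around an empty region")
  inner <- bm & !erode_mask(bm, cfg$band_width)
  outer <- dilate_mask(bm, cfg$band_width) & !bm
  outer <- outer & slice$pixels > 0L
  inner <- inner & slice$pixels > 0L
  if (!any(inner) || !any(outer)) {
    stop("training bands are empty on one side of the boundary; ",
         "the region may touch the image edge or masked background ",
         "everywhere - widen band_width or check the masking")
  }
  pos <- which(inner, arr.ind = TRUE)
  neg <- which(outer, arr.ind = TRUE)
  n <- min(nrow(pos), nrow(neg), cfg$cap)
  with_rng(cfg$seed, {
    pos <- pos[sample(nrow(pos), n), , drop = FALSE]
    neg <- neg[sample(nrow(neg), n), , drop = FALSE]
  })
  structure(list(
    coords = rbind(pos, neg),
    y = c(rep(1, n), rep(-1, n)),
    provenance = factor(rep(c("inside", "outside"), each = n))),
    class = "svm_training_set")
}

# rule features for arbitrary pixels: V is taken relative to the nearest
# boundary pixel (the training-time analog of the window center)
training_features <- function(coords, slice, foci, t_opt, grad) {
  g <- as.numeric(slice$pixels[coords])
  d <- sqrt((coords[, 1] - foci[1])^2 + (coords[, 2] - foci[2])^2)
  d2 <- outer(coords[, 1], t_opt[, 1], "-")^2 +
    outer(coords[, 2], t_opt[, 2], "-")^2
  nearest <- t_opt[max.col(-d2, ties.method = "first"), , drop = FALSE]
  v <- as.numeric(slice$pixels[nearest]) - g
  cbind(gray = g, dist = d, var = v, grad = grad[coords])
}

standardize <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  list(x = sweep(sweep(x, 2, mu), 2, sdv, "/"), mu = mu, sd = sdv)
}

# map a standardized-space hyperplane back to raw feature space
unstandardize_weights <- function(w_std, b_std, mu, sdv) {
  w_raw <- w_std / sdv
  list(w = w_raw, b = b_std - sum(w_std * mu / sdv))
}

train_case <- function(feat, y, cfg) {
  st <- standardize(feat)
  cv <- select_penalty(st$x, y, grid = cfg$penalty_grid, folds = cfg$folds,
                       seed = cfg$seed)
  sol <- solve_svm_dual(st$x, y, cv$best_c)
  raw <- unstandardize_weights(sol$w0, sol$b0, st$mu, st$sd)
  train_acc <- mean(svm_decide(st$x, sol) == y)
  list(weights = c(raw$w, bias = raw$b), penalty_c = cv$best_c,
       cv_accuracy = cv$best_accuracy, train_accuracy = train_acc,
       folds_used = cv$folds_used, bias_fallback = sol$bias_fallback,
       n_sv = sol$n_sv, n_fsv = sol$n_fsv)
}

#' Optimize the case rule weights for one image
#'
#' Samples the boundary bands once, then trains the 2-feature machine
#' (gray, distance-to-foci) for Case 2 and the 4-feature machine (gray,
#' distance, gray variation, gradient magnitude) for Case 3 on the same
#' pixels, each with its own cross-validated penalty. Features are
#' standardized for the solve and the hyperplanes mapped back to raw
#' feature space, so the returned weights plug directly into the case
#' rules.
#'
#' @param slice masked `ct_slice`.
#' @param b_opt `region_mask` from the MIM stage.
#' @param cfg `svm_config`.
#' @return object of class `rule_weights`: `case2` (w1, w2, b), `case3`
#'   (w3..w6, b1), per-case penalty, CV/train accuracy and solver
#'   diagnostics, and the sample size used.
#' @export
optimize_rule_weights <- function(slice, b_opt, cfg = svm_config()) {
  ts <- sample_training_data(b_opt, slice, cfg)
  t_opt <- extract_boundary(b_opt)
  foci <- locate_foci(b_opt, slice)
  grad <- gradient_magnitude(slice)
  feat <- training_features(ts$coords, slice, foci, t_opt, grad)
  case2 <- train_case(feat[, c("gray", "dist")], ts$y, cfg)
  case3 <- train_case(feat, ts$y, cfg)
  structure(list(
    case2 = unname(case2$weights), case3 = unname(case3$weights),
    penalty_c2 = case2$penalty_c, penalty_c3 = case3$penalty_c,
    cv_accuracy = c(case2 = case2$cv_accuracy, case3 = case3$cv_accuracy),
    train_accuracy = c(case2 = case2$train_accuracy,
                       case3 = case3$train_accuracy),
    bias_fallback = c(case2 = case2$bias_fallback,
                      case3 = case3$bias_fallback),
    n_per_class = sum(ts$y > 0), seed = cfg$seed),
    class = "rule_weights")
}

#' @export
print.rule_weights <- function(x, ...) {
  cat(sprintf(
    "<rule_weights: case2 (%.4g, %.4g, b=%.4g) C=%g; case3 C=%g; n=%d/class>\n",
    x$case2[1], x$case2[2], x$case2[3], x$penalty_c2, x$penalty_c3,
    x$n_per_class))
  invisible(x)
}
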