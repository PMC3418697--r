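# Independent brute-force oracles used to freeze expected values. Each is
# a direct, unoptimized restatement of the definition it checks, kept free
# of the package's own code paths.

# gray matrix -> ct_slice with background zeros allowed
mk_slice <- function(m, depth = 255L, id = "test") {
  ct_slice(matrix(as.integer(m), nrow(m), ncol(m)), gray_depth = depth,
           id = id)
}

mk_mask <- function(m, label = "generic", id = "test") {
  region_mask(matrix(as.logical(m), nrow(m), ncol(m)), label = label,
              slice_id = id)
}

# filled rectangle mask inside an h x w grid
rect_mask <- function(h, w, r1, r2, c1, c2, id = "test") {
  m <- matrix(FALSE, h, w)
  m[r1:r2, c1:c2] <- TRUE
  mk_mask(m, id = id)
}

# oracle: boundary by checking each member's 4-neighborhood one pixel at a
# time
oracle_boundary <- function(m) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
    if (!m[r, c]) next
    nb <- c(
      if (r > 1) m[r - 1, c] else FALSE,
      if (r < nrow(m)) m[r + 1, c] else FALSE,
      if (c > 1) m[r, c - 1] else FALSE,
      if (c < ncol(m)) m[r, c + 1] else FALSE)
    if (!all(nb)) out[r, c] <- TRUE
  }
  out
}

# oracle: Shannon entropy straight from the definition
oracle_entropy <- function(v) {
  p <- as.vector(table(v)) / length(v)
  -sum(p * log2(p))
}

# oracle: MI from the joint histogram, independent of img_entropy
oracle_mi <- function(a, b) {
  ja <- as.vector(a); jb <- as.vector(b)
  pj <- table(ja, jb) / length(ja)
  pa <- rowSums(pj); pb <- colSums(pj)
  s <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb)) {
    if (pj[i, j] > 0) s <- s + pj[i, j] * log2(pj[i, j] / (pa[i] * pb[j]))
  }
  as.numeric(s)
}

# oracle: exact soft-margin SVM dual optimum by KKT active-set enumeration.
# Every point is assigned to {zero, box, free}; the free block solves the
# stationarity system with the equality constraint; KKT feasibility is
# checked and the best feasible objective returned. Exact for n <= ~8.
oracle_svm_dual <- function(x, y, C) {
  x <- as.matrix(x); n <- nrow(x)
  K <- tcrossprod(x)
  H <- (y %o% y) * K
  obj <- function(a) sum(a) - 0.5 * drop(t(a) %*% H %*% a)
  best <- list(obj = -Inf, alpha = NULL)
  states <- expand.grid(rep(list(0:2), n))  # 0 zero, 1 box, 2 free
  for (k in seq_len(nrow(states))) {
    st <- as.integer(states[k, ])
    a <- numeric(n)
    a[st == 1L] <- C
    fr <- which(st == 2L)
    if (length(fr)) {
      # stationarity for free set: H_ff a_f + lam y_f = 1 - H_fb C
      rhs <- rep(1, length(fr)) - if (any(st == 1L)) {
        rowSums(H[fr, st == 1L, drop = FALSE]) * C
      } else rep(0, length(fr))
      A <- rbind(cbind(H[fr, fr, drop = FALSE], y[fr]),
                 c(y[fr], 0))
      b <- c(rhs, -C * sum(y[st == 1L]))
      sol <- tryCatch(solve(A, b), error = function(e) NULL)
      if (is.null(sol)) next
      af <- sol[seq_along(fr)]; lam <- sol[length(sol)]
      if (any(af < -1e-9) || any(af > C + 1e-9)) next
      a[fr] <- pmin(pmax(af, 0), C)
    } else {
      if (abs(sum(y * a)) > 1e-9) next
      # lam must satisfy sign conditions; pick any feasible lam via bounds
      g <- 1 - drop(H %*% a)
      lo <- suppressWarnings(max((g / y)[st == 0L & y > 0 | st == 1L & y < 0],
                                 -Inf))
      hi <- suppressWarnings(min((g / y)[st == 0L & y < 0 | st == 1L & y > 0],
                                 Inf))
      if (lo > hi + 1e-9) next
      lam <- max(min(0, hi), lo)
    }
    if (abs(sum(y * a)) > 1e-8) next
    g <- 1 - drop(H %*% a)  # dual gradient; stationarity: g_i = lam*y_i
    zi <- st == 0L; bi <- st == 1L
    # zero: increasing a_i must not improve => g_i - lam*y_i <= 0
    # box:  decreasing must not improve     => g_i - lam*y_i >= 0
    if (length(fr)) lam <- lam  # from the solve
    if (any(zi) && any(g[zi] - lam * y[zi] > 1e-7)) next
    if (any(bi) && any(g[bi] - lam * y[bi] < -1e-7)) next
    o <- obj(a)
    if (o > best$obj) best <- list(obj = o, alpha = a)
  }
  best
}

# oracle: missegmented area via explicit coordinate-set enumeration
oracle_misseg <- function(a1, a2) {
  c1 <- which(a1, arr.ind = TRUE); c2 <- which(a2, arr.ind = TRUE)
  k1 <- paste(c1[, 1], c1[, 2]); k2 <- paste(c2[, 1], c2[, 2])
  K <- union(setdiff(k1, k2), setdiff(k2, k1))
  length(K) / length(k1) * 100
}

# small, fast phantom for unit tests
small_phantom_spec <- function(seed = 1, ...) {
  phantom_spec(size = c(96L, 96L), seed = seed,
               tissue = list(axes = c(42, 36)),
               bone = list(count = 1L, axes_range = c(4, 7)),
               artery = list(count = 2L),
               hemorrhage = list(radius = 8), ...)
}

small_config <- function(seed = 0L) {
  pipeline_config(mim = mim_config(roi_size = 60L), seed = seed)
}
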