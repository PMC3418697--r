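test_that("foci location takes the maximum-gray pixel, row-major on ties", {
  px <- matrix(10L, 6, 6)
  px[3, 4] <- 90L
  s <- mk_slice(px)
  expect_equal(unname(locate_foci(rect_mask(6, 6, 2, 5, 2, 5), s)), c(3, 4))
  # single-pixel region
  one <- mk_mask(matrix(seq_len(36) == 9, 6, 6))  # pixel (3, 2)
  expect_equal(unname(locate_foci(one, s)), c(3, 2))
  # two equal maxima -> lexicographically first
  px2 <- matrix(10L, 6, 6); px2[4, 2] <- 90L; px2[2, 5] <- 90L
  expect_equal(unname(locate_foci(rect_mask(6, 6, 1, 6, 1, 6),
                                  mk_slice(px2))), c(2, 5))
  expect_error(locate_foci(mk_mask(matrix(FALSE, 6, 6)), s), "empty")
})

test_that("window classification follows the gray-level census", {
  expect_equal(classify_window(matrix(120L, 3, 3), 100L), 1L)
  w <- matrix(c(rep(120L, 5), rep(80L, 4)), 3, 3)
  expect_equal(classify_window(w, 100L), 2L)  # 5 of 9 above, not all
  w2 <- matrix(c(rep(120L, 4), rep(80L, 5)), 3, 3)
  expect_equal(classify_window(w2, 100L), 3L)  # majority below
})

test_that("pixel features realize distance, variation, and gradient", {
  px <- matrix(50L, 8, 8); px[4, 5] <- 30L
  s <- mk_slice(px)
  f <- pixel_features(c(4, 5), center = c(4, 4), foci = c(1, 1), slice = s)
  expect_equal(unname(f["dist"]), 5)  # 3-4-5 triangle
  expect_equal(unname(f["var"]), 50 - 30)
  f0 <- pixel_features(c(4, 4), center = c(4, 4), foci = c(1, 1), slice = s)
  expect_equal(unname(f0["var"]), 0)
  # column ramp of slope 1: central differences give |grad| = 1 inside
  ramp <- mk_slice(matrix(rep(1:10, each = 10), 10, 10, byrow = FALSE))
  gm <- gradient_magnitude(ramp)
  expect_true(all(abs(gm[2:9, 2:9] - 1) < 1e-12))
})

# fixture: square region of bright pixels on a dark background with a
# case-2 fringe engineered around its lower-right corner
rule_fixture <- function() {
  px <- matrix(10L, 8, 8)
  px[2:5, 2:5] <- 120L
  px[2, 2] <- 130L          # unique foci
  px[4, 6] <- 115L          # fringe pixel, majority-maker
  px[5, 6] <- 100L          # target pixel at D = 5 from the foci
  s <- mk_slice(px)
  b_opt <- region_mask(px >= 120L, "segmented_hemorrhage", s$id)
  list(slice = s, b_opt = b_opt)
}

test_that("case rules add pixels by direct substitution into the hyperplane", {
  fx <- rule_fixture()
  weights <- list(case2 = c(1, -0.1, -99), case3 = c(0, 0, 0, 0, -1))
  r <- apply_rules(fx$b_opt, fx$slice, g_opt = 110L, g_max = 130L,
                   weights = weights, m = 3L)
  # target pixel: gray 100 at D = 5 -> 100 - 0.5 - 99 = 0.5 > 0, added
  expect_true(r$mask[5, 6])
  # background pixels fail the same rule: 10 - 0.1 D - 99 < 0
  expect_false(any(r$mask & fx$slice$pixels == 10L))
  # rules only add
  expect_true(all(r$mask[fx$b_opt$mask]))
  expect_error(apply_rules(fx$b_opt, fx$slice, 110L, 130L, weights, m = 4L),
               "odd")
})

test_that("a window fully in range joins the region via Case 1", {
  px <- matrix(0L, 7, 7)
  px[2:6, 2:6] <- 150L
  s <- mk_slice(px)
  b_opt <- rect_mask(7, 7, 3, 5, 3, 5, id = s$id)  # interior 3x3 of plateau
  weights <- list(case2 = c(0, 0, -1), case3 = c(0, 0, 0, 0, -1))
  r <- apply_rules(b_opt, s, g_opt = 140L, g_max = 160L, weights, m = 3L)
  # every boundary window lies wholly in [G_opt, G_max]: the full ring of
  # window pixels joins R
  expect_true(all(r$mask[2:6, 2:6]))
  expect_false(any(r$mask[1, ]))
})

# independent re-evaluation of the whole rule pass, straight from the
# definitions (fresh loops, no shared helpers)
oracle_rules <- function(b_opt, px, g_opt, g_max, w2, w3, grad) {
  m <- b_opt
  h <- nrow(px); w <- ncol(px)
  fidx <- which(px == max(px[b_opt]) & b_opt, arr.ind = TRUE)
  fidx <- fidx[order(fidx[, 1], fidx[, 2]), , drop = FALSE][1, ]
  add <- matrix(FALSE, h, w)
  for (r in 1:h) for (c in 1:w) {
    if (!b_opt[r, c]) next
    nb_all <- TRUE
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      inside <- rr >= 1 && rr <= h && cc >= 1 && cc <= w
      if (!inside || !b_opt[rr, cc]) nb_all <- FALSE
    }
    if (nb_all) next  # not a boundary pixel
    rows <- max(1, r - 1):min(h, r + 1); cols <- max(1, c - 1):min(w, c + 1)
    vals <- px[rows, cols]
    cs <- if (all(vals >= g_opt)) 1 else if (mean(vals >= g_opt) > 0.5) 2 else 3
    for (rr in rows) for (cc in cols) {
      g <- px[rr, cc]
      if (cs == 1) { if (g >= g_opt && g <= g_max) add[rr, cc] <- TRUE; next }
      if (g <= 0) next
      D <- sqrt((fidx[1] - rr)^2 + (fidx[2] - cc)^2)
      ok <- if (cs == 2) w2[1] * g + w2[2] * D + w2[3] > 0 else
        w3[1] * g + w3[2] * D + w3[3] * (px[r, c] - g) + w3[4] * grad[rr, cc] +
        w3[5] > 0
      if (ok) add[rr, cc] <- TRUE
    }
  }
  m | add
}

test_that("apply_rules matches per-pixel re-evaluation with learned weights", {
  set.seed(51)
  px <- matrix(10L, 14, 14)
  px[4:10, 4:10] <- sample(95:140, 49, TRUE)
  px[7, 7] <- 150L
  s <- mk_slice(px)
  b_opt <- region_mask(px >= 110L, "segmented_hemorrhage", s$id)
  w <- list(case2 = c(0.8, -2, -70), case3 = c(0.5, -1, -0.2, 0.1, -45))
  got <- apply_rules(b_opt, s, g_opt = 110L, g_max = 150L, w, m = 3L)
  want <- oracle_rules(b_opt$mask, px, 110L, 150L, w$case2, w$case3,
                       gradient_magnitude(s))
  expect_identical(got$mask, want)
  # determinism
  again <- apply_rules(b_opt, s, g_opt = 110L, g_max = 150L, w, m = 3L)
  expect_identical(again$mask, got$mask)
})

test_that("case-2 membership is monotone in gray and distance", {
  # with w_gray > 0 and w_dist < 0, raising an added pixel's gray keeps it
  fx <- rule_fixture()
  weights <- list(case2 = c(1, -0.1, -99), case3 = c(0, 0, 0, 0, -1))
  base <- apply_rules(fx$b_opt, fx$slice, 110L, 130L, weights, m = 3L)
  px2 <- fx$slice$pixels
  px2[5, 6] <- px2[5, 6] + 5L  # brighter target
  r2 <- apply_rules(region_mask(px2 >= 120L & px2 != 115L,
                                "segmented_hemorrhage", "test"),
                    mk_slice(px2), 110L, 130L, weights, m = 3L)
  expect_true(base$mask[5, 6])
  expect_true(r2$mask[5, 6])
})
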