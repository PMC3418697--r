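test_that("the two-point toy problem solves in closed form", {
  # x = -1 (y = -1), x = +1 (y = +1): L_d = 2a - 2a^2, maximized at
  # a = 0.5, giving w0 = 1, b0 = 0
  s <- solve_svm_dual(matrix(c(-1, 1), 2, 1), c(-1, 1), c_penalty = 100)
  expect_equal(s$alphas, c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(unname(s$w0), 1, tolerance = 1e-8)
  expect_equal(s$b0, 0, tolerance = 1e-8)
  expect_equal(s$objective, 0.5, tolerance = 1e-8)
  expect_equal(s$n_sv, 2L)
})

test_that("every solve satisfies dual feasibility and KKT conditions", {
  set.seed(61)
  for (k in 1:20) {
    n <- sample(4:10, 1)
    x <- matrix(rnorm(2 * n), n, 2)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- -y[1]
    C <- sample(c(0.1, 1, 10), 1)
    s <- solve_svm_dual(x, y, C)
    expect_true(all(s$alphas >= 0 & s$alphas <= C))
    expect_lt(abs(sum(y * s$alphas)), 1e-8)
    expect_true(s$converged)
    # KKT complementarity: free SVs sit on the margin y d(x) = 1
    d <- drop(x %*% s$w0) + s$b0
    free <- s$alphas > 1e-6 & s$alphas < C - 1e-6
    if (any(free) && !s$bias_fallback) {
      expect_true(all(abs(y[free] * d[free] - 1) < 1e-4))
    }
  }
})

test_that("the dual objective matches brute-force enumeration on random instances", {
  set.seed(71)
  for (k in 1:50) {
    n <- sample(3:8, 1)
    x <- matrix(rnorm(2 * n), n, 2)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- -y[1]
    C <- sample(c(0.1, 1), 1)
    o <- oracle_svm_dual(x, y, C)
    s <- solve_svm_dual(x, y, C)
    expect_lt(abs(o$obj - s$objective), 1e-6)
  }
})

test_that("the hard-margin limit reproduces the max-margin hyperplane", {
  x <- matrix(c(-1, 1), 2, 1); y <- c(-1, 1)
  for (C in c(1, 10, 1000)) {
    s <- solve_svm_dual(x, y, C)
    if (C >= 1) {
      expect_equal(unname(s$w0), 1, tolerance = 1e-6)
      expect_equal(s$b0, 0, tolerance = 1e-6)
    }
  }
})

test_that("the decision rule signs points and resolves zero to +1", {
  s <- solve_svm_dual(matrix(c(-1, 1), 2, 1), c(-1, 1), 100)
  expect_equal(svm_decide(2, s), 1)
  expect_equal(svm_decide(-3, s), -1)
  expect_equal(svm_decide(0, s), 1)  # documented zero rule
  expect_error(svm_decide(c(1, 2), s), "dimension")
})

test_that("penalty selection cross-validates and breaks ties upward", {
  set.seed(81)
  # linearly separable set: some grid value reaches accuracy 1
  n <- 30
  x <- rbind(cbind(rnorm(n, -3), rnorm(n)), cbind(rnorm(n, 3), rnorm(n)))
  y <- rep(c(-1, 1), each = n)
  sel <- select_penalty(x, y, grid = c(0.1, 0.01, 0.001), folds = 10,
                        seed = 1)
  expect_equal(sel$best_accuracy, 1)
  # single-value grid returns that value
  one <- select_penalty(x, y, grid = 0.05, folds = 5, seed = 1)
  expect_equal(one$best_c, 0.05)
  # deterministic under a fixed seed
  sel2 <- select_penalty(x, y, grid = c(0.1, 0.01, 0.001), folds = 10,
                         seed = 1)
  expect_identical(sel$accuracy, sel2$accuracy)
  # ties resolve to the larger C
  expect_equal(sel$best_c, max(sel$accuracy[sel$accuracy == max(sel$accuracy)] |>
                                 names() |> as.numeric()))
})

test_that("boundary-band sampling is balanced, in-bounds, and non-background", {
  p <- generate_phantom(small_phantom_spec(seed = 14))
  clean <- remove_artifacts(p$slice)
  bone <- segment_and_mask_bone(clean)
  rng <- estimate_gray_range(bone$masked, p$truth$artery)
  masked <- mask_arteries(bone$masked, p$truth$artery)
  seed <- detect_hemorrhage(masked, detection_config(artery_gray_range = rng))
  ts <- sample_training_data(seed$mask, masked, svm_config(seed = 4))
  expect_equal(sum(ts$y > 0), sum(ts$y < 0))
  expect_true(all(masked$pixels[ts$coords] > 0L))
  inside <- ts$provenance == "inside"
  expect_true(all(seed$mask$mask[ts$coords[inside, , drop = FALSE]]))
  expect_false(any(seed$mask$mask[ts$coords[!inside, , drop = FALSE]]))
})

test_that("band sampling on a filled square takes the inner and outer rings", {
  px <- matrix(0L, 12, 12); px[2:11, 2:11] <- 100L
  px[4:9, 4:9] <- 150L
  s <- mk_slice(px)
  sq <- rect_mask(12, 12, 4, 9, 4, 9, id = s$id)
  cfg <- svm_config(band_width = 1L, cap = 1000L, seed = 0)
  ts <- sample_training_data(sq, s, cfg)
  inner_ring <- sq$mask & !rect_mask(12, 12, 5, 8, 5, 8)$mask
  outer_ring <- rect_mask(12, 12, 3, 10, 3, 10)$mask & !sq$mask
  pos <- ts$coords[ts$y > 0, , drop = FALSE]
  neg <- ts$coords[ts$y < 0, , drop = FALSE]
  expect_true(all(inner_ring[pos]))
  expect_true(all(outer_ring[neg]))
  expect_equal(nrow(pos), nrow(neg))
})

test_that("per-image weight optimization learns the expected sign pattern", {
  p <- generate_phantom(small_phantom_spec(seed = 16))
  clean <- remove_artifacts(p$slice)
  bone <- segment_and_mask_bone(clean)
  rng <- estimate_gray_range(bone$masked, p$truth$artery)
  masked <- mask_arteries(bone$masked, p$truth$artery)
  seed <- detect_hemorrhage(masked, detection_config(artery_gray_range = rng))
  mim <- mim_search(masked, seed, mim_config(roi_size = 60L))
  w <- optimize_rule_weights(masked, mim$b_opt, svm_config(seed = 2))
  # hemorrhage is brighter and nearer the foci by construction
  expect_gt(w$case2[1], 0)   # weight on gray
  expect_lt(w$case2[2], 0)   # weight on distance
  expect_true(w$penalty_c2 %in% c(0.1, 0.01, 0.001))
  # training-set accuracy does not fall far below the CV estimate
  expect_gte(w$train_accuracy[["case2"]], w$cv_accuracy[["case2"]] - 0.05)
  expect_gte(w$train_accuracy[["case3"]], w$cv_accuracy[["case3"]] - 0.05)
  # reproducible under the same seed
  w2 <- optimize_rule_weights(masked, mim$b_opt, svm_config(seed = 2))
  expect_identical(w$case2, w2$case2)
  expect_identical(w$case3, w2$case3)
})
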