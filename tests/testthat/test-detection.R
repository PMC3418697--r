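test_that("artifact removal keeps only the largest component", {
  # phantom with a table band: band removed, body ellipse intact
  sp <- small_phantom_spec(seed = 6, table_artifact = TRUE)
  p <- generate_phantom(sp)
  clean <- remove_artifacts(p$slice)
  band_rows <- (sp$size[1] - 6):(sp$size[1] - 4)
  body <- p$noiseless > 0L
  body[band_rows, ] <- body[band_rows, ] & FALSE
  expect_equal(sum(clean$pixels[band_rows, ] > 0 &
                     p$noiseless[band_rows, ] == 0), 0L)
  # idempotence on an artifact-free image
  again <- remove_artifacts(clean)
  expect_identical(again$pixels, clean$pixels)
  # two components, areas 500 vs 40: only the larger survives
  px <- matrix(0L, 40, 40)
  px[2:21, 2:26] <- 90L   # 500 px
  px[30:34, 30:37] <- 90L # 40 px
  out <- remove_artifacts(mk_slice(px))
  expect_equal(sum(out$pixels > 0), 500L)
  expect_true(all(out$pixels[30:34, 30:37] == 0L))
  expect_error(remove_artifacts(mk_slice(matrix(0L, 4, 4))), "background")
})

test_that("bone segmentation recovers the phantom bone and zeroes it", {
  p <- generate_phantom(small_phantom_spec(seed = 8))
  res <- segment_and_mask_bone(remove_artifacts(p$slice))
  alg <- mask_algebra(res$bone, p$truth$bone)
  expect_lt(alg$areas[["symmetric_difference"]] /
              alg$areas[["b"]], 0.05)
  # masked output has zero at every bone pixel
  expect_true(all(res$masked$pixels[res$bone$mask] == 0L))
  # no pixel above threshold: empty mask, image unchanged
  low <- mk_slice(matrix(50L, 6, 6))
  res2 <- segment_and_mask_bone(low, detection_config(bone_threshold = 200L))
  expect_equal(mask_area(res2$bone), 0L)
  expect_identical(res2$masked$pixels, low$pixels)
})

test_that("artery masking zeroes exactly the artery pixels", {
  p <- generate_phantom(small_phantom_spec(seed = 8))
  masked <- mask_arteries(p$slice, p$truth$artery)
  expect_true(all(masked$pixels[p$truth$artery$mask] == 0L))
  keep <- !p$truth$artery$mask
  expect_identical(masked$pixels[keep], p$slice$pixels[keep])
  # empty mask is a no-op; re-masking is idempotent
  empty <- region_mask(matrix(FALSE, p$slice$height, p$slice$width),
                       "artery", p$slice$id)
  expect_identical(mask_arteries(p$slice, empty)$pixels, p$slice$pixels)
  expect_identical(mask_arteries(masked, p$truth$artery)$pixels,
                   masked$pixels)
})

test_that("seed detection finds the hemorrhage and its centroid", {
  p <- generate_phantom(small_phantom_spec(seed = 10))
  clean <- remove_artifacts(p$slice)
  bone <- segment_and_mask_bone(clean)
  rng <- estimate_gray_range(bone$masked, p$truth$artery)
  masked <- mask_arteries(bone$masked, p$truth$artery)
  seed <- detect_hemorrhage(masked,
                            detection_config(artery_gray_range = rng))
  expect_true(seed$found)
  # arterial-phase seed covers at least half the true hemorrhage
  inter <- sum(seed$mask$mask & p$truth$hemorrhage$mask)
  expect_gte(inter / mask_area(p$truth$hemorrhage), 0.5)
  # the seed never contains masked-to-zero pixels and respects the range
  expect_true(all(masked$pixels[seed$mask$mask] > 0L))
  expect_true(all(masked$pixels[seed$mask$mask] >= rng[1]))
})

test_that("hemorrhage-free images yield the explicit no-hemorrhage result", {
  sp <- small_phantom_spec(seed = 3)
  sp$hemorrhage$count <- 0L
  p <- generate_phantom(sp)
  clean <- remove_artifacts(p$slice)
  bone <- segment_and_mask_bone(clean)
  rng <- estimate_gray_range(bone$masked, p$truth$artery)
  masked <- mask_arteries(bone$masked, p$truth$artery)
  seed <- detect_hemorrhage(masked,
                            detection_config(artery_gray_range = rng))
  expect_false(seed$found)
})

test_that("seed centroid equals the brute-force coordinate mean", {
  px <- matrix(0L, 12, 12)
  px[4:9, 5:8] <- 150L
  s <- mk_slice(px)
  seed <- detect_hemorrhage(s, detection_config(
    artery_gray_range = c(140L, 160L), min_object_area = 4L))
  idx <- which(px == 150L, arr.ind = TRUE)
  expect_equal(seed$centroid, c(mean(idx[, 1]), mean(idx[, 2])))
  expect_equal(mask_area(seed$mask), nrow(idx))
})
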