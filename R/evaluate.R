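# Segmentation evaluation: the missegmented-area metric compares the
# segmented region A2 with the ground-truth region A1 through their
# symmetric difference K = (A1 u A2) \ (A1 n A2), reported as a percent of
# the ground-truth area, and bands results as good (<10%), acceptable
# (10-20%) or unacceptable (>20%).

#' Missegmented area
#'
#' `|K| / |A1| * 100` with `K` the symmetric difference of ground truth
#' `A1` and segmentation `A2`. Can exceed 100% for grossly oversegmented
#' results; 0% iff the masks agree exactly.
#'
#' @param a1 ground-truth `region_mask` (non-empty).
#' @param a2 segmented `region_mask`.
#' @return percent (numeric).
#' @export
missegmented_area <- function(a1, a2) {
  if (mask_area(a1) == 0L) {
    stop("ground-truth region is empty; missegmented area is undefined")
  }
  alg <- mask_algebra(a1, a2)
  alg$areas[["symmetric_difference"]] / alg$areas[["a"]] * 100
}

#' Band a missegmented-area percentage
#'
#' Below `good_max` percent is `good`; between `good_max` and
#' `acceptable_max` (both boundaries inclusive) is `acceptable`; above is
#' `unacceptable`.
#'
#' @param misseg missegmented area in percent (>= 0).
#' @param good_max,acceptable_max band boundaries (defaults 10 and 20).
#' @return character band label.
#' @export
classify_band <- function(misseg, good_max = 10, acceptable_max = 20) {
  if (any(misseg < 0)) stop("missegmented area cannot be negative")
  ifelse(misseg < good_max, "good",
         ifelse(misseg <= acceptable_max, "acceptable", "unacceptable"))
}

#' Stage-to-stage area growth percentile
#'
#' `(cur - prev) / cur * 100`: the share of the later-stage area that was
#' added by that stage (same convention as the region-growing epoch rate).
#'
#' @param prev_area,cur_area pixel counts with
#'   `cur_area >= prev_area >= 0` and `cur_area > 0`.
#' @return percent in `[0, 100]`.
#' @export
stage_growth <- function(prev_area, cur_area) {
  if (cur_area <= 0) stop("current-stage area must be positive")
  if (prev_area < 0 || prev_area > cur_area) {
    stop("areas must satisfy 0 <= prev_area <= cur_area")
  }
  (cur_area - prev_area) / cur_area * 100
}

#' Dice coefficient of two masks
#' @param a,b `region_mask`s over the same slice.
#' @return Dice similarity in `[0, 1]`.
#' @export
dice_coef <- function(a, b) {
  alg <- mask_algebra(a, b)
  den <- alg$areas[["a"]] + alg$areas[["b"]]
  if (den == 0L) return(1)
  2 * alg$areas[["intersection"]] / den
}

#' Jaccard index of two masks
#' @param a,b `region_mask`s over the same slice.
#' @return Jaccard similarity in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  alg <- mask_algebra(a, b)
  if (alg$areas[["union"]] == 0L) return(1)
  alg$areas[["intersection"]] / alg$areas[["union"]]
}

#' Evaluate a segmentation against ground truth
#'
#' @param truth ground-truth `region_mask`.
#' @param segmented segmented `region_mask`.
#' @param good_max,acceptable_max band boundaries in percent.
#' @return list: `area_truth`, `area_segmented`, `k_area`,
#'   `missegmented_area_pct`, `band`, `dice`, `jaccard`.
#' @export
evaluate_segmentation <- function(truth, segmented, good_max = 10,
                                  acceptable_max = 20) {
  mis <- missegmented_area(truth, segmented)
  alg <- mask_algebra(truth, segmented)
  list(area_truth = alg$areas[["a"]],
       area_segmented = alg$areas[["b"]],
       k_area = alg$areas[["symmetric_difference"]],
       missegmented_area_pct = mis,
       band = classify_band(mis, good_max, acceptable_max),
       dice = dice_coef(truth, segmented),
       jaccard = jaccard_index(truth, segmented))
}

#' Summarize bands over a batch of evaluations
#'
#' @param bands character vector of band labels.
#' @return named percentage vector over good/acceptable/unacceptable.
#' @export
band_summary <- function(bands) {
  lv <- c("good", "acceptable", "unacceptable")
  100 * table(factor(bands, levels = lv)) / length(bands)
}
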