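# Pipeline glue: configuration, the detect -> match -> optimize -> rules
# -> grow -> evaluate chain, and report/mask serialization.

#' Full pipeline configuration
#'
#' Bundles the per-stage configurations. All randomness (training-pixel
#' sampling, cross-validation folds) flows from the single `seed`.
#'
#' @param detection `detection_config`.
#' @param mim `mim_config`.
#' @param svm `svm_config`.
#' @param grow `grow_config`.
#' @param rule_m odd rule-window side.
#' @param good_max,acceptable_max evaluation band boundaries in percent.
#' @param seed master RNG seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(detection = detection_config(),
                            mim = mim_config(),
                            svm = svm_config(),
                            grow = grow_config(),
                            rule_m = 3L,
                            good_max = 10, acceptable_max = 20,
                            seed = 0L) {
  if (rule_m %% 2L == 0L) stop("rule_m must be odd")
  if (rule_m >= mim$roi_size) stop("rule_m must be smaller than the MIM ROI")
  svm$seed <- as.integer(seed)
  structure(list(detection = detection, mim = mim, svm = svm, grow = grow,
                 rule_m = as.integer(rule_m), good_max = good_max,
                 acceptable_max = acceptable_max, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_constructors <- function() {
  list(detection = detection_config, mim = mim_config, svm = svm_config,
       grow = grow_config)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `detection`, `mim`, `svm`, `grow`, `rule_m`, `good_max`,
#' `acceptable_max`, `seed` map onto [pipeline_config()]; unknown keys at
#' any level are rejected.
#'
#' @param path YAML file path.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  ctors <- config_constructors()
  top_known <- c(names(ctors), "rule_m", "good_max", "acceptable_max", "seed")
  unknown <- setdiff(names(raw), top_known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  args <- list()
  for (nm in names(ctors)) {
    sub <- raw[[nm]] %||% list()
    known <- names(formals(ctors[[nm]]))
    bad <- setdiff(names(sub), known)
    if (length(bad)) {
      stop("unknown keys under '", nm, "': ", paste(bad, collapse = ", "))
    }
    args[[nm]] <- do.call(ctors[[nm]], sub)
  }
  for (nm in c("rule_m", "good_max", "acceptable_max", "seed")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  }
  do.call(pipeline_config, args)
}

#' Echo the effective configuration to YAML
#' @param cfg `pipeline_config`.
#' @param path output path.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(rapply(unclass(cfg), unclass, how = "replace"), path)
  invisible(path)
}

report_stage_areas <- function(seed_area, bopt_area, rules_area,
                               final_area) {
  list(seed = seed_area, b_opt = bopt_area, post_rules = rules_area,
       final = final_area,
       growth_mim_to_rules_pct = stage_growth(bopt_area, rules_area),
       growth_rules_to_grow_pct = stage_growth(rules_area, final_area))
}

#' Run the full segmentation pipeline on one slice
#'
#' Executes artifact removal, bone segmentation and masking, artery
#' masking, seed detection, mutual-information matching, per-image SVM
#' rule optimization, rule application, region growing, and (when ground
#' truth is supplied) evaluation. A failed detection short-circuits into
#' an explicit no-hemorrhage report. The run is deterministic given the
#' configuration seed.
#'
#' @param slice input `ct_slice`.
#' @param config `pipeline_config`.
#' @param arteries `region_mask` of artery pixels; required unless
#'   `config$detection$artery_gray_range` is set and arteries are already
#'   masked out of `slice`.
#' @param truth optional ground-truth `region_mask`; enables evaluation.
#' @param output_dir optional directory; when given, per-stage masks,
#'   weights, the MI curve, the epoch trace, the effective config, and the
#'   JSON report are written there.
#' @return `segmentation_report` list; see the package vignette for the
#'   field-by-field description.
#' @export
run_pipeline <- function(slice, config = pipeline_config(), arteries = NULL,
                         truth = NULL, output_dir = NULL) {
  t0 <- Sys.time()
  clean <- remove_artifacts(slice)
  bone <- segment_and_mask_bone(clean, config$detection)
  masked <- bone$masked
  det_cfg <- config$detection
  if (!is.null(arteries)) {
    if (is.null(det_cfg$artery_gray_range)) {
      det_cfg$artery_gray_range <- estimate_gray_range(masked, arteries)
    }
    masked <- mask_arteries(masked, arteries)
  } else if (is.null(det_cfg$artery_gray_range)) {
    stop("either an artery mask or detection$artery_gray_range is required")
  }
  seed <- detect_hemorrhage(masked, det_cfg)
  report <- list(slice_id = slice$id, found = seed$found,
                 artery_gray_range = det_cfg$artery_gray_range,
                 seed_config = config$seed)
  if (!seed$found) {
    report$message <- "no hemorrhage detected"
    if (!is.null(output_dir)) write_report_files(report, NULL, output_dir,
                                                 config)
    return(structure(report, class = "segmentation_report"))
  }
  mim <- mim_search(masked, seed, config$mim)
  weights <- optimize_rule_weights(masked, mim$b_opt, config$svm)
  ruled <- apply_rules(mim$b_opt, masked, mim$g_opt, seed$g_max, weights,
                       config$rule_m)
  grown <- grow_region(ruled, masked, mim$g_opt, config$grow)
  report$g_opt <- mim$g_opt
  report$g_max <- seed$g_max
  report$stage_areas <- report_stage_areas(
    mask_area(seed$mask), mask_area(mim$b_opt), mask_area(ruled),
    mask_area(grown$mask))
  report$weights <- list(case2 = weights$case2, case3 = weights$case3,
                         penalty_c2 = weights$penalty_c2,
                         penalty_c3 = weights$penalty_c3,
                         cv_accuracy = as.list(weights$cv_accuracy))
  report$epochs <- grown$trace
  if (!is.null(truth)) {
    report$evaluation <- evaluate_segmentation(
      truth, grown$mask, config$good_max, config$acceptable_max)
  }
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  masks <- list(seed = seed$mask, b_opt = mim$b_opt, post_rules = ruled,
                final = grown$mask)
  if (!is.null(output_dir)) {
    write_report_files(report, masks, output_dir, config, mim)
  }
  out <- structure(report, class = "segmentation_report")
  attr(out, "masks") <- masks
  out
}

#' @export
print.segmentation_report <- function(x, ...) {
  if (!isTRUE(x$found)) {
    cat("<segmentation_report: no hemorrhage detected>\n")
    return(invisible(x))
  }
  cat(sprintf("<segmentation_report '%s': G_opt %d, final area %d>\n",
              x$slice_id, x$g_opt, x$stage_areas$final))
  if (!is.null(x$evaluation)) {
    cat(sprintf("  missegmented area %.2f%% -> %s\n",
                x$evaluation$missegmented_area_pct, x$evaluation$band))
  }
  invisible(x)
}

report_to_json <- function(report) {
  rep <- unclass(report)
  rep$elapsed_s <- NULL  # keep report bytes reproducible across runs
  jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, dataframe = "rows",
                   pretty = TRUE, null = "null")
}

write_report_files <- function(report, masks, output_dir, config,
                               mim = NULL) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(report_to_json(report), file.path(output_dir, "report.json"))
  write_pipeline_config(config, file.path(output_dir, "config.yaml"))
  if (!is.null(masks)) {
    for (nm in names(masks)) {
      write_mask_png(masks[[nm]], file.path(output_dir,
                                            paste0("mask_", nm, ".png")))
      jsonlite::write_json(mask_to_rle(masks[[nm]]),
                           file.path(output_dir,
                                     paste0("mask_", nm, ".rle.json")),
                           auto_unbox = TRUE)
    }
  }
  if (!is.null(mim)) write_mi_curve(mim, file.path(output_dir,
                                                   "mi_curve.csv"))
  invisible(output_dir)
}

#' Run the pipeline on a generated phantom
#'
#' Convenience wrapper used by the batch evaluation and the command line:
#' generates the phantom, feeds its artery ground truth to the pipeline,
#' and evaluates against the hemorrhage ground truth.
#'
#' @param spec `phantom_spec`.
#' @param config `pipeline_config`.
#' @param output_dir optional output directory.
#' @return `segmentation_report`.
#' @export
run_phantom_pipeline <- function(spec, config = pipeline_config(),
                                 output_dir = NULL) {
  ph <- generate_phantom(spec)
  run_pipeline(ph$slice, config, arteries = ph$truth$artery,
               truth = ph$truth$hemorrhage, output_dir = output_dir)
}
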