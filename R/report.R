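#' Published reference summary of a femoral-metastasis segmentation study
#'
#' Per-lesion-type mean (SD) Dice coefficients and mean (SD) segmentation
#' volumes reported by a published two-operator, two-session reliability
#' study of manual segmentation in 54 metastatic femurs (19 osteolytic,
#' 17 osteoblastic, 18 mixed). These values are used in two ways: as the
#' calibration targets of the synthetic-cohort generator's volume
#' distributions, and for arithmetic consistency checks (the n-weighted mean
#' of the per-type Dice means must reproduce the study's overall per-set
#' means of 0.54, 0.50, 0.56 and 0.71).
#'
#' @return A tibble with columns `set`, `lesion_type`, `n`, `dice_mean`,
#'   `dice_sd`, `volume_mean`, `volume_sd` (volumes in cm^3).
#' @export
reference_cohort_summary <- function() {
  tibble::tibble(
    set = rep(comparison_set_levels, each = 3),
    lesion_type = rep(c("osteolytic", "osteoblastic", "mixed"), times = 4),
    n = rep(c(19L, 17L, 18L), times = 4),
    dice_mean = c(0.54, 0.57, 0.51,
                  0.45, 0.60, 0.46,
                  0.56, 0.60, 0.52,
                  0.63, 0.78, 0.74),
    dice_sd = c(0.26, 0.28, 0.29,
                0.31, 0.27, 0.34,
                0.26, 0.28, 0.30,
                0.27, 0.12, 0.23),
    volume_mean = c(14.48, 33.35, 41.20,
                    12.88, 37.12, 35.00,
                    14.44, 32.51, 28.72,
                    12.92, 37.95, 47.48),
    volume_sd = c(13.83, 32.42, 27.47,
                  10.79, 40.56, 28.39,
                  13.65, 36.74, 24.78,
                  11.76, 37.77, 35.82)
  )
}

#' Compile the full reliability report for a study table
#'
#' Runs every summary of the analysis on one study table: per-type and
#' overall agreement, size-stratified agreement with good-DC fractions, and
#' the Kruskal-Wallis lesion-type comparisons.
#'
#' @inheritParams split_by_size
#' @inheritParams test_dc_by_type
#' @return An object of class `segrel_report`: a list of tibbles
#'   `per_femur`, `per_type`, `overall`, `per_size`, `tests`, plus the
#'   thresholds used.
#' @export
compile_report <- function(study, dc_threshold = 0.7, size_threshold = 60,
                           alpha = 0.05) {
  study <- check_study(study)
  if (dc_threshold <= 0) stop("`dc_threshold` must be positive", call. = FALSE)
  structure(list(
    per_femur = study,
    per_type = summarize_by_type(study),
    overall = summarize_overall(study),
    per_size = split_by_size(study, size_threshold = size_threshold,
                             dc_threshold = dc_threshold),
    tests = test_dc_by_type(study, alpha = alpha),
    dc_threshold = dc_threshold,
    size_threshold = size_threshold,
    alpha = alpha
  ), class = "segrel_report")
}

#' @export
print.segrel_report <- function(x, ...) {
  cat(sprintf("<segrel_report> %d femurs, %d comparisons\n",
              length(unique(x$per_femur$femur_id)), nrow(x$per_femur)))
  cat("\nOverall Dice per comparison set:\n")
  print(x$overall, ...)
  cat(sprintf("\nSize strata (threshold %g cm^3, good DC > %g):\n",
              x$size_threshold, x$dc_threshold))
  print(x$per_size, ...)
  cat("\nLesion-type Kruskal-Wallis tests:\n")
  print(x$tests, ...)
  invisible(x)
}

#' @rdname compile_report
#' @param x A `segrel_report`.
#' @param ... Unused.
#' @export
glance.segrel_report <- function(x, ...) {
  ov <- x$overall
  tibble::tibble(
    n_femurs = length(unique(x$per_femur$femur_id)),
    n_comparisons = nrow(x$per_femur),
    dice_inter_1 = ov$dice_mean[ov$set == "inter_1"],
    dice_inter_2 = ov$dice_mean[ov$set == "inter_2"],
    dice_intra_I = ov$dice_mean[ov$set == "intra_I"],
    dice_intra_II = ov$dice_mean[ov$set == "intra_II"],
    n_good_sets = sum(ov$dice_mean > x$dc_threshold)
  )
}

round_df <- function(df, digits = 2) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), ~ round(.x, digits)))
}

#' Write a reliability report to disk
#'
#' Writes the report as CSV tables (`per_femur.csv`, `per_type.csv`,
#' `overall.csv`, `per_size.csv`, `tests.csv`) at full precision, plus
#' `report.json` containing both the full-precision numbers and a
#' presentation copy rounded to 2 decimals (the conventional precision for
#' Dice and cm^3 summaries).
#'
#' @param report A `segrel_report` from [compile_report()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "segrel_report")) {
    stop("`report` must come from compile_report()", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("per_femur", "per_type", "overall", "per_size", "tests")
  for (t in tabs) {
    readr::write_csv(report[[t]], file.path(dir, paste0(t, ".csv")), na = "NA")
  }
  payload <- list(
    thresholds = list(dc_threshold = report$dc_threshold,
                      size_threshold = report$size_threshold,
                      alpha = report$alpha),
    full = purrr::map(report[tabs], ~ .x),
    rounded = purrr::map(report[tabs], round_df)
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
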