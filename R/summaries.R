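check_study <- function(study) {
  study <- tibble::as_tibble(study)
  needed <- c("femur_id", "lesion_type", "kind", "set", "dice", "mean_volume")
  miss <- setdiff(needed, names(study))
  if (length(miss)) {
    stop("study table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(study)) stop("study table is empty", call. = FALSE)
  study
}

#' Per-lesion-type agreement summary
#'
#' Mean and sample standard deviation (n - 1 denominator) of the per-femur
#' Dice coefficient and of the per-femur mean segmentation volume, for every
#' comparison set and lesion type. A (set, type) cell with no femurs is
#' simply absent from the output rather than reported as zero.
#'
#' @param study A `segrel_study` table from [assemble_study_table()].
#' @return A tibble with columns `set`, `lesion_type`, `n`, `dice_mean`,
#'   `dice_sd`, `volume_mean`, `volume_sd` (volumes in cm^3).
#' @export
summarize_by_type <- function(study) {
  study <- check_study(study)
  study |>
    dplyr::group_by(.data$set, .data$lesion_type) |>
    dplyr::summarise(
      n = dplyr::n(),
      dice_mean = mean(.data$dice),
      dice_sd = if (dplyr::n() > 1) stats::sd(.data$dice) else NA_real_,
      volume_mean = mean(.data$mean_volume),
      volume_sd = if (dplyr::n() > 1) stats::sd(.data$mean_volume) else NA_real_,
      .groups = "drop"
    )
}

#' Overall per-comparison-set summary
#'
#' Mean and sample SD of the per-femur Dice coefficient and of the
#' non-overlapping segmentation volume across all lesion types, per
#' comparison set. Because lesion types partition the femurs, each overall
#' Dice mean equals the n-weighted mean of the per-type means exactly.
#'
#' @inheritParams summarize_by_type
#' @return A tibble with columns `set`, `n`, `dice_mean`, `dice_sd`,
#'   `non_overlap_mean`, `non_overlap_sd`, `volume_mean`, `volume_sd`.
#' @export
summarize_overall <- function(study) {
  study <- check_study(study)
  study |>
    dplyr::group_by(.data$set) |>
    dplyr::summarise(
      n = dplyr::n(),
      dice_mean = mean(.data$dice),
      dice_sd = if (dplyr::n() > 1) stats::sd(.data$dice) else NA_real_,
      non_overlap_mean = mean(.data$non_overlap_volume),
      non_overlap_sd = if (dplyr::n() > 1) stats::sd(.data$non_overlap_volume) else NA_real_,
      volume_mean = mean(.data$mean_volume),
      volume_sd = if (dplyr::n() > 1) stats::sd(.data$mean_volume) else NA_real_,
      .groups = "drop"
    )
}

#' Pool per-group means into an overall mean
#'
#' The n-weighted mean of group means. When groups partition the sample
#' (e.g. lesion types within a comparison set), this reproduces the overall
#' mean exactly; it is the arithmetic identity used to cross-check published
#' per-type and overall summaries against each other.
#'
#' @param means Numeric vector of group means.
#' @param n Integer vector of group sizes.
#' @return The pooled mean.
#' @examples
#' pool_group_means(c(0.54, 0.57, 0.51), c(19, 17, 18))
#' @export
pool_group_means <- function(means, n) {
  if (length(means) != length(n)) stop("`means` and `n` differ in length", call. = FALSE)
  stats::weighted.mean(means, n)
}

#' Fraction of comparisons with good agreement
#'
#' The proportion of Dice coefficients strictly greater than the threshold.
#' A DC above 0.7 is conventionally taken to indicate good segmentation
#' reliability; the inequality is strict, so a value exactly at the threshold
#' does not count as good.
#'
#' @param dc Numeric vector of Dice coefficients (non-empty).
#' @param threshold Good-agreement threshold (default 0.7).
#' @return Fraction in `[0, 1]`.
#' @export
good_dc_fraction <- function(dc, threshold = 0.7) {
  if (!length(dc)) stop("no Dice values supplied", call. = FALSE)
  if (anyNA(dc)) stop("Dice values contain NA", call. = FALSE)
  mean(dc > threshold)
}

#' Size-stratified agreement summary
#'
#' Splits the comparison rows at a mean-segmentation-volume threshold
#' (default 60 cm^3) and summarises the Dice coefficient within each stratum,
#' pooling the two inter-operator sets and the two intra-operator sets
#' separately. The mean segmentation volume of a row is `(|A| + |B|) / 2`
#' over the two masks of that comparison, so the inter strata average the two
#' operators within a session and the intra strata average one operator's two
#' sessions. Rows exactly at the threshold fall in the lower (small) stratum:
#' both strata are defined by strict inequalities, and the boundary is
#' resolved downwards.
#'
#' @inheritParams summarize_by_type
#' @param size_threshold Volume threshold in cm^3 (default 60).
#' @param dc_threshold Good-agreement Dice threshold passed to
#'   [good_dc_fraction()] (default 0.7).
#' @return A tibble with columns `kind` (`inter`/`intra`), `size_stratum`
#'   (`large` for > threshold, `small` otherwise), `n`, `dice_mean`,
#'   `dice_sd`, `good_dc_fraction`. Empty strata are absent.
#' @export
split_by_size <- function(study, size_threshold = 60, dc_threshold = 0.7) {
  study <- check_study(study)
  if (size_threshold <= 0) stop("`size_threshold` must be positive", call. = FALSE)
  study |>
    dplyr::mutate(size_stratum = ifelse(.data$mean_volume > size_threshold,
                                        "large", "small")) |>
    dplyr::group_by(.data$kind, .data$size_stratum) |>
    dplyr::summarise(
      n = dplyr::n(),
      dice_mean = mean(.data$dice),
      dice_sd = if (dplyr::n() > 1) stats::sd(.data$dice) else NA_real_,
      good_dc_fraction = good_dc_fraction(.data$dice, dc_threshold),
      .groups = "drop"
    )
}

#' Kruskal-Wallis rank test
#'
#' Rank-based one-way comparison of two or more independent groups, with tie
#' correction; the p-value comes from the chi-square approximation with
#' k - 1 degrees of freedom (adequate for group sizes in the tens, as in a
#' 19/17/18 lesion-type design; nonparametric because per-femur Dice
#' distributions are far from normal). The computation is delegated to
#' [stats::kruskal.test()].
#'
#' One degenerate case is handled explicitly: when every observation is
#' identical the tie correction divides by zero; by convention the statistic
#' is 0 with p = 1 (no evidence of any difference), and a warning is issued.
#'
#' @param values Numeric vector of observations (e.g. per-femur Dice values).
#' @param groups Grouping vector of the same length with at least two
#'   distinct non-empty groups; total n must be at least 3.
#' @return An object of class `segrel_kw`: a list with `statistic` (H), `df`,
#'   `p.value`, `n`, `k` and `method`. [generics::tidy()] and
#'   [generics::glance()] methods return it as a one-row tibble.
#' @examples
#' kruskal_wallis(1:9, rep(c("a", "b", "c"), each = 3))
#' @export
kruskal_wallis <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop("`values` and `groups` differ in length", call. = FALSE)
  }
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.factor(as.character(groups[keep]))
  k <- nlevels(droplevels(groups))
  if (k < 2) stop("Kruskal-Wallis needs at least 2 groups", call. = FALSE)
  if (length(values) < 3) stop("Kruskal-Wallis needs total n >= 3", call. = FALSE)
  if (length(unique(values)) == 1L) {
    warning("all observations identical; H = 0, p = 1 by convention", call. = FALSE)
    res <- list(statistic = 0, df = k - 1L, p.value = 1)
  } else {
    kt <- stats::kruskal.test(values, groups)
    res <- list(statistic = unname(kt$statistic), df = unname(kt$parameter),
                p.value = kt$p.value)
  }
  structure(c(res, list(n = length(values), k = k,
                        method = "Kruskal-Wallis rank sum test")),
            class = "segrel_kw")
}

#' @export
print.segrel_kw <- function(x, ...) {
  cat(sprintf("%s: H = %.4g, df = %d, p = %.4g (n = %d, k = %d)\n",
              x$method, x$statistic, x$df, x$p.value, x$n, x$k))
  invisible(x)
}

#' @rdname kruskal_wallis
#' @param x A `segrel_kw` object.
#' @param ... Unused.
#' @export
tidy.segrel_kw <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
                 method = x$method)
}

#' @rdname kruskal_wallis
#' @export
glance.segrel_kw <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
                 n = x$n, k = x$k)
}

#' Test Dice differences between lesion types
#'
#' Applies the Kruskal-Wallis test of per-femur Dice coefficients across the
#' three lesion types, once per comparison set. The two inter-operator
#' sessions are the primary tests of the design (does segmentation agreement
#' differ between osteolytic, osteoblastic and mixed lesions?); the intra
#' sets are reported alongside for completeness.
#'
#' @inheritParams summarize_by_type
#' @param alpha Significance level used only to set the `significant` flag
#'   (default 0.05).
#' @return A tibble with one row per comparison set: `set`, `primary`,
#'   `statistic`, `df`, `p.value`, `significant`.
#' @export
test_dc_by_type <- function(study, alpha = 0.05) {
  study <- check_study(study)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  sets <- intersect(comparison_set_levels, unique(study$set))
  purrr::map_dfr(sets, function(s) {
    sub <- study[study$set == s, ]
    kw <- kruskal_wallis(sub$dice, sub$lesion_type)
    tibble::tibble(set = s, primary = s %in% c("inter_1", "inter_2"),
                   statistic = kw$statistic, df = kw$df, p.value = kw$p.value,
                   significant = kw$p.value < alpha)
  })
}
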