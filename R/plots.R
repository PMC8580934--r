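#' Plot Dice agreement against mean segmentation volume
#'
#' Scatter of per-femur Dice coefficient versus mean segmentation volume,
#' faceted into inter- and intra-operator comparisons, with the good-DC and
#' size thresholds drawn as reference lines. This is the standard diagnostic
#' view of a reliability study: larger lesions tend to sit above the good-DC
#' line, smaller ones below.
#'
#' @param object A `segrel_study` table from [assemble_study_table()].
#' @param dc_threshold Good-agreement Dice reference line (default 0.7).
#' @param size_threshold Lesion-size reference line in cm^3 (default 60).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.segrel_study <- function(object, dc_threshold = 0.7,
                                  size_threshold = 60, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_volume, y = .data$dice,
                                       colour = .data$set)) +
    ggplot2::geom_point(alpha = 0.75) +
    ggplot2::geom_hline(yintercept = dc_threshold, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = size_threshold, linetype = "dotted") +
    ggplot2::facet_wrap(~kind) +
    ggplot2::labs(x = "mean segmentation volume (cm³)",
                  y = "Dice coefficient", colour = "comparison") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot per-lesion-type Dice distributions
#'
#' Boxplots of per-femur Dice coefficients by lesion type, one panel per
#' comparison set. Companion view to [test_dc_by_type()].
#'
#' @inheritParams autoplot.segrel_study
#' @param study A `segrel_study` table.
#' @return A ggplot object.
#' @export
plot_dice_by_type <- function(study, dc_threshold = 0.7) {
  ggplot2::ggplot(study, ggplot2::aes(x = .data$lesion_type, y = .data$dice,
                                      fill = .data$lesion_type)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.5) +
    ggplot2::geom_hline(yintercept = dc_threshold, linetype = "dashed") +
    ggplot2::facet_wrap(~set) +
    ggplot2::labs(x = NULL, y = "Dice coefficient") +
    ggplot2::guides(fill = "none") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}
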