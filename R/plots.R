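#' Paired pre- vs early-treatment box plots
#'
#' Box-and-whisker plot of every texture feature at both timepoints on
#' the rater-averaged cohort table, the visual companion of the paired
#' signed-rank comparisons (each feature on its own free scale).
#'
#' @param averaged Rater-averaged cohort table from [average_raters()].
#' @return A ggplot object.
#' @export
plot_paired_features <- function(averaged) {
  long <- do.call(rbind, lapply(feature_names(), function(f) {
    data.frame(parameter = f, timepoint = averaged$timepoint,
               value = averaged[[f]], stringsAsFactors = FALSE)
  }))
  long$timepoint <- factor(long$timepoint, levels = c("pre", "early"))
  ggplot2::ggplot(long, ggplot2::aes(x = timepoint, y = value)) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "feature value",
                  title = "Texture features before vs early during chemoradiotherapy") +
    ggplot2::theme_bw()
}

#' ROC curves of single features and the combined model
#'
#' Overlays the ROC coordinate paths from a [response_analysis()] result.
#'
#' @param analysis A [response_analysis()] result.
#' @return A ggplot object.
#' @export
plot_roc_curves <- function(analysis) {
  curves <- lapply(names(analysis$roc), function(f) {
    cbind(analysis$roc[[f]]$curve, predictor = f)
  })
  if (!is.null(analysis$roc_combined)) {
    curves <- c(curves, list(cbind(analysis$roc_combined$curve,
                                   predictor = "combined")))
  }
  df <- do.call(rbind, curves)
  ggplot2::ggplot(df, ggplot2::aes(x = fpr, y = tpr, color = predictor)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC: %s, %s scan", analysis$label,
                                  analysis$timepoint)) +
    ggplot2::coord_equal() +
    ggplot2::theme_bw()
}

# non-standard-evaluation column names used in ggplot2 aes()
utils::globalVariables(c("timepoint", "value", "fpr", "tpr", "predictor"))
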