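#' Covariate proportion scatter plot
#'
#' Plots comparator versus target covariate proportions, one point per
#' binary covariate, faceted by extraction window. Points above/below the
#' diagonal show covariates over-represented in one cohort; day-0 panels
#' make visit-coupling effects immediately visible.
#'
#' @param scatter output of [export_scatter()].
#' @param title optional plot title.
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot_covariate_scatter <- function(scatter, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_covariate_scatter requires the 'ggplot2' package")
  s <- as.data.table(scatter)
  s[, window_name := factor(window_name,
                            levels = intersect(c("day0", "day_minus1", "short",
                                                 "medium", "long"),
                                               unique(window_name)))]
  ggplot2::ggplot(s, ggplot2::aes(x = proportion_comparator,
                                  y = proportion_target)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6, size = 1.2) +
    ggplot2::facet_wrap(~window_name, nrow = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "covariate proportion, comparator",
                  y = "covariate proportion, target", title = title) +
    ggplot2::theme_minimal()
}
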