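#' Distribution of a cumulative CNV risk score
#'
#' Histogram of a per-sample score on a started-log axis, with the share
#' of exact zeros (individuals with no genic CNV of that state) annotated
#' — the point mass plus right tail that motivates the log and indicator
#' transforms.
#'
#' @param profile [score_samples()] output.
#' @param score Score column to plot.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(profile, score = "del_sum_pHI", bins = 40) {
  p_zero <- mean(profile[[score]] == 0)
  ggplot2::ggplot(profile, ggplot2::aes(x = log1p(.data[[score]]))) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30") +
    ggplot2::labs(
      x = paste0("log(1 + ", score, ")"), y = "individuals",
      title = paste("Cumulative", score, "distribution"),
      subtitle = sprintf("%.1f%% of individuals score exactly 0", 100 * p_zero)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_score_distribution Forest plot of a fitted model's
#'   focal standardized effects with 95% CIs.
#' @param object A `cnv_fit`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.cnv_fit <- function(object, ...) {
  d <- tidy(object, focal_only = TRUE)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "standardized β (95% CI)", y = NULL,
                  title = paste(object$family, "model of", object$outcome)) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_score_distribution AIC profile across the stepwise
#'   model ladder.
#' @exportS3Method ggplot2::autoplot
autoplot.cnv_ladder <- function(object, ...) {
  d <- mutate(object$comparison,
              model = factor(.data$model, levels = .data$model))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data$AIC, group = 1)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = "AIC",
                  title = paste("Model ladder:", object$outcome)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' @describeIn plot_score_distribution Deviation percentage by CNV-risk
#'   category.
#' @param crosstab Crosstab tibble from [deviation_association()].
#' @export
plot_deviation_crosstab <- function(crosstab) {
  ggplot2::ggplot(crosstab,
                  ggplot2::aes(x = .data$risk_category, y = .data$pct_deviant)) +
    ggplot2::geom_col(fill = "grey30", width = 0.6) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d/%d", .data$n_deviant,
                                                    .data$n)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "CNV-risk category", y = "% high brain deviation") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
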