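#' Plot the group accuracy traces per condition
#'
#' Thin lines show individual observers, thick lines the estimated group
#' mean, and ribbons the posterior SD of the group mean. Trial times within
#' the smoothing caution margin rest on shrunken windows.
#'
#' @param report A `cue_report` from [run_analysis()].
#' @return A ggplot object.
#' @export
plot_group_traces <- function(report) {
  ggplot2::ggplot(report$group,
                  ggplot2::aes(x = .data$trial_time, colour = .data$condition)) +
    ggplot2::geom_line(
      data = report$smoothed,
      ggplot2::aes(y = .data$accuracy, group = interaction(
        .data$observer_id, .data$condition)),
      linewidth = 0.2, alpha = 0.35
    ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mu - .data$se_mu, ymax = .data$mu + .data$se_mu,
                   fill = .data$condition),
      alpha = 0.3, colour = NA
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mu), linewidth = 0.9) +
    ggplot2::labs(x = "trial time", y = "accuracy",
                  colour = "condition", fill = "condition") +
    ggplot2::theme_minimal()
}

#' Plot the benefit trace with fitted growth models
#'
#' @param report A `cue_report`.
#' @return A ggplot object.
#' @export
plot_benefit <- function(report) {
  ben <- report$benefit
  fits <- purrr::imap_dfr(report$comparison$fits, function(f, m) {
    tibble::tibble(trial_time = f$x, value = f$fitted, model = m)
  })
  ggplot2::ggplot(ben, ggplot2::aes(x = .data$trial_time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$benefit - .data$se,
                                      ymax = .data$benefit + .data$se),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$benefit), colour = "grey40") +
    ggplot2::geom_line(data = fits,
                       ggplot2::aes(y = .data$value, colour = .data$model),
                       linewidth = 0.8) +
    ggplot2::labs(x = "trial time", y = "retro-cue benefit (accuracy)",
                  colour = "model") +
    ggplot2::theme_minimal()
}

#' Plot the evidence trace
#'
#' Bayes factors on a log axis with reference lines at 1 and at the crossing
#' threshold, plus the standardized effect size.
#'
#' @param report A `cue_report`.
#' @return A ggplot object.
#' @export
plot_evidence <- function(report) {
  thr <- report$config$bf_threshold
  ggplot2::ggplot(report$evidence, ggplot2::aes(x = .data$trial_time)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "solid", colour = "grey60") +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$bf10), colour = "#3366aa") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "trial time", y = "BF (benefit > 0)") +
    ggplot2::theme_minimal()
}

#' Assemble the three panel plots of a report
#'
#' Stacks the group traces, the benefit trace with model fits, and the
#' evidence trace (uses `patchwork` when installed, otherwise returns a list
#' of the three plots).
#'
#' @param object A `cue_report`.
#' @param ... Unused.
#' @return A patchwork object or list of ggplots.
#' @exportS3Method ggplot2::autoplot
autoplot.cue_report <- function(object, ...) {
  panels <- list(plot_group_traces(object), plot_benefit(object),
                 plot_evidence(object))
  if (requireNamespace("patchwork", quietly = TRUE)) {
    patchwork::wrap_plots(panels, ncol = 1)
  } else {
    panels
  }
}
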