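#' Plot stabilized weights over follow-up
#'
#' Box-plot-style ribbons of SW(t) by month since ART initiation: the
#' interquartile band, the 5th-95th percentile band, and the monthly mean.
#' A well-behaved weight set hugs 1 at every month.
#'
#' @param object a `weight_diagnostics` (or WeightSet tibble).
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot weight_diagnostics
#' @export
autoplot.weight_diagnostics <- function(object, ...) {
  bm <- object$by_month
  ggplot2::ggplot(bm, ggplot2::aes(x = .data$month)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q05, ymax = .data$q95),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "Month since ART initiation", y = "Stabilized weight SW(t)",
                  title = "Stabilized weights over follow-up") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.weight_diagnostics
#' @param weights WeightSet tibble.
#' @export
plot_weights <- function(weights, ...) {
  autoplot(weight_diagnostics(weights), ...)
}

#' Forest plot of switching rate ratios by current eGFR
#'
#' Adjusted incidence rate ratios of switching away from each regimen type as
#' current eGFR declines (reference: eGFR > 90).
#'
#' @param irr tibble from [fit_negbin_irr()].
#' @return A ggplot.
#' @export
plot_switch_irr <- function(irr) {
  irr$egfr_cat <- factor(irr$egfr_cat, levels = rev(egfr_levels()))
  ggplot2::ggplot(irr, ggplot2::aes(x = .data$irr, y = .data$egfr_cat)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
      height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~regimen) +
    ggplot2::labs(x = "Incidence rate ratio of switching (log scale)",
                  y = "Current eGFR (ml/min/1.73m²)") +
    ggplot2::theme_minimal()
}

#' Forest plot of hazard ratios across estimators
#'
#' @param report a `ckd_report` from [run_pipeline()] (needs the causal
#'   stage) or the `causal` tidy tibble itself.
#' @return A ggplot.
#' @export
plot_estimator_comparison <- function(report) {
  d <- if (inherits(report, "ckd_report")) report$causal else report
  d <- d %>% filter(!.data$suppressed)
  d$term <- sub("^exposure_initial", "", d$term)
  d$estimator <- factor(d$estimator,
                        levels = c("crude", "adjusted", "weighted",
                                   "doubly_robust"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hr, y = .data$estimator)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
      height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~term) +
    ggplot2::labs(x = "Hazard ratio vs TDF+/NNRTI (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
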