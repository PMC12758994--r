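#' Robustness figures
#'
#' ggplot2-based views of the pipeline outputs: the distribution of PTV
#' coverage deltas across motion scenarios, the per-control-point mAUC
#' series with the sensitivity threshold, aperture area against sAUC, and a
#' DVH band (static curve plus the scenario envelope). ggplot2 is an
#' optional dependency; each function errors informatively when it is not
#' installed.
#'
#' @param metrics Data frame from [scenario_metrics()].
#' @name robustness-plots
NULL

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
}

#' @rdname robustness-plots
#' @export
plot_coverage_hist <- function(metrics) {
  .need_ggplot()
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data$delta_vrx)) +
    ggplot2::geom_histogram(bins = 25, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = expression(Delta * V[Rx] ~ "(percentage points)"),
                  y = "motion traces")
}

#' @rdname robustness-plots
#' @param records Data frame from [cp_auc_metrics()].
#' @param threshold_mgy Threshold drawn as horizontal guides (mGy).
#' @export
plot_mauc_series <- function(records, threshold_mgy = 0.05) {
  .need_ggplot()
  ggplot2::ggplot(records, ggplot2::aes(x = .data$cp_index,
                                        y = .data$mauc_mgy)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$sensitive), size = 0.8) +
    ggplot2::geom_hline(yintercept = c(-threshold_mgy, threshold_mgy),
                        linetype = 2) +
    ggplot2::labs(x = "control point", y = "mAUC (mGy)")
}

#' @rdname robustness-plots
#' @export
plot_aperture_sauc <- function(records) {
  .need_ggplot()
  ggplot2::ggplot(records, ggplot2::aes(x = .data$sauc_mgy,
                                        y = .data$aperture_area_mm2)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.9) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "sAUC (mGy)", y = expression(aperture ~ area ~ (mm^2)))
}

#' @rdname robustness-plots
#' @param static_dvh A [compute_dvh()] curve for the static plan.
#' @param scenario_dvhs List of curves for the motion scenarios (common bin
#'   edges).
#' @export
plot_dvh_band <- function(static_dvh, scenario_dvhs) {
  .need_ggplot()
  vf <- vapply(scenario_dvhs, function(d) d$volume_fraction,
               numeric(length(static_dvh$dose)))
  band <- data.frame(dose = static_dvh$dose,
                     lo = apply(vf, 1, min), hi = apply(vf, 1, max),
                     static = static_dvh$volume_fraction)
  ggplot2::ggplot(band, ggplot2::aes(x = .data$dose)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.35) +
    ggplot2::geom_line(ggplot2::aes(y = .data$static), linewidth = 0.6) +
    ggplot2::labs(x = "dose (Gy)", y = "volume (%)")
}
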