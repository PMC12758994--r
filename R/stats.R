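#' Partition control points into motion-sensitive and motion-resistant sets
#'
#' Splits a [cp_auc_metrics()] table across a threshold on `|mAUC|`:
#' control points with `|mAUC|` above the threshold are motion sensitive,
#' the rest motion resistant. With `threshold_mgy = "auto"` the threshold is
#' one standard deviation of the mAUC population.
#'
#' @param records Data frame from [cp_auc_metrics()].
#' @param threshold_mgy Threshold (mGy) or `"auto"`.
#' @return List with data frames `sensitive` and `resistant` (aperture
#'   areas attached) and the numeric `threshold_mgy` used.
#' @export
partition_control_points <- function(records, threshold_mgy = 0.05) {
  thr <- if (identical(threshold_mgy, "auto")) {
    stats::sd(records$mauc_mgy)
  } else {
    threshold_mgy
  }
  sens <- abs(records$mauc_mgy) > thr
  list(sensitive = records[sens, , drop = FALSE],
       resistant = records[!sens, , drop = FALSE],
       threshold_mgy = thr)
}

#' Correlation between MLC aperture area and control-point sensitivity
#'
#' Pearson correlation of per-control-point aperture area against sAUC
#' within one plan, with the 95% confidence interval from the Fisher
#' z-transform and the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param records Data frame with columns `aperture_area_mm2` and
#'   `sauc_mgy` (e.g. from [cp_auc_metrics()]), or two numeric vectors via
#'   `x` and `y`.
#' @param x,y Optional numeric vectors overriding `records`.
#' @return List of class `correlation_result`: `r`, `ci_low`, `ci_high`,
#'   `p_value`, `n`.
#' @export
correlate_aperture_sensitivity <- function(records = NULL, x = NULL,
                                           y = NULL) {
  if (is.null(x)) {
    x <- records$aperture_area_mm2
    y <- records$sauc_mgy
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = 0.95)
  structure(
    list(r = unname(ct$estimate), ci_low = ct$conf.int[1],
         ci_high = ct$conf.int[2], p_value = ct$p.value, n = length(x)),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (95%% CI %.3f to %.3f), p = %.3g, n = %d\n",
              x$r, x$ci_low, x$ci_high, x$p_value, x$n))
  invisible(x)
}

#' Welch t-test between aperture-area subpopulations
#'
#' Two-sided Welch-corrected t-test (Satterthwaite degrees of freedom)
#' comparing MLC aperture areas of motion-sensitive versus motion-resistant
#' control points. An equal-variance pooled t-test is available as a
#' cross-check mode.
#'
#' @param sensitive_areas,resistant_areas Numeric vectors of aperture areas
#'   (mm^2), each with at least 2 values.
#' @param var_equal Use the pooled equal-variance test instead,
#'   default `FALSE`.
#' @return List of class `ttest_result`: `t_stat`, `dof`, `p_value`,
#'   `group_means` (mm^2), `group_ns`.
#' @export
welch_subpopulation_test <- function(sensitive_areas, resistant_areas,
                                     var_equal = FALSE) {
  if (length(sensitive_areas) < 2 || length(resistant_areas) < 2) {
    stop("both groups need at least 2 control points", call. = FALSE)
  }
  tt <- stats::t.test(sensitive_areas, resistant_areas,
                      var.equal = var_equal)
  structure(
    list(t_stat = unname(tt$statistic), dof = unname(tt$parameter),
         p_value = tt$p.value,
         group_means = c(sensitive = mean(sensitive_areas),
                         resistant = mean(resistant_areas)),
         group_ns = c(sensitive = length(sensitive_areas),
                      resistant = length(resistant_areas))),
    class = "ttest_result"
  )
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("t = %.3f, df = %.1f, p = %.3g; means %.1f vs %.1f mm^2 (n = %d/%d)\n",
              x$t_stat, x$dof, x$p_value, x$group_means[1], x$group_means[2],
              x$group_ns[1], x$group_ns[2]))
  invisible(x)
}

#' Cohort coverage-loss summary
#'
#' Per-plan and pooled summary of plan-level scenario metrics: the range of
#' PTV coverage deltas, the fraction of motion traces producing any coverage
#' loss (`delta_vrx < 0`), the range of GTV D99% relative differences, and
#' normality descriptives (mean, SD, skewness) of the V_Rx populations.
#'
#' @param metrics Data frame of [scenario_metrics()] rows; a `plan_id`
#'   column groups plans (a single unnamed plan is assumed otherwise).
#' @return Data frame with one row per plan plus a pooled row (`plan_id`
#'   `"pooled"`).
#' @export
coverage_summary <- function(metrics) {
  if (is.null(metrics$plan_id)) metrics$plan_id <- "plan"
  one <- function(df, id) {
    v <- df$delta_vrx
    data.frame(plan_id = id, n_traces = nrow(df),
               min_delta_vrx = min(v), max_delta_vrx = max(v),
               frac_loss = mean(v < 0),
               min_delta_d99_pct = min(df$delta_d99_pct),
               max_delta_d99_pct = max(df$delta_d99_pct),
               mean_vrx = mean(df$vrx), sd_vrx = stats::sd(df$vrx),
               skew_vrx = .skewness(df$vrx))
  }
  per <- do.call(rbind, lapply(split(metrics, metrics$plan_id),
                               function(df) one(df, df$plan_id[1])))
  rbind(per, one(metrics, "pooled"))
}

.skewness <- function(x) {
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0) return(NA_real_)
  m <- mean(x)
  (sum((x - m)^3) / n) / (sum((x - m)^2) / n)^1.5
}
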