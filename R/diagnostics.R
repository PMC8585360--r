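#' Regression diagnostics for a calibrated fit
#'
#' Standard significance diagnostics reported alongside each calibration:
#' the coefficient of determination `R^2 = 1 - SSE/SST` on the fitting
#' scale, the regression F statistic `(SSR/df_reg)/(SSE/df_res)` with its
#' degrees of freedom and p-value, the residuals, per-point relative
#' error rates `100 |pred - obs| / obs` on the newton (or coefficient)
#' scale, and the residual range.
#'
#' @param fit A [fit_power_law()] or [fit_anisotropy()] object.
#' @param ... Unused.
#' @return An object of class `"regression_diagnostics"`: a list with
#'   elements `r_squared`, `f_statistic`, `df`, `p_value`, `residuals`,
#'   `rel_error_pct`, `residual_range`, `scale`, `n`.
#' @examples
#' d <- plough_coefficients()
#' regression_diagnostics(fit_anisotropy(d$theta_deg, d$fp))
#' @export
regression_diagnostics <- function(fit, ...) {
  UseMethod("regression_diagnostics")
}

#' @export
regression_diagnostics.power_law_fit <- function(fit, ...) {
  diag_from_fitlist(fit$fit, fit$r_squared, fit$fit$scale)
}

#' @export
regression_diagnostics.anisotropy_fit <- function(fit, ...) {
  diag_from_fitlist(fit$fit, fit$r_squared, "response")
}

diag_from_fitlist <- function(f, r2, scale) {
  if (f$sst <= 0)
    stop("zero-variance response: diagnostics are undefined", call. = FALSE)
  structure(list(r_squared = r2,
                 f_statistic = f$f_statistic,
                 df = f$df,
                 p_value = f$p_value,
                 residuals = f$residuals,
                 rel_error_pct = f$rel_error_pct,
                 residual_range = range(f$residuals),
                 scale = scale, n = f$n),
            class = "regression_diagnostics")
}

#' @export
print.regression_diagnostics <- function(x, ...) {
  cat("Regression diagnostics\n")
  cat(sprintf("  R^2 = %.5g (on the %s scale, n = %d)\n",
              x$r_squared, x$scale, x$n))
  if (is.finite(x$f_statistic))
    cat(sprintf("  F = %.5g on (%d, %d) df, p = %.3g\n",
                x$f_statistic, x$df[["regression"]], x$df[["residual"]],
                x$p_value))
  cat(sprintf("  residual range: (%.4g, %.4g); relative error: %.3g%% max, %.3g%% mean\n",
              x$residual_range[1], x$residual_range[2],
              max(x$rel_error_pct), mean(x$rel_error_pct)))
  invisible(x)
}

#' Per-trial prediction error rates
#'
#' Compares the tangential forces predicted by the calibrated models with
#' the observed per-trial means: for each summarized trial, the predicted
#' `Fp` at the trial's volume `V(h)` and angle `theta`, the observed mean
#' `Fp`, and the relative error rate `100 |pred - obs| / obs` (percent).
#' Error rates are additionally aggregated (min/max/mean) per cutting
#' condition.
#'
#' @param summaries A summary data frame (from [summarize_trials()] or
#'   [read_trial_summaries()]) with columns `h_mm`, `theta_deg`,
#'   `fp_mean_n`.
#' @param nmodel A [normal_force_model()].
#' @param amodel An [anisotropy_model()].
#' @param tool A [tool_geometry()] used to convert depth to volume.
#' @return A list of class `"error_rate_table"` with elements `table`
#'   (per-trial rows with `predicted_fp_n` and `error_rate_pct`) and
#'   `by_condition` (aggregates per `(h_mm, theta_deg)`).
#' @export
error_rate_table <- function(summaries, nmodel, amodel,
                             tool = tool_geometry()) {
  if (missing(nmodel) || missing(amodel) ||
      !inherits(nmodel, "normal_force_model") ||
      !inherits(amodel, "anisotropy_model"))
    stop("calibrated 'nmodel' and 'amodel' are required", call. = FALSE)
  need <- c("h_mm", "theta_deg", "fp_mean_n")
  if (!all(need %in% names(summaries)))
    stop("summaries must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  V <- indentation_volume(summaries$h_mm, tool)
  pred <- tangential_force(V, summaries$theta_deg, nmodel, amodel)
  tab <- cbind(summaries,
               predicted_fp_n = pred$Fp,
               error_rate_pct = 100 * abs(pred$Fp - summaries$fp_mean_n) /
                 summaries$fp_mean_n)
  agg <- do.call(rbind, lapply(
    split(tab, interaction(tab$h_mm, tab$theta_deg, drop = TRUE)),
    function(g) data.frame(h_mm = g$h_mm[1], theta_deg = g$theta_deg[1],
                           n = nrow(g),
                           min_pct = min(g$error_rate_pct),
                           max_pct = max(g$error_rate_pct),
                           mean_pct = mean(g$error_rate_pct))))
  rownames(agg) <- NULL
  structure(list(table = tab, by_condition = agg),
            class = "error_rate_table")
}

#' @export
print.error_rate_table <- function(x, digits = 4, ...) {
  cat("Tangential-force prediction error rates by condition:\n")
  print(x$by_condition, digits = digits, row.names = FALSE)
  cat(sprintf("Overall: min %.3g%%, max %.3g%%, mean %.3g%% over %d trials\n",
              min(x$table$error_rate_pct), max(x$table$error_rate_pct),
              mean(x$table$error_rate_pct), nrow(x$table)))
  invisible(x)
}
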