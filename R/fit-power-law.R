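#' Calibrate the normal-force power law from indentation data
#'
#' Fits \eqn{F_z = C V^{\alpha}} to observed (volume, normal force)
#' pairs.  The default method, `"loglog"`, is ordinary least squares of
#' `log(Fz)` on `log(V)` — the multiplicative-error reading under which
#' measurement error scales with the force level, which is the natural
#' weighting for forces spanning an order of magnitude.  The `"nls"`
#' method instead minimises squared error on the original newton scale by
#' Gauss-Newton iteration (started from the log-log solution).
#' Diagnostics (R-squared, F statistic, residuals) are computed on the
#' fitting scale of the chosen method.
#'
#' @param V Indented volumes, mm^3; strictly positive.
#' @param Fz Normal forces, N; strictly positive; same length as `V`.
#' @param method `"loglog"` (default) or `"nls"`.
#' @return An object of classes `"power_law_fit"` and
#'   `"normal_force_model"`, usable directly by
#'   [empirical_normal_force()] and [tangential_force()].  Components
#'   include `C`, `alpha`, `r_squared`, and a `fit` list with `n`,
#'   `sse`, `sst`, `df` (regression, residual), `f_statistic`,
#'   `p_value`, `residuals` (fitting scale), `rel_error_pct`
#'   (per-point `100 |pred - obs| / obs` on the newton scale), `scale`,
#'   and the data.
#' @examples
#' nm <- calibrated_normal_model()
#' d <- generate_indentation(nm, n = 200, noise = noise_spec(sd = 0.01,
#'                                                           seed = 7))
#' fit <- fit_power_law(d$V, d$Fz)
#' coef(fit)
#' summary(fit)
#' @seealso [regression_diagnostics()], [generate_indentation()]
#' @export
fit_power_law <- function(V, Fz, method = c("loglog", "nls")) {
  method <- match.arg(method)
  if (length(V) != length(Fz))
    stop("'V' and 'Fz' must have the same length", call. = FALSE)
  if (length(V) < 2L)
    stop("need at least 2 points to fit the power law", call. = FALSE)
  if (any(!is.finite(V)) || any(!is.finite(Fz)) || any(V <= 0) ||
      any(Fz <= 0))
    stop("all 'V' and 'Fz' must be finite and strictly positive",
         call. = FALSE)
  if (length(unique(V)) < 2L)
    stop("singular design: all volumes are equal", call. = FALSE)

  lx <- log(V); ly <- log(Fz)
  lmfit <- stats::lm(ly ~ lx)
  C0 <- exp(unname(stats::coef(lmfit)[1]))
  a0 <- unname(stats::coef(lmfit)[2])

  if (method == "loglog") {
    C <- C0; alpha <- a0
    resid_fit <- unname(stats::residuals(lmfit))
    fitted_fit <- unname(stats::fitted(lmfit))
    obs_fit <- ly
    scale <- "log"
  } else {
    # "port" is robust to (near-)zero-residual problems, where the
    # default Gauss-Newton line search stalls
    nlsfit <- stats::nls(Fz ~ C * V^alpha,
                         start = list(C = C0, alpha = a0),
                         algorithm = "port",
                         lower = c(C = .Machine$double.xmin, alpha = -3),
                         control = stats::nls.control(maxiter = 500))
    cf <- stats::coef(nlsfit)
    C <- unname(cf["C"]); alpha <- unname(cf["alpha"])
    resid_fit <- unname(stats::residuals(nlsfit))
    fitted_fit <- unname(stats::fitted(nlsfit))
    obs_fit <- Fz
    scale <- "response"
  }

  n <- length(V)
  sse <- sum(resid_fit^2)
  sst <- sum((obs_fit - mean(obs_fit))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  df_reg <- 1L
  df_res <- n - 2L
  fstat <- if (df_res > 0 && sse > 0)
    (max(sst - sse, 0) / df_reg) / (sse / df_res) else NA_real_
  pval <- if (is.finite(fstat))
    stats::pf(fstat, df_reg, df_res, lower.tail = FALSE) else NA_real_

  pred <- C * V^alpha
  rel_err <- 100 * abs(pred - Fz) / Fz

  model <- normal_force_model(C = C, alpha = alpha,
                              r_squared = if (is.na(r2)) NA_real_
                                          else max(0, min(1, r2)))
  model$fit <- list(method = method, scale = scale, n = n,
                    sse = sse, sst = sst,
                    df = c(regression = df_reg, residual = df_res),
                    f_statistic = fstat, p_value = pval,
                    confidence_level = 0.95,
                    residuals = resid_fit, fitted = fitted_fit,
                    rel_error_pct = rel_err,
                    data = data.frame(V = V, Fz = Fz))
  class(model) <- c("power_law_fit", class(model))
  model
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law normal-force fit (%s least squares)\n",
              if (x$fit$method == "loglog") "log-log" else "nonlinear"))
  cat(sprintf("  Fz = %.6g * V^%.4g    (n = %d, R^2 = %.5g)\n",
              x$C, x$alpha, x$fit$n, x$r_squared))
  invisible(x)
}

#' @export
coef.power_law_fit <- function(object, ...) {
  c(C = object$C, alpha = object$alpha)
}

#' @export
predict.power_law_fit <- function(object, newdata = NULL, ...) {
  V <- if (is.null(newdata)) object$fit$data$V
       else if (is.list(newdata)) newdata$V
       else newdata
  empirical_normal_force(V, object)
}

#' @export
fitted.power_law_fit <- function(object, ...) {
  empirical_normal_force(object$fit$data$V, object)
}

#' @export
residuals.power_law_fit <- function(object,
                                    type = c("fitting", "response"), ...) {
  type <- match.arg(type)
  if (type == "fitting") object$fit$residuals
  else object$fit$data$Fz - fitted(object)
}

#' @export
summary.power_law_fit <- function(object, ...) {
  structure(list(fit = object,
                 diagnostics = regression_diagnostics(object)),
            class = "summary.power_law_fit")
}

#' @export
print.summary.power_law_fit <- function(x, ...) {
  print(x$fit)
  print(x$diagnostics)
  invisible(x)
}

#' @export
plot.power_law_fit <- function(x, ...) {
  d <- x$fit$data
  ord <- order(d$V)
  graphics::plot(d$V, d$Fz, pch = 1, xlab = "indented volume V (mm^3)",
                 ylab = "normal force Fz (N)",
                 main = sprintf("Fz = %.4g V^%.3g", x$C, x$alpha), ...)
  graphics::lines(d$V[ord], empirical_normal_force(d$V[ord], x),
                  col = "red3", lwd = 2)
  invisible(x)
}
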