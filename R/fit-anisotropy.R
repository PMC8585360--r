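#' Calibrate the anisotropy sinusoid from replicate ploughing coefficients
#'
#' Least-squares fit of the orientation response
#' \eqn{f_p(\theta) = C_1 + C_2 \sin(C_3 \theta + \theta_0)} to replicate
#' observations of the ploughing coefficient at several cutting angles
#' (`theta` in degrees, sinusoid argument in radians).
#'
#' The phase-rate `C3` is only identifiable up to aliasing on a sparse
#' angle design: any `C3'` with `sin(C3' theta + theta0) = sin(C3 theta +
#' theta0)` at the design angles fits equally well.  The fit is therefore
#' constrained to the first branch `0 < C3 * max(theta) <= pi`, which
#' pins down a unique solution; equivalent aliased values (including
#' compact roundings such as the conventional 0.45 for the bundled data)
#' are listed in the returned `branch` report.  For fixed `C3` the model
#' is linear in `(C1, C2)`, so the fit profiles the residual sum of
#' squares over `C3` with an exact linear solve at each candidate — no
#' starting values are needed and the global first-branch optimum is
#' found by unimodal search refined to near machine precision.
#'
#' With exactly three distinct angles and `theta0 = 0` fixed the
#' least-squares problem decomposes into the per-angle means, and the
#' result coincides with the closed-form three-mean solver
#' ([solve_three_angle()]); this identity is the package's cross-check of
#' the optimiser.
#'
#' The amplitude sign convention is `C2 > 0`.  If the profiled optimum
#' has a nonpositive amplitude there is no feasible first-branch
#' solution; the fit then fails with a diagnostic rather than silently
#' wrapping to another branch.
#'
#' @param theta Cutting angles, degrees; at least 3 distinct values.
#' @param fp Observed ploughing coefficients, dimensionless, positive;
#'   same length as `theta`.
#' @param theta0 Phase angle, fixed at 0 by default.
#' @param fit_theta0 Logical; if `TRUE`, `theta0` is estimated as well
#'   (via the linearisation `C2 sin(C3 theta + theta0) = a sin(C3 theta)
#'   + b cos(C3 theta)`).
#' @return An object of classes `"anisotropy_fit"` and
#'   `"anisotropy_model"` (canonical convention), usable directly by
#'   [ploughing_coefficient()] and [tangential_force()].  Extra
#'   components in `$fit`: per-angle means, residuals, `sse`, `sst`,
#'   `r_squared`, `f_statistic`, `df`, and a `branch` report with the
#'   first-branch phase and aliased `C3` values.
#' @examples
#' d <- plough_coefficients()
#' fit <- fit_anisotropy(d$theta_deg, d$fp)
#' coef(fit)                      # C1 ~ 0.294, C2 ~ 0.934
#' round(predict(fit, c(0, 45, 90)), 2)
#' @seealso [solve_three_angle()], [plough_coefficients()]
#' @export
fit_anisotropy <- function(theta, fp, theta0 = 0, fit_theta0 = FALSE) {
  if (length(theta) != length(fp))
    stop("'theta' and 'fp' must have the same length", call. = FALSE)
  check_angle(theta)
  if (any(!is.finite(fp)) || any(fp <= 0))
    stop("all 'fp' must be finite and strictly positive", call. = FALSE)
  angles <- sort(unique(theta))
  if (length(angles) < 3L)
    stop("need at least 3 distinct cutting angles", call. = FALSE)
  theta_max <- max(theta)

  basis <- function(C3) {
    if (fit_theta0) cbind(1, sin(C3 * theta), cos(C3 * theta))
    else cbind(1, sin(C3 * theta + theta0))
  }
  sse_of <- function(C3) {
    f <- stats::lm.fit(basis(C3), fp)
    sum(f$residuals^2)
  }
  upper <- pi / theta_max
  # coarse scan guards against multimodal profiles before the local refine
  grid <- seq(upper / 400, upper, length.out = 400)
  sse_grid <- vapply(grid, sse_of, numeric(1))
  j <- which.min(sse_grid)
  lo <- grid[max(1L, j - 1L)]
  hi <- grid[min(length(grid), j + 1L)]
  opt <- stats::optimize(sse_of, c(lo, hi), tol = 1e-12)
  C3 <- opt$minimum
  # the branch endpoint can beat the interior optimum on degenerate data
  if (sse_of(upper) < opt$objective) C3 <- upper
  lf <- stats::lm.fit(basis(C3), fp)
  cf <- unname(lf$coefficients)
  if (fit_theta0) {
    C1 <- cf[1]
    C2 <- sqrt(cf[2]^2 + cf[3]^2)
    theta0_hat <- atan2(cf[3], cf[2])
  } else {
    C1 <- cf[1]; C2 <- cf[2]; theta0_hat <- theta0
  }
  if (!is.finite(C2) || C2 < 0)
    stop("no feasible first-branch solution: the profiled optimum has a ",
         "nonpositive amplitude (C2 = ", format(C2),
         "); the orientation response does not rise on the first branch",
         call. = FALSE)

  resid <- unname(lf$residuals)
  n <- length(fp)
  sse <- sum(resid^2)
  sst <- sum((fp - mean(fp))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  n_par <- if (fit_theta0) 4L else 3L
  df_reg <- n_par - 1L
  df_res <- n - n_par
  fstat <- if (df_res > 0 && sse > 0)
    (max(sst - sse, 0) / df_reg) / (sse / df_res) else NA_real_

  means <- tapply(fp, theta, mean)
  phase_max <- C3 * theta_max + theta0_hat
  alias <- alias_phase_rates(C3, theta0_hat, theta_max)

  model <- anisotropy_model(C1 = C1, C2 = max(C2, .Machine$double.eps),
                            C3 = C3, theta0 = theta0_hat,
                            r_squared = if (is.na(r2)) NA_real_
                                        else max(0, min(1, r2)))
  grid <- seq(0, min(theta_max, 90), length.out = 181)
  if (any(sinusoid_factor(grid, model) <= 0))
    warning("fitted ploughing coefficient is not strictly positive over ",
            "[0, 90] degrees", call. = FALSE)
  model$fit <- list(n = n, angles = angles,
                    angle_means = as.numeric(means),
                    sse = sse, sst = sst,
                    df = c(regression = df_reg, residual = df_res),
                    f_statistic = fstat,
                    p_value = if (is.finite(fstat))
                      stats::pf(fstat, df_reg, df_res, lower.tail = FALSE)
                      else NA_real_,
                    residuals = resid,
                    rel_error_pct = 100 * abs(resid) / fp,
                    fit_theta0 = fit_theta0,
                    branch = list(phase_at_theta_max = phase_max,
                                  constraint = "0 < C3 * max(theta) <= pi",
                                  aliases = alias),
                    data = data.frame(theta = theta, fp = fp))
  class(model) <- c("anisotropy_fit", class(model))
  model
}

# phase-rate values equivalent to C3 at every multiple of the design's
# angle spacing (assumes the common 0/45/90-style grid: equivalence is
# reported at the max angle and its half)
alias_phase_rates <- function(C3, theta0, theta_max, k_max = 3L) {
  half <- theta_max / 2
  x <- C3 * half + theta0
  ks <- seq_len(k_max)
  same <- (x + 2 * pi * ks - theta0) / half
  reflected <- (pi - x + 2 * pi * ks - theta0) / half
  sort(c(same, reflected))
}

#' @export
print.anisotropy_fit <- function(x, ...) {
  cat("Anisotropy fit: fp(theta) = C1 + C2 * sin(C3 * theta + theta0)\n")
  cat(sprintf("  C1 = %.4g, C2 = %.4g, C3 = %.6g rad/deg, theta0 = %.4g\n",
              x$C1, x$C2, x$C3, x$theta0))
  cat(sprintf("  n = %d over angles {%s} deg; R^2 = %.4g\n",
              x$fit$n, paste(x$fit$angles, collapse = ", "), x$r_squared))
  cat(sprintf("  first-branch phase at max angle: %.4g rad (aliases of C3: %s, ...)\n",
              x$fit$branch$phase_at_theta_max,
              paste(format(utils::head(x$fit$branch$aliases, 2),
                           digits = 4), collapse = ", ")))
  invisible(x)
}

#' @export
coef.anisotropy_fit <- function(object, ...) {
  c(C1 = object$C1, C2 = object$C2, C3 = object$C3,
    theta0 = object$theta0)
}

#' @export
predict.anisotropy_fit <- function(object, newdata = NULL, ...) {
  theta <- if (is.null(newdata)) object$fit$data$theta
           else if (is.list(newdata)) newdata$theta
           else newdata
  ploughing_coefficient(theta, object)
}

#' @export
fitted.anisotropy_fit <- function(object, ...) {
  ploughing_coefficient(object$fit$data$theta, object)
}

#' @export
residuals.anisotropy_fit <- function(object, ...) object$fit$residuals

#' @export
summary.anisotropy_fit <- function(object, ...) {
  structure(list(fit = object,
                 diagnostics = regression_diagnostics(object)),
            class = "summary.anisotropy_fit")
}

#' @export
print.summary.anisotropy_fit <- function(x, ...) {
  print(x$fit)
  print(x$diagnostics)
  invisible(x)
}

#' @export
plot.anisotropy_fit <- function(x, ...) {
  d <- x$fit$data
  grid <- seq(0, max(d$theta), length.out = 200)
  graphics::plot(d$theta, d$fp, pch = 1,
                 xlab = "cutting angle theta (deg)",
                 ylab = "ploughing coefficient fp",
                 main = "Orientation response of the ploughing coefficient",
                 ...)
  graphics::lines(grid, ploughing_coefficient(grid, x), col = "red3",
                  lwd = 2)
  graphics::points(x$fit$angles, x$fit$angle_means, pch = 19)
  invisible(x)
}

#' Closed-form sinusoid calibration from three angle means
#'
#' Exact solver for the 0/45/90-degree design: given the mean ploughing
#' coefficients `m0`, `m45`, `m90` at cutting angles 0, 45 and 90
#' degrees and phase `theta0 = 0`, the model
#' \eqn{f_p(\theta) = C_1 + C_2 \sin(C_3\theta)} interpolating the three
#' means is
#' \deqn{C_1 = m_0,\quad \cos x = \frac{m_{90} - m_0}{2 (m_{45} - m_0)},
#'   \quad C_2 = \frac{m_{45} - m_0}{\sin x},\quad C_3 = x / 45,}
#' with `x = C3 * 45` (radians) taken on the first branch `(0, pi)`.
#' (The identity behind it: `sin(2x) = 2 sin(x) cos(x)`.)  This is the
#' independent oracle against which the iterative [fit_anisotropy()] is
#' checked on three-angle designs.
#'
#' Degenerate isotropic input (`m45 == m0` and `m90 == m0`) returns
#' `C2 = 0` with `C3 = NA`; otherwise `m45 > m0` is required (the
#' response must rise towards 45 degrees), and `|cos x| > 1` is reported
#' as infeasible.
#'
#' @param m0,m45,m90 Mean ploughing coefficients at 0, 45 and 90
#'   degrees.
#' @return A list with elements `C1`, `C2`, `C3` (radians per degree)
#'   and `phase45` (`= C3 * 45`, radians).
#' @examples
#' solve_three_angle(0.294, 1.218, 0.562)
#' @export
solve_three_angle <- function(m0, m45, m90) {
  stopifnot(is.numeric(m0), is.numeric(m45), is.numeric(m90))
  if (m45 == m0 && m90 == m0)
    return(list(C1 = m0, C2 = 0, C3 = NA_real_, phase45 = NA_real_))
  if (m45 <= m0)
    stop("infeasible three-mean system: the response must rise at 45 ",
         "degrees (m45 > m0)", call. = FALSE)
  cosx <- (m90 - m0) / (2 * (m45 - m0))
  if (abs(cosx) > 1)
    stop("infeasible three-mean system: |cos x| = ", format(abs(cosx)),
         " > 1; no sinusoid through these means", call. = FALSE)
  x <- acos(cosx)                        # first branch, (0, pi)
  list(C1 = m0, C2 = (m45 - m0) / sin(x), C3 = x / 45, phase45 = x)
}
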