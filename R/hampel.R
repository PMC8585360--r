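#' Hampel filter: robust outlier removal for force signals
#'
#' A rolling robust outlier detector for dynamometer traces.  For each
#' sample, the median and MAD of a window of `window` samples on either
#' side are computed; the sample is declared an outlier and replaced by
#' the window median when its deviation from that median exceeds
#' `k * 1.4826 * MAD` (1.4826 is the consistency constant that makes the
#' MAD estimate the standard deviation under Gaussian noise).  Spikes from
#' instrument/acquisition glitches are thereby removed without smoothing
#' the underlying signal.
#'
#' Edge handling: windows are truncated at the series ends — no values are
#' padded or fabricated, so the first and last samples are judged against
#' shorter one-sided windows.  When a window's MAD is exactly zero (a
#' locally constant signal), any nonzero deviation from the window median
#' is flagged.
#'
#' The default `window = 5` samples on either side corresponds to a
#' filtering spacing of 5 at the 1 kHz acquisition rate used for the
#' cutting trials; set `halfwidth = FALSE` to interpret `window` as the
#' total window width instead.
#'
#' @param x Numeric series; length must exceed `2 * window`.
#' @param window Window half-width in samples (or total width when
#'   `halfwidth = FALSE`); at least 1.
#' @param k MAD-multiple threshold (default 3).
#' @param halfwidth Logical; whether `window` is a half-width (default)
#'   or a total width.
#' @return A list with components `x` (the filtered series, same length
#'   as the input) and `outliers` (logical mask of replaced samples).
#' @examples
#' x <- c(5, 5, 5, 5, 5, 50, 5, 5, 5, 5, 5)
#' f <- hampel_filter(x)
#' f$x            # spike replaced by 5
#' which(f$outliers)
#' @export
hampel_filter <- function(x, window = 5, k = 3, halfwidth = TRUE) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("'x' must be a finite numeric series", call. = FALSE)
  if (!is.numeric(window) || length(window) != 1L || window < 1)
    stop("'window' must be a positive number of samples", call. = FALSE)
  w <- if (halfwidth) as.integer(window) else as.integer(window) %/% 2L
  if (w < 1L) stop("effective window half-width must be >= 1", call. = FALSE)
  if (k < 0) stop("'k' must be nonnegative", call. = FALSE)
  n <- length(x)
  if (n <= 2L * w)
    stop("series too short: length must exceed 2 * window", call. = FALSE)

  out <- x
  outliers <- logical(n)
  for (i in seq_len(n)) {
    win <- x[max(1L, i - w):min(n, i + w)]
    med <- stats::median(win)
    sigma <- 1.4826 * stats::median(abs(win - med))
    dev <- abs(x[i] - med)
    if (dev > k * sigma || (sigma == 0 && dev > 0)) {
      out[i] <- med
      outliers[i] <- TRUE
    }
  }
  list(x = out, outliers = outliers)
}
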