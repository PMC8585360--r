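#' Force trace from one ploughing trial
#'
#' Container for one dynamometer recording: a uniform time grid (1 kHz by
#' default in the cutting experiments) with simultaneous normal (`fz`)
#' and tangential (`fp`) force channels, plus the trial's design factors.
#'
#' @param time Time stamps, seconds; strictly increasing and uniform
#'   (spacing constant to within 1e-9 s); length at least 3.
#' @param fz Normal-force channel, N; same length as `time`.
#' @param fp Tangential-force channel, N; same length as `time`.
#' @param h Uncut chip thickness of the trial, mm.
#' @param theta Cutting angle of the trial, degrees.
#' @param speed Ploughing speed, mm/min.
#' @param replicate Replicate id.
#' @param trial_id Optional trial identifier string.
#' @param truth Optional ground-truth list (used by the synthetic
#'   generator to embed the noiseless plateau levels and engagement
#'   indices for testing).
#' @return An object of class `"force_trace"`.
#' @export
force_trace <- function(time, fz, fp, h = NA_real_, theta = NA_real_,
                        speed = NA_real_, replicate = NA_integer_,
                        trial_id = NULL, truth = NULL) {
  n <- length(time)
  if (n < 3L) stop("a force trace needs at least 3 samples", call. = FALSE)
  if (length(fz) != n || length(fp) != n)
    stop("'fz' and 'fp' must have the same length as 'time'", call. = FALSE)
  dt <- diff(time)
  if (any(dt <= 0)) stop("'time' must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-9)
    stop("'time' must be a uniform grid (spacing constant within 1e-9 s)",
         call. = FALSE)
  structure(list(time = as.numeric(time), fz = as.numeric(fz),
                 fp = as.numeric(fp),
                 meta = list(h = h, theta = theta, speed = speed,
                             replicate = replicate, trial_id = trial_id),
                 truth = truth),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  m <- x$meta
  cat(sprintf("Force trace: %d samples at %.6g Hz", length(x$time),
              1 / (x$time[2] - x$time[1])))
  if (!is.na(m$h))
    cat(sprintf(" (h = %g mm, theta = %g deg, replicate %s)",
                m$h, m$theta, as.character(m$replicate)))
  cat("\n")
  cat(sprintf("  Fz range: [%.4g, %.4g] N; Fp range: [%.4g, %.4g] N\n",
              min(x$fz), max(x$fz), min(x$fp), max(x$fp)))
  invisible(x)
}

#' Locate the steady-state cutting window of a trace
#'
#' Trials start and end with the tool out of the bone, so a trace has a
#' zero-force lead-in/out around the engaged stroke.  Engagement is
#' detected as the longest contiguous run of samples whose normal force
#' exceeds `threshold` times the trace's robust maximum (the 95th
#' percentile of `fz`, immune to residual spikes); the central
#' `1 - 2 * trim_fraction` portion of that run is returned as the
#' steady-state window, discarding entry/exit transients.
#'
#' @param trace A [force_trace()].
#' @param trim_fraction Fraction trimmed off each end of the engaged run;
#'   in `[0, 0.5)`.  Default 0.1 (keep the central 80 percent).
#' @param threshold Engagement threshold as a fraction of the robust
#'   maximum (default 0.1).
#' @return Named integer vector `c(start, end)` of sample indices.
#' @export
segment_steady_state <- function(trace, trim_fraction = 0.1,
                                 threshold = 0.1) {
  stopifnot(inherits(trace, "force_trace"))
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    stop("'trim_fraction' must lie in [0, 0.5)", call. = FALSE)
  fz <- trace$fz
  robust_max <- stats::quantile(fz, 0.95, names = FALSE, type = 7)
  if (!is.finite(robust_max) || robust_max <= 0)
    stop("no engaged region found: trace carries no positive normal force",
         call. = FALSE)
  engaged <- fz > threshold * robust_max
  runs <- rle(engaged)
  if (!any(runs$values))
    stop("no engaged region found above the engagement threshold",
         call. = FALSE)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- which(runs$values)
  best <- ok[which.max(runs$lengths[ok])]
  i0 <- starts[best]; i1 <- ends[best]
  m <- i1 - i0 + 1L
  drop <- as.integer(floor(trim_fraction * m))
  c(start = i0 + drop, end = i1 - drop)
}

#' Summarize one cutting trial
#'
#' Full per-trial preprocessing: both force channels are cleaned with the
#' Hampel filter ([hampel_filter()]), the steady-state cutting window is
#' located on the filtered normal force ([segment_steady_state()]), and
#' means/standard deviations over that window are reported together with
#' the observed ploughing coefficient `fp_observed = Fp_mean / Fz_mean`.
#'
#' @param trace A [force_trace()].
#' @param window,k Hampel filter parameters (see [hampel_filter()]).
#' @param trim_fraction Steady-state trim fraction (see
#'   [segment_steady_state()]).
#' @return An object of class `"trial_summary"`: a list with elements
#'   `h`, `theta`, `replicate`, `trial_id`, `fz_mean`, `fp_mean`,
#'   `fz_sd`, `fp_sd`, `fp_observed`, `n_used`, `window` (the retained
#'   index range).
#' @examples
#' nm <- calibrated_normal_model(); am <- calibrated_anisotropy_model()
#' tr <- generate_plough_trial(0.7, 45, nm, am,
#'                             design = experiment_design(sampling_hz = 200),
#'                             noise = noise_spec(sd = 0, seed = 1))
#' summarize_trial(tr)
#' @export
summarize_trial <- function(trace, window = 5, k = 3, trim_fraction = 0.1) {
  stopifnot(inherits(trace, "force_trace"))
  fz_f <- hampel_filter(trace$fz, window = window, k = k)
  fp_f <- hampel_filter(trace$fp, window = window, k = k)
  filtered <- trace
  filtered$fz <- fz_f$x
  filtered$fp <- fp_f$x
  win <- segment_steady_state(filtered, trim_fraction = trim_fraction)
  idx <- win["start"]:win["end"]
  fz_mean <- mean(fz_f$x[idx]); fp_mean <- mean(fp_f$x[idx])
  structure(list(h = trace$meta$h, theta = trace$meta$theta,
                 replicate = trace$meta$replicate,
                 trial_id = trace$meta$trial_id,
                 fz_mean = fz_mean, fp_mean = fp_mean,
                 fz_sd = stats::sd(fz_f$x[idx]),
                 fp_sd = stats::sd(fp_f$x[idx]),
                 fp_observed = fp_mean / fz_mean,
                 n_used = length(idx), window = win),
            class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf(
    "Trial summary (h = %g mm, theta = %g deg):\n", x$h, x$theta))
  cat(sprintf("  Fz = %.4g +/- %.3g N, Fp = %.4g +/- %.3g N (n = %d)\n",
              x$fz_mean, x$fz_sd, x$fp_mean, x$fp_sd, x$n_used))
  cat(sprintf("  observed ploughing coefficient: %.4g\n", x$fp_observed))
  invisible(x)
}

#' @export
as.data.frame.trial_summary <- function(x, ...) {
  data.frame(trial_id = if (is.null(x$trial_id)) NA_character_ else x$trial_id,
             h_mm = x$h, theta_deg = x$theta,
             replicate = x$replicate,
             fz_mean_n = x$fz_mean, fp_mean_n = x$fp_mean,
             fz_sd_n = x$fz_sd, fp_sd_n = x$fp_sd,
             fp_observed = x$fp_observed, n_used = x$n_used,
             stringsAsFactors = FALSE)
}

#' Summarize every trial of an experiment
#'
#' Applies [summarize_trial()] to a list of traces and stacks the results
#' into one data frame (one row per trial, in the summary-CSV column
#' layout).
#'
#' @param traces A list of [force_trace()] objects.
#' @inheritParams summarize_trial
#' @return A data frame with columns `trial_id`, `h_mm`, `theta_deg`,
#'   `replicate`, `fz_mean_n`, `fp_mean_n`, `fz_sd_n`, `fp_sd_n`,
#'   `fp_observed`, `n_used`.
#' @export
summarize_trials <- function(traces, window = 5, k = 3,
                             trim_fraction = 0.1) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  rows <- lapply(traces, function(tr)
    as.data.frame(summarize_trial(tr, window = window, k = k,
                                  trim_fraction = trim_fraction)))
  do.call(rbind, rows)
}

#' Read and write trace and summary CSV files
#'
#' Plain-CSV dialects for exchanging trials:
#' * trace CSV (one file per trial): columns `time_s`, `fz_n`, `fp_n`,
#'   header row required;
#' * manifest CSV: columns `trial_id`, `h_mm`, `theta_deg`,
#'   `speed_mm_min`, `replicate` (plus `seed` when written by the
#'   synthetic generator);
#' * summary CSV: the column layout of [summarize_trials()].
#'
#' @param trace A [force_trace()].
#' @param path File path.
#' @param h,theta,speed,replicate,trial_id Trial metadata attached on
#'   read (e.g. looked up from a manifest row).
#' @param summaries A summary data frame from [summarize_trials()].
#' @return Readers return the parsed object; writers return `path`
#'   invisibly.
#' @name trace_io
#' @export
write_force_trace <- function(trace, path) {
  stopifnot(inherits(trace, "force_trace"))
  utils::write.csv(data.frame(time_s = trace$time, fz_n = trace$fz,
                              fp_n = trace$fp),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_force_trace <- function(path, h = NA_real_, theta = NA_real_,
                             speed = NA_real_, replicate = NA_integer_,
                             trial_id = NULL) {
  d <- utils::read.csv(path)
  need <- c("time_s", "fz_n", "fp_n")
  if (!all(need %in% names(d)))
    stop("trace CSV must have columns time_s, fz_n, fp_n", call. = FALSE)
  force_trace(d$time_s, d$fz_n, d$fp_n, h = h, theta = theta,
              speed = speed, replicate = replicate, trial_id = trial_id)
}

#' @rdname trace_io
#' @export
write_trial_summaries <- function(summaries, path) {
  utils::write.csv(summaries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_trial_summaries <- function(path) {
  d <- utils::read.csv(path)
  need <- c("h_mm", "theta_deg", "fz_mean_n", "fp_mean_n", "fp_observed")
  if (!all(need %in% names(d)))
    stop("summary CSV is missing required columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  d
}

#' Read a simulated or recorded experiment directory
#'
#' Loads a `manifest.csv` plus its per-trial trace CSVs (as written by
#' [generate_experiment()] with `dir` set, or by [run_simulate()]).
#'
#' @param dir Directory containing `manifest.csv` and the trace files it
#'   names.
#' @return A list with elements `traces` (list of [force_trace()]) and
#'   `manifest` (data frame).
#' @export
read_experiment <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir, call. = FALSE)
  manifest <- utils::read.csv(mf)
  traces <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    read_force_trace(file.path(dir, paste0(row$trial_id, ".csv")),
                     h = row$h_mm, theta = row$theta_deg,
                     speed = row$speed_mm_min, replicate = row$replicate,
                     trial_id = row$trial_id)
  })
  list(traces = traces, manifest = manifest)
}
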