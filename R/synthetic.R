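#' Full-factorial ploughing experiment design
#'
#' Describes the cutting-trial design emulated by the synthetic
#' generator.  Defaults reproduce the reference experiment: uncut chip
#' thickness 0.5/0.6/0.7/0.8 mm crossed with cutting angles 0/45/90
#' degrees, five replicates per cell, a 10 mm stroke at 100 mm/min
#' (slow, to keep frictional heating negligible), sampled at 1 kHz.
#'
#' @param uct Uncut chip thickness levels, mm.
#' @param angles Cutting angle levels, degrees.
#' @param replicates Replicates per cell (>= 1).
#' @param stroke_mm Ploughing stroke length, mm.
#' @param speed_mm_min Ploughing speed, mm/min.
#' @param sampling_hz Sampling rate, Hz.
#' @param lead_s Zero-force lead-in/lead-out duration, s.
#' @param ramp_s Linear engagement ramp duration at each stroke edge, s.
#' @return An object of class `"experiment_design"`.
#' @examples
#' experiment_design()
#' experiment_design(sampling_hz = 200, replicates = 2)  # scaled down
#' @export
experiment_design <- function(uct = c(0.5, 0.6, 0.7, 0.8),
                              angles = c(0, 45, 90),
                              replicates = 5,
                              stroke_mm = 10, speed_mm_min = 100,
                              sampling_hz = 1000,
                              lead_s = 0.5, ramp_s = 0.05) {
  if (length(uct) < 1L || any(!is.finite(uct)) || any(uct <= 0))
    stop("'uct' must be a nonempty vector of positive depths", call. = FALSE)
  if (length(angles) < 1L)
    stop("'angles' must be a nonempty vector of cutting angles",
         call. = FALSE)
  check_angle(angles)
  for (nm in c("replicates", "stroke_mm", "speed_mm_min", "sampling_hz")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm),
           call. = FALSE)
  }
  if (replicates < 1) stop("'replicates' must be >= 1", call. = FALSE)
  if (lead_s < 0 || ramp_s < 0)
    stop("'lead_s' and 'ramp_s' must be nonnegative", call. = FALSE)
  structure(list(uct = uct, angles = angles,
                 replicates = as.integer(replicates),
                 stroke_mm = stroke_mm, speed_mm_min = speed_mm_min,
                 sampling_hz = sampling_hz, lead_s = lead_s,
                 ramp_s = ramp_s),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Full-factorial ploughing experiment design\n")
  cat(sprintf("  UCT levels (mm): %s; angles (deg): %s; %d replicates\n",
              paste(x$uct, collapse = "/"),
              paste(x$angles, collapse = "/"), x$replicates))
  cat(sprintf("  stroke %g mm at %g mm/min, sampled at %g Hz (%d trials)\n",
              x$stroke_mm, x$speed_mm_min, x$sampling_hz,
              length(x$uct) * length(x$angles) * x$replicates))
  invisible(x)
}

#' Instrument-noise specification for the synthetic generator
#'
#' Noise on the force channels is multiplicative log-normal (forces are
#' positive and instrument error scales with signal level):
#' `F = F_true * exp(eps)`, `eps ~ Normal(0, sd)`.  Occasional
#' acquisition glitches are emulated as isolated spikes that multiply the
#' signal by `spike_magnitude`.
#'
#' @param sd Standard deviation of the log-normal noise (default 0.01,
#'   i.e. about 1 percent).
#' @param spike_rate Expected spikes per 1000 samples of engaged signal
#'   (default 0).
#' @param spike_magnitude Spike multiplier (default 10).
#' @param seed Integer RNG seed; mandatory whenever `sd > 0` or
#'   `spike_rate > 0` so that every generated dataset is reproducible.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(sd = 0.01, spike_rate = 0, spike_magnitude = 10,
                       seed = NULL) {
  if (sd < 0 || spike_rate < 0 || spike_magnitude < 0)
    stop("noise parameters must be nonnegative", call. = FALSE)
  if ((sd > 0 || spike_rate > 0) && is.null(seed))
    stop("'seed' is mandatory for any nonzero randomness", call. = FALSE)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(sd = sd, spike_rate = spike_rate,
                 spike_magnitude = spike_magnitude, seed = seed),
            class = "noise_spec")
}

with_generator_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
  }
  expr
}

#' Generate synthetic indentation data
#'
#' Draws (volume, normal force) records from the calibrated power law:
#' volumes uniform on `v_range`, forces `Fz = C * V^alpha * exp(eps)`
#' with log-normal noise per [noise_spec()].  Deterministic given the
#' seed.
#'
#' @param nmodel A [normal_force_model()] acting as the generator.
#' @param v_range Volume interval, mm^3, within `(0, Inf)`.
#' @param n Number of records (>= 2).
#' @param noise A [noise_spec()].
#' @return A data frame with columns `V` and `Fz`; the generating
#'   coefficients are stored in `attr(, "truth")`.
#' @examples
#' d <- generate_indentation(calibrated_normal_model(), n = 100,
#'                           noise = noise_spec(sd = 0.01, seed = 1))
#' coef(fit_power_law(d$V, d$Fz))
#' @export
generate_indentation <- function(nmodel, v_range = c(0.05, 0.6), n = 1000,
                                 noise = noise_spec(sd = 0.01, seed = 1)) {
  stopifnot(inherits(nmodel, "normal_force_model"),
            inherits(noise, "noise_spec"))
  if (length(v_range) != 2L || any(!is.finite(v_range)) ||
      v_range[1] <= 0 || v_range[2] <= v_range[1])
    stop("'v_range' must be an increasing positive interval", call. = FALSE)
  if (n < 2L) stop("'n' must be at least 2", call. = FALSE)
  with_generator_seed(noise$seed, {
    V <- stats::runif(n, v_range[1], v_range[2])
    eps <- if (noise$sd > 0) stats::rnorm(n, 0, noise$sd) else 0
    out <- data.frame(V = V, Fz = empirical_normal_force(V, nmodel) *
                        exp(eps))
    attr(out, "truth") <- list(C = nmodel$C, alpha = nmodel$alpha,
                               sd = noise$sd, seed = noise$seed)
    out
  })
}

#' Generate one synthetic ploughing trial
#'
#' Emulates a dynamometer recording of one cutting pass: zero-force
#' lead-in, a linear engagement ramp, a plateau at the model forces
#' `Fz = C V(h)^alpha` and `Fp = fp(theta) * Fz` lasting
#' `stroke / speed`, a ramp out and a zero-force lead-out, with
#' per-sample multiplicative noise and optional injected spikes in the
#' plateau.  The noiseless plateau levels, the ploughing coefficient and
#' the engagement/plateau index ranges are embedded as ground truth in
#' `$truth` for pipeline testing; injected spikes never alter that
#' ground truth.
#'
#' @param h Uncut chip thickness, mm.
#' @param theta Cutting angle, degrees.
#' @param nmodel A [normal_force_model()].
#' @param amodel An [anisotropy_model()].
#' @param design An [experiment_design()] (stroke, speed, sampling and
#'   ramp/lead durations are used).
#' @param noise A [noise_spec()].
#' @param tool A [tool_geometry()] converting depth to volume.
#' @param replicate,trial_id Metadata stamped on the trace.
#' @return A [force_trace()].
#' @export
generate_plough_trial <- function(h, theta, nmodel, amodel,
                                  design = experiment_design(),
                                  noise = noise_spec(sd = 0.01, seed = 1),
                                  tool = tool_geometry(),
                                  replicate = 1L, trial_id = NULL) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(noise, "noise_spec"))
  check_depth(h); check_angle(theta)
  fs <- design$sampling_hz
  engaged_s <- design$stroke_mm / design$speed_mm_min * 60
  n_lead <- as.integer(round(design$lead_s * fs))
  n_engaged <- as.integer(round(engaged_s * fs))
  n_ramp <- min(as.integer(round(design$ramp_s * fs)), n_engaged %/% 2L)
  n_total <- 2L * n_lead + n_engaged

  fz_true <- empirical_normal_force(indentation_volume(h, tool), nmodel)
  fp_coef <- ploughing_coefficient(theta, amodel)
  fp_true <- fp_coef * fz_true

  envelope <- c(rep(0, n_lead),
                if (n_ramp > 0) seq_len(n_ramp) / n_ramp else numeric(0),
                rep(1, n_engaged - 2 * n_ramp),
                if (n_ramp > 0) rev(seq_len(n_ramp) / n_ramp) else numeric(0),
                rep(0, n_lead))

  with_generator_seed(noise$seed, {
    ez <- if (noise$sd > 0) exp(stats::rnorm(n_total, 0, noise$sd)) else 1
    ep <- if (noise$sd > 0) exp(stats::rnorm(n_total, 0, noise$sd)) else 1
    fz <- fz_true * envelope * ez
    fp <- fp_true * envelope * ep
    spikes <- integer(0)
    if (noise$spike_rate > 0) {
      plateau_idx <- (n_lead + n_ramp + 1L):(n_lead + n_engaged - n_ramp)
      n_spikes <- stats::rpois(1, noise$spike_rate * n_engaged / 1000)
      if (n_spikes > 0) {
        spikes <- sort(sample(plateau_idx, min(n_spikes,
                                               length(plateau_idx))))
        fz[spikes] <- fz[spikes] * noise$spike_magnitude
        fp[spikes] <- fp[spikes] * noise$spike_magnitude
      }
    }
    force_trace(time = (seq_len(n_total) - 1) / fs, fz = fz, fp = fp,
                h = h, theta = theta, speed = design$speed_mm_min,
                replicate = replicate, trial_id = trial_id,
                truth = list(fz_true = fz_true, fp_true = fp_true,
                             fp_coef = fp_coef,
                             engaged = c(n_lead + 1L, n_lead + n_engaged),
                             plateau = c(n_lead + n_ramp + 1L,
                                         n_lead + n_engaged - n_ramp),
                             spikes = spikes, seed = noise$seed))
  })
}

#' Generate a full synthetic ploughing experiment
#'
#' One [generate_plough_trial()] per design cell and replicate (the
#' default design yields 4 x 3 x 5 = 60 trials).  Each trial uses the
#' derived seed `noise$seed + i - 1` (trial index `i` in manifest
#' order), so the whole experiment is byte-for-byte reproducible from
#' `(design, models, noise)`.  With `dir` set, the trace CSVs, the
#' manifest CSV and a per-trial ground-truth JSON sidecar are written
#' there.
#'
#' @inheritParams generate_plough_trial
#' @param dir Optional output directory (created if missing).
#' @return A list with elements `traces` (list of [force_trace()]) and
#'   `manifest` (data frame with columns `trial_id`, `h_mm`,
#'   `theta_deg`, `speed_mm_min`, `replicate`, `seed`), invisibly when
#'   `dir` is given.
#' @examples
#' ex <- generate_experiment(design = experiment_design(sampling_hz = 100,
#'                                                      replicates = 1),
#'                           noise = noise_spec(sd = 0.01, seed = 42))
#' nrow(ex$manifest)   # 12 trials
#' @export
generate_experiment <- function(design = experiment_design(),
                                nmodel = calibrated_normal_model(),
                                amodel = calibrated_anisotropy_model(),
                                noise = noise_spec(sd = 0.01, seed = 1),
                                tool = tool_geometry(), dir = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  cells <- expand.grid(replicate = seq_len(design$replicates),
                       theta = design$angles, h = design$uct,
                       KEEP.OUT.ATTRS = FALSE)
  base_seed <- if (is.null(noise$seed)) NULL else noise$seed
  traces <- vector("list", nrow(cells))
  manifest <- data.frame(trial_id = sprintf("trial_%03d",
                                            seq_len(nrow(cells))),
                         h_mm = cells$h, theta_deg = cells$theta,
                         speed_mm_min = design$speed_mm_min,
                         replicate = cells$replicate,
                         seed = if (is.null(base_seed)) NA_integer_
                                else base_seed + seq_len(nrow(cells)) - 1L,
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cells))) {
    noise_i <- noise
    noise_i$seed <- if (is.null(base_seed)) NULL else manifest$seed[i]
    traces[[i]] <- generate_plough_trial(
      cells$h[i], cells$theta[i], nmodel, amodel, design = design,
      noise = noise_i, tool = tool, replicate = cells$replicate[i],
      trial_id = manifest$trial_id[i])
  }
  out <- list(traces = traces, manifest = manifest)
  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
      stop("cannot create output directory: ", dir, call. = FALSE)
    for (i in seq_along(traces)) {
      write_force_trace(traces[[i]],
                        file.path(dir, paste0(manifest$trial_id[i], ".csv")))
      jsonlite::write_json(traces[[i]]$truth,
                           file.path(dir, paste0(manifest$trial_id[i],
                                                 "_truth.json")),
                           auto_unbox = TRUE, digits = NA)
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
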