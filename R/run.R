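#' Validated run configuration for the pipeline drivers
#'
#' A single flat configuration drives the simulate/calibrate/predict
#' stages.  Unknown keys are rejected up front so typos cannot silently
#' fall back to defaults.  All defaults equal the reference-experiment
#' values, so the zero-override configuration reproduces the emulated
#' study conditions.
#'
#' Recognised keys and defaults:
#' \describe{
#'   \item{`input_dir`, `output_dir`}{paths (default `NULL`).}
#'   \item{`uct`, `angles`, `replicates`, `stroke_mm`, `speed_mm_min`,
#'     `sampling_hz`}{experiment design (see [experiment_design()]).}
#'   \item{`noise_sd`, `spike_rate`, `spike_magnitude`, `seed`}{noise
#'     model (see [noise_spec()]); `seed` defaults to 1.}
#'   \item{`window`, `k`, `trim_fraction`}{preprocessing parameters.}
#'   \item{`fit_method`}{`"loglog"` or `"nls"` for the power-law fit.}
#'   \item{`convention`}{`"canonical"` or `"literal"` ploughing
#'     coefficient convention.}
#'   \item{`model_config`}{path to a coefficient file (see
#'     [read_model_config()]); `NULL` means the reference calibrated
#'     coefficients.}
#'   \item{`verbose`}{logical.}
#' }
#'
#' @param ... Key-value overrides, or a single named list of them; or a
#'   path to a YAML/JSON file holding them.
#' @return A validated list of class `"run_config"`.
#' @examples
#' cfg <- run_config(sampling_hz = 200, replicates = 2, seed = 7)
#' cfg$seed
#' @export
run_config <- function(...) {
  defaults <- list(input_dir = NULL, output_dir = NULL,
                   uct = c(0.5, 0.6, 0.7, 0.8), angles = c(0, 45, 90),
                   replicates = 5, stroke_mm = 10, speed_mm_min = 100,
                   sampling_hz = 1000,
                   noise_sd = 0.01, spike_rate = 0, spike_magnitude = 10,
                   seed = 1L,
                   window = 5, k = 3, trim_fraction = 0.1,
                   fit_method = "loglog", convention = "canonical",
                   model_config = NULL, verbose = FALSE)
  args <- list(...)
  if (length(args) == 1L && is.null(names(args))) {
    arg <- args[[1]]
    if (is.character(arg) && length(arg) == 1L) {
      ext <- tolower(tools::file_ext(arg))
      arg <- if (ext == "json") jsonlite::read_json(arg,
                                                    simplifyVector = TRUE)
             else yaml::read_yaml(arg)
    }
    if (!is.list(arg)) stop("config must be a named list or a file path",
                            call. = FALSE)
    args <- arg
  }
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, args)
  # validation by the component constructors
  experiment_design(uct = cfg$uct, angles = cfg$angles,
                    replicates = cfg$replicates, stroke_mm = cfg$stroke_mm,
                    speed_mm_min = cfg$speed_mm_min,
                    sampling_hz = cfg$sampling_hz)
  noise_spec(sd = cfg$noise_sd, spike_rate = cfg$spike_rate,
             spike_magnitude = cfg$spike_magnitude, seed = cfg$seed)
  if (!cfg$fit_method %in% c("loglog", "nls"))
    stop("'fit_method' must be \"loglog\" or \"nls\"", call. = FALSE)
  if (!cfg$convention %in% c("canonical", "literal"))
    stop("'convention' must be \"canonical\" or \"literal\"", call. = FALSE)
  if (cfg$trim_fraction < 0 || cfg$trim_fraction >= 0.5)
    stop("'trim_fraction' must lie in [0, 0.5)", call. = FALSE)
  structure(cfg, class = "run_config")
}

config_design <- function(cfg) {
  experiment_design(uct = cfg$uct, angles = cfg$angles,
                    replicates = cfg$replicates, stroke_mm = cfg$stroke_mm,
                    speed_mm_min = cfg$speed_mm_min,
                    sampling_hz = cfg$sampling_hz)
}

config_models <- function(cfg) {
  if (!is.null(cfg$model_config)) {
    m <- read_model_config(cfg$model_config)
  } else {
    m <- list(normal = calibrated_normal_model(),
              anisotropy = calibrated_anisotropy_model())
  }
  m$anisotropy$convention <- cfg$convention
  m
}

echo_config <- function(cfg, dir) {
  jsonlite::write_json(unclass(cfg), file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

log_msg <- function(cfg, ...) {
  if (isTRUE(cfg$verbose)) message(...)
  invisible(NULL)
}

#' Pipeline drivers: simulate, calibrate, predict
#'
#' Thin configuration-driven wrappers over the package's stages,
#' mirroring how the cutting experiments are processed:
#'
#' * `run_simulate(cfg)` generates the full-factorial synthetic
#'   experiment into `cfg$output_dir` (trace CSVs, manifest, ground-truth
#'   sidecars, plus a `run_config.json` echo of the configuration used).
#' * `run_calibrate(cfg)` reads an experiment directory
#'   (`cfg$input_dir`; or a summary CSV at `cfg$input_dir` if it is a
#'   file), Hampel-filters and summarizes each trace, fits the anisotropy
#'   sinusoid to the observed ploughing coefficients, optionally fits the
#'   normal-force power law to an `indentation.csv` (columns `V`, `Fz`)
#'   found next to the traces, and writes a JSON + text report and a
#'   coefficient file (`model_config.json`, readable by
#'   [read_model_config()]) to `cfg$output_dir`.
#' * `run_predict(cfg, h =, theta =)` (or `V =`) evaluates the calibrated
#'   models at the requested conditions and returns the
#'   [tangential_force()] prediction.
#'
#' @param cfg A [run_config()] (or anything accepted by it).
#' @param h,V,theta Prediction conditions for `run_predict()`: depths in
#'   mm (converted through [indentation_volume()]) or volumes in mm^3,
#'   and cutting angles in degrees.
#' @return `run_simulate()`: the manifest data frame, invisibly.
#'   `run_calibrate()`: a list with `summaries`, `anisotropy_fit`,
#'   `power_law_fit` (or `NULL`), `error_table`, `report`, invisibly.
#'   `run_predict()`: a [tangential_force()] prediction data frame.
#' @name pipeline
#' @export
run_simulate <- function(cfg = run_config()) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  if (is.null(cfg$output_dir))
    stop("'output_dir' is required for run_simulate", call. = FALSE)
  parent <- dirname(cfg$output_dir)
  if (!dir.exists(parent))
    stop("cannot create output directory: parent path does not exist: ",
         parent, call. = FALSE)
  models <- config_models(cfg)
  design <- config_design(cfg)
  log_msg(cfg, "simulating ", length(design$uct) * length(design$angles) *
            design$replicates, " trials (seed ", cfg$seed, ")")
  ex <- generate_experiment(design, models$normal, models$anisotropy,
                            noise = noise_spec(sd = cfg$noise_sd,
                                               spike_rate = cfg$spike_rate,
                                               spike_magnitude =
                                                 cfg$spike_magnitude,
                                               seed = cfg$seed),
                            dir = cfg$output_dir)
  echo_config(cfg, cfg$output_dir)
  invisible(ex$manifest)
}

#' @rdname pipeline
#' @export
run_calibrate <- function(cfg = run_config()) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  if (is.null(cfg$input_dir))
    stop("'input_dir' is required for run_calibrate", call. = FALSE)

  if (dir.exists(cfg$input_dir)) {
    ex <- read_experiment(cfg$input_dir)
    log_msg(cfg, "summarizing ", length(ex$traces), " traces")
    summaries <- summarize_trials(ex$traces, window = cfg$window,
                                  k = cfg$k,
                                  trim_fraction = cfg$trim_fraction)
  } else if (file.exists(cfg$input_dir)) {
    summaries <- read_trial_summaries(cfg$input_dir)
  } else {
    stop("input not found: ", cfg$input_dir, call. = FALSE)
  }

  afit <- fit_anisotropy(summaries$theta_deg, summaries$fp_observed)
  afit$convention <- cfg$convention

  pfit <- NULL
  ind_path <- if (dir.exists(cfg$input_dir))
    file.path(cfg$input_dir, "indentation.csv") else ""
  if (nzchar(ind_path) && file.exists(ind_path)) {
    ind <- utils::read.csv(ind_path)
    pfit <- fit_power_law(ind$V, ind$Fz, method = cfg$fit_method)
  }

  nmodel <- if (is.null(pfit)) config_models(cfg)$normal else pfit
  etab <- error_rate_table(summaries, nmodel, afit)

  report <- list(
    anisotropy = list(coefficients = as.list(coef(afit)),
                      fp0 = afit$fp0, r_squared = afit$r_squared,
                      branch = afit$fit$branch,
                      angle_means = afit$fit$angle_means),
    power_law = if (is.null(pfit)) NULL else
      list(coefficients = as.list(coef(pfit)),
           r_squared = pfit$r_squared,
           f_statistic = pfit$fit$f_statistic),
    error_rates = etab$by_condition,
    settings = list(window = cfg$window, k = cfg$k,
                    trim_fraction = cfg$trim_fraction,
                    fit_method = cfg$fit_method,
                    convention = cfg$convention))

  if (!is.null(cfg$output_dir)) {
    if (!dir.exists(cfg$output_dir) &&
        !dir.create(cfg$output_dir, recursive = TRUE))
      stop("cannot create output directory: ", cfg$output_dir,
           call. = FALSE)
    jsonlite::write_json(report,
                         file.path(cfg$output_dir, "calibration.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows")
    write_model_config(nmodel, afit,
                       file.path(cfg$output_dir, "model_config.json"))
    write_trial_summaries(summaries,
                          file.path(cfg$output_dir, "summaries.csv"))
    txt <- c(utils::capture.output(print(afit)),
             if (!is.null(pfit)) utils::capture.output(print(pfit)),
             utils::capture.output(print(etab)))
    writeLines(txt, file.path(cfg$output_dir, "calibration.txt"))
    echo_config(cfg, cfg$output_dir)
  }
  invisible(list(summaries = summaries, anisotropy_fit = afit,
                 power_law_fit = pfit, error_table = etab,
                 report = report))
}

#' @rdname pipeline
#' @export
run_predict <- function(cfg = run_config(), h = NULL, V = NULL,
                        theta = 0) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  if (is.null(V)) {
    if (is.null(h))
      stop("supply either 'h' (mm) or 'V' (mm^3)", call. = FALSE)
    V <- indentation_volume(h)
  }
  models <- config_models(cfg)
  tangential_force(V, theta, models$normal, models$anisotropy)
}
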