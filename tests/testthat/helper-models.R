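# Shared fixtures: reference calibrated models and an independent
# brute-force Hampel oracle.

ref_normal <- function() normal_force_model(C = 707.53, alpha = 0.39)

ref_aniso <- function(convention = "canonical") {
  anisotropy_model(C1 = 0.294, C2 = 0.934, C3 = 0.45, theta0 = 0,
                   fp0 = 0.29, convention = convention)
}

# first-branch equivalent of the reference phase rate (exact three-mean
# solution of the bundled replicate data)
ref_aniso_firstbranch <- function() {
  s <- solve_three_angle(0.294, 1.218, 0.562)
  anisotropy_model(C1 = s$C1, C2 = s$C2, C3 = s$C3)
}

# Brute-force rolling median/MAD outlier oracle, written from the
# definition with its own sorting-based median.
naive_hampel <- function(x, w = 5, k = 3) {
  mid <- function(v) {
    s <- sort(v)
    L <- length(s)
    if (L %% 2 == 1) s[(L + 1) / 2] else (s[L / 2] + s[L / 2 + 1]) / 2
  }
  n <- length(x)
  out <- x
  mask <- logical(n)
  for (i in 1:n) {
    lo <- if (i - w < 1) 1 else i - w
    hi <- if (i + w > n) n else i + w
    win <- x[lo:hi]
    med <- mid(win)
    scale <- 1.4826 * mid(abs(win - med))
    if (abs(x[i] - med) > k * scale ||
        (scale == 0 && abs(x[i] - med) > 0)) {
      out[i] <- med
      mask[i] <- TRUE
    }
  }
  list(x = out, outliers = mask)
}

# small, fast design for pipeline tests (reduced sampling rate and leads;
# the generator's physics is rate-independent)
fast_design <- function(replicates = 2, sampling_hz = 100, ...) {
  experiment_design(replicates = replicates, sampling_hz = sampling_hz,
                    lead_s = 0.2, ...)
}
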