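test_that("indentation generator is deterministic and calibrated to its noise", {
  nm <- ref_normal()
  d1 <- generate_indentation(nm, n = 500,
                             noise = noise_spec(sd = 0.01, seed = 12))
  d2 <- generate_indentation(nm, n = 500,
                             noise = noise_spec(sd = 0.01, seed = 12))
  expect_identical(d1, d2)

  # noiseless points close the loop exactly
  d0 <- generate_indentation(nm, n = 50, noise = noise_spec(sd = 0))
  fit <- fit_power_law(d0$V, d0$Fz)
  expect_equal(fit$C, nm$C, tolerance = 1e-9)
  expect_equal(fit$alpha, nm$alpha, tolerance = 1e-9)

  # log-residual spread matches the requested 1% (chi-square bound on a
  # sample sd at n = 1000)
  d <- generate_indentation(nm, n = 1000,
                            noise = noise_spec(sd = 0.01, seed = 99))
  lres <- log(d$Fz) - log(empirical_normal_force(d$V, nm))
  expect_true(sd(lres) > 0.008 && sd(lres) < 0.012)

  expect_error(generate_indentation(nm, v_range = c(0.5, 0.1)),
               "interval")
  expect_error(noise_spec(sd = 0.01, seed = NULL), "seed")
})

test_that("a plough trial has the designed timing and plateau structure", {
  nm <- ref_normal(); am <- ref_aniso()
  tr <- generate_plough_trial(0.7, 45, nm, am,
                              noise = noise_spec(sd = 0, seed = NULL))
  # 10 mm stroke at 100 mm/min: 6 s engaged, 6000 samples at 1 kHz
  expect_identical(unname(diff(tr$truth$engaged)) + 1L, 6000L)
  # plateau exactly constant at the model forces
  plateau <- tr$truth$plateau[1]:tr$truth$plateau[2]
  expect_equal(unique(tr$fz[plateau]), tr$truth$fz_true, tolerance = 1e-12)
  expect_equal(unique(tr$fp[plateau]), tr$truth$fp_true, tolerance = 1e-12)
  expect_equal(tr$truth$fp_true / tr$truth$fz_true, tr$truth$fp_coef,
               tolerance = 1e-15)

  # plateau ratio across angles equals the coefficient ratio
  tr0 <- generate_plough_trial(0.7, 0, nm, am, design = fast_design(),
                               noise = noise_spec(sd = 0, seed = NULL))
  tr45 <- generate_plough_trial(0.7, 45, nm, am, design = fast_design(),
                                noise = noise_spec(sd = 0, seed = NULL))
  expect_equal(tr45$truth$fp_true / tr0$truth$fp_true,
               ploughing_coefficient(45, am) / ploughing_coefficient(0, am),
               tolerance = 1e-12)
})

test_that("spike injection marks the trace but never the embedded truth", {
  nm <- ref_normal(); am <- ref_aniso()
  mk <- function(rate) generate_plough_trial(
    0.6, 90, nm, am, design = fast_design(),
    noise = noise_spec(sd = 0.01, spike_rate = rate, seed = 404))
  clean <- mk(0); spiked <- mk(5)
  expect_identical(spiked$truth$fz_true, clean$truth$fz_true)
  expect_identical(spiked$truth$fp_true, clean$truth$fp_true)
  expect_identical(spiked$truth$plateau, clean$truth$plateau)
  expect_gt(length(spiked$truth$spikes), 0)
  expect_true(all(spiked$fz[spiked$truth$spikes] >
                    5 * clean$truth$fz_true))
})

test_that("the full factorial experiment is reproducible and complete", {
  nm <- ref_normal(); am <- ref_aniso()
  # default design arithmetic: 4 UCT x 3 angles x 5 replicates
  d <- experiment_design()
  expect_identical(length(d$uct) * length(d$angles) * d$replicates, 60L)
  expect_error(experiment_design(angles = numeric(0)), "nonempty")

  des <- fast_design(uct = c(0.5, 0.7), sampling_hz = 50)
  ex1 <- generate_experiment(des, nm, am,
                             noise = noise_spec(sd = 0.01, seed = 7))
  expect_identical(nrow(ex1$manifest), 2L * 3L * 2L)
  expect_identical(length(ex1$traces), 12L)

  # byte-identical CSV output from the same seed
  d1 <- tempfile(); d2 <- tempfile()
  generate_experiment(des, nm, am, noise = noise_spec(sd = 0.01, seed = 7),
                      dir = d1)
  generate_experiment(des, nm, am, noise = noise_spec(sd = 0.01, seed = 7),
                      dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
  # manifest names every trace written
  mf <- read.csv(file.path(d1, "manifest.csv"))
  expect_true(all(file.exists(file.path(d1, paste0(mf$trial_id, ".csv")))))
  back <- read_experiment(d1)
  expect_equal(back$traces[[3]]$fz, ex1$traces[[3]]$fz, tolerance = 1e-12)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("closed-loop pipeline recovers the generating coefficients, with bias shrinking as noise shrinks", {
  nm <- ref_normal(); am <- ref_aniso_firstbranch()
  err_at <- function(sd) {
    ex <- generate_experiment(fast_design(uct = 0.7, sampling_hz = 50),
                              nm, am, noise = noise_spec(sd = sd, seed = 1234))
    sm <- summarize_trials(ex$traces)
    fit <- fit_anisotropy(sm$theta_deg, sm$fp_observed)
    abs(fit$C1 - am$C1) + abs(fit$C2 - am$C2)
  }
  errs <- vapply(c(0.08, 0.01, 0.001), err_at, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[2])
  expect_lt(errs[3], 1e-3)

  # at the study's 1% noise with spikes, recovery lands within +/- 0.02
  ex <- generate_experiment(fast_design(), nm, am,
                            noise = noise_spec(sd = 0.01, spike_rate = 2,
                                               seed = 55))
  sm <- summarize_trials(ex$traces)
  fit <- fit_anisotropy(sm$theta_deg, sm$fp_observed)
  expect_lt(abs(fit$C1 - am$C1), 0.02)
  expect_lt(abs(fit$C2 - am$C2), 0.02)
})
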