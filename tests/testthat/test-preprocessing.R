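test_that("force_trace validates its grid and channels", {
  t <- seq(0, 1, by = 0.01)
  expect_s3_class(force_trace(t, t * 0 + 1, t * 0 + 2), "force_trace")
  expect_error(force_trace(t[1:2], 1:2, 1:2), "at least 3")
  expect_error(force_trace(t, t[-1], t), "same length")
  expect_error(force_trace(rev(t), t, t), "increasing")
  tj <- t; tj[5] <- tj[5] + 1e-4
  expect_error(force_trace(tj, t, t), "uniform")
})

test_that("steady-state segmentation excludes the lead-in/out and trims transients", {
  nm <- ref_normal(); am <- ref_aniso()
  tr <- generate_plough_trial(0.7, 45, nm, am, design = fast_design(),
                              noise = noise_spec(sd = 0, seed = NULL))
  win <- segment_steady_state(tr, trim_fraction = 0.1)
  # recovered window sits inside the generator's engaged region...
  expect_gte(win["start"], tr$truth$engaged[1])
  expect_lte(win["end"], tr$truth$engaged[2])
  # ...and the retained fraction is the central ~80% of the detected run
  run_len <- diff(tr$truth$engaged) + 1
  expect_equal(unname(diff(win) + 1) / run_len, 0.8, tolerance = 0.03)

  # fully engaged trace: central 80% of all samples
  t <- seq(0, 0.99, by = 0.01)
  flat <- force_trace(t, rep(10, 100), rep(5, 100))
  expect_identical(segment_steady_state(flat, 0.1),
                   c(start = 11L, end = 90L))

  # no engagement at all
  dead <- force_trace(t, rep(0, 100), rep(0, 100))
  expect_error(segment_steady_state(dead), "no engaged region")
  expect_error(segment_steady_state(flat, trim_fraction = 0.6),
               "trim_fraction")
})

test_that("noiseless trial summaries reproduce the generator truth exactly", {
  nm <- ref_normal(); am <- ref_aniso()
  tr <- generate_plough_trial(0.7, 45, nm, am, design = fast_design(),
                              noise = noise_spec(sd = 0, seed = NULL))
  s <- summarize_trial(tr)
  expect_equal(s$fz_mean, tr$truth$fz_true, tolerance = 1e-12)
  expect_equal(s$fp_mean, tr$truth$fp_true, tolerance = 1e-12)
  expect_equal(s$fp_observed, tr$truth$fp_coef, tolerance = 1e-12)
  expect_identical(s$fp_observed, s$fp_mean / s$fz_mean)
  expect_gte(s$n_used, 1)
})

test_that("noisy summaries stay within sampling error of the truth", {
  nm <- ref_normal(); am <- ref_aniso()
  tr <- generate_plough_trial(0.7, 45, nm, am, design = fast_design(),
                              noise = noise_spec(sd = 0.01, seed = 5))
  s <- summarize_trial(tr)
  # mean of n multiplicative 1% errors: sd of the mean ~ 0.01/sqrt(n)
  se <- 0.01 / sqrt(s$n_used)
  expect_lt(abs(s$fz_mean / tr$truth$fz_true - 1), 3 * se)
  expect_lt(abs(s$fp_observed / tr$truth$fp_coef - 1), 3 * sqrt(2) * se)
})

test_that("summaries are invariant to injected isolated spikes", {
  nm <- ref_normal(); am <- ref_aniso()
  clean <- generate_plough_trial(0.6, 0, nm, am, design = fast_design(),
                                 noise = noise_spec(sd = 0, seed = NULL))
  spiked <- clean
  idx <- seq(clean$truth$plateau[1] + 5, clean$truth$plateau[2] - 5,
             by = 37)
  spiked$fz[idx] <- spiked$fz[idx] * 12
  spiked$fp[idx] <- spiked$fp[idx] * 12
  s0 <- summarize_trial(clean)
  s1 <- summarize_trial(spiked)
  expect_equal(s1$fz_mean, s0$fz_mean, tolerance = 1e-12)
  expect_equal(s1$fp_mean, s0$fp_mean, tolerance = 1e-12)
  expect_equal(s1$fp_observed, s0$fp_observed, tolerance = 1e-12)
})

test_that("trace and summary CSVs round-trip", {
  nm <- ref_normal(); am <- ref_aniso()
  tr <- generate_plough_trial(0.5, 90, nm, am, design = fast_design(),
                              noise = noise_spec(sd = 0.01, seed = 9),
                              replicate = 2L, trial_id = "trial_x")
  path <- tempfile(fileext = ".csv")
  write_force_trace(tr, path)
  back <- read_force_trace(path, h = 0.5, theta = 90, replicate = 2L)
  expect_equal(back$fz, tr$fz, tolerance = 1e-12)
  expect_equal(back$fp, tr$fp, tolerance = 1e-12)
  expect_equal(back$meta$h, 0.5)
  unlink(path)

  sm <- summarize_trials(list(tr))
  expect_identical(nrow(sm), 1L)
  spath <- tempfile(fileext = ".csv")
  write_trial_summaries(sm, spath)
  sm2 <- read_trial_summaries(spath)
  expect_equal(sm2$fp_observed, sm$fp_observed, tolerance = 1e-12)
  unlink(spath)

  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_force_trace(bad), "columns")
  expect_error(read_trial_summaries(bad), "missing")
  unlink(bad)
})
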