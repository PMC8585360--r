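test_that("three-mean solver matches its defining algebra", {
  s <- solve_three_angle(0.294, 1.218, 0.562)
  expect_equal(s$C1, 0.294)
  expect_equal(s$C2, 0.9339, tolerance = 1e-4)
  expect_equal(s$phase45, 1.4253, tolerance = 1e-4)
  expect_equal(s$C3 * 45, s$phase45, tolerance = 1e-12)
  # interpolates all three means
  fp_hat <- s$C1 + s$C2 * sin(s$C3 * c(0, 45, 90))
  expect_equal(fp_hat, c(0.294, 1.218, 0.562), tolerance = 1e-12)

  # symmetric input: quarter-period phase, C2 = m45 - m0
  s2 <- solve_three_angle(0.3, 1.0, 0.3)
  expect_equal(s2$phase45, pi / 2, tolerance = 1e-12)
  expect_equal(s2$C2, 0.7, tolerance = 1e-12)

  # degenerate isotropic input
  s3 <- solve_three_angle(0.4, 0.4, 0.4)
  expect_equal(s3$C2, 0)
  expect_equal(s3$C1, 0.4)

  expect_error(solve_three_angle(0.5, 0.4, 0.6), "rise")
  # |cos x| > 1 is infeasible
  expect_error(solve_three_angle(0.3, 0.31, 0.9), "cos")
})

test_that("C2 magnitude is branch-invariant under the sign convention", {
  # both branches of acos give the same positive amplitude magnitude
  s <- solve_three_angle(0.294, 1.218, 0.562)
  x2 <- -acos((0.562 - 0.294) / (2 * (1.218 - 0.294)))  # mirrored branch
  expect_equal(abs((1.218 - 0.294) / sin(x2)), s$C2, tolerance = 1e-12)
})

test_that("exact sinusoidal data is recovered on the first branch", {
  C3_true <- 0.0316725
  th <- rep(c(0, 45, 90), each = 5)
  fp <- 0.294 + 0.934 * sin(C3_true * th)
  fit <- fit_anisotropy(th, fp)
  expect_equal(fit$C1, 0.294, tolerance = 1e-8)
  expect_equal(fit$C2, 0.934, tolerance = 1e-8)
  expect_equal(fit$C3, C3_true, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("least squares on a three-angle design equals the three-mean solver", {
  d <- plough_coefficients()
  fit <- fit_anisotropy(d$theta_deg, d$fp)
  means <- tapply(d$fp, d$theta_deg, mean)
  s <- solve_three_angle(means[["0"]], means[["45"]], means[["90"]])
  expect_equal(fit$C1, s$C1, tolerance = 1e-8)
  expect_equal(fit$C2, s$C2, tolerance = 1e-8)
  expect_equal(fit$C3, s$C3, tolerance = 1e-8)
  # fitted curve passes through the per-angle means within residual scatter
  expect_equal(unname(predict(fit, c(0, 45, 90))), as.numeric(means),
               tolerance = 1e-8)
  # first-branch constraint honoured, aliases reported
  expect_lte(fit$C3 * 90, pi)
  expect_gt(fit$C3, 0)
  aliases <- fit$fit$branch$aliases
  expect_true(any(abs(aliases - 0.45) < 0.05))  # the compact alias
})

test_that("phase aliasing: the conventional compact phase rate fits the design angles identically", {
  s <- solve_three_angle(0.294, 1.218, 0.562)
  th <- c(0, 45, 90)
  # 0.45 * 45 mod 2pi lands on the same first-branch phase region
  expect_equal(sin(0.45 * 45), sin(20.25 - 6 * pi), tolerance = 1e-12)
  expect_equal(0.294 + s$C2 * sin(s$C3 * th),
               0.294 + s$C2 * sin(s$phase45 * th / 45), tolerance = 1e-12)
})

test_that("anisotropy fit preconditions and infeasibility reporting", {
  expect_error(fit_anisotropy(c(0, 45), c(0.3, 1.2)), "same length|distinct")
  expect_error(fit_anisotropy(rep(c(0, 45), 3), rep(c(0.3, 1.2), 3)),
               "3 distinct")
  expect_error(fit_anisotropy(c(0, 45, 90), c(0.3, 1.2, -0.1)),
               "positive")
  # falling response: no rising first-branch sinusoid
  expect_error(fit_anisotropy(rep(c(0, 45, 90), 2),
                              rep(c(1.2, 0.6, 0.3), 2)),
               "first-branch|amplitude")
})

test_that("estimating the phase angle reproduces a shifted generator", {
  C3_true <- 0.02; th0_true <- 0.4
  th <- rep(c(0, 30, 60, 90), each = 3)
  fp <- 0.5 + 0.3 * sin(C3_true * th + th0_true)
  fit <- fit_anisotropy(th, fp, fit_theta0 = TRUE)
  expect_equal(fit$C1, 0.5, tolerance = 1e-6)
  expect_equal(fit$C2, 0.3, tolerance = 1e-6)
  expect_equal(fit$theta0, th0_true, tolerance = 1e-5)
  expect_equal(fit$C3, C3_true, tolerance = 1e-6)
})
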