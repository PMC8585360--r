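test_that("empirical power law evaluates, and is increasing and concave for alpha < 1", {
  nm <- ref_normal()
  expect_equal(empirical_normal_force(1, nm), 707.53)
  expect_identical(empirical_normal_force(0, nm), 0)
  expect_equal(empirical_normal_force(indentation_volume(0.7), nm),
               474.6, tolerance = 1e-3)

  V <- seq(0.01, 1, by = 0.01)
  Fz <- empirical_normal_force(V, nm)
  expect_true(all(diff(Fz) > 0))
  expect_true(all(diff(diff(Fz)) < 0))   # growth slows down

  expect_error(empirical_normal_force(-0.1, nm), "nonnegative")
  expect_error(normal_force_model(C = -1, alpha = 0.39), "positive")
  expect_error(normal_force_model(C = 1, alpha = 3.5), "alpha")
})

test_that("ploughing coefficient reproduces the calibrated orientation response", {
  am <- ref_aniso()
  # degree input, radian argument: the only convention matching the
  # measured endpoint coefficients
  expect_equal(round(ploughing_coefficient(0, am), 2), 0.29)
  expect_equal(round(ploughing_coefficient(45, am), 2), 1.21)
  # ordering across the design: smallest along the osteons, peak at 45
  fp <- ploughing_coefficient(c(0, 45, 90), am)
  expect_true(fp[1] < fp[3] && fp[3] < fp[2])
  expect_true(all(fp > 0))
  # the compact phase rate is an alias valid at the design angles; only
  # its first-branch equivalent is positive over the whole quadrant
  expect_true(all(ploughing_coefficient(seq(0, 90, by = 0.5),
                                        ref_aniso_firstbranch()) > 0))

  # isotropic limit
  iso <- anisotropy_model(C1 = 0.5, C2 = 0, C3 = 1)
  expect_equal(ploughing_coefficient(c(0, 30, 90), iso), rep(0.5, 3))

  # literal composed form scales by fp0
  lit <- ref_aniso("literal")
  expect_equal(ploughing_coefficient(45, lit),
               0.29 * ploughing_coefficient(45, am), tolerance = 1e-12)

  expect_error(ploughing_coefficient(-10, am), "\\[0, 180\\]")
  bad <- ref_aniso(); bad$convention <- "mystery"
  expect_error(ploughing_coefficient(45, bad), "convention")
})

test_that("shear stress and flank tangential force follow the sinusoid", {
  am <- ref_aniso()
  mat <- bone_material(tau_s = 3)
  # theta = theta0 = 0 gives C1 * tau_s
  expect_equal(shear_stress(0, am, mat), 0.294 * 3, tolerance = 1e-12)
  expect_equal(shear_stress(45, am, mat) / mat$tau_s, 1.2145,
               tolerance = 1e-4)

  expect_equal(physical_tangential_force(0.5, 0, am, mat), 0.2205,
               tolerance = 1e-4)
  expect_identical(physical_tangential_force(0, 45, am, mat), 0)
  # scales with h^2 and equals A_p * tau_p
  expect_equal(physical_tangential_force(1, 30, am, mat),
               4 * physical_tangential_force(0.5, 30, am, mat),
               tolerance = 1e-12)
  expect_equal(physical_tangential_force(0.6, 70, am, mat),
               indentation_state(0.6)$A_p * shear_stress(70, am, mat),
               tolerance = 1e-12)
})

test_that("tangential force prediction keeps the Fp = fp * Fz identity", {
  nm <- ref_normal(); am <- ref_aniso()
  pred <- tangential_force(indentation_volume(0.7), 45, nm, am)
  expect_equal(pred$Fp, 576.4, tolerance = 1e-3)
  expect_identical(pred$Fp, pred$fp * pred$Fz)

  # the identity holds to machine precision across conditions
  V <- rep(indentation_volume(c(0.5, 0.6, 0.7, 0.8)), each = 3)
  th <- rep(c(0, 45, 90), times = 4)
  pred <- tangential_force(V, th, nm, am)
  expect_identical(pred$Fp, pred$fp * pred$Fz)
  expect_equal(pred$Fp / empirical_normal_force(V, nm),
               ploughing_coefficient(th, am), tolerance = 1e-15)
  expect_true(all(pred$Fz >= 0 & pred$Fp >= 0))

  # zero volume, and the angle with maximal fp maximises Fp at fixed V
  expect_identical(tangential_force(0, 45, nm, am)$Fp, 0)
  grid <- tangential_force(rep(0.2, 91), 0:90, nm, am)
  expect_equal(grid$theta[which.max(grid$Fp)],
               grid$theta[which.max(grid$fp)])
})

test_that("model coefficients round-trip losslessly through JSON and YAML", {
  nm <- normal_force_model(C = 707.53, alpha = 0.39)
  am <- anisotropy_model(C1 = 0.294, C2 = 0.9338724478,
                         C3 = 0.03167247732, theta0 = 0, fp0 = 0.29)
  for (ext in c(".json", ".yaml")) {
    path <- tempfile(fileext = ext)
    write_model_config(nm, am, path)
    back <- read_model_config(path)
    expect_identical(back$normal$C, nm$C)
    expect_identical(back$normal$alpha, nm$alpha)
    expect_identical(back$anisotropy$C1, am$C1)
    expect_identical(back$anisotropy$C2, am$C2)
    expect_identical(back$anisotropy$C3, am$C3)
    expect_identical(back$anisotropy$fp0, am$fp0)
    expect_identical(back$anisotropy$convention, am$convention)
    unlink(path)
  }
  expect_error(read_model_config(tempfile(fileext = ".json")), "not found")
})
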