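test_that("effective diffusion time arithmetic", {
  expect_equal(effective_diffusion_time(400, 7), 400 - 7 / 3)
  expect_equal(display_diffusion_time(400, 7), 398)
  expect_equal(display_diffusion_time(20, 7), 18)
  expect_equal(display_diffusion_time(100, 7), 98)
  expect_error(effective_diffusion_time(2, 7), "positive")
})

test_that("b-value and gradient strength round-trip", {
  g <- aqpdwi:::g_from_b_value(1000, delta = 7, Delta = 100)
  b <- aqpdwi:::b_value_from_g(g, delta = 7, Delta = 100)
  expect_equal(b, 1000, tolerance = 1e-9)
  sch <- gradient_scheme(Delta = 100, delta = 7, b_values = c(0, 500, 1000))
  expect_equal(b_value(sch), c(0, 500, 1000), tolerance = 1e-9)
  sch2 <- gradient_scheme(Delta = 100, delta = 7, g = sch$g)
  expect_equal(sch2$b_values, c(0, 500, 1000), tolerance = 1e-9)
  expect_error(gradient_scheme(Delta = 100, delta = 7, g = sch$g,
                               b_values = c(0, 400, 1000)), "disagree")
  expect_error(gradient_scheme(Delta = 5, delta = 7, b_values = 100))
})

test_that("attenuation and MSD estimators recover a Gaussian ensemble", {
  sch <- gradient_scheme(Delta = 400, b_values = seq(0, 800, 100))
  D_true <- 1.1 # um^2 ms^-1
  set.seed(31)
  disp <- matrix(rnorm(6000 * 3, 0, sqrt(2 * D_true * sch$Delta_eff)), ncol = 3)
  res <- adc_from_trajectories(disp, sch)
  expect_s3_class(res, "adc_result")
  expect_equal(res$adc, 1100, tolerance = 0.05)
  expect_equal(res$adc_msd, 1100, tolerance = 0.05)
  expect_equal(res$adc_msd3d / res$adc_msd, 3, tolerance = 0.05)
  expect_lt(abs(res$adc - res$adc_msd), 3 * (res$standard_error +
                                               res$standard_error_msd))
  expect_gt(res$r_squared, 0.99)
  # vector input: no 3-D readout
  res_v <- adc_from_trajectories(disp[, 1], sch)
  expect_true(is.na(res_v$adc_msd3d))
  expect_equal(res_v$adc_msd, res$adc_msd)
})

test_that("adc_from_trajectories input validation", {
  sch <- gradient_scheme(Delta = 400, b_values = c(0, 500))
  expect_error(adc_from_trajectories(rnorm(50), sch), "at least 100 walkers")
  # a phase-inverted ensemble (E <= 0) is refused deterministically
  sch1 <- gradient_scheme(Delta = 400, b_values = 1000)
  k <- sqrt(1000 * 1e6 / (sch1$Delta_eff / 1000)) * 1e-6 # rad um^-1
  expect_error(
    adc_from_trajectories(rep(pi / k, 500), sch1),
    "non-positive echo attenuation")
})

test_that("decay-curve ADC fit round-trips exactly without noise", {
  cur <- gen_decay_curve(adc_true = 754.3, S0 = 87,
                         b_values = seq(0, 800, 100))
  fit <- adc_from_decay(cur)
  expect_equal(fit$adc, 754.3, tolerance = 1e-10)
  expect_equal(fit$intercept_S0, 87, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # two-point curve
  cur2 <- decay_curve(c(0, 800), c(100, 100 * exp(-800e-6 * 1250)))
  expect_equal(adc_from_decay(cur2)$adc, 1250, tolerance = 1e-10)
  # weighted variant agrees on noiseless data
  expect_equal(adc_from_decay(cur, weighted = TRUE)$adc, 754.3,
               tolerance = 1e-10)
})

test_that("decay fit is invariant to rescaling and validates input", {
  cur <- gen_decay_curve(500, S0 = 1, b_values = seq(0, 800, 200))
  scaled <- decay_curve(cur$b_values, cur$signals * 1e4)
  expect_equal(adc_from_decay(scaled)$adc, adc_from_decay(cur)$adc,
               tolerance = 1e-12)
  expect_error(adc_from_decay(decay_curve(c(100, 100), c(1, 1))),
               "2 distinct b-values")
  expect_error(adc_from_decay(decay_curve(c(0, 500), c(1, -0.1))),
               "positive")
})

test_that("decay curves round-trip through CSV", {
  cur <- gen_decay_curve(421.7, S0 = 50, b_values = seq(0, 800, 100),
                         noise = noise_model("GAUSSIAN", 0.5), seed = 3)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_decay_csv(cur, path)
  back <- read_decay_csv(path)
  expect_equal(back$b_values, cur$b_values)
  expect_equal(back$signals, cur$signals, tolerance = 1e-12)
})

test_that("ADC result printing reports both estimators", {
  sch <- gradient_scheme(Delta = 400, b_values = seq(0, 800, 200))
  set.seed(2)
  res <- adc_from_trajectories(matrix(rnorm(900, 0, 20), ncol = 3), sch)
  expect_output(print(res), "ADC:")
  expect_output(print(res), "MSD estimator")
})
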