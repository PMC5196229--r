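# small synthetic sweep table used for inversion unit tests
mk_sweep <- function(P = c(0.03, 0.1, 0.3, 0.6), adc = c(380, 480, 640, 700),
                     Delta_eff = 398) {
  out <- data.frame(axis = P, Delta_eff = Delta_eff, adc = adc, adc_se = 5,
                    adc_msd = adc, n_walkers = 1000L, seed = 1L)
  class(out) <- c("sweep_table", "data.frame")
  attr(out, "axis_kind") <- "permeability"
  out
}

test_that("inversion returns grid points and midpoints exactly", {
  sw <- mk_sweep()
  expect_equal(invert_adc_to_permeability(480, sw), 0.1)
  expect_equal(invert_adc_to_permeability(380, sw), 0.03)
  # midway between two grid ADCs -> midway P under linear interpolation
  expect_equal(invert_adc_to_permeability((480 + 640) / 2, sw), (0.1 + 0.3) / 2)
  # vectorised
  expect_equal(invert_adc_to_permeability(c(380, 700), sw), c(0.03, 0.6))
})

test_that("inversion smooths Monte Carlo noise monotonically", {
  sw <- mk_sweep(adc = c(380, 500, 495, 700)) # non-monotone wiggle
  p <- invert_adc_to_permeability(497.5, sw)
  expect_gte(p, 0.1)
  expect_lte(p, 0.3)
})

test_that("inversion refuses extrapolation and reports bracketing values", {
  sw <- mk_sweep()
  expect_error(invert_adc_to_permeability(1084, sw),
               "outside simulated range \\[380, 700\\]")
  expect_error(invert_adc_to_permeability(100, sw), "outside simulated range")
  expect_error(invert_adc_to_permeability(480, sw, Delta_eff = 18),
               "does not cover")
  # opt-in clamping returns the grid endpoint with a warning
  expect_warning(p <- invert_adc_to_permeability(1084, sw,
                                                 out_of_range = "clamp"),
                 "bound")
  expect_equal(p, 0.6)
  expect_warning(p0 <- invert_adc_to_permeability(100, sw,
                                                  out_of_range = "clamp"))
  expect_equal(p0, 0.03)
})

test_that("permeability sweep produces a well-formed, ordered table", {
  sw <- permeability_sweep(c(0.034, 0.39), Delta_values = 100,
                           sim_config = list(n_walkers = 600), seed = 5)
  expect_s3_class(sw, "sweep_table")
  expect_equal(nrow(sw), 2)
  expect_equal(sw$axis, c(0.034, 0.39))
  expect_equal(sw$Delta_eff, rep(100 - 7 / 3, 2))
  expect_true(all(sw$adc > 0))
  expect_true(all(sw$adc_se > 0))
  # higher permeability diffuses faster, well beyond Monte Carlo noise
  expect_gt(sw$adc[2] - sw$adc[1], 2 * sqrt(sum(sw$adc_se^2)))
  # reproducible
  sw2 <- permeability_sweep(c(0.034, 0.39), Delta_values = 100,
                            sim_config = list(n_walkers = 600), seed = 5)
  expect_equal(sw$adc, sw2$adc)
})

test_that("fraction sweep endpoints match uniform-permeability simulations", {
  base <- list(n_walkers = 600)
  fr <- fraction_sweep(c(0, 1), n_arrangements = 3, Delta = 100,
                       sim_config = base, seed = 11)
  expect_equal(nrow(fr), 2)
  un <- permeability_sweep(c(0.039, 0.14), Delta_values = 100,
                           sim_config = base, seed = 12)
  expect_lt(abs(fr$adc[1] - un$adc[1]),
            2 * sqrt(fr$adc_se[1]^2 + un$adc_se[1]^2) + 1e-9)
  expect_lt(abs(fr$adc[2] - un$adc[2]),
            2 * sqrt(fr$adc_se[2]^2 + un$adc_se[2]^2) + 1e-9)
  expect_gt(fr$adc[2], fr$adc[1])
})

test_that("expression arithmetic reproduces the worked numbers", {
  est <- permeability_to_concentration(0.55)
  expect_equal(est$volumetric_flow, 209)
  expect_equal(est$channels_per_cell, 209 / 6e-5)
  expect_equal(est$concentration_uM, 8.3, tolerance = 0.01)
  est_big <- permeability_to_concentration(0.55, cell_volume = 1317)
  expect_equal(est_big$concentration_uM, 4.4, tolerance = 0.01)
  expect_equal(permeability_to_concentration(0)$concentration_uM, 0)
  expect_output(print(est), "channels/cell")
})

test_that("expression estimate is linear in P and inverse in conductance", {
  c1 <- permeability_to_concentration(0.1)$concentration_uM
  c2 <- permeability_to_concentration(0.2)$concentration_uM
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
  half <- permeability_to_concentration(0.1,
                                        unit_conductance = 1.2e-4)$concentration_uM
  expect_equal(half, c1 / 2, tolerance = 1e-12)
  expect_error(permeability_to_concentration(0.1, surface_area = -1))
})

test_that("low-dose extrapolation reproduces 457 nM", {
  expect_equal(extrapolate_low_dose_concentration(2.54, 0.18), 457.2)
  expect_equal(extrapolate_low_dose_concentration(), 457.2)
})

test_that("derived seeds are valid R seeds and deterministic", {
  s <- vapply(1:200, function(i) aqpdwi:::derive_seed(123, i), numeric(1))
  expect_true(all(s >= 1 & s < 2^31))
  expect_equal(s, vapply(1:200, function(i) aqpdwi:::derive_seed(123, i),
                         numeric(1)))
  expect_false(aqpdwi:::derive_seed(1, 1) == aqpdwi:::derive_seed(2, 1))
})
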