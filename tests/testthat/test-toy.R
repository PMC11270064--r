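test_that("toy resting potential follows the chord-conductance closed form", {
  m <- toy_model(gK = 0.9, gNaL = 0.1, EK = -90, ENa = 60)
  expect_equal(toy_resting_potential(m), -75)
  out <- osmoAP:::ode_segment(m, m$init, c(0, 1000), NULL, 0, 1e-8, 1e-8)
  expect_equal(unname(out[nrow(out), 2]), -75, tolerance = 0.05)
  # without the Na+ leak the cell rests at EK exactly
  m0 <- toy_model(gNaL = 0)
  expect_equal(toy_resting_potential(m0), -90)
  out0 <- osmoAP:::ode_segment(m0, m0$init, c(0, 1000), NULL, 0, 1e-8, 1e-8)
  expect_equal(unname(out0[nrow(out0), 2]), -90, tolerance = 0.05)
  expect_error(toy_model(gK = 0), "gK")
  expect_error(toy_model(gReg = -1), "non-negative")
})

test_that("bisection threshold agrees with an exhaustive grid search", {
  m <- toy_model()
  amps <- seq(0.5, 100, by = 0.25)
  oracle <- grid_threshold(m, m$init, NULL, amps)
  thr <- find_threshold(m, m$init, rel_tol = 0.002)
  expect_lte(abs(thr$ith - oracle), 0.25)
  expect_true(thr$bracket["sub"] < thr$ith)
  expect_true(thr$ith <= thr$bracket["supra"])
})

test_that("threshold is independent of the initial bracket", {
  m <- toy_model()
  t1 <- find_threshold(m, m$init, bracket = c(1, 60))
  t2 <- find_threshold(m, m$init, bracket = c(0.2, 500))
  t3 <- find_threshold(m, m$init, bracket = c(30, 31))
  expect_equal(t2$ith, t1$ith, tolerance = 0.01)
  expect_equal(t3$ith, t1$ith, tolerance = 0.01)
})

test_that("zero amplitude never fires; halving the regenerative conductance raises Ith", {
  m <- toy_model()
  out <- osmoAP:::ode_segment(m, m$init, seq(0, 50, 0.5), NULL, 0, 1e-8, 1e-8)
  expect_lt(max(out[, 2]), 0)
  half <- toy_model(gReg = 2.5)
  th_full <- find_threshold(m, m$init)$ith
  th_half <- find_threshold(half, half$init)$ith
  expect_gt(th_half, th_full)
  # oracle confirms on the halved model too
  oracle <- grid_threshold(half, half$init, NULL, seq(0.5, 200, by = 0.25))
  expect_lte(abs(th_half - oracle), 0.25)
})

test_that("strict bracketing mode reports invalid brackets", {
  m <- toy_model()
  th <- find_threshold(m, m$init)$ith
  expect_error(find_threshold(m, m$init, bracket = c(2 * th, 4 * th),
                              expand = FALSE), "both ends fire")
  expect_error(find_threshold(m, m$init, bracket = c(th / 8, th / 4),
                              expand = FALSE), "neither end fires")
})

test_that("toy hypernatremia sweep: rest hyperpolarizes and Ith rises with level", {
  sw <- toy_condition_sweep(c(0, 0.1, 0.2, 0.5))
  expect_equal(sw$rmp[1], toy_resting_potential(toy_model()), tolerance = 0.05)
  expect_true(all(diff(sw$rmp) < 0))
  expect_true(all(diff(sw$rmp_closed_form) < 0))
  expect_true(all(diff(sw$ith) > 0))
  expect_equal(sw$rmp, sw$rmp_closed_form, tolerance = 0.1)
})
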