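test_that("nernst matches closed-form arithmetic and rejects bad input", {
  expect_equal(nernst(1, 5, 5), 0)
  expect_equal(nernst(1, 10, 1, 310), 61.5, tolerance = 1e-3)
  expect_equal(nernst(1, 5.4, 144, 310), -87.7, tolerance = 1e-3)
  expect_equal(nernst(2, 10, 1, 310), nernst(1, 10, 1, 310) / 2)
  expect_error(nernst(0, 5, 5), "valence")
  expect_error(nernst(1, -1, 5), "positive")
})

test_that("synthetic AP train recovers its closed-form biomarkers", {
  tr <- synthetic_ap_trace(rest = -85, peak = 35, apd90_true = 300,
                           rate = 60, beats = 5, dt = 0.1)
  truth <- attr(tr, "truth")
  b <- ap_biomarkers(tr)
  expect_equal(b$rmp, -85)
  expect_equal(b$apa, 120, tolerance = 0.01)
  expect_equal(b$apd90, 300, tolerance = 0.3)      # within ~one sample step
  expect_equal(b$apd50, truth$apd50, tolerance = 0.3)
  expect_equal(b$dvdt_max, truth$dvdt_max, tolerance = 0.01 * truth$dvdt_max)
  ca <- calcium_biomarkers(tr)
  expect_equal(ca$ca_peak, truth$ca_peak, tolerance = 1e-3)
  expect_equal(ca$ca_diastolic, truth$ca_diastolic, tolerance = 1e-6)
})

test_that("last-beat rule: one beat gives the same biomarkers as five", {
  b1 <- ap_biomarkers(synthetic_ap_trace(beats = 1))
  b5 <- ap_biomarkers(synthetic_ap_trace(beats = 5))
  for (nm in names(b1))   # identical to within one sample step
    expect_equal(b1[[nm]], b5[[nm]], tolerance = 1e-3, info = nm)
})

test_that("biomarkers are invariant under time shift and supersampling", {
  b0 <- ap_biomarkers(synthetic_ap_trace(beats = 3, t0 = 0))
  bs <- ap_biomarkers(synthetic_ap_trace(beats = 3, t0 = 1375.5))
  expect_equal(bs, b0)
  bf <- ap_biomarkers(synthetic_ap_trace(beats = 3, dt = 0.025))
  for (nm in names(b0))
    expect_equal(bf[[nm]], b0[[nm]], tolerance = 1e-3, info = nm)
})

test_that("a constant trace raises a no-AP error", {
  expect_error(ap_biomarkers(flat_trace(-85)), "no action potential")
})

test_that("a trace without a calcium series raises an error", {
  tr <- synthetic_ap_trace(beats = 2)
  tr$states <- tr$states[, c("vm", "nai", "ki")]
  expect_error(calcium_biomarkers(tr), "Ca2\\+ series")
})

test_that("quasi-steady check: exact repetition passes, a drifting [Na+]i fails", {
  tr <- synthetic_ap_trace(beats = 4)
  qs <- quasi_steady_check(tr)
  expect_true(qs$steady)
  expect_lt(qs$delta_apd90, 1e-3)   # sample-step jitter only
  expect_equal(qs$delta_nai, 0)
  # impose a 1% per beat linear drift on [Na+]i
  tr$states[, "nai"] <- 12 * (1 + 0.01 * tr$time / tr$cl)
  qs2 <- quasi_steady_check(tr)
  expect_false(qs2$steady)
  expect_gt(qs2$delta_nai, 0.005)
  expect_error(quasi_steady_check(synthetic_ap_trace(beats = 1)),
               "at least 2")
})
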