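test_that("scaling factors lie on the anchor lines and reproduce the parameter table", {
  # the full published settings: per level, {ICaL, IKr, IKs, IK1, INaCa, INaK}
  expected <- list(
    `0` = c(1, 1, 1, 1, 1, 1),
    `0.1` = c(1, 0.920, 0.900, 1, 1.077, 0.867),
    `0.2` = c(1, 0.840, 0.800, 1, 1.153, 0.733),
    `0.5` = c(1, 0.600, 0.500, 1, 1.383, 0.333))
  for (lvl in names(expected)) {
    f <- scaling_factors(as.numeric(lvl))
    expect_equal(round(unname(unclass(f)), 3), expected[[lvl]],
                 info = paste("level", lvl))
  }
  # anchors themselves, plus the hand-derived 30% line values for IKr/IKs
  f30 <- scaling_factors(0.3)
  expect_equal(round(f30[["f_INaCa"]], 2), 1.23)
  expect_equal(round(f30[["f_INaK"]], 2), 0.60)
  expect_equal(round(f30[["f_IKr"]], 2), 0.76)
  expect_equal(round(f30[["f_IKs"]], 2), 0.70)
})

test_that("scaling factor errors: negative level and non-positive extrapolation", {
  expect_error(scaling_factors(-0.1), "level")
  # the IKs line 1 - level reaches zero at level 1
  expect_error(scaling_factors(1.2), "f_IKs.*<= 0")
})

test_that("milieu perturbation adds NaCl equimolarly", {
  bps <- baseline_milieu("BPS2020")
  expect_equal(unname(unclass(bps)), c(144, 5.4, 2.7, 154.8))
  # baseline Cl- from cation charge balance
  expect_equal(bps[["cl_e"]], bps[["na_e"]] + bps[["k_e"]] + 2 * bps[["ca_e"]])
  p <- perturbed_milieu(0.5, bps)
  expect_equal(unname(unclass(p)), c(216, 5.4, 2.7, 226.8))
  expect_equal(unclass(perturbed_milieu(0, bps)), unclass(bps))
  tor <- baseline_milieu("ToRORd")
  p2 <- perturbed_milieu(0.2, tor)
  expect_equal(p2[["na_e"]], 168)
  expect_equal(p2[["cl_e"]], 178)
  expect_equal(p2[["k_e"]], 5.0)
  expect_equal(p2[["ca_e"]], 1.8)
  expect_error(perturbed_milieu(-0.1, tor), "level")
})

test_that("relative cell volume reproduces the printed values to two decimals", {
  tor <- baseline_milieu("ToRORd")
  bps <- baseline_milieu("BPS2020")
  expect_equal(round(100 * volume_fraction(0.1, tor), 2), 94.14)
  expect_equal(round(100 * volume_fraction(0.2, tor), 2), 89.21)
  expect_equal(round(100 * volume_fraction(0.5, tor), 2), 78.21)
  expect_equal(round(100 * volume_fraction(0.1, bps), 2), 94.17)
  expect_equal(round(100 * volume_fraction(0.2, bps), 2), 89.25)
  expect_equal(round(100 * volume_fraction(0.5, bps), 2), 78.28)
  expect_equal(volume_fraction(0, tor), 1)
  expect_equal(volume_fraction(0, bps), 1)
})

test_that("volume is decreasing, gain increasing, and solute amount is conserved", {
  tor <- baseline_milieu("ToRORd")
  levels <- seq(0, 0.8, by = 0.05)
  v <- vapply(levels, volume_fraction, numeric(1), baseline = tor)
  g <- vapply(levels, shrinkage_concentration_gain, numeric(1), baseline = tor)
  expect_true(all(diff(v) < 0))
  expect_true(all(diff(g) > 0))
  expect_equal(v[1], 1); expect_equal(g[1], 0)
  # (v - inactive) * osm(level) = (1 - inactive) * osm0 exactly
  osm0 <- osmolarity(tor)
  osml <- osm0 * (1 + g)
  expect_equal((v - 0.32) * osml, rep((1 - 0.32) * osm0, length(v)))
})

test_that("active-volume concentration gain matches the stated examples", {
  tor <- baseline_milieu("ToRORd")
  bps <- baseline_milieu("BPS2020")
  expect_equal(round(shrinkage_concentration_gain(0.5, tor), 2), 0.47)
  expect_equal(shrinkage_concentration_gain(0, tor), 0)
  expect_equal(shrinkage_concentration_gain(0.1, bps), 2 * 0.1 * 144 / 306.9,
               tolerance = 1e-12)
})

test_that("build_condition honours toggles and the ICaL scenario", {
  cc <- hypernatremia_condition(0.5, "BPS2020")
  expect_equal(round(unname(unclass(cc$factors)), 3),
               c(1, 0.600, 0.500, 1, 1.383, 0.333))
  expect_equal(round(100 * cc$volume_fraction, 2), 78.28)

  noscale <- hypernatremia_condition(0.5, "BPS2020",
                                     apply_current_scaling = FALSE)
  expect_true(all(unclass(noscale$factors) == 1))
  expect_equal(round(100 * noscale$volume_fraction, 2), 78.28)
  expect_equal(unclass(noscale$milieu), unclass(cc$milieu))

  noshrink <- hypernatremia_condition(0.5, "ToRORd", apply_shrinkage = FALSE)
  expect_equal(noshrink$volume_fraction, 1)
  expect_equal(noshrink$concentration_gain, 0)
  expect_equal(unclass(noshrink$factors), unclass(
    hypernatremia_condition(0.5, "ToRORd")$factors))

  ical <- hypernatremia_condition(0.5, "ToRORd", icl_scenario = 1.45)
  expect_equal(ical$factors[["f_ICaL"]], 1.45)
  expect_equal(ical$factors[["f_IKr"]],
               hypernatremia_condition(0.5, "ToRORd")$factors[["f_IKr"]])

  expect_error(hypernatremia_condition(0.5, "nosuchmodel"), "unknown model")
  expect_error(hypernatremia_condition(0.5, "ToRORd", icl_scenario = -1),
               "icl_scenario")

  # double ablation at any level reduces to a milieu-only perturbation,
  # and equals baseline exactly at level 0
  both_off <- hypernatremia_condition(0.3, "ToRORd",
                                      apply_shrinkage = FALSE,
                                      apply_current_scaling = FALSE)
  expect_true(all(unclass(both_off$factors) == 1))
  expect_equal(both_off$volume_fraction, 1)
  expect_equal(unclass(both_off$milieu),
               unclass(perturbed_milieu(0.3, baseline_milieu("ToRORd"))))
  id0 <- hypernatremia_condition(0, "ToRORd",
                                 apply_shrinkage = FALSE,
                                 apply_current_scaling = FALSE)
  expect_identical(unclass(id0$milieu),
                   unclass(hypernatremia_condition(0, "ToRORd")$milieu))
})

test_that("condition_table reproduces all parameter cells at printed precision", {
  tab <- condition_table()
  expect_equal(nrow(tab), 8)
  bps <- tab[tab$model == "BPS2020", ]
  expect_equal(round(bps$vcell_pct, 2), c(100, 94.17, 89.25, 78.28))
  expect_equal(bps$na_e, c(144, 158.4, 172.8, 216))
  expect_equal(bps$cl_e, c(154.8, 169.2, 183.6, 226.8))
  tor <- tab[tab$model == "ToRORd", ]
  expect_equal(round(tor$vcell_pct, 2), c(100, 94.14, 89.21, 78.21))
  expect_equal(tor$na_e, c(140, 154, 168, 210))
  expect_equal(round(tab$f_INaK, 3), rep(c(1, 0.867, 0.733, 0.333), 2))
})

test_that("a plain-text config round-trips into a condition", {
  f <- tempfile()
  writeLines(c("# extreme hypernatremia, scaling-only ablation",
               "model = BPS2020", "level = 0.5", "rate = 50",
               "apply_shrinkage = false", "icl_scenario = 1.45"), f)
  cfg <- read_condition_config(f)
  unlink(f)
  expect_equal(cfg$rate, 50)
  expect_equal(cfg$condition$model_id, "BPS2020")
  expect_equal(cfg$condition$level, 0.5)
  expect_false(cfg$condition$apply_shrinkage)
  expect_equal(cfg$condition$volume_fraction, 1)
  expect_equal(cfg$condition$factors[["f_ICaL"]], 1.45)
})
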