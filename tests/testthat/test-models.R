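# a mid-AP probe state with active currents, obtained by stimulating the
# published initial state for 1 ms and coasting 5 ms
probe_state <- function(model) {
  m <- osmoAP:::as_cell_model(model)
  cond <- hypernatremia_condition(0, m$id)
  atol <- osmoAP:::default_atol(m)
  o1 <- osmoAP:::ode_segment(m, initial_state(m), c(0, 1), cond, -40, 1e-7, atol)
  y <- o1[nrow(o1), 1 + seq_len(m$n_state)]
  o2 <- osmoAP:::ode_segment(m, y, c(1, 6), cond, 0, 1e-7, atol)
  y <- o2[nrow(o2), 1 + seq_len(m$n_state)]
  names(y) <- m$state_names
  y
}

test_that("published initial states satisfy the state invariants", {
  for (mid in c("ToRORd", "BPS2020")) {
    m <- cell_model(mid)
    y <- initial_state(m)
    conc <- y[m$conc_states]
    expect_true(all(conc > 0), info = mid)
    gates <- y[setdiff(m$state_names, c("vm", m$conc_states,
                                        "Jrelnp", "Jrelp", "CaMKt"))]
    expect_true(all(gates >= 0 & gates <= 1), info = mid)
    expect_true(y[["vm"]] > -95 && y[["vm"]] < -80, info = mid)
  }
})

test_that("the identity condition leaves the right-hand side bitwise unchanged", {
  for (mid in c("ToRORd", "BPS2020")) {
    m <- cell_model(mid)
    y <- probe_state(m)
    d0 <- derivatives(m, y, hypernatremia_condition(0, mid))
    d1 <- derivatives(m, y, hypernatremia_condition(0, mid,
                                                    apply_shrinkage = FALSE,
                                                    apply_current_scaling = FALSE))
    d2 <- derivatives(m, y)   # NULL condition = baseline
    expect_identical(d0, d1, info = mid)
    expect_identical(d0, d2, info = mid)
  }
})

test_that("scaling factors multiply their currents exactly at a pinned state", {
  for (mid in c("ToRORd", "BPS2020")) {
    m <- cell_model(mid)
    y <- probe_state(m)
    c0 <- currents(m, y, hypernatremia_condition(0, mid))
    scale_one <- function(nm, val) {
      cc <- hypernatremia_condition(0, mid)
      cc$factors[[nm]] <- val
      currents(m, y, cc)
    }
    expect_equal(scale_one("f_INaK", 0.5)[["i_nak"]], 0.5 * c0[["i_nak"]],
                 tolerance = 1e-12, info = mid)
    expect_equal(scale_one("f_INaCa", 1.383)[["i_naca"]],
                 1.383 * c0[["i_naca"]], tolerance = 1e-12, info = mid)
    expect_equal(scale_one("f_IKs", 0.5)[["i_ks"]], 0.5 * c0[["i_ks"]],
                 tolerance = 1e-12, info = mid)
    expect_equal(scale_one("f_ICaL", 0.72)[["i_cal"]], 0.72 * c0[["i_cal"]],
                 tolerance = 1e-12, info = mid)
    # zero conductance removes the current and shifts dVm/dt by exactly it
    ckr <- hypernatremia_condition(0, mid); ckr$factors[["f_IKr"]] <- 0
    c1 <- currents(m, y, ckr)
    expect_equal(c1[["i_kr"]], 0, info = mid)
    d0 <- derivatives(m, y, hypernatremia_condition(0, mid))
    d1 <- derivatives(m, y, ckr)
    expect_equal(d1[["vm"]] - d0[["vm"]], c0[["i_kr"]],
                 tolerance = 1e-9, info = mid)
  }
})

test_that("membrane equation: dVm/dt equals minus the sum of all currents", {
  for (mid in c("ToRORd", "BPS2020")) {
    m <- cell_model(mid)
    y <- probe_state(m)
    res <- osmoAP:::eval_rhs(m, y, hypernatremia_condition(0, mid))
    cur <- res$currents
    tot <- sum(cur[c("i_na", "i_nal", "i_to", "i_cal", "i_cana", "i_cak",
                     "i_kr", "i_ks", "i_k1", "i_naca", "i_nak", "i_nab",
                     "i_kb", "i_cab", "i_pca", "i_cl")])
    expect_equal(res$deriv[["vm"]], -tot, tolerance = 1e-9, info = mid)
  }
})

test_that("background Na+ current vanishes at its reversal potential", {
  m <- cell_model("BPS2020")
  y <- initial_state(m)
  y["vm"] <- nernst(1, 144, y[["nai"]])   # ENa for the baseline milieu
  cu <- currents(m, y)
  expect_equal(cu[["i_nab"]], 0, tolerance = 1e-10)
})

test_that("a quiescent cell settles near its resting potential", {
  m <- cell_model("BPS2020")
  out <- osmoAP:::ode_segment(m, initial_state(m), c(0, 2000),
                              hypernatremia_condition(0, m$id), 0, 1e-7,
                              osmoAP:::default_atol(m))
  vend <- out[nrow(out), 2]
  expect_true(vend > -95 && vend < -80)
})

test_that("with membrane currents forced to zero, Na+/K+ stay fixed and total Ca2+ is conserved", {
  for (mid in c("ToRORd", "BPS2020")) {
    m <- cell_model(mid)
    cond <- hypernatremia_condition(0, mid)
    y0 <- initial_state(m)
    out <- osmoAP:::ode_segment(m, y0, c(0, 10000), cond, 0, 1e-9,
                                osmoAP:::default_atol(m) / 100, i_mult = 0)
    y1 <- out[nrow(out), 1 + seq_len(m$n_state)]
    names(y1) <- m$state_names
    # compartments may redistribute internally; the total amount of each
    # ion must be conserved to solver tolerance
    a0 <- ion_amounts(m, y0, cond); a1 <- ion_amounts(m, y1, cond)
    for (nm in c("na", "k", "ca"))
      expect_equal(a1[[nm]], a0[[nm]], tolerance = 1e-6,
                   info = paste(mid, nm))
  }
})

test_that("non-finite states and mismatched conditions are rejected with clear messages", {
  m <- cell_model("ToRORd")
  y <- initial_state(m)
  y["cai"] <- NaN
  expect_error(derivatives(m, y), "non-finite state component: cai")
  expect_error(derivatives(m, initial_state(m),
                           hypernatremia_condition(0.1, "BPS2020")),
               "built for model")
})

test_that("shrinkage scales compartment volumes but never the capacitive area", {
  g1 <- model_geometry("ToRORd", 1)
  g2 <- model_geometry("ToRORd", 0.7821)
  for (nm in c("vmyo", "vnsr", "vjsr", "vss"))
    expect_equal(g2[[nm]], 0.7821 * g1[[nm]], info = nm)
  expect_equal(g2$acap, g1$acap)
})

test_that("the concentration step raises concentration states by the osmotic gain", {
  cc <- hypernatremia_condition(0.5, "ToRORd")
  m <- cell_model("ToRORd")
  y0 <- initial_state(m, cc, step_concentrations = FALSE)
  y1 <- initial_state(m, cc, step_concentrations = TRUE)
  expect_equal(unname(y1[m$conc_states] / y0[m$conc_states]),
               rep(1 + cc$concentration_gain, length(m$conc_states)))
  expect_equal(y1[["vm"]], y0[["vm"]])
  # no shrinkage, no step
  nos <- hypernatremia_condition(0.5, "ToRORd", apply_shrinkage = FALSE)
  expect_identical(initial_state(m, nos), initial_state(m))
})
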