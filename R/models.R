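#' @useDynLib osmoAP, .registration = TRUE
#' @importFrom stats approx setNames
#' @importFrom utils write.table tail head
NULL

CURRENT_NAMES <- c("i_na", "i_nal", "i_to", "i_cal", "i_kr", "i_ks", "i_k1",
                   "i_nak", "i_naca", "i_nab", "i_kb", "i_cab", "i_pca",
                   "i_cl", "i_cana", "i_cak", "i_naca_i", "i_naca_ss",
                   "j_rel", "j_up")

TOR_STATE_NAMES <- c("vm", "nai", "nass", "ki", "kss", "cai", "cass",
                     "cansr", "cajsr", "m", "h", "j", "hp", "jp",
                     "mL", "hL", "hLp", "a", "iF", "iS", "ap", "iFp", "iSp",
                     "d", "ff", "fs", "fcaf", "fcas", "jca", "ffp", "fcafp",
                     "nca_ss", "nca_i", "xrf", "xrs", "xs1", "xs2",
                     "Jrelnp", "Jrelp", "CaMKt")

BPS_STATE_NAMES <- c("vm", "nai", "nass", "ki", "kss", "cai", "cass",
                     "cansr", "cajsr", "m", "hf", "hs", "j", "hsp", "jp",
                     "mL", "hL", "hLp", "a", "iF", "iS", "ap", "iFp", "iSp",
                     "d", "ff", "fs", "fcaf", "fcas", "jca", "nca",
                     "ffp", "fcafp", "xrf", "xrs", "xs1", "xs2", "xk1",
                     "Jrelnp", "Jrelp", "CaMKt")

tor_init_state <- function() {
  setNames(c(-88.76, 12.1025, 12.1029, 142.30, 142.30,
             8.158e-5, 7.031e-5, 1.5211, 1.5214,
             8.057e-4, 0.8286, 0.8284, 0.6707, 0.8281,
             1.629e-4, 0.5255, 0.2872,
             9.51e-4, 0.9996, 0.5936, 4.85e-4, 0.9996, 0.6538,
             8.11e-9, 1, 0.939, 1, 0.9999, 1, 1, 1,
             6.6e-4, 1.2e-3,
             8.3e-6, 0.4532, 0.248, 1.77e-4,
             0, 0, 0.0111),
           TOR_STATE_NAMES)
}

bps_init_state <- function() {
  setNames(c(-87.5, 7.268, 7.268, 144.65, 144.65,
             8.6e-5, 8.49e-5, 1.61, 1.56,
             7.344e-3, 0.6926, 0.6926, 0.6925, 0.4485, 0.6924,
             1.940e-4, 0.4961, 0.2659,
             1.0118e-3, 0.99954, 0.5896, 5.1557e-4, 0.99954, 0.6419,
             2.43e-9, 1, 0.9107, 1, 0.99982, 0.999977, 2.6717e-3, 1, 1,
             8.2661e-6, 0.4533, 0.2705, 1.963e-4, 0.99680,
             2.5394e-5, 3.1726e-7, 0.0124065),
           BPS_STATE_NAMES)
}

#' Registered cell models
#'
#' Returns the model descriptor used by [pace()], [find_threshold()],
#' [derivatives()] and [currents()]. Two endocardial human ventricular
#' ionic models are registered (`"ToRORd"` and `"BPS2020"`), plus the
#' analytic `"toy"` excitable cell (see [toy_model()]).
#'
#' @param model_id Model identifier.
#' @return An object of class `"cell_model"`.
#' @export
cell_model <- function(model_id) {
  id <- normalize_model_id(model_id)
  if (id == "toy") return(toy_model())
  if (id == "ToRORd") {
    structure(list(id = "ToRORd", kind = "compiled", cmid = 1L,
                   func = "torord_derivs", n_state = 40L,
                   state_names = TOR_STATE_NAMES,
                   conc_states = TOR_STATE_NAMES[2:9],
                   init = tor_init_state(),
                   baseline_milieu = baseline_milieu("ToRORd"),
                   temperature = 310,
                   current_names = CURRENT_NAMES),
              class = "cell_model")
  } else {
    structure(list(id = "BPS2020", kind = "compiled", cmid = 2L,
                   func = "bps_derivs", n_state = 41L,
                   state_names = BPS_STATE_NAMES,
                   conc_states = BPS_STATE_NAMES[2:9],
                   init = bps_init_state(),
                   baseline_milieu = baseline_milieu("BPS2020"),
                   temperature = 310,
                   current_names = CURRENT_NAMES),
              class = "cell_model")
  }
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("cell model '%s' (%d state variables)\n", x$id, x$n_state))
  invisible(x)
}

as_cell_model <- function(model) {
  if (inherits(model, "cell_model")) model else cell_model(model)
}

#' Published initial state of a model
#'
#' Returns the resting initial conditions of the source model. When a
#' perturbed condition with shrinkage is supplied, the intracellular
#' concentration states are, by default, stepped up by the osmotic
#' concentration gain (mole conservation in the shrinking active water
#' volume) so that integration starts from the physically consistent
#' post-shrinkage state.
#'
#' @param model Model id or [cell_model()] object.
#' @param condition Optional [hypernatremia_condition()].
#' @param step_concentrations Apply the mole-conservation concentration step
#'   at shrinkage onset (default `TRUE`).
#' @return Named state vector.
#' @export
initial_state <- function(model, condition = NULL, step_concentrations = TRUE) {
  model <- as_cell_model(model)
  y <- model$init
  if (!is.null(condition) && isTRUE(condition$apply_shrinkage) &&
      step_concentrations && condition$concentration_gain > 0) {
    y[model$conc_states] <- y[model$conc_states] *
      (1 + condition$concentration_gain)
  }
  y
}

#' Translate a condition into the compiled parameter vector
#'
#' @param model A [cell_model()].
#' @param condition A [hypernatremia_condition()] or `NULL` for baseline.
#' @param i_stim Stimulus current (A/F, signed; depolarizing is negative).
#' @param i_mult Multiplier on every membrane current (1; the conservation
#'   test hook).
#' @return Numeric parameter vector for the compiled right-hand sides.
#' @keywords internal
condition_parms <- function(model, condition = NULL, i_stim = 0, i_mult = 1) {
  model <- as_cell_model(model)
  if (is.null(condition)) condition <- hypernatremia_condition(0, model$id)
  if (!identical(condition$model_id, model$id))
    stop("condition was built for model ", condition$model_id,
         ", not ", model$id)
  m <- condition$milieu
  f <- condition$factors
  c(nao = m[["na_e"]], ko = m[["k_e"]], cao = m[["ca_e"]], clo = m[["cl_e"]],
    f_ical = f[["f_ICaL"]], f_ikr = f[["f_IKr"]], f_iks = f[["f_IKs"]],
    f_ik1 = f[["f_IK1"]], f_inaca = f[["f_INaCa"]], f_inak = f[["f_INaK"]],
    vfrac = condition$volume_fraction, istim = i_stim, imult = i_mult)
}

eval_rhs <- function(model, state, condition = NULL, i_stim = 0, i_mult = 1) {
  model <- as_cell_model(model)
  if (any(!is.finite(state))) {
    bad <- model$state_names[which(!is.finite(state))[1]]
    stop("non-finite state component: ", bad)
  }
  if (model$kind == "compiled") {
    p <- condition_parms(model, condition, i_stim, i_mult)
    res <- .Call(C_osmo_eval, model$cmid, as.numeric(state), as.numeric(p))
    names(res$deriv) <- model$state_names
    names(res$currents) <- model$current_names
    res
  } else {
    model$eval(state, condition, i_stim, i_mult)
  }
}

#' Time derivatives of the model state
#'
#' Evaluates the model right-hand side at one state under a perturbed
#' condition. Identical to the unperturbed source model when the condition is
#' the identity (level 0, all toggles default).
#'
#' @inheritParams initial_state
#' @param state Named state vector.
#' @param condition A [hypernatremia_condition()] (or `NULL` for baseline).
#' @param i_stim Stimulus current in A/F (inward negative).
#' @return Named vector of d(state)/dt.
#' @export
derivatives <- function(model, state, condition = NULL, i_stim = 0) {
  eval_rhs(model, state, condition, i_stim)$deriv
}

#' Membrane currents at one state
#'
#' Pure function of state and condition, consistent with the current values
#' used inside [derivatives()].
#'
#' @inheritParams derivatives
#' @return Named vector of current densities (A/F) and SR fluxes.
#' @export
currents <- function(model, state, condition = NULL) {
  eval_rhs(model, state, condition)$currents
}

#' Compartment geometry of a model, under optional shrinkage
#'
#' @inheritParams initial_state
#' @param volume_fraction Relative cell volume (1 = baseline). Scales every
#'   intracellular compartment volume; the capacitive area is never scaled.
#' @return List with `vmyo`, `vnsr`, `vjsr`, `vss` (uL) and `acap` (cm^2).
#' @export
model_geometry <- function(model, volume_fraction = 1) {
  len <- 0.01; rad <- 0.0011
  vcell <- 1000 * 3.14 * rad^2 * len
  ageo <- 2 * 3.14 * rad^2 + 2 * 3.14 * rad * len
  list(vmyo = 0.68 * vcell * volume_fraction,
       vnsr = 0.0552 * vcell * volume_fraction,
       vjsr = 0.0048 * vcell * volume_fraction,
       vss = 0.02 * vcell * volume_fraction,
       acap = 2 * ageo)
}

#' Total intracellular ion amounts (free + buffered)
#'
#' Used by the charge/mole bookkeeping checks: the change of these amounts
#' over a beat must match the time-integral of the corresponding membrane
#' currents (plus the stimulus, which is carried by K+).
#'
#' @inheritParams derivatives
#' @return Named vector of Na+, K+ and total Ca2+ amounts
#'   (nmol-equivalent, mmol/L x uL).
#' @export
ion_amounts <- function(model, state, condition = NULL) {
  model <- as_cell_model(model)
  vf <- if (is.null(condition)) 1 else condition$volume_fraction
  g <- model_geometry(model, vf)
  buf <- function(bmax, km, ca) bmax * ca / (ca + km)
  cai <- state[["cai"]]; cass <- state[["cass"]]
  cansr <- state[["cansr"]]; cajsr <- state[["cajsr"]]
  ca_myo <- cai + buf(0.05, 0.00238, cai) + buf(0.07, 0.0005, cai)
  ca_ss <- cass + buf(0.047, 0.00087, cass) + buf(1.124, 0.0087, cass)
  ca_jsr <- cajsr + buf(10, 0.8, cajsr)
  c(na = state[["nai"]] * g$vmyo + state[["nass"]] * g$vss,
    k = state[["ki"]] * g$vmyo + state[["kss"]] * g$vss,
    ca = ca_myo * g$vmyo + ca_ss * g$vss + cansr * g$vnsr + ca_jsr * g$vjsr)
}
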