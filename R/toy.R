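#' Analytic toy excitable cell
#'
#' A three-variable excitable membrane used as a fast test fixture for the
#' pacing, threshold-search and biomarker machinery. It has a K+ leak, a Na+
#' leak, and a regenerative inward current gated by a fast activation
#' variable `w` and a slower inactivation variable `hgate`:
#' \deqn{C_m dV/dt = -(g_K (V-E_K) + g_{NaL} (V-E_{Na}) +
#'   g_{reg} w h (V-E_{Na}) + I_{stim})}
#' At rest the regenerative current is essentially closed, so the resting
#' potential has the chord-conductance closed form
#' `(gK EK + gNaL ENa) / (gK + gNaL)`, and the firing threshold is monotone
#' in the regenerative conductance.
#'
#' @param gK,gNaL,gReg Conductances (mS/uF); `gK > 0`, others `>= 0`.
#' @param EK,ENa Fixed Nernst potentials (mV).
#' @param v_half_w,k_w,tau_w Activation midpoint (mV), slope (mV) and time
#'   constant (ms) of the regenerative gate.
#' @param v_half_h,k_h,tau_h Same for the inactivation gate (closes on
#'   depolarization, which repolarizes the cell).
#' @return A `"cell_model"` object usable with [pace()],
#'   [find_threshold()], [derivatives()] and [currents()].
#' @examples
#' m <- toy_model()
#' toy_resting_potential(m)   # chord-conductance closed form
#' @export
toy_model <- function(gK = 0.9, gNaL = 0.1, gReg = 5,
                      EK = -90, ENa = 60,
                      v_half_w = -30, k_w = 4, tau_w = 1,
                      v_half_h = -50, k_h = 5, tau_h = 30) {
  if (!is.finite(gK) || gK <= 0) stop("gK must be positive")
  if (gNaL < 0 || gReg < 0) stop("conductances must be non-negative")
  if (tau_w <= 0 || tau_h <= 0) stop("time constants must be positive")
  params <- list(gK = gK, gNaL = gNaL, gReg = gReg, EK = EK, ENa = ENa,
                 v_half_w = v_half_w, k_w = k_w, tau_w = tau_w,
                 v_half_h = v_half_h, k_h = k_h, tau_h = tau_h)
  rest <- (gK * EK + gNaL * ENa) / (gK + gNaL)
  winf <- function(v) 1 / (1 + exp(-(v - v_half_w) / k_w))
  hinf <- function(v) 1 / (1 + exp((v - v_half_h) / k_h))
  init <- c(vm = rest, w = winf(rest), hgate = hinf(rest))

  effective <- function(condition) {
    p <- params
    if (!is.null(condition)) {
      if (!is.null(condition$gK_scale)) p$gK <- p$gK * condition$gK_scale
      if (!is.null(condition$gNaL_scale)) p$gNaL <- p$gNaL * condition$gNaL_scale
      if (!is.null(condition$gReg_scale)) p$gReg <- p$gReg * condition$gReg_scale
      if (!is.null(condition$ek_shift)) p$EK <- p$EK + condition$ek_shift
    }
    p
  }
  rhs <- function(v, w, h, p, i_stim, i_mult) {
    i_k <- p$gK * (v - p$EK)
    i_leak <- p$gNaL * (v - p$ENa)
    i_reg <- p$gReg * w * h * (v - p$ENa)
    list(dv = -(i_mult * (i_k + i_leak + i_reg) + i_stim),
         dw = (1 / (1 + exp(-(v - p$v_half_w) / p$k_w)) - w) / p$tau_w,
         dh = (1 / (1 + exp((v - p$v_half_h) / p$k_h)) - h) / p$tau_h,
         cur = c(i_k = i_k, i_leak = i_leak, i_reg = i_reg))
  }

  structure(list(
    id = "toy", kind = "r", n_state = 3L,
    state_names = c("vm", "w", "hgate"),
    conc_states = character(0),
    init = init,
    params = params,
    baseline_milieu = NULL,
    temperature = 310,
    current_names = c("i_k", "i_leak", "i_reg"),
    rfunc = function(t, y, parms) {
      p <- effective(parms$condition)
      r <- rhs(y[1], y[2], y[3], p, parms$i_stim, parms$i_mult)
      list(c(r$dv, r$dw, r$dh), r$cur)
    },
    eval = function(state, condition, i_stim, i_mult) {
      p <- effective(condition)
      r <- rhs(state[[1]], state[[2]], state[[3]], p, i_stim, i_mult)
      list(deriv = c(vm = r$dv, w = r$dw, hgate = r$dh), currents = r$cur)
    }),
    class = "cell_model")
}

#' Closed-form resting potential of the toy cell
#'
#' Chord-conductance weighted mean of the leak reversal potentials,
#' neglecting the (essentially closed) regenerative gate.
#'
#' @param model A [toy_model()].
#' @param condition Optional toy condition (list with `gK_scale`,
#'   `gNaL_scale`, `ek_shift`).
#' @return Resting membrane potential (mV).
#' @export
toy_resting_potential <- function(model, condition = NULL) {
  p <- model$params
  gK <- p$gK; gNaL <- p$gNaL; EK <- p$EK
  if (!is.null(condition)) {
    if (!is.null(condition$gK_scale)) gK <- gK * condition$gK_scale
    if (!is.null(condition$gNaL_scale)) gNaL <- gNaL * condition$gNaL_scale
    if (!is.null(condition$ek_shift)) EK <- EK + condition$ek_shift
  }
  (gK * EK + gNaL * p$ENa) / (gK + gNaL)
}
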