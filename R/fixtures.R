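#' Synthetic action-potential train with closed-form biomarkers
#'
#' Builds a piecewise-linear AP train (rest, 1-ms stimulus latency, linear
#' upstroke, linear repolarization) together with a raised-cosine calcium
#' transient, packaged as a `"paced_trace"` so every downstream stage
#' (biomarker extraction, quasi-steady checks, serialization) can be tested
#' in milliseconds against known ground truth.
#'
#' Ground truth attached as attribute `"truth"`: `apa = peak - rest`,
#' `apd90 = apd90_true`, `apd50 = rise + 0.5 * (apd90_true - rise) / 0.9`,
#' `dvdt_max = (peak - rest) / rise`, `ca_peak = ca_dia + ca_amp`.
#'
#' @param rest,peak Resting and peak potential (mV), `rest < peak`.
#' @param apd90_true Target APD90 (ms), must fit within the cycle.
#' @param rate Beats per minute.
#' @param beats Number of beats.
#' @param rise Upstroke duration (ms).
#' @param pulse_width Stimulus latency before the upstroke (ms).
#' @param dt Sample step (ms).
#' @param t0 Time of the first stimulus (ms); nonzero values exercise
#'   time-shift invariance.
#' @param ca_dia,ca_amp,ca_dur Diastolic level (mmol/L), transient
#'   amplitude (mmol/L) and duration (ms) of the calcium transient.
#' @return A `"paced_trace"` with attribute `"truth"`.
#' @export
synthetic_ap_trace <- function(rest = -85, peak = 35, apd90_true = 300,
                               rate = 60, beats = 5, rise = 2,
                               pulse_width = 1, dt = 0.1, t0 = 0,
                               ca_dia = 1e-4, ca_amp = 4e-4, ca_dur = 300) {
  if (rest >= peak) stop("rest must be below peak")
  cl <- 60000 / rate
  t_rep <- (apd90_true - rise) / 0.9
  if (pulse_width + rise + t_rep >= cl)
    stop("infeasible geometry: AP does not fit within the cycle")
  time <- seq(t0, t0 + beats * cl, by = dt)
  phase <- (time - t0) %% cl
  vm <- rep(rest, length(time))
  up <- phase >= pulse_width & phase < pulse_width + rise
  vm[up] <- rest + (peak - rest) * (phase[up] - pulse_width) / rise
  dn <- phase >= pulse_width + rise & phase < pulse_width + rise + t_rep
  vm[dn] <- peak - (peak - rest) * (phase[dn] - pulse_width - rise) / t_rep
  last_cycle <- (time - t0) >= beats * cl - 1e-9  # end point of final beat
  vm[last_cycle] <- rest
  cai <- rep(ca_dia, length(time))
  ct <- phase >= pulse_width & phase < pulse_width + ca_dur
  cai[ct] <- ca_dia + ca_amp * 0.5 *
    (1 - cos(2 * pi * (phase[ct] - pulse_width) / ca_dur))
  cai[last_cycle] <- ca_dia
  states <- cbind(vm = vm, nai = 12, ki = 140, cai = cai)
  truth <- list(rmp = rest, apa = peak - rest, apd90 = apd90_true,
                apd50 = rise + 0.5 * t_rep, dvdt_max = (peak - rest) / rise,
                ca_peak = 1000 * (ca_dia + ca_amp),
                ca_diastolic = 1000 * ca_dia)
  structure(list(time = time, vm = vm, states = states, currents = NULL,
                 stim_times = t0 + (seq_len(beats) - 1) * cl,
                 pulse_width = pulse_width, stim_amplitude = NA_real_,
                 rate = rate, cl = cl, duration = beats * cl,
                 analysis_window = beats * cl,
                 model_id = "synthetic", condition = NULL,
                 y_end = c(vm = rest), solver = list(method = "analytic")),
            class = "paced_trace", truth = truth)
}

#' Toy-model sweep across hypernatremia levels
#'
#' Applies the hypernatremia perturbation to the analytic toy cell: the K+
#' leak plays the (unscaled) inward-rectifier role and its Nernst potential
#' is shifted by the osmotic concentration gain of intracellular K+,
#' `-RT/F log(1 + gain)`; the depolarizing Na+ leak plays the pump-like
#' role and is scaled by the INaK factor. Returns the resting potential
#' (chord-conductance closed form and simulated) and the bisection
#' threshold current per level, for cheap verification of the monotone RMP
#' and Ith trends.
#'
#' @param levels Hypernatremia levels (fractions).
#' @param model A [toy_model()].
#' @param baseline Reference milieu for the osmotic gain.
#' @return data.frame with `level`, `rmp_closed_form`, `rmp`, `ith`.
#' @export
toy_condition_sweep <- function(levels = c(0, 0.1, 0.2, 0.5),
                                model = toy_model(),
                                baseline = baseline_milieu("ToRORd")) {
  rows <- lapply(levels, function(l) {
    f <- scaling_factors(l)
    gain <- shrinkage_concentration_gain(l, baseline)
    cond <- list(gK_scale = f[["f_IK1"]],
                 gNaL_scale = f[["f_INaK"]],
                 ek_shift = -nernst(1, 1 + gain, 1))
    rest_cf <- toy_resting_potential(model, cond)
    y <- model$init
    y["vm"] <- rest_cf
    out <- ode_segment(model, y, c(0, 500), cond, 0, 1e-8, 1e-8)
    y_rest <- out[nrow(out), 1 + seq_len(model$n_state)]
    names(y_rest) <- model$state_names
    thr <- find_threshold(model, y_rest, cond, bracket = c(0.5, 40))
    data.frame(level = l, rmp_closed_form = rest_cf,
               rmp = unname(y_rest["vm"]), ith = thr$ith)
  })
  do.call(rbind, rows)
}
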