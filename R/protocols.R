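`%||%` <- function(a, b) if (is.null(a)) b else a

default_atol <- function(model) {
  model <- as_cell_model(model)
  if (model$kind != "compiled") return(1e-8)
  atol <- rep(1e-7, model$n_state)
  names(atol) <- model$state_names
  atol[names(atol) %in% c("cai", "cass")] <- 1e-9
  atol[names(atol) == "vm"] <- 1e-6
  atol
}

ode_segment <- function(model, y, times, condition, i_stim, rtol, atol,
                        i_mult = 1) {
  if (model$kind == "compiled") {
    p <- condition_parms(model, condition, i_stim, i_mult)
    out <- deSolve::lsoda(y = y, times = times, func = model$func, parms = p,
                          dllname = "osmoAP", initfunc = "osmo_initmod",
                          nout = length(model$current_names),
                          outnames = model$current_names,
                          rtol = rtol, atol = atol, maxsteps = 100000)
  } else {
    out <- deSolve::lsoda(y = y, times = times, func = model$rfunc,
                          parms = list(condition = condition,
                                       i_stim = i_stim, i_mult = i_mult),
                          rtol = rtol, atol = atol, maxsteps = 100000)
  }
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0)
    stop(sprintf("solver failure (istate %d); last valid time %.3f ms",
                 istate[1], max(out[, 1])))
  if (any(!is.finite(out[nrow(out), ])))
    stop(sprintf("non-finite solution at t = %.3f ms", out[nrow(out), 1]))
  out
}

#' Pace a model to quasi-steady state and capture the analysis window
#'
#' Integrates the model ODE system under a perturbed condition with periodic
#' 1-ms stimulus pulses, and returns the final seconds at high output
#' resolution (fine grid around the upstroke of each beat, coarser grid
#' elsewhere).
#'
#' @inheritParams derivatives
#' @param rate Stimuli per minute (50, 75 or 100 in the standard protocol).
#' @param stim_amplitude Pulse amplitude magnitude (A/F); the applied
#'   current is depolarizing (inward). Normally 2x the condition's threshold
#'   current, see [run_condition()].
#' @param duration Total paced duration (ms; default 10 simulated minutes).
#' @param analysis_window Final window captured at full resolution (ms).
#' @param pulse_width Stimulus duration (ms).
#' @param y0 Starting state; defaults to [initial_state()] under the
#'   condition (with the mole-conservation concentration step if shrinkage
#'   is active).
#' @param step_concentrations Passed to [initial_state()] when `y0` is NULL.
#' @param fine_dt,coarse_dt,upstroke_window Output grid (ms): `fine_dt`
#'   within `upstroke_window` of pulse onset, `coarse_dt` elsewhere.
#' @param rtol,atol Solver tolerances (adaptive stiff integrator).
#' @return A `"paced_trace"` object: time grid, state and current matrices,
#'   stimulus metadata, the condition, and the final state `y_end`.
#' @export
pace <- function(model, condition = NULL, rate = 75, stim_amplitude,
                 duration = 600000, analysis_window = NULL, pulse_width = 1,
                 y0 = NULL, step_concentrations = TRUE,
                 fine_dt = 0.05, coarse_dt = 0.5, upstroke_window = 20,
                 rtol = 1e-7, atol = NULL) {
  model <- as_cell_model(model)
  if (is.null(condition) && model$kind == "compiled")
    condition <- hypernatremia_condition(0, model$id)
  analysis_window <- analysis_window %||% min(5000, duration)
  stopifnot(rate > 0, pulse_width > 0, analysis_window <= duration,
            stim_amplitude >= 0)
  atol <- atol %||% default_atol(model)
  cl <- 60000 / rate
  n_beats <- floor(duration / cl + 1e-9)
  if (n_beats < 1) stop("duration shorter than one cycle")
  t_detail <- n_beats * cl - analysis_window
  if (is.null(y0))
    y0 <- initial_state(model, condition, step_concentrations)
  y <- y0
  rows <- list()
  stim_times <- numeric(0)
  for (b in seq_len(n_beats)) {
    t_on <- (b - 1) * cl
    t_off <- t_on + pulse_width
    t_end <- b * cl
    detailed <- t_end > t_detail + 1e-9
    if (detailed) {
      ta <- unique(c(seq(t_on, t_off, by = fine_dt), t_off))
      tb <- unique(c(seq(t_off, min(t_off + upstroke_window, t_end),
                         by = fine_dt),
                     seq(t_off + upstroke_window, t_end, by = coarse_dt),
                     t_end))
      tb <- sort(tb[tb >= t_off & tb <= t_end])
    } else {
      ta <- c(t_on, t_off)
      tb <- c(t_off, t_end)
    }
    outa <- ode_segment(model, y, ta, condition, -stim_amplitude, rtol, atol)
    y <- outa[nrow(outa), 1 + seq_len(model$n_state)]
    outb <- ode_segment(model, y, tb, condition, 0, rtol, atol)
    y <- outb[nrow(outb), 1 + seq_len(model$n_state)]
    if (detailed) {
      stim_times <- c(stim_times, t_on)
      rows[[length(rows) + 1]] <- outa[-nrow(outa), , drop = FALSE]
      rows[[length(rows) + 1]] <- outb[-nrow(outb), , drop = FALSE]
    }
  }
  last <- outb[nrow(outb), , drop = FALSE]
  full <- do.call(rbind, c(rows, list(last)))
  time <- full[, 1]
  keep <- time >= t_detail - 1e-9
  full <- full[keep, , drop = FALSE]
  time <- time[keep]
  states <- full[, 1 + seq_len(model$n_state), drop = FALSE]
  colnames(states) <- model$state_names
  cur_cols <- ncol(full) - 1 - model$n_state
  currents <- if (cur_cols > 0) {
    m <- full[, (2 + model$n_state):ncol(full), drop = FALSE]
    colnames(m) <- model$current_names
    m
  } else NULL
  names(y) <- model$state_names
  structure(list(time = time, vm = states[, "vm"], states = states,
                 currents = currents,
                 stim_times = stim_times[stim_times >= t_detail - 1e-9],
                 pulse_width = pulse_width, stim_amplitude = stim_amplitude,
                 rate = rate, cl = cl, duration = duration,
                 analysis_window = analysis_window,
                 model_id = model$id, condition = condition, y_end = y,
                 solver = list(method = "lsoda", rtol = rtol, atol = atol)),
            class = "paced_trace")
}

#' @export
print.paced_trace <- function(x, ...) {
  cat(sprintf("paced trace: %s, %g min^-1, %.1f s window, %d stimuli\n",
              x$model_id %||% "synthetic", x$rate,
              diff(range(x$time)) / 1000, length(x$stim_times)))
  if (!is.null(x$condition) && inherits(x$condition, "hyperna_condition"))
    cat(sprintf("condition: level %.0f%%\n", 100 * x$condition$level))
  cat(sprintf("Vm range [%.1f, %.1f] mV\n", min(x$vm), max(x$vm)))
  invisible(x)
}

#' @export
summary.paced_trace <- function(object, ...) biomarkers(object, ...)

#' @export
plot.paced_trace <- function(x, what = c("vm", "cai"), ...) {
  op <- graphics::par(mfrow = c(length(what), 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  for (w in what) {
    yv <- if (w == "vm") x$vm else x$states[, w]
    graphics::plot(x$time / 1000, yv, type = "l", xlab = "time (s)",
                   ylab = w, ...)
  }
  invisible(x)
}

#' Threshold stimulus current by bisection
#'
#' Finds the minimal 1-ms pulse amplitude that elicits an action potential
#' (membrane potential exceeding 0 mV within `fire_window` ms of pulse
#' onset) from a given diastolic state, by bisection on the pulse amplitude.
#'
#' @inheritParams pace
#' @param state Diastolic state to stimulate from (normally the
#'   quasi-steady `y_end` of a paced trace).
#' @param fire_window Detection window after pulse onset (ms).
#' @param rel_tol Relative bracket width at convergence.
#' @param bracket Initial `(sub, supra)` amplitude bracket (A/F). Expanded
#'   automatically unless `expand = FALSE`, in which case an invalid bracket
#'   (both ends fire, or neither does) is an error.
#' @param expand Auto-expand an invalid initial bracket.
#' @return A `"threshold_result"`: `ith` (A/F), `bracket`, `iterations`.
#' @export
find_threshold <- function(model, state, condition = NULL, pulse_width = 1,
                           fire_window = 50, rel_tol = 0.005,
                           bracket = c(1, 60), expand = TRUE,
                           rtol = 1e-7, atol = NULL) {
  model <- as_cell_model(model)
  if (is.null(condition) && model$kind == "compiled")
    condition <- hypernatremia_condition(0, model$id)
  atol <- atol %||% default_atol(model)
  fires <- function(amp) {
    if (amp <= 0) return(FALSE)
    ta <- seq(0, pulse_width, by = 0.25)
    outa <- ode_segment(model, state, ta, condition, -amp, rtol, atol)
    ya <- outa[nrow(outa), 1 + seq_len(model$n_state)]
    if (max(outa[, 2]) > 0) return(TRUE)
    tb <- seq(pulse_width, fire_window, by = 0.5)
    outb <- ode_segment(model, ya, tb, condition, 0, rtol, atol)
    max(outb[, 2]) > 0
  }
  lo <- min(bracket); hi <- max(bracket)
  it <- 0
  lo_fires <- fires(lo); hi_fires <- fires(hi)
  if (!expand && (lo_fires || !hi_fires))
    stop("initial bracket invalid: ",
         if (lo_fires) "both ends fire" else "neither end fires")
  while (lo_fires && it < 30) { hi <- lo; hi_fires <- TRUE
                                lo <- lo / 2; lo_fires <- fires(lo); it <- it + 1 }
  while (!hi_fires && it < 30) { lo <- hi; lo_fires <- FALSE
                                 hi <- hi * 2; hi_fires <- fires(hi); it <- it + 1 }
  if (lo_fires || !hi_fires)
    stop("could not bracket the threshold: ",
         if (lo_fires) "every tested amplitude fires"
         else "no tested amplitude fires")
  while ((hi - lo) > rel_tol * hi) {
    mid <- 0.5 * (lo + hi)
    if (fires(mid)) hi <- mid else lo <- mid
    it <- it + 1
  }
  structure(list(ith = hi, bracket = c(sub = lo, supra = hi),
                 iterations = it),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("threshold current Ith = %.4g A/F (bracket [%.4g, %.4g], %d iterations)\n",
              x$ith, x$bracket[1], x$bracket[2], x$iterations))
  invisible(x)
}

#' Quasi-steady-state check on a paced trace
#'
#' Reports the maximum relative beat-to-beat change of APD90 and of
#' diastolic intracellular Na+ across the analysis window; the trace is
#' flagged quasi-steady when both stay below `tol`.
#'
#' @param trace A [pace()] trace with at least two complete beats.
#' @param tol Relative beat-to-beat tolerance (default 0.5%).
#' @return List with `steady` flag, `delta_apd90`, `delta_nai` (maximum
#'   relative changes) and the per-beat table.
#' @export
quasi_steady_check <- function(trace, tol = 0.005) {
  pb <- per_beat_table(trace)
  pb <- pb[pb$complete & pb$fired, , drop = FALSE]
  if (nrow(pb) < 2) stop("need at least 2 complete beats")
  rel <- function(x) if (all(is.finite(x))) max(abs(diff(x)) / abs(x[-length(x)])) else NA_real_
  d_apd <- rel(pb$apd90)
  d_nai <- if ("nai" %in% colnames(trace$states)) rel(pb$na_i_diastolic) else 0
  list(steady = is.finite(d_apd) && d_apd < tol && (!is.finite(d_nai) || d_nai < tol),
       delta_apd90 = d_apd, delta_nai = d_nai, beats = pb)
}

#' Run one condition end to end (threshold-calibrated pacing)
#'
#' The full per-condition protocol: build the perturbed condition, estimate
#' a provisional threshold from the (concentration-stepped) initial state,
#' pace for the protocol duration at 2x threshold, re-measure the threshold
#' at the final quasi-steady diastolic state, and re-pace once if the
#' threshold moved materially, so that threshold and pacing are solved
#' self-consistently.
#'
#' @inheritParams pace
#' @param level Hypernatremia level (fraction).
#' @param scenario One of `"default"`, `"ical_0.72"`, `"ical_1.45"`,
#'   `"no_shrinkage"`, `"no_scaling"`; or pass `condition` directly.
#' @param condition Optional prebuilt [hypernatremia_condition()].
#' @param stim_multiple Stimulus amplitude as a multiple of threshold (2).
#' @param amp_rtol Re-pace when the threshold moved by more than this
#'   relative amount (0.2).
#' @param max_paces Upper bound on pacing passes (2).
#' @return List with `trace`, `threshold` (a [find_threshold()] result at
#'   the final state), `biomarkers`, `condition`, `paces`.
#' @export
run_condition <- function(model, level = 0, rate = 75, scenario = "default",
                          condition = NULL, duration = 600000,
                          stim_multiple = 2, amp_rtol = 0.2, max_paces = 2,
                          step_concentrations = TRUE, ...) {
  model <- as_cell_model(model)
  if (is.null(condition)) condition <- scenario_condition(level, model$id, scenario)
  y0 <- initial_state(model, condition, step_concentrations)
  ith <- find_threshold(model, y0, condition, ...)$ith
  paces <- 0
  repeat {
    trace <- pace(model, condition, rate = rate,
                  stim_amplitude = stim_multiple * ith,
                  duration = duration,
                  step_concentrations = step_concentrations, ...)
    paces <- paces + 1
    thr <- find_threshold(model, trace$y_end, condition, ...)
    if (abs(thr$ith - ith) <= amp_rtol * ith || paces >= max_paces) break
    ith <- thr$ith
  }
  bm <- biomarkers(trace, threshold = thr$ith)
  list(trace = trace, threshold = thr, biomarkers = bm,
       condition = condition, paces = paces)
}

scenario_condition <- function(level, model_id, scenario = "default") {
  switch(scenario,
         default = hypernatremia_condition(level, model_id),
         ical_0.72 = hypernatremia_condition(level, model_id,
                                             icl_scenario = 0.72),
         ical_1.45 = hypernatremia_condition(level, model_id,
                                             icl_scenario = 1.45),
         no_shrinkage = hypernatremia_condition(level, model_id,
                                                apply_shrinkage = FALSE),
         no_scaling = hypernatremia_condition(level, model_id,
                                              apply_current_scaling = FALSE),
         stop("unknown scenario: ", scenario))
}

#' Export a paced trace as a delimited table with a metadata sidecar
#'
#' Writes time (ms), Vm (mV), concentrations (mmol/L) and currents (A/F) as
#' a tab-delimited table, and a `<file>.meta` sidecar naming the model,
#' condition and solver settings.
#'
#' @param trace A [pace()] trace.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_trace <- function(trace, file) {
  conc <- intersect(c("nai", "ki", "cai", "nass", "kss", "cass",
                      "cansr", "cajsr"),
                    colnames(trace$states))
  tab <- data.frame(time_ms = trace$time, vm_mV = trace$vm,
                    trace$states[, conc, drop = FALSE],
                    check.names = FALSE)
  if (!is.null(trace$currents)) tab <- cbind(tab, trace$currents)
  write.table(tab, file, sep = "\t", row.names = FALSE, quote = FALSE)
  cond <- trace$condition
  meta <- c(sprintf("model\t%s", trace$model_id %||% "synthetic"),
            sprintf("rate_per_min\t%g", trace$rate),
            sprintf("stim_amplitude_AF\t%g", trace$stim_amplitude %||% NA),
            sprintf("pulse_width_ms\t%g", trace$pulse_width),
            if (inherits(cond, "hyperna_condition")) c(
              sprintf("level\t%g", cond$level),
              sprintf("volume_fraction\t%.6f", cond$volume_fraction),
              sprintf("apply_shrinkage\t%s", cond$apply_shrinkage),
              sprintf("apply_current_scaling\t%s", cond$apply_current_scaling),
              sprintf("icl_scenario\t%g", cond$icl_scenario)),
            sprintf("solver\t%s rtol %g", trace$solver$method %||% "lsoda",
                    trace$solver$rtol %||% NA))
  writeLines(meta, paste0(file, ".meta"))
  invisible(file)
}
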