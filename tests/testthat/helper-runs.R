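# Memoised full-protocol runs shared across test files (everything in the
# package is deterministic, so caching is exact).
run_cache <- new.env(parent = emptyenv())

cached_run <- function(model, level = 0, rate = 75, scenario = "default",
                       duration = 600000, step_concentrations = TRUE) {
  key <- paste(model, level, rate, scenario, duration, step_concentrations,
               sep = "|")
  if (is.null(run_cache[[key]])) {
    run_cache[[key]] <- run_condition(model, level = level, rate = rate,
                                      scenario = scenario,
                                      duration = duration,
                                      step_concentrations = step_concentrations)
  }
  run_cache[[key]]
}

# a constant-Vm trace (never fires) for error-path tests
flat_trace <- function(vm = -85, beats = 2, rate = 60, dt = 0.5) {
  cl <- 60000 / rate
  time <- seq(0, beats * cl, by = dt)
  v <- rep(vm, length(time))
  structure(list(time = time, vm = v,
                 states = cbind(vm = v, nai = 10, ki = 140, cai = 1e-4),
                 currents = NULL,
                 stim_times = (seq_len(beats) - 1) * cl,
                 pulse_width = 1, stim_amplitude = NA_real_,
                 rate = rate, cl = cl, duration = beats * cl,
                 analysis_window = beats * cl, model_id = "synthetic",
                 condition = NULL, y_end = c(vm = vm),
                 solver = list(method = "analytic")),
            class = "paced_trace")
}

# exhaustive grid-search oracle for the threshold current
grid_threshold <- function(model, state, condition = NULL, amps) {
  fires <- vapply(amps, function(a) {
    tr <- tryCatch({
      outa <- osmoAP:::ode_segment(model, state, seq(0, 1, by = 0.25),
                                   condition, -a, 1e-7,
                                   osmoAP:::default_atol(model))
      ya <- outa[nrow(outa), 1 + seq_len(model$n_state)]
      outb <- osmoAP:::ode_segment(model, ya, seq(1, 50, by = 0.5),
                                   condition, 0, 1e-7,
                                   osmoAP:::default_atol(model))
      max(outa[, 2], outb[, 2]) > 0
    }, error = function(e) NA)
    isTRUE(tr)
  }, logical(1))
  if (!any(fires)) stop("no amplitude in the grid fires")
  amps[min(which(fires))]
}
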