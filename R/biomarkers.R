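#' Nernst equilibrium potential
#'
#' @param z Ion valence (non-zero integer).
#' @param conc_out,conc_in Extracellular / intracellular concentrations
#'   (mmol/L, strictly positive).
#' @param temperature Absolute temperature (K).
#' @return Equilibrium potential (mV).
#' @examples
#' nernst(1, 5.4, 144)    # EK of a typical ventricular myocyte, ~ -88 mV
#' @export
nernst <- function(z, conc_out, conc_in, temperature = 310) {
  if (z == 0) stop("valence must be non-zero")
  if (any(conc_out <= 0) || any(conc_in <= 0))
    stop("concentrations must be strictly positive")
  1000 * 8.314 * temperature / (z * 96485) * log(conc_out / conc_in)
}

#' Per-beat measurements of a paced trace
#'
#' One row per stimulus in the analysis window: resting (pre-stimulus)
#' potential, peak, amplitude, maximum upstroke velocity (measured from
#' pulse offset to exclude the stimulus artifact), APD50/APD90 measured
#' from the instant of maximum upstroke velocity to the
#' amplitude-referenced repolarization crossings (linear interpolation
#' between samples), and diastolic/peak ionic values where the trace
#' carries them.
#'
#' @param trace A `"paced_trace"`.
#' @return data.frame, one row per stimulus.
#' @export
per_beat_table <- function(trace) {
  t <- trace$time; vm <- trace$vm
  st <- trace$states
  has <- function(nm) !is.null(st) && nm %in% colnames(st)
  tmax <- max(t)
  onsets <- trace$stim_times
  if (length(onsets) == 0) stop("trace contains no stimuli")
  rows <- lapply(seq_along(onsets), function(b) {
    t_on <- onsets[b]
    t_next <- if (b < length(onsets)) onsets[b + 1] else t_on + trace$cl
    ipre <- max(which(t <= t_on + 1e-9))
    rmp <- vm[ipre]
    seg <- which(t >= t_on - 1e-9 & t <= t_next + 1e-9)
    complete <- t_next <= tmax + 1e-6
    ipk <- seg[which.max(vm[seg])]
    peak <- vm[ipk]
    fired <- peak > 0
    apa <- peak - rmp
    # ionic upstroke velocity: the stimulus contributes exactly +amplitude
    # to dVm/dt while the pulse is on, so subtract it there rather than
    # discarding the pulse window (at strong stimuli the upstroke can
    # complete before pulse offset)
    amp <- trace$stim_amplitude
    if (!is.finite(amp)) amp <- 0
    up <- seg[seg <= ipk & t[seg] >= t_on - 1e-9]
    dvdt_max <- NA_real_; t_d <- NA_real_
    if (length(up) >= 2) {
      tm <- 0.5 * (t[up][-1] + t[up][-length(up)])
      dv <- diff(vm[up]) / diff(t[up])
      dv[tm < t_on + trace$pulse_width] <-
        dv[tm < t_on + trace$pulse_width] - amp
      k <- which.max(dv)
      dvdt_max <- dv[k]
      t_d <- tm[k]
    }
    crossing <- function(frac) {
      lvl <- rmp + frac * apa
      post <- seg[seg >= ipk]
      if (length(post) < 2) return(NA_real_)
      i <- post[-length(post)]
      hit <- which(vm[i] >= lvl & vm[i + 1] < lvl)
      if (length(hit) == 0) return(NA_real_)
      i1 <- i[hit[1]]
      t[i1] + (lvl - vm[i1]) * (t[i1 + 1] - t[i1]) / (vm[i1 + 1] - vm[i1])
    }
    apd50 <- apd90 <- NA_real_
    if (fired && is.finite(t_d)) {
      apd50 <- crossing(0.5) - t_d
      apd90 <- crossing(0.1) - t_d
    }
    data.frame(beat = b, t_on = t_on, complete = complete, fired = fired,
               rmp = rmp, peak = peak, apa = apa,
               dvdt_max = dvdt_max, t_dvdt = t_d,
               apd50 = apd50, apd90 = apd90,
               na_i_diastolic = if (has("nai")) st[ipre, "nai"] else NA_real_,
               k_i_diastolic = if (has("ki")) st[ipre, "ki"] else NA_real_,
               ca_diastolic = if (has("cai")) st[ipre, "cai"] else NA_real_,
               ca_peak = if (has("cai")) max(st[seg, "cai"]) else NA_real_)
  })
  do.call(rbind, rows)
}

last_complete_beat <- function(trace) {
  pb <- per_beat_table(trace)
  ok <- pb$complete & pb$fired
  if (!any(pb$fired)) stop("no action potential in trace")
  if (!any(ok)) stop("no complete beat in trace")
  pb[max(which(ok)), , drop = FALSE]
}

#' Action-potential biomarkers of a paced trace
#'
#' Reports, for the last complete beat: resting membrane potential (RMP,
#' the pre-stimulus diastolic potential), AP amplitude (APA), maximum
#' upstroke velocity ((dVm/dt)max, V/s), and APD50/APD90 (ms) measured from
#' the maximum-upstroke instant to 50%/90% repolarization of the amplitude.
#'
#' @param trace A `"paced_trace"` with at least one complete beat.
#' @return Named list with `rmp`, `apa`, `apd50`, `apd90`, `dvdt_max`.
#' @export
ap_biomarkers <- function(trace) {
  lb <- last_complete_beat(trace)
  if (!is.finite(lb$apd90))
    stop("repolarization never reaches the APD90 level within the cycle")
  list(rmp = lb$rmp, apa = lb$apa, apd50 = lb$apd50, apd90 = lb$apd90,
       dvdt_max = lb$dvdt_max)
}

#' Calcium-transient biomarkers of a paced trace
#'
#' Peak and pre-stimulus (diastolic) myoplasmic free Ca2+ of the last
#' complete beat, in umol/L.
#'
#' @inheritParams ap_biomarkers
#' @return Named list with `ca_peak` and `ca_diastolic` (umol/L).
#' @export
calcium_biomarkers <- function(trace) {
  if (is.null(trace$states) || !("cai" %in% colnames(trace$states)))
    stop("trace carries no myoplasmic Ca2+ series")
  lb <- last_complete_beat(trace)
  list(ca_peak = 1000 * lb$ca_peak, ca_diastolic = 1000 * lb$ca_diastolic)
}

#' Full biomarker set of a paced trace
#'
#' Combines the AP biomarkers, the calcium-transient biomarkers, the
#' diastolic Na+/K+ concentrations, and the Na+/K+ equilibrium potentials
#' computed from the diastolic intracellular and the condition's
#' extracellular concentrations. The threshold current may be attached when
#' it has been measured for the same condition.
#'
#' @inheritParams ap_biomarkers
#' @param threshold Optional threshold current Ith (A/F).
#' @return An object of class `"biomarker_set"`.
#' @export
biomarkers <- function(trace, threshold = NULL) {
  ap <- ap_biomarkers(trace)
  lb <- last_complete_beat(trace)
  ca <- if (!is.null(trace$states) && "cai" %in% colnames(trace$states)) {
    calcium_biomarkers(trace)
  } else list(ca_peak = NA_real_, ca_diastolic = NA_real_)
  cond <- trace$condition
  ek <- ena <- NA_real_
  if (inherits(cond, "hyperna_condition") && is.finite(lb$k_i_diastolic)) {
    ek <- nernst(1, cond$milieu[["k_e"]], lb$k_i_diastolic)
    ena <- nernst(1, cond$milieu[["na_e"]], lb$na_i_diastolic)
  }
  structure(list(rmp = ap$rmp, apa = ap$apa, apd50 = ap$apd50,
                 apd90 = ap$apd90, dvdt_max = ap$dvdt_max,
                 ith = threshold %||% NA_real_,
                 ek = ek, ena = ena,
                 ca_peak = ca$ca_peak, ca_diastolic = ca$ca_diastolic,
                 na_i_diastolic = lb$na_i_diastolic,
                 k_i_diastolic = lb$k_i_diastolic),
            class = "biomarker_set")
}

#' @export
print.biomarker_set <- function(x, ...) {
  cat(sprintf("RMP %.1f mV, APA %.1f mV, APD50 %.1f ms, APD90 %.1f ms\n",
              x$rmp, x$apa, x$apd50, x$apd90))
  cat(sprintf("(dVm/dt)max %.0f V/s", x$dvdt_max))
  if (is.finite(x$ith)) cat(sprintf(", Ith %.2f A/F", x$ith))
  cat("\n")
  if (is.finite(x$ek))
    cat(sprintf("EK %.1f mV, ENa %.1f mV\n", x$ek, x$ena))
  if (is.finite(x$ca_peak))
    cat(sprintf("[Ca2+]i peak %.3f, diastolic %.4f umol/L\n",
                x$ca_peak, x$ca_diastolic))
  if (is.finite(x$na_i_diastolic))
    cat(sprintf("[Na+]i %.2f, [K+]i %.1f mmol/L (diastolic)\n",
                x$na_i_diastolic, x$k_i_diastolic))
  invisible(x)
}

#' @export
as.data.frame.biomarker_set <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}
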