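# Charge/mole bookkeeping over one complete beat: the time-integral of each
# ion's membrane currents (stimulus charge assigned to K+) must match the
# change in that ion's total intracellular amount.
trapz <- function(t, x) sum(diff(t) * (x[-1] + x[-length(x)]) / 2)

beat_bookkeeping <- function(res) {
  tr <- res$trace
  m <- cell_model(tr$model_id)
  ons <- tr$stim_times
  t1 <- ons[length(ons) - 1]; t2 <- ons[length(ons)]
  idx <- which(tr$time >= t1 - 1e-9 & tr$time <= t2 + 1e-9)
  tt <- tr$time[idx]
  cu <- tr$currents[idx, , drop = FALSE]
  g <- model_geometry(m, tr$condition$volume_fraction)
  afc <- g$acap / 96485
  i_na <- cu[, "i_na"] + cu[, "i_nal"] + cu[, "i_cana"] + cu[, "i_nab"] +
    3 * (cu[, "i_naca_i"] + cu[, "i_naca_ss"]) + 3 * cu[, "i_nak"]
  i_k <- cu[, "i_to"] + cu[, "i_kr"] + cu[, "i_ks"] + cu[, "i_k1"] +
    cu[, "i_kb"] + cu[, "i_cak"] - 2 * cu[, "i_nak"]
  i_ca <- (cu[, "i_cal"] + cu[, "i_cab"] + cu[, "i_pca"] -
             2 * (cu[, "i_naca_i"] + cu[, "i_naca_ss"])) / 2
  stim_charge <- -tr$stim_amplitude * tr$pulse_width   # K+-carried
  row_state <- function(i) {
    y <- tr$states[i, ]; names(y) <- m$state_names; y
  }
  a1 <- ion_amounts(m, row_state(idx[1]), tr$condition)
  a2 <- ion_amounts(m, row_state(idx[length(idx)]), tr$condition)
  out <- data.frame(ion = c("na", "k", "ca"),
                    predicted = c(-trapz(tt, i_na) * afc,
                                  -(trapz(tt, i_k) + stim_charge) * afc,
                                  -trapz(tt, i_ca) * afc),
                    actual = c(a2[["na"]] - a1[["na"]],
                               a2[["k"]] - a1[["k"]],
                               a2[["ca"]] - a1[["ca"]]),
                    throughput = c(trapz(tt, abs(i_na)) * afc,
                                   (trapz(tt, abs(i_k)) +
                                      abs(stim_charge)) * afc,
                                   trapz(tt, abs(i_ca)) * afc))
  out$rel_err <- abs(out$predicted - out$actual) / out$throughput
  out
}
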