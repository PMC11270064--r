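#' Run the full experiment grid
#'
#' For every (model, rate, level, scenario) cell: find the threshold
#' current, pace for the protocol duration at 2x threshold, extract the
#' biomarker set, and tabulate absolute and percent changes against the
#' same-model, same-rate baseline (level 0, default scenario). Failures in
#' individual cells are recorded and do not stop the remaining cells.
#'
#' @param models Model ids.
#' @param rates Stimulus rates (min^-1).
#' @param levels Hypernatremia levels (fractions). Level 0 with the default
#'   scenario is always included as the reference.
#' @param scenarios Scenario labels understood by [run_condition()].
#' @param duration Paced duration per cell (ms).
#' @param output_dir Optional directory for the summary table and per-cell
#'   trace exports.
#' @param ... Passed to [run_condition()].
#' @return data.frame with one row per cell (biomarkers, changes vs
#'   baseline, error message for failed cells).
#' @export
run_grid <- function(models = c("ToRORd", "BPS2020"),
                     rates = c(50, 75, 100),
                     levels = c(0, 0.1, 0.2, 0.5),
                     scenarios = "default",
                     duration = 600000, output_dir = NULL, ...) {
  if (!0 %in% levels) levels <- c(0, levels)
  if (!"default" %in% scenarios) scenarios <- c("default", scenarios)
  if (!is.null(output_dir) &&
      !dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  cells <- expand.grid(model = models, rate = rates, level = levels,
                       scenario = scenarios, stringsAsFactors = FALSE)
  # baseline cells only need the default scenario
  cells <- cells[!(cells$level == 0 & cells$scenario != "default"), ]
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cc <- cells[i, ]
    row <- data.frame(model = normalize_model_id(cc$model), rate = cc$rate,
                      level = cc$level, scenario = cc$scenario,
                      error = NA_character_)
    res <- tryCatch(
      run_condition(cc$model, level = cc$level, rate = cc$rate,
                    scenario = cc$scenario, duration = duration, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      row$error <- conditionMessage(res)
    } else {
      row <- cbind(row, as.data.frame(res$biomarkers))
      row$steady <- quasi_steady_check(res$trace)$steady
      if (!is.null(output_dir)) {
        fn <- file.path(output_dir,
                        sprintf("trace_%s_%gbpm_%03d_%s.tsv",
                                row$model, cc$rate, round(100 * cc$level),
                                cc$scenario))
        write_trace(res$trace, fn)
      }
    }
    rows[[i]] <- row
  }
  tab <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(c("model", "rate", "level", "scenario", "error",
                      names(unclass(biomarker_template())), "steady"),
                    names(r))
    for (m in miss) r[[m]] <- NA
    r
  }))
  tab <- add_baseline_changes(tab)
  if (!is.null(output_dir))
    write.table(tab, file.path(output_dir, "biomarker_summary.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  tab
}

biomarker_template <- function() {
  structure(as.list(setNames(rep(NA_real_, 12),
                             c("rmp", "apa", "apd50", "apd90", "dvdt_max",
                               "ith", "ek", "ena", "ca_peak", "ca_diastolic",
                               "na_i_diastolic", "k_i_diastolic"))),
            class = "biomarker_set")
}

#' Absolute and percent changes against the same-rate baseline
#'
#' @param tab A [run_grid()] table.
#' @return The table with `d_rmp` (mV), and `pct_apd90`, `pct_apd50`,
#'   `pct_dvdt_max`, `pct_ith` (%) columns added.
#' @export
add_baseline_changes <- function(tab) {
  tab$d_rmp <- NA_real_
  for (p in c("apd90", "apd50", "dvdt_max", "ith"))
    tab[[paste0("pct_", p)]] <- NA_real_
  for (i in seq_len(nrow(tab))) {
    b <- tab$model == tab$model[i] & tab$rate == tab$rate[i] &
      tab$level == 0 & tab$scenario == "default"
    if (!any(b)) next
    base <- tab[which(b)[1], ]
    tab$d_rmp[i] <- tab$rmp[i] - base$rmp
    for (p in c("apd90", "apd50", "dvdt_max", "ith"))
      tab[[paste0("pct_", p)]][i] <-
        100 * (tab[[p]][i] - base[[p]]) / base[[p]]
  }
  tab
}

#' Pair the two models cell by cell
#'
#' @param tab A [run_grid()] table containing both models at identical
#'   (rate, level, scenario) cells.
#' @return data.frame with one row per cell and per-model biomarker columns
#'   plus their differences.
#' @export
compare_models <- function(tab) {
  a <- tab[tab$model == "ToRORd", ]
  b <- tab[tab$model == "BPS2020", ]
  key <- c("rate", "level", "scenario")
  m <- merge(a, b, by = key, suffixes = c("_ToRORd", "_BPS2020"))
  if (nrow(m) < max(nrow(a), nrow(b)))
    warning("some cells are missing in one of the models")
  for (p in c("rmp", "apd90", "na_i_diastolic", "ca_peak", "d_rmp"))
    m[[paste0("diff_", p)]] <-
      m[[paste0(p, "_ToRORd")]] - m[[paste0(p, "_BPS2020")]]
  m[order(m$rate, m$level), ]
}
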