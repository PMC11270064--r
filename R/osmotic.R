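#' Extracellular milieu
#'
#' Bundle of the four extracellular ion concentrations used by the ionic
#' models. For the BPS2020 baseline the chloride concentration is not a model
#' parameter but is computed from charge balance of the cations,
#' `cl_e = na_e + k_e + 2 ca_e`.
#'
#' @param na_e,k_e,ca_e,cl_e Extracellular Na+, K+, Ca2+ and Cl-
#'   concentrations (mmol/L). If `cl_e` is `NULL` it is filled in from cation
#'   charge balance.
#' @return An object of class `"milieu"`: a named numeric vector with
#'   elements `na_e`, `k_e`, `ca_e`, `cl_e`.
#' @examples
#' milieu(144, 5.4, 2.7)           # BPS2020 baseline, Cl- from charge balance
#' milieu(140, 5.0, 1.8, 150)      # ToR-ORd baseline
#' @export
milieu <- function(na_e, k_e, ca_e, cl_e = NULL) {
  if (is.null(cl_e)) cl_e <- na_e + k_e + 2 * ca_e
  m <- c(na_e = na_e, k_e = k_e, ca_e = ca_e, cl_e = cl_e)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("all extracellular concentrations must be strictly positive")
  structure(m, class = "milieu")
}

#' @export
print.milieu <- function(x, ...) {
  cat(sprintf("[Na+]e %g, [K+]e %g, [Ca2+]e %g, [Cl-]e %g mmol/L\n",
              x[["na_e"]], x[["k_e"]], x[["ca_e"]], x[["cl_e"]]))
  invisible(x)
}

#' Baseline extracellular milieu of a registered model
#'
#' @param model_id `"ToRORd"` or `"BPS2020"` (case-insensitive; `"-"`
#'   ignored).
#' @return A [milieu()] object.
#' @export
baseline_milieu <- function(model_id) {
  switch(normalize_model_id(model_id),
         ToRORd  = milieu(140, 5.0, 1.8, 150),
         BPS2020 = milieu(144, 5.4, 2.7))
}

normalize_model_id <- function(model_id) {
  id <- tolower(gsub("[-_ ]", "", model_id))
  if (id %in% c("torord", "tor")) return("ToRORd")
  if (id %in% c("bps2020", "bps", "ord")) return("BPS2020")
  if (id == "toy") return("toy")
  stop("unknown model_id: ", model_id)
}

#' Extracellular osmolarity
#'
#' Defined as the plain sum of the four milieu concentrations, each species
#' counted once. This is the definition under which the osmotic volume model
#' reproduces the relative cell volumes used throughout the package.
#'
#' @param m A [milieu()] object.
#' @return Osmolarity-equivalent concentration (mmol/L).
#' @export
osmolarity <- function(m) sum(unclass(m))

#' Perturb the extracellular milieu by equimolar NaCl addition
#'
#' Hypernatremia at fractional level `level` raises `[Na+]e` by
#' `level * na_e` and `[Cl-]e` by the same amount; K+ and Ca2+ are unchanged.
#'
#' @param level Hypernatremia level as a fraction (0.5 = 50%).
#' @param baseline Baseline [milieu()].
#' @return The perturbed [milieu()].
#' @export
perturbed_milieu <- function(level, baseline) {
  stopifnot(inherits(baseline, "milieu"))
  if (!is.finite(level) || level < 0) stop("level must be >= 0")
  add <- level * baseline[["na_e"]]
  milieu(baseline[["na_e"]] + add, baseline[["k_e"]], baseline[["ca_e"]],
         baseline[["cl_e"]] + add)
}

#' Default ion-current scaling anchors
#'
#' Experimentally derived (hyperosmolarity level, scaling factor) anchor per
#' current; the point (0, 1) is always implicit and factors at other levels
#' lie on the straight line through both points (linear interpolation or
#' extrapolation). ICaL and IK1 are unscaled in the default scenario.
#'
#' @return A named list of `c(level, factor)` pairs.
#' @export
default_anchors <- function() {
  list(f_ICaL  = c(level = 0.5, factor = 1.00),
       f_IKr   = c(level = 0.5, factor = 0.60),
       f_IKs   = c(level = 0.5, factor = 0.50),
       f_IK1   = c(level = 0.5, factor = 1.00),
       f_INaCa = c(level = 0.3, factor = 1.23),
       f_INaK  = c(level = 0.3, factor = 0.60))
}

#' Ion-current scaling factors at a hypernatremia level
#'
#' Evaluates, for each of ICaL, IKr, IKs, IK1, INaCa and INaK, the line
#' through (0, 1) and the current's experimental anchor at the requested
#' level. At level 0 all factors are exactly 1.
#'
#' @inheritParams perturbed_milieu
#' @param anchors Anchor table as produced by [default_anchors()].
#' @return An object of class `"scaling_factors"`: named numeric vector
#'   `f_ICaL, f_IKr, f_IKs, f_IK1, f_INaCa, f_INaK`.
#' @examples
#' scaling_factors(0.10)
#' @export
scaling_factors <- function(level, anchors = default_anchors()) {
  if (!is.finite(level) || level < 0) stop("level must be >= 0")
  f <- vapply(names(anchors), function(nm) {
    a <- anchors[[nm]]
    val <- 1 + level * (a[["factor"]] - 1) / a[["level"]]
    if (val <= 0)
      stop(sprintf("scaling factor %s extrapolates to %.4g <= 0 at level %g",
                   nm, val, level))
    val
  }, numeric(1))
  structure(f, class = "scaling_factors")
}

#' @export
print.scaling_factors <- function(x, ...) {
  cat("ion-current scaling factors:\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Relative cell volume under hyperosmotic shrinkage
#'
#' An osmotically inactive fraction of the cell volume (default 32%) does not
#' exchange water; the active remainder shrinks inversely with extracellular
#' osmolarity. The result is the cell volume relative to baseline,
#' `inactive + (1 - inactive) * osm0 / osm(level)`.
#'
#' @inheritParams perturbed_milieu
#' @param baseline Baseline [milieu()] (sets the baseline osmolarity).
#' @param inactive_fraction Osmotically inactive volume fraction in `[0, 1)`.
#' @return Relative cell volume in (inactive_fraction, 1].
#' @examples
#' volume_fraction(0.5, baseline_milieu("ToRORd"))   # 0.7821
#' @export
volume_fraction <- function(level, baseline, inactive_fraction = 0.32) {
  if (!is.finite(level) || level < 0) stop("level must be >= 0")
  stopifnot(inactive_fraction >= 0, inactive_fraction < 1)
  osm0 <- osmolarity(baseline)
  osm  <- osm0 + 2 * level * baseline[["na_e"]]
  inactive_fraction + (1 - inactive_fraction) * osm0 / osm
}

#' Concentration gain of a conserved solute in the shrinking active volume
#'
#' The fractional rise in concentration of a solute confined to the
#' osmotically active water when that water shrinks inversely with
#' extracellular osmolarity: `osm(level)/osm0 - 1`. At 50% hypernatremia this
#' evaluates to approximately 47%.
#'
#' @inheritParams volume_fraction
#' @return Dimensionless fractional gain (0 at level 0).
#' @examples
#' shrinkage_concentration_gain(0.5, baseline_milieu("ToRORd"))  # ~0.472
#' @export
shrinkage_concentration_gain <- function(level, baseline) {
  if (!is.finite(level) || level < 0) stop("level must be >= 0")
  osm0 <- osmolarity(baseline)
  (osm0 + 2 * level * baseline[["na_e"]]) / osm0 - 1
}

#' Build a complete perturbed condition
#'
#' Bundles the milieu perturbation, ion-current scaling and osmotic cell
#' shrinkage for one hypernatremia level, honouring the ablation toggles and
#' the optional ICaL scenario factor.
#'
#' @inheritParams perturbed_milieu
#' @param model_id Registered model, see [baseline_milieu()].
#' @param apply_shrinkage If `FALSE`, the cell volume stays at baseline (the
#'   milieu change is kept).
#' @param apply_current_scaling If `FALSE`, all scaling factors are 1 (the
#'   milieu change is kept).
#' @param icl_scenario ICaL scenario scaling factor (default 1; the
#'   experimental alternatives are 0.72 and 1.45). Overrides `f_ICaL`.
#' @param inactive_fraction Osmotically inactive volume fraction.
#' @param anchors Scaling anchor table, see [default_anchors()].
#' @return An object of class `"hyperna_condition"` with elements `level`,
#'   `model_id`, `milieu`, `factors`, `volume_fraction`,
#'   `concentration_gain`, `apply_shrinkage`, `apply_current_scaling`,
#'   `icl_scenario`.
#' @examples
#' hypernatremia_condition(0.5, "BPS2020")
#' @export
hypernatremia_condition <- function(level, model_id,
                                    apply_shrinkage = TRUE,
                                    apply_current_scaling = TRUE,
                                    icl_scenario = 1,
                                    inactive_fraction = 0.32,
                                    anchors = default_anchors()) {
  base <- baseline_milieu(model_id)
  if (!is.finite(icl_scenario) || icl_scenario <= 0)
    stop("icl_scenario must be a positive scaling factor")
  factors <- scaling_factors(level, anchors)
  if (!apply_current_scaling) factors[] <- 1
  factors[["f_ICaL"]] <- factors[["f_ICaL"]] * icl_scenario
  vf <- if (apply_shrinkage) {
    volume_fraction(level, base, inactive_fraction)
  } else 1
  gain <- if (apply_shrinkage) {
    shrinkage_concentration_gain(level, base)
  } else 0
  structure(list(level = level,
                 model_id = normalize_model_id(model_id),
                 milieu = perturbed_milieu(level, base),
                 factors = factors,
                 volume_fraction = vf,
                 concentration_gain = gain,
                 apply_shrinkage = apply_shrinkage,
                 apply_current_scaling = apply_current_scaling,
                 icl_scenario = icl_scenario),
            class = "hyperna_condition")
}

#' @export
print.hyperna_condition <- function(x, ...) {
  cat(sprintf("hypernatremia condition: %s, level %.0f%%\n",
              x$model_id, 100 * x$level))
  print(x$milieu)
  cat(sprintf("volume %.2f%% of baseline (shrinkage %s), solute gain %.1f%%\n",
              100 * x$volume_fraction, if (x$apply_shrinkage) "on" else "off",
              100 * x$concentration_gain))
  cat(sprintf("current scaling %s", if (x$apply_current_scaling) "on" else "off"))
  if (x$icl_scenario != 1)
    cat(sprintf(", ICaL scenario factor %.2f", x$icl_scenario))
  cat(":\n")
  print(round(unclass(x$factors), 3))
  invisible(x)
}

#' Parameter table for both models across hypernatremia levels
#'
#' Convenience reproduction of the per-level parameter settings: scaling
#' factors, extracellular milieu and relative cell volume for each model at
#' the standard levels.
#'
#' @param levels Hypernatremia levels (fractions).
#' @param models Model ids.
#' @return A data.frame with one row per (model, level).
#' @export
condition_table <- function(levels = c(0, 0.1, 0.2, 0.5),
                            models = c("ToRORd", "BPS2020")) {
  rows <- lapply(models, function(mid) {
    do.call(rbind, lapply(levels, function(l) {
      cc <- hypernatremia_condition(l, mid)
      data.frame(model = cc$model_id, level = l,
                 f_ICaL = cc$factors[["f_ICaL"]], f_IKr = cc$factors[["f_IKr"]],
                 f_IKs = cc$factors[["f_IKs"]], f_IK1 = cc$factors[["f_IK1"]],
                 f_INaCa = cc$factors[["f_INaCa"]],
                 f_INaK = cc$factors[["f_INaK"]],
                 na_e = cc$milieu[["na_e"]], k_e = cc$milieu[["k_e"]],
                 ca_e = cc$milieu[["ca_e"]], cl_e = cc$milieu[["cl_e"]],
                 vcell_pct = 100 * cc$volume_fraction)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a perturbed condition from a plain-text config
#'
#' Key/value lines (`key = value` or `key value`; `#` comments) naming the
#' model, hypernatremia level, stimulus rate, ablation toggles and the ICaL
#' scenario factor, e.g.
#' ```
#' model  ToRORd
#' level  0.5
#' rate   50
#' apply_shrinkage        true
#' apply_current_scaling  true
#' icl_scenario           1.00
#' ```
#'
#' @param file Path to the config file.
#' @return List with `condition` (a [hypernatremia_condition()]) and `rate`.
#' @export
read_condition_config <- function(file) {
  ln <- trimws(readLines(file))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  kv <- do.call(rbind, lapply(ln, function(x) {
    parts <- strsplit(sub("=", " ", x, fixed = TRUE), "[[:space:]]+")[[1]]
    if (length(parts) < 2) stop("malformed config line: ", x)
    c(parts[1], parts[2])
  }))
  vals <- setNames(kv[, 2], tolower(kv[, 1]))
  get <- function(key, default) if (key %in% names(vals)) vals[[key]] else default
  as_flag <- function(x) tolower(x) %in% c("true", "yes", "1", "on")
  cond <- hypernatremia_condition(
    level = as.numeric(get("level", "0")),
    model_id = get("model", "ToRORd"),
    apply_shrinkage = as_flag(get("apply_shrinkage", "true")),
    apply_current_scaling = as_flag(get("apply_current_scaling", "true")),
    icl_scenario = as.numeric(get("icl_scenario", "1")))
  list(condition = cond, rate = as.numeric(get("rate", "75")))
}
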