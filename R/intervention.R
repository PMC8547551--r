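# Acetazolamide-style interventions on the steady-state model, the canonical
# four-scenario report, and baseline/shift sensitivity sweeps of the relative
# loop-gain reduction.

# Physiological sweep ranges used to warn about off-range grids.
SWEEP_RANGES <- list(
  controller_gain = c(0.5, 3),     # L/min/mmHg
  paco2_eup       = c(30, 50),     # mmHg
  vco2            = c(155, 255)    # ml/min
)

#' Pooled baseline inputs for the steady-state model
#'
#' The three anchors that determine the whole model: CO2 production, eupneic
#' paCO2 and the apnea threshold. Defaults are the pooled control-group
#' values from meta-analyses of acetazolamide studies in sleep-apnea
#' patients: 206 ml/min, 38.2 mmHg and 33.5 mmHg.
#'
#' @param vco2 CO2 production, ml/min; positive.
#' @param paco2_eup Eupneic paCO2, mmHg; must exceed `apnea_threshold`.
#' @param apnea_threshold Apnea-threshold paCO2, mmHg; positive.
#'
#' @return An object of class `baseline_inputs`.
#' @export
baseline_inputs <- function(vco2 = 206, paco2_eup = 38.2, apnea_threshold = 33.5) {
  vco2 <- scalar_pos(vco2, "vco2")
  paco2_eup <- scalar_pos(paco2_eup, "paco2_eup")
  apnea_threshold <- scalar_pos(apnea_threshold, "apnea_threshold")
  if (paco2_eup <= apnea_threshold) {
    stop("invalid geometry: `paco2_eup` must exceed `apnea_threshold`",
         call. = FALSE)
  }
  structure(
    list(vco2 = vco2, paco2_eup = paco2_eup, apnea_threshold = apnea_threshold),
    class = "baseline_inputs"
  )
}

#' Intervention specification as percent changes
#'
#' Describes an intervention by multiplicative percent changes applied to the
#' apnea threshold (negative = left shift of the chemosensitivity line, the
#' primary effect of acetazolamide), CO2 production, and controller gain.
#'
#' @param at_shift_pct Percent change of the apnea threshold (e.g. -15).
#' @param vco2_change_pct Percent change of CO2 production (e.g. +9).
#' @param cg_change_pct Percent change of controller gain (e.g. -11).
#'
#' @return An object of class `intervention_spec`.
#' @export
intervention_spec <- function(at_shift_pct = 0, vco2_change_pct = 0,
                              cg_change_pct = 0) {
  for (nm in c("at_shift_pct", "vco2_change_pct", "cg_change_pct")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= -100) {
      stop("`", nm, "` must be a single finite percent change > -100",
           call. = FALSE)
    }
  }
  structure(
    list(
      at_shift_pct = as.numeric(at_shift_pct),
      vco2_change_pct = as.numeric(vco2_change_pct),
      cg_change_pct = as.numeric(cg_change_pct)
    ),
    class = "intervention_spec"
  )
}

model_from_baseline <- function(base) {
  curve <- metabolic_curve(base$vco2)
  ctrl <- derive_controller(base$vco2, base$paco2_eup, base$apnea_threshold)
  list(curve = curve, ctrl = ctrl, op = solve_eupnea(curve, ctrl))
}

#' Apply an intervention to a baseline model
#'
#' Derives the controller line from the baseline anchors, applies the
#' percent changes of `spec` multiplicatively to the apnea threshold, CO2
#' production and controller gain, re-solves the eupneic operating point,
#' and reports percent changes in all derived quantities.
#'
#' @param base A [baseline_inputs()].
#' @param spec An [intervention_spec()].
#'
#' @return An object of class `model_comparison`: list with the baseline and
#'   post-intervention `operating_point`s, `pct_change` (named vector:
#'   `va_eup`, `paco2_eup`, `co2_reserve`, `va_reserve`, `plant_gain`,
#'   `loop_gain`, in percent) and `delta_mmHg` (absolute changes of
#'   `paco2_eup` and `apnea_threshold`).
#' @examples
#' apply_intervention(baseline_inputs(), intervention_spec(at_shift_pct = -15))
#' @export
apply_intervention <- function(base, spec) {
  stopifnot(inherits(base, "baseline_inputs"), inherits(spec, "intervention_spec"))
  m0 <- model_from_baseline(base)

  at1 <- base$apnea_threshold * (1 + spec$at_shift_pct / 100)
  vco21 <- base$vco2 * (1 + spec$vco2_change_pct / 100)
  g1 <- m0$ctrl$gain * (1 + spec$cg_change_pct / 100)
  if (at1 <= 0 || vco21 <= 0 || g1 <= 0) {
    stop("invalid geometry: intervention drives a parameter to zero or below",
         call. = FALSE)
  }
  curve1 <- metabolic_curve(vco21)
  op1 <- solve_eupnea(curve1, chemo_controller(g1, at1))

  pct <- function(new, old) 100 * (new / old - 1)
  op0 <- m0$op
  structure(
    list(
      baseline = op0,
      intervention = op1,
      spec = spec,
      pct_change = c(
        va_eup = pct(op1$va_eup, op0$va_eup),
        paco2_eup = pct(op1$paco2_eup, op0$paco2_eup),
        co2_reserve = pct(op1$co2_reserve, op0$co2_reserve),
        va_reserve = pct(op1$va_reserve, op0$va_reserve),
        plant_gain = pct(op1$plant_gain, op0$plant_gain),
        loop_gain = pct(op1$loop_gain, op0$loop_gain)
      ),
      delta_mmHg = c(
        paco2_eup = op1$paco2_eup - op0$paco2_eup,
        apnea_threshold = at1 - base$apnea_threshold
      )
    ),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(
    "Intervention: apnea threshold %+g%%, CO2 production %+g%%, controller gain %+g%%\n",
    x$spec$at_shift_pct, x$spec$vco2_change_pct, x$spec$cg_change_pct
  ))
  pc <- round(x$pct_change, 1)
  for (nm in names(pc)) cat(sprintf("  %-12s %+6.1f %%\n", nm, pc[[nm]]))
  cat(sprintf("  eupneic paCO2 change  %+5.1f mmHg\n", x$delta_mmHg[["paco2_eup"]]))
  cat(sprintf("  apnea threshold shift %+5.1f mmHg\n", x$delta_mmHg[["apnea_threshold"]]))
  invisible(x)
}

#' Compose a loop-gain percent change from its factors
#'
#' Loop gain is the product of controller and plant gain, so relative
#' changes compose multiplicatively:
#' `%dLG = ((1 + %dCG/100) * (1 + %dPG/100) - 1) * 100`.
#'
#' @param dcg_pct Percent change in controller gain (> -100).
#' @param dpg_pct Percent change in plant gain (> -100).
#'
#' @return Percent change in loop gain.
#' @export
compose_lg_change <- function(dcg_pct, dpg_pct) {
  if (any(dcg_pct <= -100) || any(dpg_pct <= -100)) {
    stop("percent changes must exceed -100", call. = FALSE)
  }
  ((1 + dcg_pct / 100) * (1 + dpg_pct / 100) - 1) * 100
}

#' Canonical four-scenario acetazolamide report
#'
#' Applies the four intervention scenarios supported by the pooled
#' meta-analytic estimates — a 15% left shift of the apnea threshold, alone
#' and combined with a 9% rise in CO2 production and/or an 11% fall in
#' controller gain — and tabulates the percent change in each derived
#' quantity.
#'
#' @param base A [baseline_inputs()]; defaults to the pooled control values.
#'
#' @return A data frame of class `intervention_table` with one row per model
#'   (1-4): the three spec columns and unrounded percent changes of
#'   `va_eup`, `paco2_eup`, `co2_reserve`, `va_reserve`, `plant_gain` and
#'   `loop_gain`. Printed rounded to 1 decimal.
#' @examples
#' intervention_table()
#' @export
intervention_table <- function(base = baseline_inputs()) {
  specs <- list(
    intervention_spec(-15, 0, 0),
    intervention_spec(-15, 9, 0),
    intervention_spec(-15, 0, -11),
    intervention_spec(-15, 9, -11)
  )
  rows <- lapply(seq_along(specs), function(i) {
    cmp <- apply_intervention(base, specs[[i]])
    data.frame(
      model = i,
      at_shift_pct = specs[[i]]$at_shift_pct,
      vco2_change_pct = specs[[i]]$vco2_change_pct,
      cg_change_pct = specs[[i]]$cg_change_pct,
      t(cmp$pct_change)
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("intervention_table", "data.frame")
  out
}

#' @export
print.intervention_table <- function(x, ...) {
  y <- as.data.frame(x)
  num <- c("va_eup", "paco2_eup", "co2_reserve", "va_reserve",
           "plant_gain", "loop_gain")
  y[num] <- lapply(y[num], round, 1)
  cat("Percent changes by intervention model (rounded to 1 decimal)\n")
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Reference loop-gain change of the primary intervention
#'
#' The percent loop-gain change produced by a pure 15% apnea-threshold left
#' shift at the given baseline (about -21.8% at the pooled baseline). Used
#' as the fixed denominator when expressing sweep results as relative
#' reductions.
#'
#' @param base A [baseline_inputs()].
#' @return Percent change in loop gain (negative).
#' @export
reference_dlg <- function(base = baseline_inputs()) {
  unname(apply_intervention(base, intervention_spec(-15, 0, 0))$pct_change["loop_gain"])
}

sweep_point <- function(vco2, paco2_eup, at, spec, shift, at_shift_mmHg) {
  # Returns c(dlg, ok). Degenerate geometry flagged, not dropped.
  if (!is.finite(at) || at <= 0 || at >= paco2_eup) {
    return(c(dlg = NA_real_, ok = 0))
  }
  base_j <- baseline_inputs(vco2, paco2_eup, at)
  spec_j <- if (shift == "absolute") {
    # fixed mmHg shift re-expressed as this baseline's own percent change
    intervention_spec(100 * at_shift_mmHg / at, spec$vco2_change_pct,
                      spec$cg_change_pct)
  } else {
    spec
  }
  cmp <- tryCatch(apply_intervention(base_j, spec_j), error = function(e) NULL)
  if (is.null(cmp)) return(c(dlg = NA_real_, ok = 0))
  c(dlg = unname(cmp$pct_change["loop_gain"]), ok = 1)
}

#' Sweep a baseline parameter and map the relative loop-gain reduction
#'
#' Varies one baseline input across a physiological range, applies the
#' intervention at every grid point, and expresses the loop-gain change as a
#' relative reduction `RR = %dLG / ref_dlg` against the fixed pooled-baseline
#' reference. At each grid point a self-consistent baseline is re-derived:
#' when sweeping `controller_gain`, CO2 production and eupneic paCO2 stay at
#' their pooled values and the apnea threshold is re-derived as
#' `paco2_eup - va_eup / gain`; when sweeping `paco2_eup` or `vco2`, the
#' controller gain stays at its pooled-baseline value and the apnea
#' threshold is re-derived the same way. This keeps each baseline on the
#' metabolic curve with a plausible chemosensitivity line.
#'
#' @param param One of `"controller_gain"` (L/min/mmHg), `"paco2_eup"`
#'   (mmHg) or `"vco2"` (ml/min).
#' @param grid Numeric vector of baseline values. Physiological ranges are
#'   0.5-3, 30-50 and 155-255 respectively; values outside trigger a warning.
#' @param spec The intervention to apply at each point; defaults to the pure
#'   -15% apnea-threshold shift.
#' @param base Pooled anchors held fixed where not swept.
#' @param ref_dlg Reference loop-gain change in percent (non-zero). Defaults
#'   to [reference_dlg()] of `base`.
#' @param shift `"relative"` applies `at_shift_pct` to each grid baseline's
#'   own apnea threshold; `"absolute"` applies the fixed mmHg shift the spec
#'   produces at the pooled baseline.
#' @param n_points Grid density used when `grid` is a range of length 2.
#'
#' @return A data frame of class `sweep_result` with columns `param`,
#'   `value`, `dlg_pct`, `rr` and `flagged` (TRUE where the re-derived
#'   baseline is geometrically degenerate; such points carry NA).
#' @examples
#' sweep_baseline("controller_gain", c(0.5, 3), n_points = 11)
#' @export
sweep_baseline <- function(param = c("controller_gain", "paco2_eup", "vco2"),
                           grid,
                           spec = intervention_spec(-15, 0, 0),
                           base = baseline_inputs(),
                           ref_dlg = NULL,
                           shift = c("relative", "absolute"),
                           n_points = 101) {
  param <- match.arg(param)
  shift <- match.arg(shift)
  stopifnot(inherits(spec, "intervention_spec"), inherits(base, "baseline_inputs"))
  if (length(grid) == 2L) grid <- seq(grid[1], grid[2], length.out = n_points)
  rng <- SWEEP_RANGES[[param]]
  if (any(grid < rng[1] | grid > rng[2])) {
    warning(sprintf("grid extends outside the physiological range [%g, %g] for %s",
                    rng[1], rng[2], param))
  }
  ref_dlg <- ref_dlg %||% reference_dlg(base)
  if (!is.numeric(ref_dlg) || length(ref_dlg) != 1L || ref_dlg == 0) {
    stop("`ref_dlg` must be a single non-zero percent change", call. = FALSE)
  }

  m0 <- model_from_baseline(base)
  g0 <- m0$ctrl$gain
  at_shift_mmHg <- base$apnea_threshold * spec$at_shift_pct / 100

  pts <- vapply(grid, function(v) {
    if (param == "controller_gain") {
      va <- K_BTPS * base$vco2 / base$paco2_eup
      sweep_point(base$vco2, base$paco2_eup, base$paco2_eup - va / v,
                  spec, shift, at_shift_mmHg)
    } else if (param == "paco2_eup") {
      va <- K_BTPS * base$vco2 / v
      sweep_point(base$vco2, v, v - va / g0, spec, shift, at_shift_mmHg)
    } else {
      va <- K_BTPS * v / base$paco2_eup
      sweep_point(v, base$paco2_eup, base$paco2_eup - va / g0,
                  spec, shift, at_shift_mmHg)
    }
  }, c(dlg = 0, ok = 0))

  out <- data.frame(
    param = param,
    value = grid,
    dlg_pct = pts["dlg", ],
    rr = pts["dlg", ] / ref_dlg,
    flagged = pts["ok", ] == 0
  )
  class(out) <- c("sweep_result", "data.frame")
  attr(out, "ref_dlg") <- ref_dlg
  out
}

#' Sweep the magnitude of the apnea-threshold left shift
#'
#' Varies the size of the left shift of the chemosensitivity line at a fixed
#' baseline and reports the relative loop-gain reduction for each shift,
#' normalised to the fixed pooled-baseline reference (so the -15% shift maps
#' to RR = 1 and no shift to RR = 0).
#'
#' @param shift_grid Percent shifts in `(-100, 0]` (negative = left shift),
#'   or a length-2 range expanded to `n_points` values.
#' @param base A [baseline_inputs()].
#' @param ref_dlg Reference loop-gain change; defaults to [reference_dlg()].
#' @param n_points Grid density when `shift_grid` is a range.
#'
#' @return A `sweep_result` data frame (`param = "at_shift_pct"`).
#' @examples
#' sweep_shift(c(-30, 0), n_points = 7)
#' @export
sweep_shift <- function(shift_grid, base = baseline_inputs(), ref_dlg = NULL,
                        n_points = 101) {
  stopifnot(inherits(base, "baseline_inputs"))
  if (length(shift_grid) == 2L) {
    shift_grid <- seq(shift_grid[1], shift_grid[2], length.out = n_points)
  }
  if (any(shift_grid > 0 | shift_grid <= -100)) {
    stop("shifts must lie in (-100, 0]", call. = FALSE)
  }
  ref_dlg <- ref_dlg %||% reference_dlg(base)
  dlg <- vapply(shift_grid, function(s) {
    if (s == 0) return(0)
    cmp <- tryCatch(apply_intervention(base, intervention_spec(s, 0, 0)),
                    error = function(e) NULL)
    if (is.null(cmp)) NA_real_ else unname(cmp$pct_change["loop_gain"])
  }, numeric(1))
  out <- data.frame(
    param = "at_shift_pct",
    value = shift_grid,
    dlg_pct = dlg,
    rr = dlg / ref_dlg,
    flagged = is.na(dlg)
  )
  class(out) <- c("sweep_result", "data.frame")
  attr(out, "ref_dlg") <- ref_dlg
  out
}
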