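# Steady-state chemoreflex model: metabolic hyperbola, chemosensitivity line,
# and the eupneic operating point with its derived gains and reserves.

# Conversion constant linking CO2 production (ml/min STPD) and paCO2 (mmHg)
# to alveolar ventilation (L/min BTPS). Fixed by convention; not a tuning knob.
K_BTPS <- 0.863

`%||%` <- function(x, y) if (is.null(x)) y else x

scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("`", name, "` must be a single positive finite number", call. = FALSE)
  }
  as.numeric(x)
}

#' Metabolic (isometabolic) curve
#'
#' The hyperbola `VA = 0.863 * vco2 / paCO2` linking alveolar ventilation to
#' alveolar/arterial CO2 tension at a fixed metabolic CO2 production. At a
#' given CO2 production, every steady state of gas exchange must lie on this
#' curve, so it is one of the two constraints that fix the eupneic operating
#' point.
#'
#' @param vco2 Metabolic CO2 production in ml/min (STPD). Must be positive.
#'
#' @return An object of class `metabolic_curve` with fields `vco2` and the
#'   fixed conversion constant `k = 0.863` (giving VA in L/min BTPS).
#' @examples
#' curve <- metabolic_curve(206)
#' metabolic_va(curve, 38.2)   # eupneic ventilation at paCO2 = 38.2 mmHg
#' @export
metabolic_curve <- function(vco2) {
  structure(
    list(vco2 = scalar_pos(vco2, "vco2"), k = K_BTPS),
    class = "metabolic_curve"
  )
}

#' Chemosensitivity line (ventilatory controller)
#'
#' Linear hypercapnic ventilatory response: above the apnea threshold,
#' ventilation rises with paCO2 at a constant slope (the controller gain,
#' i.e. the ventilatory response to CO2); at and below the threshold
#' ventilation is zero. The line is rectified because negative ventilation is
#' physically meaningless and the threshold is, by definition, where
#' ventilation stops.
#'
#' @param gain Controller gain (chemosensitivity slope) in L/min/mmHg; > 0.
#' @param apnea_threshold paCO2 at which ventilation ceases, in mmHg; > 0.
#'
#' @return An object of class `chemo_controller`.
#' @examples
#' ctrl <- chemo_controller(gain = 0.99, apnea_threshold = 33.5)
#' controller_va(ctrl, c(30, 33.5, 38.2))
#' @export
chemo_controller <- function(gain, apnea_threshold) {
  structure(
    list(
      gain = scalar_pos(gain, "gain"),
      apnea_threshold = scalar_pos(apnea_threshold, "apnea_threshold")
    ),
    class = "chemo_controller"
  )
}

#' Alveolar ventilation on the metabolic curve
#'
#' @param curve A [metabolic_curve()].
#' @param paco2 paCO2 in mmHg; strictly positive (vectorised).
#'
#' @return Alveolar ventilation in L/min, `k * vco2 / paco2`.
#' @export
metabolic_va <- function(curve, paco2) {
  stopifnot(inherits(curve, "metabolic_curve"))
  if (!is.numeric(paco2) || any(!is.finite(paco2)) || any(paco2 <= 0)) {
    stop("`paco2` must be positive and finite", call. = FALSE)
  }
  curve$k * curve$vco2 / paco2
}

#' Ventilatory drive from the chemosensitivity line
#'
#' @param ctrl A [chemo_controller()].
#' @param paco2 paCO2 in mmHg; non-negative (vectorised).
#'
#' @return Ventilation in L/min: `max(0, gain * (paco2 - apnea_threshold))`.
#' @export
controller_va <- function(ctrl, paco2) {
  stopifnot(inherits(ctrl, "chemo_controller"))
  if (!is.numeric(paco2) || any(!is.finite(paco2)) || any(paco2 < 0)) {
    stop("`paco2` must be non-negative and finite", call. = FALSE)
  }
  pmax(0, ctrl$gain * (paco2 - ctrl$apnea_threshold))
}

#' Derive the chemosensitivity line from anchor observations
#'
#' Fixes the controller line from two anchors: the eupneic point, which must
#' lie on the metabolic curve for the given CO2 production, and the apnea
#' threshold (its x-intercept). The slope is then
#' `VA(paco2_eup) / (paco2_eup - apnea_threshold)`. This is how a pooled set
#' of control-condition observations (CO2 production, eupneic paCO2, apnea
#' threshold) determines a complete model.
#'
#' @param vco2 CO2 production, ml/min.
#' @param paco2_eup Eupneic paCO2, mmHg; must exceed `apnea_threshold`.
#' @param apnea_threshold Apnea-threshold paCO2, mmHg.
#'
#' @return A [chemo_controller()] whose line passes through the eupneic point.
#' @examples
#' derive_controller(206, 38.2, 33.5)  # gain ~ 0.990 L/min/mmHg
#' @export
derive_controller <- function(vco2, paco2_eup, apnea_threshold) {
  vco2 <- scalar_pos(vco2, "vco2")
  paco2_eup <- scalar_pos(paco2_eup, "paco2_eup")
  apnea_threshold <- scalar_pos(apnea_threshold, "apnea_threshold")
  if (paco2_eup <= apnea_threshold) {
    stop("invalid geometry: `paco2_eup` must exceed `apnea_threshold` ",
         "(the eupneic point lies above the x-intercept)", call. = FALSE)
  }
  va_eup <- K_BTPS * vco2 / paco2_eup
  chemo_controller(
    gain = va_eup / (paco2_eup - apnea_threshold),
    apnea_threshold = apnea_threshold
  )
}

#' Plant gain of the metabolic curve at a given paCO2
#'
#' Plant gain is the efficiency of CO2 excretion: the reciprocal slope
#' (d paCO2 / d VA) of the metabolic hyperbola's tangent, equal to
#' `paco2^2 / (k * vco2)`. It satisfies the tangent identity
#' `plant_gain * VA(paco2) = paco2` exactly.
#'
#' @param curve A [metabolic_curve()].
#' @param paco2 paCO2 in mmHg; positive (vectorised).
#'
#' @return Plant gain in mmHg per L/min.
#' @export
plant_gain_at <- function(curve, paco2) {
  stopifnot(inherits(curve, "metabolic_curve"))
  if (!is.numeric(paco2) || any(!is.finite(paco2)) || any(paco2 <= 0)) {
    stop("`paco2` must be positive and finite", call. = FALSE)
  }
  paco2^2 / (curve$k * curve$vco2)
}

#' Loop gain as the product of controller and plant gain
#'
#' The steady-state loop gain of the ventilatory feedback loop is
#' proportional to controller gain times plant gain; this package uses the
#' raw product and interprets only its relative changes.
#'
#' @param gain Controller gain, L/min/mmHg; positive.
#' @param plant_gain Plant gain, mmHg per L/min; positive.
#'
#' @return Dimensionless loop gain (the product).
#' @export
loop_gain <- function(gain, plant_gain) {
  if (any(gain <= 0) || any(plant_gain <= 0)) {
    stop("`gain` and `plant_gain` must be positive", call. = FALSE)
  }
  gain * plant_gain
}

#' Solve for the eupneic operating point
#'
#' The eupneic steady state is the intersection of the chemosensitivity line
#' and the metabolic hyperbola above the apnea threshold. Substituting the
#' line into the hyperbola gives the quadratic
#' `gain * p^2 - gain * AT * p - k * vco2 = 0`, whose unique root above the
#' threshold is `p = (AT + sqrt(AT^2 + 4 k vco2 / gain)) / 2`. The root
#' always exists and is unique for valid inputs, so the closed form is used
#' directly (no iteration).
#'
#' @param curve A [metabolic_curve()].
#' @param ctrl A [chemo_controller()].
#'
#' @return An object of class `operating_point`: a list with
#'   `paco2_eup` (mmHg), `va_eup` (L/min), `plant_gain` (mmHg/L/min),
#'   `loop_gain` (dimensionless), `co2_reserve` (mmHg; eupneic paCO2 minus
#'   apnea threshold) and `va_reserve` (L/min; extra ventilation, along the
#'   metabolic curve, needed to drive paCO2 down to the apnea threshold).
#' @examples
#' op <- solve_eupnea(metabolic_curve(206), derive_controller(206, 38.2, 33.5))
#' op$paco2_eup  # 38.2
#' op$loop_gain  # ~ 8.13
#' @export
solve_eupnea <- function(curve, ctrl) {
  stopifnot(inherits(curve, "metabolic_curve"), inherits(ctrl, "chemo_controller"))
  at <- ctrl$apnea_threshold
  kv <- curve$k * curve$vco2
  p <- (at + sqrt(at^2 + 4 * kv / ctrl$gain)) / 2
  va <- kv / p
  pg <- p^2 / kv
  structure(
    list(
      paco2_eup = p,
      va_eup = va,
      plant_gain = pg,
      loop_gain = ctrl$gain * pg,
      co2_reserve = p - at,
      va_reserve = kv / at - va,
      curve = curve,
      controller = ctrl
    ),
    class = "operating_point"
  )
}

#' @export
print.operating_point <- function(x, digits = 3, ...) {
  cat("Eupneic operating point\n")
  cat(sprintf("  paCO2 at eupnea : %s mmHg\n", format(x$paco2_eup, digits = digits)))
  cat(sprintf("  VA at eupnea    : %s L/min\n", format(x$va_eup, digits = digits)))
  cat(sprintf("  plant gain      : %s mmHg/L/min\n", format(x$plant_gain, digits = digits)))
  cat(sprintf("  controller gain : %s L/min/mmHg\n", format(x$controller$gain, digits = digits)))
  cat(sprintf("  loop gain       : %s\n", format(x$loop_gain, digits = digits)))
  cat(sprintf("  CO2 reserve     : %s mmHg\n", format(x$co2_reserve, digits = digits)))
  cat(sprintf("  VA reserve      : %s L/min\n", format(x$va_reserve, digits = digits)))
  invisible(x)
}

#' Flatten an operating point to a named numeric record
#'
#' @param op An `operating_point`.
#' @return A named numeric vector of all scalar quantities.
#' @export
as_record <- function(op) {
  stopifnot(inherits(op, "operating_point"))
  c(
    vco2 = op$curve$vco2,
    controller_gain = op$controller$gain,
    apnea_threshold = op$controller$apnea_threshold,
    paco2_eup = op$paco2_eup,
    va_eup = op$va_eup,
    plant_gain = op$plant_gain,
    loop_gain = op$loop_gain,
    co2_reserve = op$co2_reserve,
    va_reserve = op$va_reserve
  )
}
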