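---
title: "Steady-state ventilatory control: model, interventions, and the meta-analysis engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady-state ventilatory control: model, interventions, and the meta-analysis engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventcontrol)
```

## The model

Breathing is controlled by a negative feedback loop: the chemoreceptors (the
*controller*) raise ventilation when arterial CO2 rises, and the lungs (the
*plant*) excrete CO2 in proportion to ventilation. The steady state of this
loop is described by two curves in the (paCO2, ventilation) plane.

The **metabolic (isometabolic) curve** is the mass-balance hyperbola

$$\dot V_A = \frac{0.863 \cdot \dot V_{CO_2}}{p_a CO_2},$$

with alveolar ventilation in L/min (BTPS), CO2 production in ml/min (STPD)
and paCO2 in mmHg; 0.863 is the standard unit-conversion constant and is
hard-coded (`metabolic_curve()` takes only the CO2 production). Alveolar and
arterial CO2 tensions are treated as equal throughout.

The **chemosensitivity line** is the linear hypercapnic ventilatory response,

$$\dot V_A = \max\{0,\; G_C \,(p_a CO_2 - AT)\},$$

where $G_C$ is the controller gain (L/min/mmHg) and $AT$ the apnea threshold
— the paCO2 at which ventilation stops. The line is rectified at zero below
the threshold because negative ventilation is meaningless; the same slope is
assumed above and below eupnea.

The **eupneic operating point** is their intersection above the threshold.
Substituting the line into the hyperbola gives a quadratic with a unique
admissible root,

$$p^* = \tfrac12\left(AT + \sqrt{AT^2 + 4 \cdot 0.863\, \dot V_{CO_2} / G_C}\right),$$

which `solve_eupnea()` evaluates in closed form — exact, branch-free, and
cheap enough to call inside dense parameter sweeps. A bracketing bisection
solver exists only in the test suite, as an independent oracle.

From the operating point follow the derived quantities:

* **plant gain** $PG = (p^*)^2 / (0.863\, \dot V_{CO_2})$, the reciprocal
  slope of the hyperbola's tangent (mmHg per L/min), which satisfies the
  identity $PG \times \dot V_A(p^*) = p^*$ exactly;
* **loop gain** $LG = G_C \times PG$ (dimensionless);
* **CO2 reserve** $p^* - AT$ (mmHg) and **ventilatory reserve**
  $0.863\,\dot V_{CO_2}/AT - \dot V_A^*$ (L/min), the protection margins
  against central apnea.

Three scalars anchor the whole model. The package defaults are the pooled
control-condition values from meta-analyses of acetazolamide studies in
sleep-apnea patients: CO2 production 206 ml/min, eupneic paCO2 38.2 mmHg,
apnea threshold 33.5 mmHg. `derive_controller()` then fixes
$G_C \approx 0.990$ L/min/mmHg, and the baseline loop gain is the raw
product $\approx 8.1$.

Two caveats about that raw product. The model-implied baseline plant gain
(about 8.2 mmHg/L/min) is larger than directly measured pooled plant gains
(about 5.4), and the geometric CO2 reserve (38.2 − 33.5 = 4.7 mmHg) is
larger than the measured pooled reserve (4.0 mmHg); the steady-state
geometry and the measurements are not reconciled here. For that reason the
package interprets loop gain **only through its relative changes** — the
raw product is never rescaled to match measured dynamic loop gains
(around 0.5), and no absolute loop-gain threshold is ever asserted.

```{r baseline}
op <- solve_eupnea(metabolic_curve(206), derive_controller(206, 38.2, 33.5))
op
```

## Interventions

Acetazolamide induces a metabolic acidosis that shifts the chemosensitivity
line left. `intervention_spec()` expresses an intervention as multiplicative
percent changes of the apnea threshold, CO2 production, and controller
gain; `apply_intervention()` re-solves the operating point and reports
percent changes of every derived quantity. Because loop gain is a product,
its percent change composes exactly as

$$\%\Delta LG = \left[(1 + \%\Delta G_C/100)(1 + \%\Delta PG/100) - 1\right] \times 100,$$

and `compose_lg_change()` makes that identity available (and testable)
separately.

`intervention_table()` applies the four scenarios consistent with the pooled
meta-analytic estimates — the 15% left shift alone, plus optional +9% CO2
production and/or −11% controller gain:

```{r table}
intervention_table()
```

The pure left shift illustrates the convexity of the hyperbola: the
threshold falls by 5.0 mmHg but eupneic paCO2 falls by only 4.4 mmHg, so
both reserves grow even though the controller's slope never changed. With
the controller gain untouched, the loop-gain change equals the plant-gain
change exactly (scenarios 1 and 2).

## Sensitivity sweeps

`sweep_baseline()` varies one baseline condition over its physiological
range (controller gain 0.5–3 L/min/mmHg, eupneic paCO2 30–50 mmHg, CO2
production 155–255 ml/min; off-range grids warn), applies the intervention
at each point, and reports the **relative reduction**
$RR = \%\Delta LG / \%\Delta LG_0$, where the reference $\%\Delta LG_0$ is
the pooled-baseline change under the pure 15% shift. Three design choices
deserve explanation:

* **Self-consistent baselines.** A swept value must still describe a
  coherent steady state. When the controller gain is swept, CO2 production
  and eupneic paCO2 are held at pooled values and the apnea threshold is
  re-derived as $p^* - \dot V_A^*/G_C$; when eupneic paCO2 or CO2
  production is swept, the controller gain is held at its pooled-derived
  value and the threshold is re-derived the same way. The alternative —
  holding the threshold fixed — reverses the direction of the eupneic-paCO2
  sensitivity and is therefore not used.
* **Fixed reference.** The denominator is the *unrounded* pooled-baseline
  change (−21.76%, conventionally quoted as −21.8%), computed once and held
  fixed across the grid, so that $RR = 1$ holds to machine precision at the
  pooled baseline. Quoting the rounded −21.8 as the denominator would shift
  every RR by ~0.2%.
* **Relative vs absolute shift.** The 15% shift is applied to each grid
  baseline's *own* threshold by default (`shift = "relative"`); whether
  published sensitivity curves used a relative or a fixed-mmHg shift at
  off-baseline grid points is not stated, so `shift = "absolute"` applies
  the pooled-baseline 5.0 mmHg shift instead. Grid density defaults to 101
  evenly spaced points. Degenerate grid points (a re-derived threshold at
  or below zero) are flagged, never silently dropped.

```{r sweep}
head(sweep_baseline("controller_gain", c(0.5, 3), n_points = 11), 4)
sweep_shift(c(-25, -15, -5, 0))
```

Higher baseline controller gain (up to ~18% greater reduction at gain 3),
higher eupneic paCO2 (~10%) and lower CO2 production (~6%) all amplify the
loop-gain reduction; the shift magnitude itself is the dominant driver
(RR ≈ 1.6 at a 25% shift).

## The meta-analysis engine

The baseline anchors above come from two-group study summaries pooled on the
**ratio of means** scale: per study, $y_i = \ln(\bar x_t / \bar x_c)$ with
delta-method variance $v_i = s_t^2/(n_t \bar x_t^2) + s_c^2/(n_c \bar
x_c^2)$ (`rom_effect()`; means must be positive, SDs positive, n ≥ 2 per
arm). `pool()` performs inverse-variance pooling with Cochran's $Q$, $I^2$,
and the DerSimonian–Laird $\tau^2$ (truncated at zero); with
`method = "auto"` a random-effects model is used exactly when $I^2 > 30\%$,
the conventional threshold for more-than-mild heterogeneity. DL is used
because it is the standard moment estimator for this class of analysis; the
Knapp–Hartung small-sample adjustment is deliberately not applied, and
p-values and CIs are two-sided normal-theory. All arms are treated as
independent two-group comparisons, including crossover and
baseline-controlled designs, because within-subject correlations are
essentially never reported in this literature — pooled variances are
therefore conservative for such designs.

Supporting operations mirror how such tables are reported:
`weighted_control_stats()` averages control-arm means and SDs with the
pooling weights (the weighted SD is the weighted average of study SDs, not
a pooled variance; a `"pooled"` option exists because the convention is
ambiguous); `absolute_difference()` maps a pooled ratio and its CI bounds
back to the control scale as $ROM \times \bar x_{wt} - \bar x_{wt}$;
`meta_regress()` runs weighted least squares of effects on a moderator
(dose, say) with $1/(v_i + \tau^2)$ weights and fixed-weight normal-theory
covariance; `leave_one_out()` re-pools with each study omitted;
`smd_effect()` provides the Hedges-corrected standardized mean difference
as a scale-free cross-check, poolable by the same engine. Meta-regression
accepts two studies (a two-point fit interpolates exactly) although three
or more are needed for any meaningful inference.

The per-study summaries behind the published pooled acetazolamide estimates
are not available anywhere, so the engine's correctness is established two
ways: against an independent reference implementation (`metafor`, in the
test suite) on a fixed fixture, and by simulation with known truth.

## The synthetic study generator

`sim_config()`/`generate_studies()` simulate the kind of study set the
engine was built for: per study a latent log ratio drawn from
$N(\ln ROM_{true}, \tau^2)$ and a true control mean drawn around a
configured location; subject-level observations are then drawn per arm and
*summarised*, so observed means and SDs are genuine sample statistics and
the small-sample noise of the delta-method variance is exercised rather
than idealised away. Defaults describe the study conditions of interest: a
true ratio of 0.85, homogeneous studies, 20 studies of 50 subjects per arm,
control means 38.2 ± 3.7 (emulating the pooled eupneic-paCO2 control
distribution) and within-arm coefficients of variation of 5–15% (the pooled
control CV of paCO2-like outcomes is about 10%). Arms are normal by
default; a lognormal option serves strictly-positive small-mean outcomes. A
seed is mandatory and the generator restores the caller's RNG state.

What the generator does **not** emulate: correlated arms (crossover
designs), reporting errors (SE-vs-SD confusion — treated as an input-data
correction, not an engine feature), publication bias, or non-normal
outcome distributions beyond the lognormal option. Passing calibration
tests therefore demonstrates the estimator's internal correctness, not
robustness to those real-data pathologies.

`recovery_experiment()` repeats generate-and-pool and aggregates bias,
RMSE, CI coverage, mean $I^2$ and the $\tau^2$ distribution. Under the
default homogeneous configuration (2000 replicates in the acceptance
suite), 95% CI coverage lies in 93–97% and mean $I^2$ below 10; with
$\tau^2 = 0.04$ and 50 studies (500 replicates), the median DL estimate
recovers $\tau^2$ within [0.02, 0.06].

```{r recovery}
recovery_experiment(sim_config(n_studies = 20, seed = 42), reps = 200)
```

## Numerical notes and limitations

* The quadratic root is evaluated directly; its discriminant
  $AT^2 + 4 \cdot 0.863 \dot V_{CO_2}/G_C$ is a sum of positive terms, so no
  cancellation occurs and no special-casing is needed. The test suite checks
  agreement with bisection to 1e−6 mmHg over 1000 random parameter draws and
  the tangent identity to 1e−9.
* Percent changes are kept unrounded internally; rounding to one decimal is
  display-only (`print` methods and the `*_1dp` companion columns written by
  `write_results()`).
* The model is steady-state and linear: dynamic (frequency-domain) loop
  gain, mixing gain and circulatory delay, the hypoxic response and its
  interaction with CO2 sensitivity, and dead-space/minute-ventilation
  partitioning are all outside its scope, as is any prediction of
  apnea-severity outcomes. Simulation sizes in the test suite (2000 and 500
  replicates; up to 200 studies of 500 subjects) were chosen so that Monte
  Carlo error is well below the tolerance bands being asserted.
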