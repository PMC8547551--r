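# ventcontrol

Steady-state modelling of the chemoreflex control of breathing, with an
intervention simulator for acetazolamide-style shifts of the
chemosensitivity line and a ratio-of-means meta-analysis engine for the
two-group study summaries that anchor the model.

## Who this is for

Sleep and respiratory physiologists studying ventilatory instability
("high loop gain") in obstructive and central sleep apnea, and
meta-analysts pooling control-of-breathing parameters across small
physiological studies. The package answers questions such as: *if a drug
shifts the apnea threshold left by 15%, how much does loop gain fall — and
how does that depend on a patient's baseline chemosensitivity?*

## The model

Two curves in the (paCO₂, ventilation) plane determine the steady state:

- the metabolic hyperbola `V̇A = 0.863 · V̇CO₂ / paCO₂` (alveolar
  ventilation in L/min, CO₂ production in ml/min, pressures in mmHg), and
- the chemosensitivity line `V̇A = max(0, G_C · (paCO₂ − AT))`, with
  controller gain `G_C` and apnea threshold `AT`.

Their intersection above the threshold — the eupneic operating point — has
the closed form `p* = (AT + √(AT² + 4·0.863·V̇CO₂/G_C)) / 2`. From it
follow plant gain `PG = p*²/(0.863·V̇CO₂)`, loop gain `LG = G_C × PG`, and
the CO₂ and ventilatory reserves. Interventions are percent changes of
`AT`, `V̇CO₂` and `G_C`; loop-gain changes compose exactly as
`%ΔLG = ((1+%ΔG_C/100)(1+%ΔPG/100)−1)·100`.

The meta-analysis engine pools log ratios of means
`y = ln(mean_t/mean_c)` with delta-method variances by inverse-variance
weighting, DerSimonian–Laird τ², Cochran's Q and I² (random effects
selected automatically when I² > 30%), plus weighted control statistics,
implied absolute differences, meta-regression, leave-one-out sensitivity
and a standardized-mean-difference cross-check. A seeded synthetic study
generator makes all of it testable against known truth.

## Worked example

```r
library(ventcontrol)

# pooled control-condition anchors: V̇CO₂ 206 ml/min, eupneic paCO₂ 38.2,
# apnea threshold 33.5 mmHg
run_model()$baseline
#>            vco2 controller_gain apnea_threshold       paco2_eup          va_eup
#>     206.0000000       0.9901860      33.5000000      38.2000000       4.6538743
#>      plant_gain       loop_gain     co2_reserve      va_reserve
#>       8.2082147       8.1276596       4.7000000       0.6529316

# the four intervention scenarios (15% threshold left shift, alone or with
# +9% CO2 production and/or -11% controller gain)
intervention_table()
#> Percent changes by intervention model (rounded to 1 decimal)
#>  model at_shift_pct vco2_change_pct cg_change_pct va_eup paco2_eup co2_reserve
#>      1          -15               0             0   13.1     -11.5        13.1
#>      2          -15               9             0   21.8     -10.5        21.8
#>      3          -15               0           -11   11.2     -10.1        25.0
#>      4          -15               9           -11   19.7      -8.9        34.5
#>  va_reserve plant_gain loop_gain
#>        50.4      -21.8     -21.8
#>        74.4      -26.5     -26.5
#>        63.5      -19.2     -28.0
#>        89.3      -23.9     -32.3
```

Reading the first row: the pure 15% left shift lowers the apnea threshold
by 5.0 mmHg but eupneic paCO₂ by only 4.4 mmHg (−11.5%), because the
hyperbola steepens as ventilation rises; both protection margins grow (CO₂
reserve +13.1%, ventilatory reserve +50.4%) and loop gain falls 21.8% —
entirely through plant gain, since the controller's slope never moved.

Sweeping baseline conditions shows who benefits most (RR is the loop-gain
reduction relative to the pooled baseline's −21.8%):

```r
sweep_shift(c(-25, -15, -5, 0))
#>          param value    dlg_pct        rr flagged
#> 1 at_shift_pct   -25 -34.441878 1.5826158   FALSE
#> 2 at_shift_pct   -15 -21.762627 1.0000000   FALSE
#> 3 at_shift_pct    -5  -7.623306 0.3502935   FALSE
#> 4 at_shift_pct     0   0.000000 0.0000000   FALSE
```

A command-line front end wrapping these functions is installed at
`system.file("scripts", "ventcontrol", package = "ventcontrol")`, with
subcommands `model`, `report`, `sweep`, `shift-sweep`, `meta` and
`simulate`.

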