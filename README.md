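# pcpredox

Quantitative analysis of competing anaerobic redox processes and reductive
dechlorination of pentachlorophenol (PCP) in flooded soil microcosms.

In an anoxic, lactate-fed paddy soil, nitrate, Fe(III) oxides, sulfate and
PCP all act as terminal electron acceptors and compete for the same electron
flow. `pcpredox` is a tidyverse-native toolkit for analysing (and
simulating) such systems:

* **Logistic kinetics** — fit the three-parameter logistic
  `C_t = a / (1 + b·e^(−kt))` to cumulative reduction curves (accumulated
  Fe(II); decrement of sulfate or PCP) and derive the maximum reaction rate
  `Vmax = 0.25·a·k` and its timing `t_Vmax = ln(b)/k`.
* **Electron-equivalent ledger** — balance donor equivalents (lactate, 12
  eeq/mol) against Fe(III) (1), NO₃⁻ (5), SO₄²⁻ (8 eeq/mol) and reductive
  dechlorination (2 eeq per chlorine removed).
* **Congener pathway bookkeeping** — chlorophenols as chlorine ring-position
  sets, with ortho/meta/para classification of each dechlorination step and
  pathway inference from time-series first detection.
* **Sequential first-order (Bateman) chain kinetics** — simulate and fit the
  metabolite cascade PCP → TeCP → TCP → DCP → 3-CP with chlorine mass
  balance and an onset lag.
* **Synthetic microcosm generator** — seeded, fully reproducible datasets
  with redox-tower structure, amendment-dependent inhibition of
  dechlorination, replicates, noise, and recorded ground truth for
  end-to-end parameter-recovery testing.

## Worked example

Derived statistics from fitted logistic parameters (a control sulfate
reduction curve: `a` = 5.91 mM, `b` = 9.03, `k` = 0.21 d⁻¹):

```r
library(pcpredox)

p <- logistic_params(a = 5.91, b = 9.03, k = 0.21)
vmax(p)    # 0.31  -> at most 0.31 mM sulfate reduced per day
t_vmax(p)  # 10.48 -> the rate peaks 10.5 days into incubation
```

Simulate a 20 mM sulfate-amended microcosm and fit every analyte:

```r
ds <- generate_microcosm(microcosm_config(seed = 1, sulfate_mM = 20))
ds
#> <synthetic_microcosm> S20: 7 analytes x 7 days x 3 replicates (seed 1)

fit_logistic_curves(ds$samples)
#>   treatment_id analyte       a       b     k   vmax t_vmax    r2 converged
#> 1          S20     fe2 119.363 233.939 0.798 23.822  6.833 0.999      TRUE
#> 2          S20     pcp 140.013  24.864 0.267  9.351 12.028 0.985      TRUE
#> 3          S20 sulfate  21.664  18.303 0.250  1.351 11.651 0.995      TRUE
```

The fitted PCP `t_vmax` of 12.0 d (vs ≈ 10 d for an unamended control — try
`sulfate_mM = 0`) shows the simulated competitive suppression of
dechlorination by sulfate; the sulfate capacity `a` ≈ 21.7 mM is 90% of the
26.67 mM pool (background + amendment).

The electron budget of a control microcosm (20 mM lactate in 0.015 L adds
3.6 mmol eeq):

```r
build_ledger("control", eeq_added(20, 0.015),
             fe3 = 1.65, no3 = 0, so4 = 0.72, dechlorination = 0.021)
#>   treatment_id added_mmol  fe3 no3  so4 dechlorination total_consumed_mmol
#> 1      control        3.6 1.65   0 0.72          0.021               2.391
```

Dechlorination consumes ~0.02 of 3.6 mmol eeq — a minor electron sink, which
is why it is so easily out-competed. Finally, the observed metabolite chain
classifies as *ortho, ortho, para, meta*:

```r
infer_pathway(c("PCP", "2,3,4,5-TeCP", "3,4,5-TCP", "3,5-DCP", "3-CP"))
#>    step parent       child        removed_position position_class
#>   1     1 PCP          2,3,4,5-TeCP                6 ortho
#>   2     2 2,3,4,5-TeCP 3,4,5-TCP                   2 ortho
#>   3     3 3,4,5-TCP    3,5-DCP                     4 para
#>   4     4 3,5-DCP      3-CP                        5 meta
```

See `vignette("anaerobic-redox-kinetics")` for the models, assumptions and
design choices, and `inst/cli/pcpredox-cli.R` for a thin command-line
wrapper over the simulate / fit / eeq / pathway pipeline.

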