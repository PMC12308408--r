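# tagkin

Kinetic analysis of self-labeling protein tag reactions in R.

Self-labeling tags (SNAP-tag and relatives) react covalently and
irreversibly with benzylguanine substrates, and photoactivatable variants
carrying a caged active-site tyrosine switch this reaction on with light.
Quantifying how fast a given variant labels — in the cuvette and in live
cells — is the central measurement for engineering and applying these
tags. tagkin is for protein engineers and imaging labs who have
polarization traces, stopped-flow families, or per-cell intensity tables
and want rate constants with honest uncertainties.

The core model is the two-step scheme

```
P + S  ⇌(k1, k−1)  PS  →(k2)  PS*
```

with dissociation constant K_d = k−1/k1 and apparent second-order
labeling rate constant

```
k_app = k1·k2 / (k2 + k−1)      [M⁻¹ s⁻¹]
```

so that under protein excess the product rises monoexponentially with
rate k_app·[P] and half-time t½ = ln 2 / (k_app·[P]).

The package provides, as tidyverse-style functions over tibbles:

* **Kinetic core** — mass-action ODE simulation (`simulate_timecourse()`),
  a closed-form pseudo-first-order solution (`pfo_trajectory()`), and the
  derived quantities (`derived_kd()`, `derived_kapp()`, `half_time()`).
* **Polarization fits** — monoexponential association fitting with a
  principled "not determinable" classification for reactions too slow for
  the measurement window (`fit_fp_trace()`, `classify_determinability()`).
* **Stopped-flow global fitting** — replicate averaging, baseline
  subtraction, and joint fitting of trace families to the two-step model
  with a fixed mixing delay, per-trace offsets, a shared response
  coefficient, and Monte-Carlo parameter SDs (`fit_sf_global()`,
  `mc_errors()`).
* **Live-cell metrics** — reference-normalized labeling time courses,
  fold increase, labeling half-lives, nuclear intensity ratios, and
  amber-suppression efficiency from per-cell region tables
  (`fit_labeling_halflife()`, `nuclear_ratio()`,
  `amber_suppression_efficiency()`).
* **Synthetic data** — seeded generators emulating each assay design
  (`gen_fp_trace()`, `gen_sf_family()`, `gen_cell_timecourse()`,
  `gen_region_table()`), so every estimator is testable end to end.

Fitted objects have `tidy()`, `glance()`, `augment()` and `autoplot()`
methods.

## Worked example

Fit a synthetic polarization trace generated at the canonical fast rate
(k_app = 6.8×10⁴ M⁻¹s⁻¹, 200 nM protein, 50 nM substrate, 2% noise):

```r
library(tagkin)
trc <- gen_fp_trace(kapp = 6.8e4, seed = 1, label = "SNAP + BG-OG")
fit_fp_trace(trc)
#> Monoexponential association fit: SNAP + BG-OG
#>   kobs  = 0.0137 +/- 0.00014 s^-1
#>   kapp  = 6.848e+04 M^-1 s^-1 at [P] = 2e-07 M
#>   t1/2  = 50.6 s
```

The fitted k_app lands within 0.7% of the generating value; the half-time
of ~51 s is what a 6.8×10⁴ M⁻¹s⁻¹ reaction gives at 200 nM protein.

A stopped-flow family (25 nM substrate; 0.1–2.5 µM protein; six replicate
recordings per condition), averaged, baseline-corrected and globally
fitted, with Monte-Carlo uncertainties:

```r
fam <- gen_sf_family(seed = 1, n_replicates = 6)
traces <- fam$traces |> average_traces() |> baseline_subtract(fam$baseline)
fit <- fit_sf_global(traces) |> mc_errors(n_reps = 200, seed = 2)
fit
#> Global two-step fit of 5 stopped-flow traces
#>   k1       = 3.971e+05 M^-1 s^-1
#>   k_minus1 = 0.2979 s^-1
#>   k2       = 0.0252 s^-1
#>   Kd = 7.502e-07 M, kapp = 3.097e+04 M^-1 s^-1
#>   response = 1.002e+07 per M, residual sigma = 0.00547
#>   Monte-Carlo SDs (200 replicates): k1 5.4e+03, k_minus1 0.0065, k2 0.00053, kapp 4.1e+02
```

All three generating constants (4×10⁵, 0.3, 0.025) are recovered within
1%, and the Monte-Carlo SD on k_app (~1.3% relative) is much tighter than
on the individual constants — the usual identifiability structure of the
two-step scheme.

A live-cell labeling time course (three replicate courses, 2-min frames,
5% multiplicative noise) and an amber-suppression cohort:

```r
tc <- gen_cell_timecourse(t_half = 4.6, n_replicates = 3, seed = 3)
fit_labeling_halflife(normalize_timecourse(tc))
#> Labeling half-life fit
#>   t1/2 = 4.61 min (rate 0.1502 min^-1), plateau 3.04

amber_suppression_efficiency(gen_region_table(n_cells = 40, seed = 4))$summary
#> # A tibble: 1 × 3
#>    mean     sd     n
#>   <dbl>  <dbl> <int>
#> 1 0.638 0.0999    40
```

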