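---
title: "Assessing fish passage through axial flow pumps: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing fish passage through axial flow pumps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pumppass)
```

This vignette documents the models and procedures the package
implements, the tunable parameters and their defaults, the choices we
made where the underlying field protocol left the design open, and
what the synthetic-data generator does and does not establish.

## 1. The measurement problem

A pumping station moves fish through an impeller in under a second.
Two physical mechanisms dominate injury risk: rapid *decompression*
(barotrauma: swim-bladder rupture, emboli) and *shear* in the strong
velocity gradients near the blades. Neither can be observed directly
on a live fish, so the assessment couples three indirect strands:
pressure-logging sensor passages, strain proxies derived from the same
sensors, and injury/survival coding of live-fish trials under the same
operating scenarios (pump type × impeller rpm, plus handling controls).

## 2. Sensor trace processing

Each deployment yields three synchronized pressure channels (hPa,
100 Hz). Processing steps, with defaults in `run_config()`:

* **Channel screening.** A failed sensor channel saturates at
  10^5 hPa; channels whose mean reaches that level are dropped and the
  rest averaged (`remove_outlier_channels()`, `mean_pressure()`). If
  all three fail the deployment is unusable and is reported as such by
  `process_batch()` rather than aborting the batch.
* **Injection** (`detect_injection()`): first reading above 1005 hPa.
  The sensor is zeroed to 1000 hPa in air, so submergence in the pump
  cellar pushes it past this threshold immediately. On a step of tens
  of hPa the rule is exact to one sample.
* **Nadir** (`detect_nadir()`): pump passages are searched 3–75 s
  after injection on a Savitzky–Golay-smoothed series (order 2,
  window 11 samples). Candidate samples are those whose smoothed
  pressure changes by more than 20 hPa over any lag shorter than
  0.1 s — the sub-second signature of the impeller dip — and the
  minimum smoothed pressure among candidates is the nadir. Control
  drifts have no transient: the raw minimum 5–75 s after injection is
  used, with no smoothing. The lag convention ("any lag below
  0.1 s") is our reading of the published change criterion; a
  consecutive-sample reading would require slew rates of
  2000 hPa/s, which only the steepest real dips reach.
* **Exit** (`detect_exit()`): the original protocol marked regions of
  interest by hand. For reproducibility we detect the exit
  automatically as the first time after the nadir at which the
  smoothed series stays within ±5 hPa of the terminal plateau (median
  of the last second) for a 1 s dwell; a manual exit time in the
  deployment metadata always wins.
* **Metrics.** `LRP = ln(1000 / nadir)` (dimensionless; positive for
  any decompression below acclimation). `ROC` is the maximum absolute
  one-sample rate `|ΔP|·fs` of the smoothed series within nadir
  ± 0.5 s. The published definition of ROC gives no window or sign
  convention; we chose the nadir neighbourhood because that is where
  the decompression transient lives, and report magnitudes. Both the
  window and the smoothing are configurable.
* **Time normalization** (`normalize_time()`): passages are registered
  onto u ∈ [0, 1] with injection at 0, nadir at 0.5, exit at 1 — 500
  equally spaced points on each half plus the landmarks (1001 points),
  linearly interpolated. This aligns the three landmarks across
  deployments at the cost of smearing any feature not locked to them.

**Numerical caveat.** The smoothed-minimum nadir estimator is biased
shallow by the filter: an order-2, window-11 filter attenuates a 50 ms
Gaussian dip by ≈ 1.2% of its depth (≈ 1.2 hPa per 100 hPa of dip).
For ensemble means over dips of 50–120 hPa this is well under the
between-deployment spread; for very deep transients (> 150 hPa) the
bias exceeds 2 hPa and a wider window or raw-minimum read-off would
be preferable. The tests assert recovery within ±2 hPa on the
50–120 hPa scale.

## 3. Strain rates from pressure differentials

The working relation is

  ε ≈ 40·ΔP / (μ·√Re),  Re = ρ·v·L/μ,

with ΔP the magnitude of the centre-to-lateral channel differential.
Temperature enters through viscosity μ (Vogel-type correlation
`μ = 2.414e-5 · 10^(247.8/(T_K − 140))` Pa·s, accurate to ~2% on
0–40 °C; the source protocol names no correlation) and density ρ
(quadratic fit around the 4 °C maximum). The deployment temperature
default is 4.5 °C.

The characteristic length `L` is **not recoverable from first
principles** — no published unit system reproduces the 3.45 hPa
threshold with a physically meaningful L (the calibrated value is
≈ 100 m). We therefore treat L as a unit-fixing constant obtained by
single-point calibration (`calibrate_char_length()`) at the published
anchor: ΔP = 3.45 hPa ↔ ε = 500 1/s at v = 5 m/s, T = 4.5 °C. Given
the calibration, thresholds at other velocities follow √v exactly:
4.88 hPa at 10 m/s and 5.98 hPa at 15 m/s, against published values
of 4.86 and 5.95. The printed 10/15 m/s values are mutually
√v-consistent with an unrounded anchor of ≈ 3.44 hPa, so we read the
0.02–0.03 hPa discrepancy as rounding/typography in the anchor; the
package reproduces the anchor it is given exactly.

The velocity default is 5 m/s — the precautionary choice, since for a
fixed ΔP the strain estimate decreases like 1/√v, and 5–15 m/s is the
plausible range in this pump type. `threshold_exceedance()` integrates
the time the mean of the left/right strain series spends above
500 1/s (the shear-injury threshold from the juvenile-salmonid
literature), with linear interpolation at the crossings; the mean and
maximum strain are reported over the impeller window (nadir ± 0.5 s),
both configurable. Left/right series are averaged *before*
thresholding (the alternative — thresholding each then combining — is
not what "intersection of the threshold with the mean strain rate"
describes).

## 4. Fish coding

* Injury codes follow the NEN 8775 catalogue (`injury_codes()`):
  class 1 none, 2.1–2.3 slight, 3.1–3.7 severe. A fish's class is the
  worst class present; within that class the highest numeric code is
  reported as `worst_code`, and all codes are kept for distribution
  tables, so the tie-break loses nothing.
* Survival: dead iff observed dead or dying, severely injured (class 3
  fish are euthanized), or dead in the 24/48 h holding period. No
  time-to-event modelling — the outcome is a single binary state.
* Decapitated/incomplete fish are counted (by heads), coded 3.2, and
  excluded from length/mass-dependent models (no measurable length).
* Scenario reassignment: fish that lingered in the pump cellar and
  passed during the next scenario are analysed under the scenario
  where they were observed; intended-scenario start counts stay fixed,
  so per-scenario recapture can exceed 100% while species totals are
  conserved.
* Length outliers: per species, lengths outside Q1 − 3·IQR or
  Q3 + 3·IQR are removed (extreme fences). Quantiles use R's default
  linear-interpolation convention (type 7), configurable; the source
  protocol does not state one.

## 5. The statistics layer

* `anova_length()`: one-way ANOVA of length on scenario per species;
  Tukey-corrected pairwise contrasts only when the omnibus p < 0.05.
* `fit_decision_tree()`: CART with Gini impurity, written in-package
  (no recursive-partitioning library is available in the target
  environment). Defaults: minimum split size 20, minimum child 7,
  split admitted only if it removes ≥ 1% of the root impurity, depth
  ≤ 6. These conservative settings produce the small trees the
  application calls for; when no split qualifies the result is an
  honest "no tree" (as happens for species whose outcome the
  predictors do not structure). Nodes are numbered root = 1, children
  2i/2i+1; left branches answer the split question affirmatively;
  binary survival nodes are labeled Dead/Alive by the 50% rule.
  Missing predictor values follow the majority branch (no surrogate
  splits), and candidate splits are charged for their unseparated NA
  rows so missingness is not rewarded.
* `fit_survival_logistic()`: Bernoulli GLM of survival on rpm
  (discrete) × length (continuous), reduced by both-direction stepwise
  AIC (`stats::step`). Strata in which every fish survived are
  excluded before fitting — their coefficients would diverge — and
  reported. Per-scenario predictions with 95% bands are computed on
  the logit scale from the asymptotic covariance at a reference length
  (default: mean length).
* `mixed_model_check()`: fits a sample-level random-intercept model
  (lme4) on samples with ≥ 6 fish; if the fit is singular (variance
  ≈ 0) the simple logistic model is recommended and all fish used.
* `fit_injury_multinomial()`: baseline-category multinomial logit
  (reference: no injury), maximised directly (BFGS + Newton polish)
  because no multinomial library is available; the two-category case
  reproduces `glm(binomial)` to 1e-6 and serves as the oracle in the
  tests. Selection is exact best-subset AIC over the
  marginality-respecting sub-models of the full formula (the candidate
  set is small), which trivially satisfies the "never worse than full
  or null" property. Probability bands come from sampling the
  asymptotic coefficient distribution (500 draws by default).
* `compare_pumps()`: survival over the three scenarios (fish-friendly
  pump at 468/550 rpm, conventional pump at 585 rpm), with and without
  length, with Wald contrasts of the conventional pump against each
  fish-friendly scenario; a flag warns when length distributions are
  imbalanced across scenarios (naturally passing fish are smaller, so
  length-adjusted contrasts extrapolate).
* `nonparametric_bds()`: Kruskal–Wallis omnibus per sensor parameter;
  when significant, pairwise two-sample Wilcoxon rank-sum tests with
  Bonferroni correction (`p_adj = min(1, m·p)`). Deployments are
  unpaired across scenarios, so the rank-sum (not signed-rank) test is
  the correct flavour. Stars bin exactly as printed: ns > 0.05,
  * to 0.01, ** to 0.001, *** to 1e-4, **** below.
* No multiplicity correction is applied across the many per-species
  models, mirroring the original analysis; p-values between 0.05 and
  0.10 are conventionally called "marginal" in this literature.

## 6. The synthetic world

`trace_scenario()`/`gen_pressure_trace()` state a pump passage as:
baseline 1000 hPa in air, a 30 hPa hydrostatic step at injection
(~0.3 m submergence), a single Gaussian impeller dip (default depth
100 hPa, σ = 50 ms — sub-second, inside the 0.1 s detection horizon),
an exit step to a 1010 hPa tailwater plateau, iid Gaussian channel
noise (default 1 hPa, the sensors' rated accuracy), and a lateral
differential pulse near the nadir split antisymmetrically across the
side channels. Controls replace the dip with a broad 25 hPa drift over
tens of seconds. `gen_bds_batch()` defaults to the field campaign's
group sizes (6 conventional-pump, 64 + 51 fish-friendly, 15 + 15
controls) and draws per-deployment nadir levels around the reported
ensemble means (854 / 964 / 933 hPa).

`cohort_scenario()`/`gen_fish_cohort()` state cohorts with species
length distributions anchored on the reported population means (bream
374 mm, roach 168 mm, eel 636 mm), survival from a logistic model
(length slope −0.01/mm, 550 rpm offset −0.5, conventional-pump offset
−2, species intercepts giving eel ≈ 100% > roach > bream), injuries
drawn conditional on outcome (severe codes dominated by 3.2 for dead
fish, slight by 2.3 for survivors), near-injury-free controls, an
optional lingering fraction, and a small delayed-mortality rate. The
intercepts and offsets are configuration, not claims about the field
magnitudes: the generator is built to reproduce the *qualitative*
structure the analysis assumes (orderings, signs, exclusions), and
that is all a green test on synthetic data establishes. What it does
not emulate: trajectory-dependent pressure histories, non-Gaussian
sensor noise, correlated channel failures, species-specific
injury–length interactions, or between-sample batch effects (unless
injected for the mixed-model check).

The per-fish model coefficients and tree split points reported from
the field data (e.g. the 200 mm and 340 mm splits) are data outcomes;
they are reproducible only with the deposited field records, which the
package reads through the same CSV interfaces but does not ship.

## 7. Degenerate inputs and numerical conventions

All pressures are hPa end to end; sampling rate comes from metadata
(default 100 Hz). The SD of a single-deployment scenario is reported
as NA, not 0 — one sensor tells you nothing about spread. Quantiles
are type 7; ties in the control-minimum search resolve to the earliest
sample; exceedance durations interpolate linearly at threshold
crossings; the multinomial optimiser subtracts row maxima before
exponentiating. Errors are signalled with stable prefixes
(`NoInjection`, `NoNadir`, `NoExit`, `AllChannelsInvalid`,
`UnknownCode`, `MissingStage`, …) so batch drivers can triage.

## 8. Known limitations

* The exit heuristic needs ≥ 1 s of terminal plateau; records cut
  immediately after the passage require a manual exit time.
* The nadir estimator's ~1.2%-of-depth attenuation bias (Section 2)
  matters for single very deep dips, not for ensemble means.
* Strain estimates inherit the uncalibratable unit system of the
  ε–ΔP relation; only ratios and threshold crossings are
  interpretable, which is how they are used.
* The CART implementation does exhaustive subset search on factor
  splits, capped at 8 levels per factor.
* `water_viscosity()` is for liquid water on (0, 40) °C only.
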