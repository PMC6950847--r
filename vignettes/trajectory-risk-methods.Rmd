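---
title: "Modelling incident diabetes from risk-factor trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling incident diabetes from risk-factor trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajrisk)
```

## The problem and the model

Electronic health records hold years of irregularly timed laboratory
results and vital signs. `trajrisk` asks how much of a patient's risk of
incident type 2 diabetes is carried by the *shape* of that history, beyond
the most recent values a conventional risk score uses.

The central construction is the **cumulative exposure** (CE). A variable's
observations are reconstructed as a piecewise-linear curve: linear
interpolation between successive observations (same-day duplicates
mean-aggregated first), the last observation carried forward at a constant
level to the prediction baseline, and *no* extrapolation before the first
observation. Over a calendar window $[a, b)$ the cumulative exposure is the
time-average

$$\mathrm{CE}_{[a,b)} \;=\; \frac{1}{b-a}\int_a^b f(t)\,dt ,$$

interpreted as the best available estimate of the average daily value in
that period, in the variable's native units (mg/dl, mm Hg, kg/m²). If the
curve's support does not cover the whole window — the first observation
falls after the window opens — the CE is missing rather than guessed. We
normalise by the window length so coefficients are per-unit-of-measurement
and comparable across the three windows and with the baseline-value
coefficients; the raw area (unit: value-days) is available via
`ce_normalize = FALSE`.

Three abutting half-open history windows (defaults 2000-01-01–2002-01-01,
2002-01-01–2004-01-01, 2004-01-01–2005-01-01, at day resolution with
baseline 2005-01-01) yield three CE predictors per variable. Two simpler
summaries complete the predictor sets: the *baseline* value (most recent
strictly before baseline) and the *extreme value* (EV) over the full
five-year history — the minimum for HDL, the maximum for every other
variable, since both low HDL and high everything-else are the adverse
directions.

Four Cox proportional-hazards variants are compared: **Baseline**
(demographics, diagnosis/medication indicators, baseline values),
**CE** (Baseline + windowed cumulative exposures), **EV** (Baseline +
extreme values) and **EV+CE** (everything). The sets are nested by
construction, so their maximised partial likelihoods are ordered — a
property the test suite checks. Ties in event times are handled with the
Efron approximation (day-resolution outcomes produce many ties; Efron is
the standard low-bias choice). The baseline cumulative hazard is the
Breslow step-function estimator computed on the uncentred covariate scale,
which gives two exact identities the tests rely on: a patient with an
all-zero feature row is predicted the baseline cumulative hazard itself,
and martingale residuals of a training fit sum to zero at machine
precision.

**Backwards elimination** removes, one at a time, the covariate with the
largest Wald p-value above $\alpha = 0.05$, breaking ties by column order.
Age, sex and the per-variable missingness indicators are never removed:
the indicators encode imputation structure rather than testable clinical
effects, and demographics define the risk-set adjustment. Wald rather than
likelihood-ratio tests keep elimination a single-fit-per-step procedure.

## Outcomes, cohort and imputation rules

The endpoint is the first strictly post-baseline diabetes indication —
a diabetes diagnosis code or a fasting glucose above 125 mg/dl
("in excess of 125": 125 itself is not diabetic). Censoring is at the
earlier of the last record date and the administrative end of follow-up;
times are in years (365.25 days). Records dated exactly on the baseline
day count as pre-baseline: a diabetes indication that day is prevalent,
not incident.

Cohort construction retains adults (≥ 18 at baseline) with at least one
record on each side of baseline, then excludes, in order: (1) pre-baseline
diabetes codes; (2) patients without fasting glucose in the history
windows; (3) suspected diabetes (any antidiabetic medication record, or a
single pre-baseline FPG above 125 mg/dl). Each excluded patient is counted
once under the first matching reason, so the ledger identity
`initial − ineligible − Σ exclusions = final` always holds; permuting the
order moves counts between reasons but never changes membership (tested).
Exclusion (2) is genuinely ambiguous in prose: we default to the weaker
reading — excluded only when *all three* windows lack FPG — and expose the
stricter any-window reading and a sensitivity mode (FPG in every window
plus ≥ 5 follow-up FPG values) as configuration.

Imputation proceeds in three steps. First, a missing CE window inherits
the nearest earlier window's value (carry-forward names the forward
direction; when the earliest window itself is missing, the earliest
available value is carried backward so patients are not discarded for a
late first observation). Second, cells still missing — a variable the
patient never had measured — receive the cohort column mean, and the
per-variable missingness indicator marks such patients. Third, fasting
glucose must be complete after step one; the cohort exclusions guarantee
it, and the code asserts it. In the bootstrap, imputation means are
recomputed on each in-bag sample and applied to the out-of-bag patients —
the leak-free order; imputing the whole table first (as an analysis that
imputes before modelling would) is available as `impute_before_split`.

## Evaluation and the subpopulation report

Model discrimination is Harrell's concordance for censored data: over
comparable pairs (the shorter follow-up ends in an event, or equal times
with exactly one event), the fraction in which the earlier-progressing
patient has the strictly higher risk score, with risk ties counting one
half. The implementation is checked against an exhaustive $O(n^2)$
pair-enumeration oracle and against an independent library implementation
on tie-free data. The risk score is the linear predictor — monotone in
predicted risk at any horizon, so the choice of horizon cannot change the
ranking.

`bootstrap_evaluate()` draws patients with replacement, fits every variant
on the in-bag sample (repeating backwards elimination per replicate by
default; `reuse_selection` performs selection once on the full data, the
plausible alternative reading of a single reported model per variant),
scores the out-of-bag patients and computes their concordance. All
variants share the same replicate index sets, so the B values per variant
are paired and compared by paired t-tests. Replicates with no out-of-bag
events are redrawn and counted.

The episodic-prediabetes analysis labels each patient by per-window
glycemic status: a window is prediabetic if any raw FPG in it lies in
100–125 mg/dl (inclusive — "between 100 and 125"), normal if measured but
never in that range, and inherits the previous window's status when
unmeasured (a first window without data is normal). Status is taken from
raw measurements rather than CE averages because the group definitions
speak of measured episodes; `status_from_ce` behaviour is available via
`classify_windows(source = "ce")`. The report's `error` is
`mean(predicted − observed)` — the sign convention of an estimation error,
which is the *negative* of the conventional martingale residual. The
10-year horizon is truncated at each patient's own follow-up, otherwise
predictions systematically exceed observations for censored patients.

## The synthetic cohort generator

Real cohorts of this kind are private, so validation rests on
`simulate_cohort()`. What it emulates:

* **Irregular visits** — a homogeneous Poisson process per patient
  (default 2 visits/year over 1995–2015), each variable recorded at a
  visit with its own probability (FPG at half of visits; lipids at a
  quarter). Records begin well before the first history window, as in a
  long-running registry; otherwise the support rule would make the first
  window's CE missing for essentially everyone.
* **Archetype trajectories** — latent FPG mean curves named by their
  window pattern (`stable_normal`, `pnn`, `npn`, `nnp`, `npp`, and a
  `progressive` riser that is mildly prediabetic throughout). The default
  mix matches the relative subpopulation sizes a primary-care cohort of
  this design reports (47.5% always-normal, ~17% episodic patterns, the
  rest risers). Each patient and window gets a bounded uniform level
  offset (±4 mg/dl FPG, ±1.5 kg/m² BMI): patients differ in their own
  levels, and the windows de-correlate, which is what makes per-window
  coefficients identifiable at all. Other variables load on a shared
  patient severity factor, giving realistic cross-variable correlation.
* **Measurement error** — Gaussian, truncated at physiological floors
  (FPG ≥ 40 mg/dl, BMI ≥ 12). The FPG standard deviation of 6 mg/dl
  reflects day-to-day biological plus analytic variability; it is also
  precisely the regime in which averaging a window beats trusting a single
  most-recent value, i.e. the method's own premise.
* **A fading-memory hazard** — after baseline the onset hazard is
  piecewise-constant on years,
  $\lambda(t) = \lambda_0 \exp\{\sum_w d(w,t)\,\beta_w (e_w - r)\}$, with
  per-window exposure averages $e_w$, reference levels $r$, and decay
  $d(w,t) = m^{(g_w + t)/2}$ — attenuation by `memory_decay` $m$ per
  2-year window of elapsed time since window $w$ (gap $g_w$ years before
  baseline). Default $m = 0.85$: mild fading, consistent with per-window
  coefficients of similar magnitude being detectable. Event times come
  from inverse-transform sampling of the piecewise-exponential survival
  function; an optional shared uniform makes coupled comparisons exact.
  The default FPG weight (0.035 per mg/dl per window) and baseline hazard
  (0.0045/year, calibrated once) give a ten-year cohort incidence near
  10%.
* **Structural nuisances** — independent exponential dropout (0.03/year),
  and small configurable fractions of ineligible, prevalent-diabetes and
  antidiabetic-medication patients so the exclusion machinery has real
  work.

What it does **not** emulate: visit timing that depends on health state
(sicker patients visit more), non-Gaussian assay error, seasonal effects,
age- or sex-dependent hazards, care-setting provenance (all values are
ambulatory fasting by construction), multi-site heterogeneity, and any
clinical-note text. Passing tests therefore show the pipeline recovers the
structure this generator encodes — not that the generator is a faithful
model of any real population.

## Validation experiments and their sizes

The acceptance suite runs four simulation experiments; sizes were chosen
to give each check statistical power on a single CPU in minutes.

* **Parameter recovery** — 20 replicates of n = 5000 with `memory_decay =
  1` (a correctly specified proportional-hazards model), dense precise
  FPG/BMI sampling (6 visits/year, 90% recording, noise 2 mg/dl), and
  known weights (FPG 0.035, BMI 0.1). The CE-model coefficients must
  average within two standard errors of truth with relative bias under
  15%. Dense sampling matters: interpolation across window boundaries
  smears adjacent windows into each other, and at sparse sampling that
  attenuation alone exceeds 15% for the middle window.
* **Qualitative replication at reduced scale** — a 2000-patient cohort
  with amplified per-window FPG weights (0.09) and B = 100 bootstrap
  replicates. The amplification is deliberate: at paper-like effect sizes
  the CE-versus-Baseline concordance gap (about +0.014 at large n in this
  generator) is undetectable in bootstrap medians at ~190 events, so the
  experiment tests whether the machinery detects trajectory dependence,
  not the effect's size.
* **Type-I control** — 100 replicates of n = 2500 with all hazard weights
  zero and a single normoglycemic archetype. The single archetype is
  essential: with elevated-exposure archetypes present, the
  glucose-above-125 outcome definition itself links covariates to events
  and the model is no longer null. Each CE coefficient must be significant
  in at most 10% of replicates.
* **Calibration identities and oracles** — the martingale-residual sum,
  the daily-grid trapezoid oracle for CE, and the pair-enumeration oracle
  for concordance, at tolerances of 1e-8, 1e-6 relative and exact
  respectively.

## Known limitations

* Under this generator the hazard is, by construction, linear in the
  per-window exposure *averages*, so the extreme-value features carry no
  information beyond the CE features; EV+CE equals CE asymptotically, and
  at small cohort sizes its seven extra candidate columns cost a little
  out-of-bag concordance rather than adding any. A real advantage for
  extremes — as peak-exposure or nonlinear effects would produce — cannot
  arise here, and the reduced-scale ordering check reflects that.
* The carry-forward rule for unmeasured windows propagates a prediabetic
  status forward, so patterns like `pnn` leak into `ppn`-shaped "other"
  labels when the following window happens to be unmeasured; group sizes
  from noisy, sparse measurement are systematically reshuffled relative to
  the latent archetypes. This mirrors what measurement sparsity does to
  any such analysis of real records.
* Wald-based backwards elimination is anti-conservative when events per
  candidate variable are very low; the null-calibration experiment sizes
  its cohort accordingly, and users should too.
* The per-window coefficient estimates are attenuated by cross-boundary
  interpolation whenever sampling is sparse relative to the window length
  — a property of the featurization, not of the fitting.

## Session info

```{r}
sessionInfo()
```
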