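---
title: "Methods: compositional time-use analysis and isotemporal reallocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional time-use analysis and isotemporal reallocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coda24)
```

## Why compositional

A 24-hour day allocates exactly 1440 minutes among sleep, sedentary behavior
(SB), light physical activity (LPA) and moderate-to-vigorous physical
activity (MVPA). These durations are *compositional*: only their relative
sizes carry information, and any increase in one behavior is necessarily an
equal decrease elsewhere. Entering the four raw durations into a regression
produces a singular design (they sum to a constant) and, worse,
coefficients with no coherent interpretation. The standard remedy is
Aitchison geometry: map the composition to unconstrained real coordinates
with an isometric log-ratio (ILR) transform, model there, and translate
conclusions back as *reallocations* of time.

## The ILR machinery

`pivot_basis(p)` builds pivot coordinates from the sequential binary
partition that isolates behavior `p` first and then peels off the remaining
parts in canonical order. For a 4-part composition the contrast matrix `V`
is 3×4 with orthonormal rows orthogonal to the all-ones vector;
`z = V log(x)` and `x = closure(exp(Vᵀz))`. Two properties matter in
practice and are enforced by tests rather than assumed:

* **Isometry.** Euclidean distance between ILR images equals the Aitchison
  distance between compositions, for every pivot.
* **Basis invariance.** The four pivot bases span the same 3-dimensional
  log-ratio space, so fitted values, the composition F-test, and all
  reallocation estimates are identical (to floating-point) whichever pivot
  is used. The original analysis style fits "four sets of three
  coordinates" mainly to read each behavior's first pivot coefficient;
  because every downstream quantity here is basis invariant, the package
  fits one basis (sleep pivot by default) and verifies invariance
  explicitly. The exact partition order of the non-pivot parts is therefore
  immaterial; we use canonical behavior order.

## Epoch processing

Minute epochs carry vector-magnitude counts/min plus wear and sleep flags.
Processing follows the common wrist-accelerometry conventions:

* **Cut-points** (half-open bands): counts < 2000 = SB, 2000–7499 = LPA,
  ≥ 7500 = MVPA. The sleep flag takes precedence over the bands: the sleep
  period is defined by its own detection algorithms upstream, and counts
  within it are not re-classified.
* **Wear validity:** a day counts if worn ≥ 16 h; a participant counts with
  ≥ 4 valid days.
* **Closure policy.** Daily behavior minutes are averaged over valid days
  and rescaled proportionally to 1440. Non-wear time is thereby
  redistributed across behaviors in proportion to observed time — a
  documented choice (`kappa`, rescaling happens at the averaging step); the
  original pipelines are typically silent on this point, and closure
  requires a full day.
* **Zero policy.** A participant with, say, zero MVPA breaks log-ratios.
  Person-level zero means are replaced by a configurable pseudo-minute
  (`zero_minutes`, default 0.5 min) before closure; with the default
  generator this never triggers, matching cohorts whose published means are
  all positive.

## Outcome model, screening, and the composition test

The outcome (%TWL) is regressed on the three ILR coordinates plus screened
covariates by ordinary least squares, implemented in-package via QR with
coefficient covariance `σ̂²(XᵀX)⁻¹` and exact t/F small-sample inference
(cohorts of ~45 make normal approximations inappropriate). Candidate
covariates (age, sex, race, BMI, surgery type) are screened one at a time
*alongside* the composition block (partial F, equal to the squared t for
single columns) and retained at `alpha = 0.05`. The wording "evaluated as
potential covariates and adjusted for if significant" does not pin the
procedure down; testing next to the composition is the default because the
final model contains the composition, and a covariate-only variant is
exposed (`method = "alone"`). Categorical covariates are reference-coded.
Complete cases only; no multiplicity adjustment is applied across the
screening tests, matching the analysis style the package emulates.

The overall association is the nested F-test of the ILR block:
`F = ((RSS_r − RSS_f)/3)/(RSS_f/df_f)` on (3, df_f) df. Under the null
generator its type-I error is calibrated (checked at 2000 replicates,
n = 45, acceptance band 0.035–0.065).

## Isotemporal reallocation

Estimates are differences of model predictions between a reallocated and a
reference composition. The reference is the **compositional center** — the
geometric-mean composition, identical to the ILR-inverse of the mean ILR
coordinates (a dual-route equality tested to 1e-9). Reallocation itself is
plain minute arithmetic: δ minutes leave one behavior and enter another,
all others fixed, total still 1440. Then

* estimate `= dᵀβ̂_comp` with `d = z(reallocated) − z(reference)`;
* `SE = √(dᵀ Σ̂_comp d)`; intercept and covariate terms cancel in the
  difference, so the covariate values at the reference are irrelevant;
* 95% CI uses the t distribution on the fit's residual df. This is a CI for
  a *mean* difference; residual noise is deliberately excluded (it is not a
  prediction interval).
* **Feasibility:** infeasible iff any part of the reallocated reference is
  ≤ 0. With a reference MVPA near 42.6 min/day, displacing 45 or 60 min
  from MVPA is infeasible toward every destination — rendered as dashes in
  the wide table. The rule is symmetric in sign so that the exact identity
  `estimate(A→B, −δ) = estimate(B→A, +δ)` holds cell-by-cell.
* **Gate:** reallocation tables are produced only when the composition
  F-test is significant at 0.05, mirroring the staged analysis protocol;
  `force = TRUE` overrides for simulation studies.
* No multiplicity adjustment across the 96 grid cells (12 ordered pairs ×
  8 deltas, −60…+60 by 15); per-cell unadjusted CIs are reported, a
  documented limitation of the emulated design.

## The synthetic cohort generator

`simulate_cohort()` exists because raw cohort data of this kind are not
publicly deposited. It draws from the *same* model family the analysis
assumes, which makes ground truth analytic:

* **Compositions** are logistic-normal: ILR coordinates (sleep pivot) are
  multivariate normal centred at the ILR image of the mean composition
  (defaults 447.3 / 583.7 / 366.0 / 42.6 min/day, typical of a
  preoperative bariatric cohort). Positivity and closure are automatic.
* **ILR covariance.** Between-person log-ratio covariance is essentially
  never reported, so the default is an assumption: a delta-method
  translation of typical per-behavior SDs (70.7 / 100.9 / 75.3 / 23.0
  min/day) into the ILR scale at the mean composition. Simulated
  minute-scale SDs land near (not exactly on) those targets — the
  delta-method linearization underestimates spread for skewed small parts —
  which is acceptable for a generator whose role is structural realism, not
  replication of any dataset.
* **Outcome.** `twl = β₀ + β_ilrᵀ(z − z_μ) + s·(RYGB − p) + ε`. The ILR and
  surgery terms are centred so that `β₀` *is* the population mean %TWL
  (default 23.8, SD of ε 5.1); an uncentred parameterization would let the
  cohort mean drift with `β_ilr`, breaking the generator's role of
  emulating stated study conditions. Reallocation ground truth is a
  difference, so centring does not affect it.
* **Default `β_ilr` = (1.255, 0.688, −5.681)** (sleep-pivot scale): the
  least-squares projection of a published pattern of reallocation estimates
  onto the analytic ILR-difference vectors, giving the realistic signature
  — into-MVPA beneficial (~+1%/15 min), out-of-MVPA strongly detrimental,
  sleep/SB/LPA exchanges near null. **Surgery effect** defaults to 5 %TWL
  (RYGB − SG), a plausible 6-month difference and large enough for the
  screening step to usually retain surgery at n = 45. Age, sex, race and
  BMI are simulated with zero true effect to exercise screening's null
  behavior.
* `true_reallocation_effect()` evaluates `β_ilrᵀ(z(realloc) − z(ref))` at
  the population reference `closure(mean_minutes)` — the estimand the
  coverage simulations target. Coverage is evaluated at that *fixed*
  reference (not each cohort's sample center) so the CI and the truth refer
  to the same quantity; with the generating model fitted (ILR + surgery)
  the t-interval is exact, and simulation confirms 92–98% per-cell coverage
  at 500 replicates.

The minute-stream generator (`simulate_minute_stream()`) adds the epoch
layer: a fixed nightly sleep window, wake minutes multinomially assigned to
SB/LPA/MVPA, lognormal counts constrained to put ≥95% of their mass in the
correct cut-point band, and optional independent per-minute non-wear. It
emulates structure, not physiology: there is no circadian autocorrelation,
no bout structure, and non-wear is not contiguous. Tests passing on these
streams show the pipeline arithmetic is right, not that the cut-points are
valid measurement — validity of cut-points and sleep detection lives
upstream of this package.

## Numerical and design notes

* Problem sizes in the shipped tests: cohorts of n = 45 (the motivating
  study scale), 10 000 for moment-convergence checks, 2000 null replicates
  for type-I calibration, 500 for CI coverage.
* OLS is QR-based; rank deficiency is an error naming the offending column
  rather than silent dropping.
* `ilr_inverse` rejects coordinates whose `exp` overflows; compositions are
  validated strictly positive everywhere (the zero policy lives in epoch
  averaging, before compositions are formed).
* Seeds: every generator accepts a seed; `run_full()` stamps seed and a
  config hash into all outputs, and reruns are byte-identical.
* Known limitations: linear-in-ILR outcome model only (no interactions or
  splines); 4-part compositions only; per-cell unadjusted inference; the
  generator's covariance default is an assumption, not an estimate.
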