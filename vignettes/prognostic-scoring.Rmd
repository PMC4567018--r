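---
title: "Additive prognostic scoring for NSCLC survival: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additive prognostic scoring for NSCLC survival: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungscore)
```

## The problem and the model

Patients with non-small cell lung cancer (NSCLC) present with widely
different prognoses, driven by pretreatment characteristics rather than
by stage alone. `lungscore` implements an additive scoring system that
turns eight pretreatment factors into a single integer score predicting
5-year overall survival:

* overall quality of life (QOL, single 0–100 item; *deficit* iff ≤ 50),
* age group (`[0,60)`, `[60,70)`, `[70,80)`, `[80,∞)` years),
* sex,
* ECOG performance status (0–1 vs 2–4),
* smoking cessation (quit vs kept smoking),
* primary tumor diameter (≤ 2 cm vs > 2 cm),
* regional nodal involvement (none / ipsilateral hilar / ipsilateral
  mediastinal / contralateral mediastinal),
* distant metastasis (absent / present).

The construction pipeline is:

1. **Screening.** Each factor is screened with a univariate Cox
   proportional-hazards model; factors surviving the univariate screen
   enter a joint multivariate Cox model. Factors significant in both
   are retained. Treatment is deliberately excluded: the score is a
   *pretreatment* instrument. Stage is likewise excluded because
   staging systems are periodically redefined.
2. **Scoring.** For each level of a retained factor the 5-year overall
   survival rate is estimated by Kaplan–Meier and divided by ten to
   give a whole-digit score (see *The rounding rule* below). A
   patient's total score is the sum over the eight factors; higher is
   better. Under the packaged reference table totals range from 24
   (worst possible) to 52 (best), with 32–52 observed in practice.
3. **Stratification.** Totals are binned into survival categories. The
   four published categorization schemes ship as configuration
   (`category_scheme("category1")` … `"category4"`); the headline
   scheme (`category4`) uses bins 32–37, 38–43, 44–47, 48–49, 50–52.
4. **Validation.** Two bootstrap procedures assess stability: the
   stepwise multivariate model is refitted on resamples (variable
   inclusion frequencies), and the per-level 5-year rates are
   re-estimated on resamples (rate stability summaries).

## The survival core

The Kaplan–Meier estimator, Greenwood variance, k-group log-rank test,
and Cox partial-likelihood fitting are implemented inside the package
(`km_fit()`, `logrank()`, `cox_fit()`), with the Cox derivative kernel
in C++. This keeps every step of the score construction inspectable and
lets the test suite compare each component against independent oracles
(brute-force risk-set products, partial-likelihood grid search, and the
`survival` package as a cross-check).

Numerical choices:

* **Ties.** Breslow tie handling is the default, with Efron
  selectable; the two coincide exactly on tie-free data. Within a tied
  time, censored subjects remain in the risk set for the events at
  that time.
* **Convergence.** Newton–Raphson from a zero start, step-halving when
  the partial likelihood would decrease (accepting float-level
  decreases relative to the magnitude of the log likelihood),
  convergence when the score max-norm falls below 1e-8, at most 50
  iterations. A coefficient escaping |β| > 15 is reported as a
  monotone-likelihood (perfect separation) signal, distinct from plain
  non-convergence.
* **Intervals.** Wald 95% CIs use z = 1.959964; p-values are
  two-sided. The global score test is evaluated at β = 0. For a single
  binary covariate without ties it coincides with the log-rank test.
* **KM rate CIs.** Plain-scale normal intervals from the Greenwood
  variance, clipped to [0, 100] — matching how the published per-bin
  intervals print a clipped 0.0% lower bound. A log–log transform is
  available via `rate_at(..., transform = "loglog")`. Median survival
  CIs are the first crossing times of the pointwise confidence curves.

## The rounding rule

The published rule — "divide the 5-year survival rate by ten, as a
whole digit" — is under-specified, and the printed tables force a
specific reading. Plain truncation fails (65% must score 7, 59% must
score 6), and a single rounding of the unrounded rate also fails (the
female level's unrounded 64.8% would give round(6.48) = 6, but it
prints as 7). The unique convention consistent with every printed pair
is **two-stage rounding**: round the rate to the nearest whole percent
(half away from zero), then divide by ten and round again (half away
from zero). So 64.8 → 65 → 7 and 58.6 → 59 → 6.

```{r}
level_score(c(62, 24, 64.8, 58.6, 13, 30))
```

`level_score()` defaults to this two-stage policy; `"round_once"` and
`"floor"` are available for sensitivity analysis. Note that base R's
`round()` rounds half to even, so the package uses explicit
half-away-from-zero rounding.

## Stepwise selection and its bootstrap

The published analysis reports only "stepwise selection". The package
implements classical forward selection with backward checks:

* **Entry**: the candidate factor (entered as a block of level
  contrasts) with the smallest block *score-test* p-value below
  `p_enter` (default 0.05) enters; ties break by smaller p, then
  declaration order. The block score test is evaluated at the current
  model's estimate with zeros for the new block, so candidate scans do
  not require refitting.
* **Stay**: after each entry, any included factor whose
  multi-degree-of-freedom Wald p exceeds `p_stay` (default 0.05) is
  removed, worst first. A removed factor may not re-enter: because
  entry uses the score test and retention the Wald test, a factor
  sitting exactly at the threshold could otherwise enter and be
  removed indefinitely.

The full entry/removal trace is returned. `bootstrap_model_inclusion()`
resamples the cohort with replacement at the original size, reruns the
stepwise selection, and tallies inclusion percentages. A single root
seed fans out into per-resample substreams by counter, so enlarging `B`
never reshuffles earlier resamples; resamples whose stepwise run fails
are excluded from the denominator and counted.

One subtlety worth stating: the inclusion percentage of a *fixed*
covariate over bootstrap resamples measures the stability of that
covariate's realized association in the original sample, not a type-I
error rate. A pure-noise covariate that happens to show |z| ≈ 1 in the
original sample will be "included" in far more than 5% of resamples.
The package's calibration tests therefore redraw the noise covariate in
each replicate when checking that the stepwise entry rate sits at the
nominal α.

## The synthetic cohort generator

`generate_cohort()` exists so the entire pipeline is exercisable and
testable without access to patient data. It emulates the study
conditions:

* **Marginals**: the eight factor levels are drawn independently with
  the demographic-table frequencies of the source cohort (e.g. QOL
  deficit 18.0%, metastasis 6.4%, contralateral mediastinal nodes
  2.2%, ECOG 2–4 at 12.5% of non-missing). Independence is a stated
  simplification; a correlation hook is deliberately not implemented
  because only marginals are available.
* **Effects**: survival times are exponential with rate
  `baseline × exp(Σ log HR)`, the log hazard ratios defaulting to the
  published multivariate effects (e.g. 1.841 for QOL deficit, 0.274
  for metastasis absence vs presence).
* **Baseline**: 8.7035 events/year for the all-reference profile
  (≥ 80, male, ECOG 2–4, kept smoking, > 2 cm, contralateral nodes,
  metastatic, QOL non-deficit), calibrated once by exact enumeration
  over the 1024 covariate cells so the pooled censoring-free 5-year
  survival is 57%, in the range the published per-level rates imply.
  An exponential baseline is chosen over Weibull because every
  statistic in the pipeline is rank-based or proportional-hazards, so
  the baseline shape is immaterial to recovery tests.
* **Censoring**: the minimum of administrative censoring at 10 years
  and a uniform(0, 15) dropout time, giving roughly 47% events.
* **Continuous covariates** are drawn within the sampled level's
  interval (age uniform within its bin, QOL integer-uniform within
  deficit/non-deficit, ECOG split 117:33:6 within 2–4, tumor diameter
  uniform below 2 cm and exponentially decaying above it).

The generator is deterministic given its seed, and `true_level_rates()`
returns the exact marginal 5-year survival for each level by cell
enumeration, so parameter-recovery tests compare estimates against
known truth.

What passing tests on this generator do **not** show: robustness to
correlated covariates, non-proportional hazards, informative censoring,
or measurement error in QOL — all present in real cohorts. The
generator validates the *machinery*, not the clinical transportability
of the score.

## Problem sizes used by the test suite

The suite checks small-sample oracles exhaustively (every instance up
to 20 subjects for the product-limit oracle, up to 8 for the
partial-likelihood grid search), parameter recovery on three n = 5000
cohorts at fixed seeds (the mean estimate over the three replicates is
compared against the generating log hazard ratios, since a single
realization's nodal contrasts have SE ≈ 0.13 from the 2.2%-prevalent
reference level), and the bootstrap behaviour at B = 200 on an
n = 2000 cohort. These sizes make every distributional claim testable
at conventional simulation precision.

## Degenerate inputs and edge policies

* Empty cohorts, empty groups, empty factor levels, and out-of-range
  totals all signal typed conditions (`lungscore_*` classes); nothing
  is silently clamped or dropped.
* Missing ECOG is the one permitted missing value on ingestion; every
  analysis is complete-case for the variables it uses, mirroring the
  source cohort's exclusion of ECOG-missing patients from total-score
  reporting.
* A subgroup whose survival curve never reaches 0.5 reports its median
  as `NA` ("not attained"); a level with all events before year 5
  scores 0.
* `categorize()` refuses totals outside a scheme's range;
  `run_pipeline()` widens only the outer bins of a scheme to the
  observed range of *its own* cohort, and says so in the exported
  table.

## Known limitations

* Covariate independence in the generator flattens marginal per-level
  rates relative to the published ones (conditional effects compose
  multiplicatively but marginal rates mix over the other factors), so
  generated per-level rates reproduce the published *ordering* and
  *magnitude pattern*, not the exact printed values.
* The stepwise procedure is the classical p-value-driven one because
  that is what the scoring system's validation used; it inherits the
  known instabilities of stepwise selection, which is precisely what
  the bootstrap inclusion summary quantifies.
* The four categorization schemes are shipped as fixed presets; no
  automatic cut-point search is provided, since the published cut
  points came from expert opinion plus unspecified empirical rules.
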