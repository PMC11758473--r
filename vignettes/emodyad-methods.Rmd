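---
title: "Methods: emodiversity, dyadic path models, and the synthetic study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emodiversity, dyadic path models, and the synthetic study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistical procedures it
implements, the choices made where the design was genuinely open, and what
the synthetic study can and cannot establish about real data.

## The data model and exclusion rules

A study consists of a long diary table — one row per person-day with 16
emotion items rated 0 ("none of the time") to 4 ("all of the time"): 7
negative (anxious, sad, angry, frustrated, disgusted, lonely, ashamed) and 9
positive — and a baseline table of per-person anxious and depressive symptom
means (questionnaire item means on a 0–3 scale) plus adolescent gender
group.

A *day of data* is a daily report with at least one non-missing emotion
rating; the package does not require complete item batteries, matching how
prompt completion is normally counted. A dyad enters analysis only when both
members have diary data at all and both have at least `min_days` (default 6)
usable days — the minimum conventionally needed for a stable emodiversity
estimate. The rules are applied jointly and symmetrized: a dyad is retained
only if each member individually qualifies, so the retained set does not
depend on the order in which rules are stated, and `apply_exclusions()` is
idempotent and monotone in `min_days` (both properties are tested).

## Emotion features

**Daily composites** are the mean of the available items of one valence
within a day (missing if the whole valence is missing); **person means**
average the daily composites unweighted over the person's available days.
Means therefore live on the 0–4 response scale.

**Emodiversity** is one minus the classical Gini inequality of the
per-emotion totals \(c_j\), computed after a stable non-decreasing sort:

\[
G \;=\; 1-\left(\frac{2\sum_{j=1}^{m} j\,c_{(j)}}{m\sum_{j=1}^{m} c_{(j)}}-\frac{m+1}{m}\right).
\]

Two open choices deserve note:

* **What \(c_j\) aggregates.** The items are frequency-worded, so the
  package sums the raw 0–4 ratings across days rather than counting binary
  daily endorsements. This preserves the relative-abundance component of
  diversity (an emotion felt "all of the time" on several days contributes
  more mass than one felt "a little"); binarized endorsement counting is the
  main alternative and would compress the abundance information.
* **The lower bound.** The formula's floor for a person who expressed a
  single emotion is \(1/m\), not 0; descriptions of the score as "ranging
  from 0 to 1" refer to the open lower limit as mass concentrates. The
  package implements the formula verbatim and does not rescale. All-zero
  totals leave diversity undefined and return `NA` with a warning rather
  than a fabricated 0 — in practice this happens for people who never
  endorse any negative emotion, which also explains why paired comparisons
  of negative emodiversity can have slightly fewer degrees of freedom than
  the dyad count suggests.

The score is invariant to permuting categories and to rescaling all totals
by a positive constant; both invariances, the \([1/m, 1]\) range, and
agreement with an independent mean-absolute-difference formulation to 1e-10
are enforced by tests.

**Between-person reliability** of the diary items uses a
generalizability-theory decomposition into person, person×item, and
residual variance with

\[
R=\frac{\sigma^2_p+\sigma^2_{pi}/k}{\sigma^2_p+\sigma^2_{pi}/k+\sigma^2_e/(k\,\bar d)},
\]

\(k\) items and \(\bar d\) the harmonic mean of person day counts.
Components are estimated by method of moments — pooled within-cell variance
for \(\sigma^2_e\), within-person across-item variance of cell means
(corrected for each cell's residual share) for \(\sigma^2_{pi}\), and the
across-person variance of person means for \(\sigma^2_p\) — with negative
moment estimates truncated at zero. Method of moments was chosen over a
mixed-model fit because it is deterministic, dependency-free, and transparent
about the unbalanced-layout weighting; a crossed random-effects fit is used
as an independent cross-check in the tests and agrees on simulated layouts.
Cronbach's alpha for the symptom scales is the standard variance-ratio form
on complete cases.

## The bivariate actor–partner model

For one valence and one symptom pair, both outcomes are regressed on the
identical six terms: each member's mean emotion, emodiversity, and their
product. Every path is estimated, so the model is just identified (zero
degrees of freedom; fit indices are vacuous and are not reported).

Choices:

* **Centering.** Mean-emotion and emodiversity columns are grand-mean
  centered and product columns are formed from centered factors (default,
  switchable). This makes main effects interpretable at average levels and
  stabilizes the product term; with a true interaction of zero it does not
  change slope estimates, only intercepts.
* **Exogenous side.** Predictors are treated as fixed regressors and their
  correlation matrix is reported as sample correlations rather than
  estimated as free Gaussian parameters — in a just-identified model the
  path estimates are identical, and this keeps the likelihood small and
  well-conditioned.
* **Estimation.** Full-information maximum likelihood over a bivariate
  normal: complete dyads contribute the bivariate density, dyads missing
  one outcome the univariate marginal of the observed one. With no missing
  outcomes the ML solution is closed-form (equation-wise least squares plus
  the ML residual cross-moment) and is used directly. Otherwise a
  quasi-Newton search runs on an unconstrained parameterization
  (log variances, tanh-transformed residual correlation) from
  available-case OLS starts, followed by Newton polishing on the natural
  scale using the analytic score and a finite-difference Hessian; the fit
  is declared converged when the total score's infinity norm is below 1e-6
  (the polish typically reaches far smaller). Non-convergence and rank
  deficiency are errors, the latter naming the collinear columns.
* **Robust covariance.** The sandwich \(A^{-1}BA^{-1}/n\) with \(A\) the
  average per-case Hessian and \(B\) the average outer product of per-case
  scores. The small-sample factor defaults to \(n/(n-p)\) with \(p\) the
  per-equation coefficient count: in the package's own 2000-replicate
  calibration at 175 dyads with realistic effect sizes, that factor gave
  95% interval coverage of 0.941 and null-path rejection of 0.063, against
  0.936 and 0.067 for the conventional \(n/(n-1)\), which is retained as an
  option (`df_adjust = "n-1"`). Either way the constant is one of several
  variants in circulation among robust-ML implementations, so
  cross-software agreement of standard errors should only ever be expected
  loosely.
* **Standardization and inference.** \(\beta = b\,\mathrm{SD}(x)/\mathrm{SD}(y)\)
  with the sample SD of each *realized* column — the product column's own SD
  for interactions — and SEs propagated by the same fixed-SD factor; p
  values from the standard normal with no small-sample df correction,
  mirroring common SEM software; CIs are \(\beta \pm z\,\mathrm{SE}\) at 95%
  in tables, with 99% available for conditional-effect bands.
* **Multigroup.** Fits are independent per stratum; strata under
  `min_group_n` (default 10, chosen because gender groups of a handful of
  adolescents cannot support a 17-parameter model) are excluded and
  reported.

**Conditional effects.** The effect of the focal path at moderator value
\(x\) is \(b_f + b_p x\) with delta-method variance
\(V_f + x^2 V_p + 2x\,C_{fp}\) from the robust covariance; the default grid
is the moderator's mean ± 2 SD in 41 steps, and curves are computed on the
unstandardized scale where the delta-method covariance is exact.

## Descriptives and screens

Correlation matrices use pairwise deletion (switchable in effect by
supplying complete cases), with t-based p values and `*`/`**` stars at .05
and .01. Exploratory missing-data comparisons use Welch's unequal-variance
t-test; paired role comparisons use the classical paired t (with the
convention that identical vectors give t = 0 rather than an error, while a
constant nonzero difference is a genuine zero-variance error). The
multicollinearity screen flags |r| > .80, and the advisory normality screen
flags |skewness| > 2 or excess kurtosis > 7. No multiple-testing correction
is applied across the correlation matrix.

## The synthetic study

The generator's defaults describe the study conditions the package is built
around: 175 dyads, 14 scheduled days, adolescent compliance 0.84 and
caregiver 0.88 (days dropped independently — missing completely at random),
trait scales on the 0–4 response metric (e.g. caregiver positive affect
mean 2.15, SD 0.55; adolescent negative affect mean 0.90, SD 0.40),
day-to-day latent SD 0.45, person-item discriminations with SD 0.15 around
1, item noise SD 0.6, a true coefficient set with dominant actor effects of
mean emotion on symptoms, residual partner correlations of 0.20–0.25, and a
5% symptom missingness rate.

Mechanics: each person draws latent positive and negative traits; each day
adds an independent normal deviation; each item's rating is latent affect ×
discrimination + noise, rounded and clamped to 0–4 (round-and-clamp was
chosen as the simplest discretization with bounded support). Emodiversity
is *emergent* — it is not set directly, but the discrimination spread moves
expected Gini monotonically downward (tested), so it functions as the
diversity knob. Baseline symptoms follow the configured linear
actor–partner model in the person's realized, sample-centered features plus
correlated bivariate-normal residuals; symptom values are deliberately not
clamped to the questionnaire's 0–3 range so that coefficient recovery is
exact in expectation (readers of generated baselines disable the range
check).

What the generator does **not** emulate — and therefore what passing tests
cannot establish about real data: temporal autocorrelation or weekday
structure in affect; within-day (momentary) sampling; ordinal item response
processes beyond round-and-clamp; missingness that depends on symptoms or
affect (everything here is MCAR, so FIML's missing-at-random assumption is
satisfied by construction); floor effects in symptom scales; and
measurement error correlated across partners.

All randomness derives from one integer seed; the same seed reproduces the
dataset byte for byte.

## Problem sizes and numerical tolerances used in validation

The validation suite uses sizes chosen to keep each claim's Monte-Carlo
error well inside its tolerance: exact algebraic identities (least-squares
equality, closed-form likelihood, standardization refits) at a few hundred
dyads with tolerances 1e-8 to 1e-12; FIML bias under 20% MCAR as a
10-replicate average at n = 2000 (bound 0.02); robust-interval calibration
as 500 replicates at n = 175 (coverage banded 92–98%, null rejection
3–7%); generator recovery of a 0.5 actor effect as a 5-replicate average at
n = 2000 (±0.05); heteroskedastic coverage at 400 replicates of n = 300.
Per-replicate sampling SDs of path estimates at these sizes are roughly
0.02–0.06 (larger for emodiversity paths, whose realized SDs are small), so
single-replicate checks at tighter bounds would be uninformative;
multi-replicate averages are used wherever a bound is close to one
sampling SD.

## Known limitations

* The pipeline is cross-sectional: symptoms are modeled as outcomes of
  emotion features measured over the same fortnight, with no longitudinal
  or multilevel structure.
* FIML handles missing *outcomes*; persons missing emotion features (e.g.
  undefined emodiversity) are dropped from the affected model rather than
  modeled.
* The reliability estimator targets the three-component layout; day-level
  crossed effects (a shared person-day component across items) are absorbed
  into the residual.
* The sandwich covariance treats dyads as independent sampling units, as
  the design intends; clustering beyond the dyad (e.g. recruitment waves)
  is not modeled.
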