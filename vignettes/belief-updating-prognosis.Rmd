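---
title: "Valence-dependent belief updating as a prognostic signal: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valence-dependent belief updating as a prognostic signal: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Euthymic bipolar patients relapse at widely varying intervals, and standard
clinical or demographic indicators predict the timing poorly. A candidate
cognitive marker is the *update bias* from the belief update task: healthy
people revise self-relevant risk beliefs more after good news (the event is
less likely than they feared) than after bad news, and a weakening of that
optimistic asymmetry accompanies — and may precede — affective symptoms.
`updatebias` implements the full analysis pipeline linking this task measure
to prospective time in euthymia: trial scoring, censored outcome
construction, a family of linear prognostic models with bootstrap and
collinearity diagnostics, exhaustive BIC-weighted model averaging,
leave-one-out predictive validation, and a synthetic-cohort generator with
known ground truth so every stage is testable without patient data.

## Task scoring

Each of the 40 trials presents an adverse life event. The participant gives
a first probability estimate (bounded to 3–77%), sees the population base
rate (always within 10–70%), and later re-estimates. A trial is *good news*
when the base rate is below the first estimate and *bad news* when above;
equal values and missing responses are excluded (the two exclusion reasons
are bookkept separately). The trial-level update is signed toward the
information,

$$\mathrm{Update} = \begin{cases}
\text{first} - \text{second} & \text{good news},\\
\text{second} - \text{first} & \text{bad news},
\end{cases}$$

and the per-subject **update bias** is the mean good-news update minus the
mean bad-news update; positive values mean optimistic updating. Memory
errors are $|\text{presented} - \text{recalled}|$. All control covariates
are good-minus-bad differences ($\Delta$ variables) of per-valence means:
estimation error, memory error, trial counts, both reaction times, and five
1–6 likert ratings (familiarity, prior experience, vividness, arousal,
negativity). Means use trial-level pairwise deletion; a subject with no
trials in one valence cannot produce a bias and is dropped with a warning.

Two scoring choices were genuinely open:

* **Estimation-error sign.** The signed error (base rate minus first
  estimate) is negative on every good-news trial and positive on every
  bad-news trial by construction, so its $\Delta$ is just a recoding of
  valence magnitudes. The default therefore uses absolute errors per
  valence, with the signed variant behind
  `score_subjects(..., estimation_error = "signed")`.
* **Units.** Everything stays on the 0–100 percent scale; no rescaling to
  proportions, no trimming or winsorizing of updates.

## Outcome construction

The outcome is months in euthymia from task completion to the next episode.
Subjects still euthymic at the 60-month follow-up horizon are assigned 60
months and flagged censored; the models then treat that value as observed.
This censor-at-horizon convention (rather than proper survival modelling)
is deliberately reproduced because it is how the prognostic analysis this
package implements was designed; its consequences are quantified below.
Raw months are strongly right-skewed, so models predict the natural log
(any other base only rescales coefficients). `distribution_diagnostics()`
reports the bias-adjusted Fisher–Pearson skewness
$G_1 = \frac{n}{(n-1)(n-2)}\sum z_i^3$ (the SPSS/SAS convention; simple
moment version behind a flag) and the Kolmogorov–Smirnov distance from a
normal law with estimated mean and sd — the Lilliefors plug-in statistic.
Lilliefors-corrected p-values are not computed; only the statistic is
reported. Next-episode polarity is coded −1 (depressive) / +1 (manic), and
is undefined for censored subjects.

## The model family

All models are OLS with intercept on complete cases. `model1` regresses log
months on the update bias plus eleven task controls; `model1a`/`model1b`
swap in the good-news/bad-news update; `model1_both` enters both;
`model_subjective` keeps only the five rating deltas (the controls that
actually differ between valences, per the paired-t screen in
`compare_good_bad()`); `model2` adds eleven clinical/demographic controls;
`model1_polarity` adds polarity and its interaction with the bias,
restricted to relapsers, since censored subjects have no next episode.

Reported alongside the raw coefficients:

* **Standardized betas** — slopes after z-scoring the outcome and every
  design column. This is the "Beta" of SPSS-family output; under
  collinearity such betas can legitimately exceed 1 in magnitude, which is
  why raw coefficients are always reported too.
* **VIF** per predictor, $1/(1-R^2_j)$, with the conventional < 4 reading
  of "no concerning collinearity"; perfect collinearity yields `Inf` with a
  warning rather than a crash.
* **BIC** on the SSE scale, $n\log(\mathrm{SSE}/n) + k\log n$ with $k$
  counting the coefficients plus the error variance. Constants shared by
  models on the same rows cancel in differences, which is all the
  averaging uses.

**Bootstrap.** `bootstrap_ci()` resamples subjects with replacement
(10,000 replicates by default), refits per replicate, and returns
percentile bounds on both the raw and standardized scale — the convention
is not always stated in published tables, so both are emitted. BCa bounds
are available behind `type = "bca"`. Rank-deficient replicates are redrawn
and counted. Fixed seed implies identical bounds.

**Power.** `required_sample_size_correlation()` implements the Fisher-z
design calculation $n = ((z_{1-\alpha/\text{tails}} +
z_{\text{power}})/\mathrm{atanh}|r|)^2 + 3$. The default is one-tailed
because that is the convention under which detecting $r = 0.50$ at
$\alpha = 0.05$ with 80% power requires 23 subjects — the design target of
the study this pipeline serves; the two-tailed answer is ≈ 29. An exact
cross-check integrates Hotelling's sampling density of the correlation
coefficient beyond the critical value (`power_correlation_exact()`), and
agrees.

## Exhaustive BIC model averaging

With $p$ candidate predictors there are $2^p - 1$ non-empty subsets (7 for
three predictors; 4095 for the 12 task predictors), enumerated in inclusion-
mask order with the intercept always included. Model $m$ receives weight
$w_m \propto \exp(-\Delta\mathrm{BIC}_m/2)$ — the standard information-
criterion weighting; weighting by raw $1/\mathrm{BIC}$ was rejected as
scale-dependent. The headline estimate for a predictor is *conditional*:
its beta averaged over the models containing it, with weights renormalized
over that subset (a predictor absent from many subsets can still carry a
nonzero estimate, matching how such analyses are reported). The
*full* average, which imputes zero when absent, is emitted alongside, as
are both confidence conventions, via the model-averaged standard error
$\sum_m w_m\sqrt{se_m^2 + (\hat\beta_m - \bar\beta)^2}$; no single CI
convention is privileged. The ranking orders subsets by BIC with ties
broken by fewer predictors then mask, and `top_k_membership()` counts how
often each predictor appears among the $k$ best models.

## Leave-one-out validation

Each subject's outcome is predicted from a model fitted to everyone else
(verified in tests against the hat-matrix identity
$\mathrm{SSE}_{\mathrm{LOO}} = \sum_i (e_i/(1-h_{ii}))^2$). Predictions are
made and scored on the log scale; back-transformed months are for display
only. Three surfaces: Pearson r between predicted and actual, a paired
t-test of the two means (zero for a calibrated predictor), and the
prediction SSE. `compare_models_loo()` aligns two specifications to their
common complete cases and reports both tuples — typically the model with
and without the update bias, the ablation that shows whether the bias
carries real predictive signal. Censored subjects participate with their
horizon value, mirroring their treatment in the fitted models.

## The synthetic cohort

The generator emulates the structure of the target study: 36 subjects by
default, 40 events each, integer base rates uniform on [10, 70], first
estimates as base rate + subject miscalibration (sd 12) + trial noise
(sd 15) clipped to [3, 77], second estimates moved toward the information
by the subject's valence-specific mean update plus noise (sd 8), recall
noise sd 10, ordinal ratings with a +0.4 latent shift on good news,
log-normal reaction times, and 4.73 (sd 4.03) trials per subject lost to
missing responses. The population update bias is N(5, 6) percentage points
around a common mean update of 10 — values typical of this task family.
Outcomes follow
$\log(\text{months}) = b_0 + b_1\,\mathrm{bias} + b_{AD}\,\mathrm{AD} +
\varepsilon$, censored at 60 months, with defaults $b_0 = \log 10$ (median
relapse near one year, consistent with about half of euthymic patients
relapsing within a year), $b_1 = 0.09$ per percentage point (a
standardized effect ≈ 0.5, the size this literature reports),
$b_{AD} = -0.35$ for antidepressant prescription, and residual sd 1.0,
which yields right-skewed raw months whose skewness the log transform
removes and a censored minority of roughly one subject in six. Polarity is
random for relapsers (no polarity dependence is built in). These defaults
were fixed once from the published structure and are not adjusted per
analysis.

Three deliberate simplifications, and what they mean for the tests: values
are clipped to bounds after adding noise (simpler than truncated sampling,
at the cost of mild boundary mass); ratings are rounded latent normals, not
a fitted ordinal model; and the three stimulus lists are collapsed into one
event catalog. The generator matches moments and structure, not mechanism —
it contains no Bayesian learner — so passing tests demonstrate that the
*pipeline* recovers what the generator planted, not that the cognitive
model of updating is correct, and real cohorts can of course violate the
generative assumptions (e.g. non-log-linear outcome dependence,
informative missingness).

### Parameter recovery and the censoring attenuation

`parameter_recovery_report()` repeats generate → score → fit cycles and
reports bias, RMSE and bootstrap-CI coverage for $b_1$. The generative
coefficient is defined on the *latent* (pre-censoring) log months, so
recovery is measured against that outcome by default: there the estimator
is unbiased (the scored bias reproduces the generator's bookkeeping to
machine precision, and OLS contains the true regressor). Fitting the
*censored* analysis outcome instead (`outcome = "censored"`) attenuates
$b_1$ by roughly 10–15% under the defaults, because censoring truncates
exactly the long-euthymia tail that high-bias subjects occupy. This is a
property of the censor-at-horizon convention itself, not of the estimator,
and it is left visible rather than corrected: the package reproduces the
published treatment, and the recovery report quantifies its cost.

## Numerical choices and degenerate inputs

* OLS via QR; subset fits reuse one design matrix and are checked in tests
  against an independent normal-equations oracle at 1e-8 relative
  tolerance.
* BIC weights are computed after subtracting the minimum BIC, so averaging
  is invariant to BIC shifts and weights sum to 1 to 1e-12.
* Zero-variance inputs (paired differences, diagnostics, validation
  vectors) raise typed degenerate-input errors instead of returning NaN;
  out-of-range data raise validation errors naming the field and row.
* A constant paired-difference vector of exactly zero is reported as
  t = 0, p = 1 (a perfectly calibrated comparison) rather than an error in
  `validate_loo()`, where it arises from exact-fit predictions.
* Ties in the BIC ranking break toward the smaller model, then the
  inclusion mask, making rankings deterministic.

## Problem sizes used by the checks

The packaged checks run the full 4095-subset averaging on 36-row cohorts,
parameter recovery with 200 replicates of 500 subjects at 500 bootstrap
resamples, ablation comparisons over 100 seeds of 60-subject cohorts with
a large generative effect ($b_1 = 0.18$, twice the default), and
oracle-equivalence sweeps over 100 (OLS) and 50 (LOO) random instances.
These sizes give stable Monte Carlo margins for the properties asserted
while keeping a full run in the order of minutes on a single core.

## Known limitations

* Censored outcomes enter OLS as observed horizon values; no Cox or
  Kaplan–Meier treatment is offered, by design.
* The exhaustive averaging refuses more than 20 candidate predictors
  rather than switching to stochastic search.
* Bootstrap intervals are percentile by default; BCa is available but
  jackknife-based and slower.
* The deposited clinical dataset is not bundled; cohort-dependent
  coefficients can only be reproduced qualitatively from the synthetic
  generator unless that dataset is supplied to the same readers.
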