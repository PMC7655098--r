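# updatebias

Valence-dependent belief updating as a prognostic marker in bipolar
disorder: scoring, modelling, and validation.

Euthymic bipolar patients relapse at intervals that clinical and
demographic indicators predict poorly. The *belief update task* offers a
cognitive candidate: participants estimate their risk for 40 adverse life
events, see the population base rate, and re-estimate. Trials where the
base rate is below the first estimate are *good news*, above it *bad
news*, and the per-subject

```
UpdateBias = mean Update(good news) − mean Update(bad news),
Update(good) = first − second estimate,   Update(bad) = second − first
```

measures optimistic updating (positive = beliefs move more after good
news). This package implements, for clinical-research analysts, the full
pipeline linking that score to prospective time in euthymia:

* **Task scoring** — valence classification, signed updates, memory
  errors, and the good-minus-bad Δ control covariates (estimation error,
  memory error, trial counts, reaction times, five subjective ratings).
* **Outcomes** — months in euthymia censored at the 60-month horizon,
  log-transformed, with skewness/Kolmogorov–Smirnov diagnostics and
  −1/+1 polarity coding.
* **Regression suite** — the named model family (task model `model1`,
  clinical model `model2`, and variants) as OLS with standardized betas,
  case-resampling bootstrap CIs (10,000 replicates), VIF collinearity
  diagnostics, and the Fisher-z design power calculation (r = 0.50,
  one-tailed α = 0.05, power 0.80 → n = 23).
* **Model averaging** — all 2^p − 1 predictor subsets (4095 for the task
  model), BIC weights ∝ exp(−ΔBIC/2), conditional and full averaged
  coefficients, and top-k membership.
* **Leave-one-out validation** — held-out predictions, predicted-vs-actual
  r, paired t, and SSE comparison between model variants (the update-bias
  ablation).
* **Synthetic cohort** — a generator with known ground truth emulating the
  study's structure, plus a parameter-recovery report.

## Worked example

```r
library(updatebias)

cfg    <- synthetic_config(seed = 2024)   # 36 subjects, 40 trials each
cohort <- generate_cohort(cfg)
tab    <- assemble_cohort(cohort)         # score trials, merge outcomes

fit <- fit_linear_model("model1", tab)
fit
#> Linear model 'model1' on 35 subjects (R^2 = 0.528, SSE = 22.987)
#>          term           estimate     se        t      p      beta
#>   (Intercept)            0.155169 4.0415  0.03839 0.9697        NA
#>   update_bias            0.084502 0.0312  2.70446 0.0129  0.544795
#>   mean_first_estimate    0.040902 0.0997  0.41038 0.6855  0.370983
#>   ...
fit$vif[["update_bias"]]
#> 1.89
```

One subject drew no good-news trials and is flagged unscorable (35 of 36
scored). The update bias has standardized beta 0.54 (p = 0.013) on log
months in euthymia — each percentage point of optimistic updating predicts
about 8.5% longer euthymia — and its VIF of 1.89 shows no collinearity
with the eleven task controls.

```r
ma <- model_average("model1", tab)
ma$averaging$table[ma$averaging$table$predictor == "update_bias", 1:4]
#>   predictor   estimate ci_low ci_high
#>   update_bias    0.557  0.256   0.858
ma$top_k[["update_bias"]]
#> 8        # the update bias appears in all 8 best-BIC models (of 4095)

cmp <- compare_models_loo("model1", drop_predictor("model1", "update_bias"), tab)
c(with = cmp$with$sse, without = cmp$without$sse)
#>  with without
#> 52.32   66.27
```

Averaged over all 4095 subset models, the bias keeps a clearly positive
weighted estimate, and leave-one-out prediction degrades markedly when it
is removed (SSE 52.3 → 66.3; held-out r = 0.39, p = 0.022) — the
signature that the update bias carries genuine prognostic signal in this
cohort.

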