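# CoxPathOmics

Sparse prognostic signatures for right-censored clinical outcomes from
linked multi-platform genomic profiles — mRNA expression, DNA methylation,
copy-number alteration and microRNA expression — of the kind produced for
serous ovarian carcinoma cohorts. The package is aimed at biostatisticians
and computational biologists who want a tested, fully reproducible
implementation of the integrated Cox-Lasso signature workflow: platform
integration, penalized path fitting, concordance-based tuning, risk
stratification and patient-specific median time-to-event prediction.

## The method

Given follow-up times `y_i` (months) with event indicators `δ_i` and
per-patient feature rows `x_i`, the core fit solves the L1-penalized,
ridge-stabilized Cox proportional hazards problem

    β̂(λ) = argmin_β  −log L(β) + λ‖β‖₁ + λ₂‖β‖₂² ,

where `−log L` is the Breslow partial likelihood over the risk sets
`R_i = {j : y_j ≥ y_i}`, along a geometric grid of penalties from
`λ_max` (all-zero model) toward 0. Around that core:

* **Integration** — copy-number, methylation and microRNA features are
  retained when their Spearman rank correlation with matched mRNA (computed
  on training samples only) clears a per-platform cutoff; retained features
  are concatenated with platform tags.
* **Tuning** — two-fold cross-validation repeated ten times scores each
  penalty with the outcome-validated Gönen–Heller concordance probability
  estimate (CPE); `λ*` maximizes the mean cv.CPE.
* **Signature** — the nonzero coefficients at `λ*`, each labelled poor
  (`β > 0`) or good (`β < 0`) prognosis, with the training standardization
  transform frozen in.
* **Evaluation** — tertile risk strata from training-derived cutoffs,
  Kaplan–Meier curves, three-group and low-vs-high log-rank p-values, the
  high-vs-low hazard ratio with Wald 95% CI, CPE on the withheld test set,
  and per-patient predicted median times from the Breslow baseline,
  `S(t|x) = exp(−Ĥ₀(t) e^η)`.
* **Synthetic cohorts** — a generator with Gaussian-copula cross-platform
  coupling, exponential proportional-hazards outcomes and calibrated
  uniform censoring provides ground truth for every claim the test suite
  makes.

## Worked example

```r
library(CoxPathOmics)

cfg <- runConfig(nSamples = 300L, seed = 7L)  # simulated 4-platform cohort
res <- runPipeline(cfg)
show(res$cv)
show(res$signature)
show(res$report)
```

which logs the stages and prints:

```
pipeline: split 240 train / 60 test
integration: METH retained 60 / 60 features (cutoff 0.30)
integration: CNA retained 60 / 60 features (cutoff 0.30)
integration: miRNA retained 19 / 20 features (cutoff 0.20)
pipeline: integrated feature space has 199 features

CVResult: 2-fold CV x 10 repeats over 100 penalties
  lambda* = 10.94 (mean cv.CPE = 0.618, 53 features)
CoxSignature: 53 features at lambda = 10.94
   CNA: 16, METH: 12, miRNA: 6, mRNA: 19
  poor-prognosis (beta > 0): 30; good-prognosis: 23
PredictionReport (53-feature signature, 60 test patients)
  c-score: p(3-group) = 0.00132, p(low-high) = 0.000145, HR = 4.34 (1.92, 9.79), CPE.test = 0.701
  t-score: p(3-group) = 0.237, p(low-high) = 0.16, HR = 1.75 (0.79, 3.86), CPE.test = 0.596
```

Reading the numbers: cross-validation keeps 53 of 199 integrated features;
on the 60 withheld patients the c-score tertiles separate survival strongly
(log-rank p = 0.0013; patients in the high-risk tertile experience events
4.3 times faster than the low-risk tertile), and the validated concordance
0.701 says the signature orders random patient pairs correctly about 70% of
the time. Per-patient predictions are in `patientTable(res$report)`:

```
  sample_id    c_score    c_stratum predicted_median_months not_reached
1     S0001 -1.6679514          low                      NA        TRUE
2     S0014 -0.4276179 intermediate               59.138208       FALSE
3     S0017 -1.0200207          low               83.045365       FALSE
4     S0028  1.9476870         high                4.320523       FALSE
5     S0029  1.6884467         high                5.580490       FALSE
```

A high-risk patient (S0028) has a predicted median time-to-event of 4.3
months; for S0001 the predicted survival curve never falls to 50% within
follow-up (`not_reached`).

Lower-level entry points — `simulateCohort()`, `integrateOmics()`,
`fitCoxPath()`, `crossValidatePath()`, `extractSignature()`,
`evaluateSignature()`, `rankFeatures()` — expose each stage separately; the
methods vignette (`vignettes/integrated-cox-signatures.Rmd`) documents the
models, defaults and their rationale.

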