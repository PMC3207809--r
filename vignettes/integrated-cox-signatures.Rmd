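---
title: "Integrated multi-omic prognostic signatures: models, choices and limits"
author: "CoxPathOmics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated multi-omic prognostic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CoxPathOmics)
```

# The problem

High-grade serous ovarian carcinoma cohorts profiled on several genomic
platforms — mRNA expression, DNA methylation (beta values), copy-number
alteration and microRNA expression — come with right-censored clinical
outcomes: progression-free survival (PFS) or overall survival (OS), recorded
in months. The goal is a *sparse prognostic signature*: a small set of
features across platforms whose weighted combination predicts a patient's
risk, stratifies a withheld cohort into low / intermediate / high risk
groups, and supports a patient-specific predicted median time-to-event.

CoxPathOmics implements that pipeline end to end: platform integration by
Spearman filtering, an L1-penalized Cox proportional hazards regularization
path, penalty tuning by repeated two-fold cross-validation of a concordance
probability estimate, tertile stratification with training-derived cutoffs,
and median-time prediction from the Breslow baseline hazard. A synthetic
multi-omic cohort generator with known ground truth makes every step
testable.

# The model

For follow-up times $y_i$ with event indicators $\delta_i$ and feature rows
$x_i$, the Cox partial likelihood (Breslow convention for ties) is

$$-\log L(\beta) = -\sum_{i:\,\delta_i = 1}\Big[x_i'\beta -
  \log\!\!\sum_{j \in R_i} e^{x_j'\beta}\Big],
  \qquad R_i = \{j : y_j \ge y_i\}.$$

The penalized fit solves, for a decreasing grid of penalties $\lambda$,

$$\hat\beta(\lambda) = \arg\min_\beta\; -\log L(\beta)
  + \lambda\lVert\beta\rVert_1 + \lambda_2\lVert\beta\rVert_2^2 .$$

The L1 term performs selection and shrinkage simultaneously; the small fixed
ridge term $\lambda_2$ (default $10^{-5}$) removes the degeneracy and
instability that strongly correlated covariates — ubiquitous after
multi-platform integration — induce in the pure Lasso. The path starts at
$\lambda_{\max}$, the largest gradient component of $-\log L$ at
$\beta = 0$, where the solution is exactly zero, and descends geometrically
over 100 grid points to $10^{-3}\lambda_{\max}$ (plus $\lambda = 0$ when the
feature count is below the event count).

## The solver

The path is computed by cyclic coordinate descent on the iteratively
reweighted quadratic approximation of the partial likelihood, warm-started
from each previous grid point — the architecture used by the established
penalized-regression solvers in this field. Each grid point is iterated
until the Karush–Kuhn–Tucker conditions of the penalized objective hold to
an absolute tolerance of $10^{-6}$; sequential strong-rule screening keeps
sweeps on the small candidate set, an objective-decrease safeguard halves
steps when the diagonal quadratic model overshoots, and per-point effort
caps keep the path affordable. Grid points that hit the caps before the
tolerance are *flagged* (`converged` slot) and still returned; in practice
this happens only past model saturation, where the active set approaches
the number of observed events and the unpenalized problem itself is barely
identifiable. Those saturated solutions never drive downstream inference:
cross-validation selects far sparser models.

Features are standardized to mean zero and unit variance *on the data used
for fitting*; coefficients live on that standardized scale and the
transform is stored, so signatures are applied to new cohorts without
re-estimating anything.

# Concordance probability

Discrimination is summarized by the Gönen–Heller concordance probability
estimate (CPE). Under proportional hazards the probability that, of two
patients, the one with the higher linear predictor fails first is the
logistic of the score difference, so the exact estimator averages
$(1 + e^{-|\eta_i - \eta_j|})^{-1}$ over patient pairs. Two conventions had
to be fixed:

* **Ties.** Pairs with exactly equal predictors carry no ordering
  information; they are excluded from the average, and a cohort whose
  predictors are all equal returns 0.5 — the random-prediction value. This
  makes the estimator hit both reference points exactly: 0.5 for a constant
  score and 1.0 for two groups separated by a wide margin.
* **Smoothing.** A bandwidth-$h$ variant replaces the pair-orientation
  indicator with $\Phi(-x_{ij}/h)$; the exact form is the default and the
  reference, with `cpeBandwidth()` providing the standard
  $0.5\,\hat\sigma(\eta)\,n^{-1/3}$ rate when smoothing is wanted.

## Validated CPE for model tuning and test-set reporting

The raw CPE is computed from linear predictors alone and grows with their
spread. Evaluating a *fixed* score on new data with the raw form therefore
rewards coefficient inflation: a saturated, overfit model produces enormous
score differences and a raw CPE near 1 regardless of whether the ordering
is right. For cross-validation and test-set reporting the package therefore
uses the *outcome-validated* form (`cpeValidated()`): the held-out outcomes
are refit with the fixed standardized score as the single covariate of a
Cox model, and the CPE of that one-covariate model is reported, after the
fitted calibration slope is shrunk by the likelihood-ratio heuristic factor
$(\chi^2 - 1)/\chi^2$ (floored at zero). The shrinkage removes the
small-sample upward bias that the folded slope otherwise carries under the
null: an uninformative score earns a slope of (or near) zero and a value of
(or near) 0.5, while a well-calibrated informative score — whose
likelihood-ratio statistic is large — keeps essentially its full
model-based concordance. This is how
the estimator is applied to external data in the literature it comes from,
and it is what makes penalty selection by CPE maximization meaningful. The
raw estimator remains available as `cpe()` and is also reported through
Harrell's C (`harrellC()`), the outcome-based concordance used as an
independent cross-check: the two move together as true effect size grows.

# Integration by Spearman filtering

Copy number, methylation and microRNA features are not independent of the
transcriptome: a gene's mRNA level tends to correlate positively with its
copy number and negatively with its promoter methylation and with targeting
microRNAs. Integration exploits this: each non-mRNA feature is paired with
its gene (identity mapping for copy number and methylation, a user-supplied
target table for microRNAs), the Spearman rank correlation with the paired
mRNA is computed **on training samples only**, and the feature is retained
when its best-matching $|\rho|$ reaches a per-platform cutoff. mRNA
features pass through unfiltered. Retained features are concatenated with
platform tags into one feature space whose standardization is likewise
estimated on training samples only — the test cohort can never influence
retention, scaling, penalty selection or signature membership, a property
the test suite asserts bitwise.

Cutoffs default to 0.3 (copy number), 0.3 (methylation) and 0.2 (microRNA):
moderate values that keep genuinely coupled features while discarding
platform noise. They are deliberately prominent in `integrationConfig()`
because no principled universal value exists; a sign-policy option
restricts retention to the biologically expected correlation direction
(positive for copy number, negative for methylation and microRNA) when
wanted, with the unsigned filter as default.

# Model selection and evaluation

The cohort is split once into 80% training and 20% withheld test samples
(`floor(0.8 n)` training; simple random by default, event-stratified
optionally). On the training half, two-fold cross-validation repeated ten
times scores the validated CPE at every grid penalty; the selected
$\lambda^\*$ maximizes the mean cv.CPE, with exact ties resolved to the
largest penalty (the sparsest model). Fold standardization is refit
in-fold; the master path fitted on all training samples supplies the
signature at $\lambda^\*$.

Evaluation on the withheld samples reports, for both the **c-score** (the
linear predictor $\sum_i x_i\beta_i$) and the **t-score** (mean of
poor-prognosis features, $\beta_i > 0$, minus mean of good-prognosis
features, on standardized values): the three-group log-rank p-value of the
tertile stratification, the low-vs-high log-rank p-value, the high-vs-low
hazard ratio with Wald 95% CI from an unpenalized Cox fit on the group
indicator, and the validated CPE of the scores. Tertile cutoffs come from
linear-interpolation quantiles of the training scores and are applied to
the test cohort verbatim; scores at a cutoff go to the lower stratum.

Patient-specific predicted median time-to-event uses the Breslow baseline
of the training fit: $S(t \mid x) = \exp(-\hat H_0(t)\,e^{\eta})$, with the
median reported at observed-knot resolution (the baseline is a step
function; no interpolation) and a `not_reached` flag when the curve stays
above 0.5 throughout follow-up. Because $S(t\mid x)$ is monotone in
$\eta$, predicted medians reverse-order the c-scores exactly.

Individual features are ranked by their own stratification power
(`rankFeatures()`): a bottom-15% / intermediate / top-15% split at
linear-interpolation quantiles of the feature's values, scored by the
three-group log-rank statistic, ranked by descending chi-square with ties
broken by feature id. The ranking runs on whatever cohort is supplied; the
full cohort is the intended default.

# The synthetic cohort generator

No public multi-platform cohort ships with the package, so the generator
(`simulateCohort()`) emulates the statistical structure the pipeline
assumes, with every choice explicit and isolated here:

* **Scale.** Defaults: 480 patients, 60 genes per gene-indexed platform,
  20 microRNAs (200 combined features), matching the order of magnitude of
  a TCGA-scale cohort after platform-level reduction.
* **Linkage.** A latent Gaussian score per gene is shared across platforms
  through a Gaussian copula; the latent Pearson correlation
  $2\sin(\pi\rho_s/6)$ induces the *target Spearman* correlation $\rho_s$
  under any monotone marginal transform. Defaults: $+0.6$ (copy number),
  $-0.5$ (methylation), $-0.4$ (targeting microRNA) — moderate coupling of
  the kind reported between expression and its regulators in tumor
  cohorts.
* **Marginals.** mRNA is Gaussian per gene with gene-specific mean and
  spread; copy number is a scaled latent (log-ratio-like); methylation maps
  the latent through a logistic squash into $(0,1)$, preserving rank
  correlations; microRNA is Gaussian around a platform-typical mean.
* **Outcomes.** A sparse causal set (default: ten features, absolute
  effect 0.5 on the standardized scale, mixed signs, spread over all four
  platforms) acts through a Cox linear predictor; event times are
  exponential with mean 60 months at $\eta = 0$, chosen so closed-form
  medians ($60\ln 2 \approx 41.6$ months, the order of an ovarian-cancer
  cohort's median OS) are available as oracles. Censoring is uniform and
  independent, with the horizon calibrated by bisection to an expected
  censored fraction of 0.443 — the fraction alive in a 481-patient OS
  cohort with 268 deaths. Tied observed times are jittered by at most
  $10^{-9}$ months to sidestep tie-convention ambiguity.

What the generator does **not** emulate: batch effects, probe-level noise,
missing-data patterns, platform-specific dynamic ranges, or linkage
disequilibrium-like structure among genes. Passing tests therefore show
the *method* behaves as specified under its own assumptions — proportional
hazards, random censoring, monotone cross-platform coupling — not that any
particular biological cohort satisfies those assumptions.

# Numerical choices and degenerate inputs

* Breslow tie handling everywhere (likelihood, baseline, path solver), for
  internal consistency.
* Constant features are dropped with a warning (unidentifiable under the
  partial likelihood); features with more than 20% missing values are
  dropped, the remainder median-imputed on training samples.
* All-censored outcomes are an explicit error for fitting operations;
  Kaplan–Meier returns the constant curve 1.
* The Newton fit reports monotone-likelihood (separation) and
  non-convergence as errors, never silently.
* An empty selected signature (possible under pure noise) produces constant
  scores: stratification is then undefined and reported as NA with a
  warning, while the validated CPE is 0.5 by construction — an empty model
  makes no false-positive claim.
* Fold draws are rejected and redrawn (bounded retries) unless every fold
  and its complement carry at least two events.
* Cross-validation fold fits run under lighter effort caps than the master
  fit — held-fold scoring needs only the ranking and calibration of the
  linear predictors — while the signature is always extracted from the
  fully converged region of the master path.

# Problem sizes used by the test suite

The suite exercises the full pipeline at $n = 300$ patients and $p = 200$
combined features with 20 replicate seeds for the signal-recovery and
null-control studies, $n$ up to 2000 for closed-form oracle checks, and
small enumerable instances (3–50 samples) for every hand-computed oracle.
These sizes give stable Monte-Carlo margins for the assertions while
keeping a full run on a single CPU comfortable.

# Known limitations

* The predictor–corrector step-size mechanics of the original path
  algorithm are not reproduced; the coordinate-descent path solves the same
  KKT systems on a fixed geometric grid, which is what downstream model
  selection consumes.
* Efron or exact tie corrections, time-varying covariates and competing
  risks are out of scope.
* Past model saturation (active features approaching the event count) path
  solutions are effort-capped and flagged rather than polished; they are
  statistically meaningless there and never selected by cross-validation.
* The raw CPE's scale sensitivity means externally supplied risk scores
  should be assessed with `cpeValidated()` (or `harrellC()`), not `cpe()`,
  whenever outcomes are available.
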