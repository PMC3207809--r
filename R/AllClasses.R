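#' Class definitions
#'
#' Central S4 containers: multi-platform cohorts, integrated feature spaces,
#' penalized Cox solution paths, cross-validation summaries, sparse prognostic
#' signatures and evaluation reports.
#'
#' @name CoxPathOmics-classes
#' @keywords internal
NULL

PLATFORMS <- c("mRNA", "METH", "CNA", "miRNA")

#' StepCurve: right-continuous step function
#'
#' Houses Kaplan-Meier survival curves and Breslow cumulative-hazard
#' estimates. The curve takes the value `start` strictly before the first
#' knot and `values[i]` on `[knots[i], knots[i+1])`.
#'
#' @slot knots Strictly increasing numeric vector of jump times (months).
#' @slot values Numeric vector, one value per knot (right-continuous).
#' @slot start Value of the curve before the first knot (1 for survival
#'   curves, 0 for cumulative hazards).
#' @slot type Either `"survival"` (nonincreasing) or `"cumhaz"`
#'   (nondecreasing).
#' @export
setClass("StepCurve",
  representation(knots = "numeric", values = "numeric", start = "numeric",
                 type = "character"),
  prototype(knots = numeric(0), values = numeric(0), start = 1,
            type = "survival"))

setValidity("StepCurve", function(object) {
  msg <- NULL
  if (length(object@knots) != length(object@values))
    msg <- c(msg, "knots and values must have equal length")
  if (length(object@knots) > 1 && any(diff(object@knots) <= 0))
    msg <- c(msg, "knots must be strictly increasing")
  if (!object@type %in% c("survival", "cumhaz"))
    msg <- c(msg, "type must be 'survival' or 'cumhaz'")
  if (object@type == "survival" &&
      length(object@values) && any(diff(c(object@start, object@values)) > 1e-12))
    msg <- c(msg, "survival curves must be nonincreasing")
  if (object@type == "cumhaz" &&
      length(object@values) && any(diff(c(object@start, object@values)) < -1e-12))
    msg <- c(msg, "cumulative hazards must be nondecreasing")
  if (is.null(msg)) TRUE else msg
})

#' MultiOmicCohort: linked per-platform feature matrices with outcomes
#'
#' Platform matrices are stored features x samples (features as rows), all
#' sharing the sample axis with the clinical table. Simulated cohorts also
#' carry the generating truth (sparse coefficient vector over the combined
#' standardized feature space and the per-sample true linear predictor).
#'
#' @slot platforms Named list of numeric matrices (features x samples);
#'   names from `mRNA`, `METH`, `CNA`, `miRNA`.
#' @slot clinical data.frame with columns `sample_id`, `time_months`,
#'   `event` and optional annotation columns.
#' @slot pairing data.frame with columns `feature`, `gene` mapping microRNAs
#'   to target genes.
#' @slot truth list; for simulated cohorts: `beta_true` (data.frame platform,
#'   feature, beta), `linear_predictor` (numeric per sample), `config`.
#' @export
setClass("MultiOmicCohort",
  representation(platforms = "list", clinical = "data.frame",
                 pairing = "data.frame", truth = "list"))

setValidity("MultiOmicCohort", function(object) {
  msg <- NULL
  if (!all(names(object@platforms) %in% PLATFORMS))
    msg <- c(msg, sprintf("platform names must be among: %s",
                          paste(PLATFORMS, collapse = ", ")))
  ids <- object@clinical$sample_id
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "clinical table needs unique sample_id values")
  for (pl in names(object@platforms)) {
    m <- object@platforms[[pl]]
    if (!identical(colnames(m), as.character(ids)))
      msg <- c(msg, sprintf("platform %s does not share the sample axis", pl))
    if (anyDuplicated(rownames(m)))
      msg <- c(msg, sprintf("platform %s has duplicate feature ids", pl))
  }
  if ("METH" %in% names(object@platforms)) {
    v <- object@platforms[["METH"]]
    if (any(v < 0 | v > 1, na.rm = TRUE))
      msg <- c(msg, "methylation beta values must lie in [0, 1]")
  }
  if (!is.null(object@clinical$time_months) &&
      any(!is.finite(object@clinical$time_months) |
          object@clinical$time_months <= 0))
    msg <- c(msg, "follow-up times must be positive and finite")
  if (!is.null(object@clinical$event) &&
      !all(object@clinical$event %in% c(0L, 1L)))
    msg <- c(msg, "event indicators must be 0/1")
  if (is.null(msg)) TRUE else msg
})

#' IntegratedDataset: combined feature space across platforms
#'
#' Samples x features matrix of the retained features, with per-feature
#' platform metadata, outcomes, train/test split labels and the
#' standardization transform estimated on training samples only.
#'
#' @slot X Numeric matrix, samples x features; column names are the unique
#'   keys `platform:feature`.
#' @slot featureMeta data.frame: `feature`, `platform`, `gene`, `rho`
#'   (best-matching Spearman correlation; NA for mRNA pass-through).
#' @slot sampleIds Character vector, rows of `X`.
#' @slot time Numeric follow-up times (months).
#' @slot event Integer 0/1 event indicators.
#' @slot split Character vector, `"train"` / `"test"` per sample.
#' @slot center,scale Named numeric: training-sample mean and standard
#'   deviation per retained feature.
#' @export
setClass("IntegratedDataset",
  representation(X = "matrix", featureMeta = "data.frame",
                 sampleIds = "character", time = "numeric", event = "integer",
                 split = "character", center = "numeric", scale = "numeric"))

setValidity("IntegratedDataset", function(object) {
  msg <- NULL
  n <- nrow(object@X)
  if (length(object@sampleIds) != n || length(object@time) != n ||
      length(object@event) != n || length(object@split) != n)
    msg <- c(msg, "sample axis lengths disagree")
  if (nrow(object@featureMeta) != ncol(object@X))
    msg <- c(msg, "featureMeta rows must match feature columns")
  if (!all(object@split %in% c("train", "test")))
    msg <- c(msg, "split labels must be 'train' or 'test'")
  if (is.null(msg)) TRUE else msg
})

#' CoxPathFit: L1-penalized Cox regularization path
#'
#' Coefficients along a decreasing penalty grid from `lambda_max` (all-zero
#' model) toward 0, with a small fixed ridge stabilizer `lambda2`.
#' Coefficients are on the standardized-feature scale; the training
#' standardization transform is stored so the fit can be applied to new
#' cohorts without re-estimation.
#'
#' @slot lambdas Strictly decreasing penalty grid.
#' @slot lambdaEntry The fit's own entry penalty (largest zero-gradient
#'   component at beta = 0); the solution is exactly zero at or above it.
#' @slot beta Matrix features x grid of coefficients.
#' @slot lambda2 Ridge constant.
#' @slot converged Logical per grid point (KKT satisfied to tolerance).
#' @slot nloglik Negative log partial likelihood at each grid point.
#' @slot featureIds Feature keys (rows of `beta`).
#' @slot center,scale Training standardization transform.
#' @slot X Standardized training matrix used for fitting (kept for off-grid
#'   refits and baseline-hazard estimation).
#' @slot time,event Training outcomes.
#' @slot standardized Logical; whether `X` was standardized internally.
#' @export
setClass("CoxPathFit",
  representation(lambdas = "numeric", lambdaEntry = "numeric",
                 beta = "matrix", lambda2 = "numeric",
                 converged = "logical", nloglik = "numeric",
                 featureIds = "character", center = "numeric",
                 scale = "numeric", X = "matrix", time = "numeric",
                 event = "integer", standardized = "logical"))

setValidity("CoxPathFit", function(object) {
  msg <- NULL
  if (length(object@lambdas) > 1 && any(diff(object@lambdas) >= 0))
    msg <- c(msg, "lambda grid must be strictly decreasing")
  if (ncol(object@beta) != length(object@lambdas))
    msg <- c(msg, "beta must have one column per grid point")
  if (length(object@lambdaEntry) == 1 &&
      object@lambdas[1] >= object@lambdaEntry - 1e-12 &&
      any(object@beta[, 1] != 0))
    msg <- c(msg, "beta at or above the entry penalty must be the zero vector")
  if (is.null(msg)) TRUE else msg
})

#' CVResult: repeated k-fold cross-validation of the penalty
#'
#' Mean and standard deviation of the held-fold concordance probability
#' estimate (cv.CPE) per penalty value, plus the selected penalty (largest
#' lambda attaining the maximal mean cv.CPE) and the path fitted on the full
#' training data.
#'
#' @slot lambdas Penalty grid (shared with the master path).
#' @slot meanCPE,sdCPE Per-lambda mean and sd of held-fold CPE.
#' @slot nonzero Number of nonzero coefficients of the master path per lambda.
#' @slot lambdaOpt Selected penalty.
#' @slot folds,repeats CV design.
#' @slot seed Seed consumed by the fold assignment.
#' @slot path The master [CoxPathFit-class] fitted on all training samples.
#' @export
setClass("CVResult",
  representation(lambdas = "numeric", meanCPE = "numeric", sdCPE = "numeric",
                 nonzero = "integer", lambdaOpt = "numeric", folds = "integer",
                 repeats = "integer", seed = "integer", path = "CoxPathFit"))

#' CoxSignature: selected nonzero-coefficient features
#'
#' The sparse prognostic signature at the tuned penalty: features with their
#' coefficients (standardized scale), prognosis direction (poor if beta > 0,
#' good if beta < 0), the training standardization transform, and the Breslow
#' baseline cumulative hazard of the fitted model (for patient-specific
#' median time-to-event prediction).
#'
#' @slot features data.frame: `feature`, `platform`, `gene`, `beta`,
#'   `direction`.
#' @slot center,scale Named numeric transform for the signature features.
#' @slot lambda,lambda2 Penalties at which the signature was extracted.
#' @slot baseline [StepCurve-class] cumulative baseline hazard from training.
#' @export
setClass("CoxSignature",
  representation(features = "data.frame", center = "numeric",
                 scale = "numeric", lambda = "numeric", lambda2 = "numeric",
                 baseline = "StepCurve"))

setValidity("CoxSignature", function(object) {
  msg <- NULL
  f <- object@features
  if (nrow(f) &&
      !all(c("feature", "platform", "beta", "direction") %in% names(f)))
    msg <- c(msg, "features must carry feature, platform, beta, direction")
  if (nrow(f) && any(f$beta == 0))
    msg <- c(msg, "signature coefficients must be nonzero")
  if (nrow(f) && (length(object@center) != nrow(f) ||
                  length(object@scale) != nrow(f)))
    msg <- c(msg, "standardization transform must cover every feature")
  if (is.null(msg)) TRUE else msg
})

#' PredictionReport: stratification and prediction metrics on a test cohort
#'
#' For both the c-score (linear predictor) and t-score (poor-minus-good
#' average) stratifications: three-group and low-vs-high log-rank p-values,
#' the high-vs-low hazard ratio with Wald 95% CI, the test-set concordance
#' probability estimate, per-stratum Kaplan-Meier curves, and per-patient
#' predicted median times-to-event.
#'
#' @slot patients data.frame: `sample_id`, `c_score`, `t_score`, `c_stratum`,
#'   `t_stratum`, `predicted_median_months`, `not_reached`.
#' @slot metrics data.frame, one row per score type: `score`, `p_3group`,
#'   `p_low_high`, `hr`, `hr_lo`, `hr_hi`, `cpe_test`.
#' @slot km Named list of per-stratum [StepCurve-class] Kaplan-Meier curves.
#' @slot cutoffs Named list of training tertile cutoffs per score type.
#' @slot signatureSize Number of features in the applied signature.
#' @export
setClass("PredictionReport",
  representation(patients = "data.frame", metrics = "data.frame", km = "list",
                 cutoffs = "list", signatureSize = "integer"))
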