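#' Construct a step curve
#'
#' @param knots Strictly increasing jump times.
#' @param values Curve value from each knot onward (right-continuous).
#' @param start Value before the first knot.
#' @param type `"survival"` or `"cumhaz"`.
#' @return A [StepCurve-class] object.
#' @export
stepCurve <- function(knots, values, start = 1, type = "survival") {
  new("StepCurve", knots = as.numeric(knots), values = as.numeric(values),
      start = as.numeric(start), type = type)
}

#' Evaluate a step curve
#'
#' @param curve A [StepCurve-class].
#' @param t Times at which to evaluate (right-continuous lookup).
#' @return Numeric vector of curve values.
#' @export
evalStep <- function(curve, t) {
  stopifnot(is(curve, "StepCurve"))
  if (length(curve@knots) == 0) return(rep(curve@start, length(t)))
  idx <- findInterval(t, curve@knots)
  c(curve@start, curve@values)[idx + 1L]
}

#' @describeIn stepCurve Number of knots.
#' @param x,object A [StepCurve-class].
#' @export
setMethod("length", "StepCurve", function(x) length(x@knots))

setMethod("show", "StepCurve", function(object) {
  cat(sprintf("StepCurve (%s) with %d knots", object@type,
              length(object@knots)))
  if (length(object@knots))
    cat(sprintf(" on [%.3g, %.3g]", min(object@knots), max(object@knots)))
  cat("\n")
})

## ---- MultiOmicCohort accessors -------------------------------------------

#' Accessors for MultiOmicCohort
#'
#' @param object A [MultiOmicCohort-class].
#' @return `platformNames`: character vector; `platformMatrix`: features x
#'   samples matrix; `clinicalData`: data.frame; `mirnaPairing`: data.frame;
#'   `cohortTruth`: list; `sampleNames`: character vector.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
platformNames <- function(object) names(object@platforms)

#' @rdname cohort-accessors
#' @param platform Platform name (`"mRNA"`, `"METH"`, `"CNA"`, `"miRNA"`).
#' @export
platformMatrix <- function(object, platform) {
  if (!platform %in% names(object@platforms))
    stop("no such platform: ", platform)
  object@platforms[[platform]]
}

#' @rdname cohort-accessors
#' @export
clinicalData <- function(object) object@clinical

#' @rdname cohort-accessors
#' @export
mirnaPairing <- function(object) object@pairing

#' @rdname cohort-accessors
#' @export
cohortTruth <- function(object) object@truth

#' @rdname cohort-accessors
#' @export
sampleNames <- function(object) as.character(object@clinical$sample_id)

setMethod("show", "MultiOmicCohort", function(object) {
  cat("MultiOmicCohort with", nrow(object@clinical), "samples\n")
  for (pl in names(object@platforms))
    cat(sprintf("  %-6s %d features\n", pl, nrow(object@platforms[[pl]])))
  ev <- sum(object@clinical$event)
  cat(sprintf("  events: %d / %d (%.1f%% censored)\n", ev,
              nrow(object@clinical),
              100 * (1 - ev / nrow(object@clinical))))
  if (length(object@truth))
    cat(sprintf("  ground truth: %d causal features\n",
                sum(object@truth$beta_true$beta != 0)))
})

## ---- IntegratedDataset accessors -----------------------------------------

#' Accessors for IntegratedDataset
#'
#' @param object An [IntegratedDataset-class].
#' @param standardized Apply the training standardization transform.
#' @return Matrices (samples x features), metadata, outcomes, split labels.
#' @name integrated-accessors
NULL

.idsOf <- function(object, which) object@sampleIds[object@split == which]

.subMatrix <- function(object, which, standardized) {
  m <- object@X[object@split == which, , drop = FALSE]
  if (standardized)
    m <- sweep(sweep(m, 2, object@center, "-"), 2, object@scale, "/")
  m
}

#' @rdname integrated-accessors
#' @export
trainMatrix <- function(object, standardized = FALSE)
  .subMatrix(object, "train", standardized)

#' @rdname integrated-accessors
#' @export
testMatrix <- function(object, standardized = FALSE)
  .subMatrix(object, "test", standardized)

#' @rdname integrated-accessors
#' @export
featureMeta <- function(object) object@featureMeta

#' @rdname integrated-accessors
#' @export
splitLabels <- function(object)
  setNames(object@split, object@sampleIds)

#' @rdname integrated-accessors
#' @param which `"train"`, `"test"` or `"all"`.
#' @export
outcomeOf <- function(object, which = "all") {
  keep <- if (which == "all") rep(TRUE, length(object@time))
          else object@split == which
  list(time = object@time[keep], event = object@event[keep],
       sample_id = object@sampleIds[keep])
}

setMethod("show", "IntegratedDataset", function(object) {
  cat(sprintf("IntegratedDataset: %d samples x %d features\n",
              nrow(object@X), ncol(object@X)))
  tab <- table(object@featureMeta$platform)
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  split: %d train / %d test\n", sum(object@split == "train"),
              sum(object@split == "test")))
})

## ---- CoxPathFit ----------------------------------------------------------

setMethod("show", "CoxPathFit", function(object) {
  nz <- colSums(object@beta != 0)
  cat(sprintf("CoxPathFit: %d features, %d grid points, lambda2 = %g\n",
              nrow(object@beta), length(object@lambdas), object@lambda2))
  cat(sprintf("  lambda: %.4g ... %.4g; nonzero: %d ... %d\n",
              object@lambdas[1], object@lambdas[length(object@lambdas)],
              nz[1], nz[length(nz)]))
  if (!all(object@converged))
    cat(sprintf("  NOTE: %d grid points did not reach KKT tolerance\n",
                sum(!object@converged)))
})

#' Nonzero-coefficient counts along the path
#'
#' @param fit A [CoxPathFit-class].
#' @return Integer vector, one count per grid point.
#' @export
nonzeroCounts <- function(fit) as.integer(colSums(fit@beta != 0))

#' Penalty grid of a path or CV result
#'
#' @param fit A [CoxPathFit-class] or [CVResult-class].
#' @return Numeric vector of penalties.
#' @export
lambdaGrid <- function(fit) fit@lambdas

## ---- CVResult ------------------------------------------------------------

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %d-fold CV x %d repeats over %d penalties\n",
              object@folds, object@repeats, length(object@lambdas)))
  i <- match(object@lambdaOpt, object@lambdas)
  cat(sprintf("  lambda* = %.4g (mean cv.CPE = %.3f, %d features)\n",
              object@lambdaOpt, object@meanCPE[i], object@nonzero[i]))
})

#' Selected penalty of a cross-validation run
#'
#' @param cv A [CVResult-class].
#' @return The penalty maximizing mean cv.CPE (largest on ties).
#' @export
lambdaOpt <- function(cv) cv@lambdaOpt

#' Cross-validation trace
#'
#' @param cv A [CVResult-class].
#' @return data.frame with `lambda`, `mean_cpe`, `sd_cpe`, `nonzero`.
#' @export
cvTrace <- function(cv) {
  data.frame(lambda = cv@lambdas, mean_cpe = cv@meanCPE, sd_cpe = cv@sdCPE,
             nonzero = cv@nonzero)
}

## ---- CoxSignature --------------------------------------------------------

setMethod("show", "CoxSignature", function(object) {
  f <- object@features
  cat(sprintf("CoxSignature: %d features at lambda = %.4g\n", nrow(f),
              object@lambda))
  if (nrow(f)) {
    tab <- table(f$platform)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
        "\n")
    cat(sprintf("  poor-prognosis (beta > 0): %d; good-prognosis: %d\n",
                sum(f$beta > 0), sum(f$beta < 0)))
  }
})

#' Signature feature table
#'
#' @param signature A [CoxSignature-class].
#' @return data.frame of features, platforms, coefficients, directions.
#' @export
signatureFeatures <- function(signature) signature@features

## ---- PredictionReport ----------------------------------------------------

setMethod("show", "PredictionReport", function(object) {
  cat(sprintf("PredictionReport (%d-feature signature, %d test patients)\n",
              object@signatureSize, nrow(object@patients)))
  m <- object@metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf(
      "  %s: p(3-group) = %.3g, p(low-high) = %.3g, HR = %.2f (%.2f, %.2f), CPE.test = %.3f\n",
      m$score[i], m$p_3group[i], m$p_low_high[i], m$hr[i], m$hr_lo[i],
      m$hr_hi[i], m$cpe_test[i]))
})

#' Per-patient predictions of a report
#'
#' @param report A [PredictionReport-class].
#' @return data.frame with scores, strata and predicted median times.
#' @export
patientTable <- function(report) report@patients

#' Summary metrics of a report
#'
#' @param report A [PredictionReport-class].
#' @return data.frame, one row per score type.
#' @export
reportMetrics <- function(report) report@metrics
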