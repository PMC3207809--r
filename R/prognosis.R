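## Signature application: c-scores, t-scores, tertile risk strata, predicted
## median time-to-event and the evaluation report.

#' Extract the sparse signature at a penalty
#'
#' Collects the nonzero-coefficient features of a path at `lambda`, labels
#' their prognosis direction (poor if beta > 0, good if beta < 0), stores the
#' training standardization transform for those features and the Breslow
#' cumulative baseline hazard of the fitted model on the training data.
#'
#' @param fit A [CoxPathFit-class].
#' @param lambda Penalty at which to extract (typically [lambdaOpt()]).
#' @param featureMeta Optional data.frame with `feature`, `platform`, `gene`
#'   columns keyed as `platform:feature` to annotate the signature (as from
#'   [featureMeta()]).
#' @return A [CoxSignature-class]; may be empty (zero features).
#' @export
extractSignature <- function(fit, lambda, featureMeta = NULL) {
  stopifnot(is(fit, "CoxPathFit"))
  beta <- pathCoefficients(fit, lambda)
  nz <- beta != 0
  feats <- names(beta)[nz]
  platform <- sub(":.*$", "", feats)
  platform[!platform %in% PLATFORMS] <- NA_character_
  gene <- rep(NA_character_, length(feats))
  if (!is.null(featureMeta)) {
    key <- paste0(featureMeta$platform, ":", featureMeta$feature)
    idx <- match(feats, key)
    platform <- featureMeta$platform[idx]
    gene <- featureMeta$gene[idx]
  }
  features <- data.frame(
    feature = feats, platform = platform, gene = gene,
    beta = unname(beta[nz]),
    direction = ifelse(beta[nz] > 0, "poor", "good"),
    stringsAsFactors = FALSE)
  baseline <- breslowBaseline(beta, fit@X, fit@time, fit@event)
  new("CoxSignature", features = features,
      center = fit@center[feats], scale = fit@scale[feats],
      lambda = lambda, lambda2 = fit@lambda2, baseline = baseline)
}

.signatureMatrix <- function(signature, X) {
  feats <- signature@features$feature
  missing <- setdiff(feats, colnames(X))
  if (length(missing))
    stop("signature features missing from the data: ",
         paste(missing, collapse = ", "))
  m <- X[, feats, drop = FALSE]
  if (any(!is.finite(m))) stop("non-finite feature values")
  sweep(sweep(m, 2, signature@center, "-"), 2, signature@scale, "/")
}

#' Prognostic scores of a signature on a cohort
#'
#' The c-score is the fitted linear predictor
#' \eqn{\sum_i x_i \beta_i} over the signature features (standardized with
#' the training transform, never refit). The t-score is the difference
#' between the average of the poor-prognosis features (beta > 0) and the
#' average of the good-prognosis features (beta < 0), on standardized
#' values; an absent direction contributes 0.
#'
#' @param signature A [CoxSignature-class].
#' @param X Samples x features matrix (raw scale) containing every signature
#'   feature column.
#' @return data.frame with `sample_id` (rownames of `X`, if any), `c_score`,
#'   `t_score`.
#' @export
computeScores <- function(signature, X) {
  stopifnot(is(signature, "CoxSignature"))
  f <- signature@features
  if (nrow(f) == 0) {
    z <- rep(0, nrow(X))
    return(data.frame(sample_id = rownames(X) %||% as.character(seq_len(nrow(X))),
                      c_score = z, t_score = z, stringsAsFactors = FALSE))
  }
  Xs <- .signatureMatrix(signature, X)
  cScore <- as.numeric(Xs %*% f$beta)
  poor <- f$direction == "poor"
  meanOr0 <- function(m) if (ncol(m)) rowMeans(m) else rep(0, nrow(m))
  tScore <- meanOr0(Xs[, poor, drop = FALSE]) -
    meanOr0(Xs[, !poor, drop = FALSE])
  data.frame(sample_id = rownames(X) %||% as.character(seq_len(nrow(X))),
             c_score = cScore, t_score = unname(tScore),
             stringsAsFactors = FALSE)
}

#' Tertile risk stratification with training-derived cutoffs
#'
#' Cutoffs at the 1/3 and 2/3 linear-interpolation quantiles of the training
#' scores; a score at or below the lower cutoff is `low`, at or below the
#' upper cutoff `intermediate`, else `high` (ties go to the lower stratum).
#' Cutoffs are applied verbatim to the test scores, never re-estimated.
#'
#' @param trainScores Numeric training scores (>= 3, not all identical).
#' @param testScores Numeric test scores (optional).
#' @return list with `cutoffs` (length 2), `train` and `test` factors with
#'   levels `low`, `intermediate`, `high`.
#' @export
stratifyRisk <- function(trainScores, testScores = NULL) {
  if (length(trainScores) < 3) stop("need at least 3 training scores")
  if (diff(range(trainScores)) == 0)
    stop("degenerate stratification: all training scores identical")
  cuts <- quantile(trainScores, c(1 / 3, 2 / 3), names = FALSE, type = 7)
  lab <- function(s)
    factor(ifelse(s <= cuts[1], "low",
                  ifelse(s <= cuts[2], "intermediate", "high")),
           levels = c("low", "intermediate", "high"))
  list(cutoffs = cuts, train = lab(trainScores),
       test = if (is.null(testScores)) NULL else lab(testScores))
}

#' Patient-specific predicted median time-to-event
#'
#' From the training Breslow baseline \eqn{\hat H_0} and a patient's linear
#' predictor \eqn{\eta}, the survival curve is
#' \eqn{S(t\mid x) = \exp(-\hat H_0(t) e^{\eta})}; the predicted median is
#' the smallest knot at which it reaches 0.5, reported at observed-knot
#' resolution. Curves that never reach 0.5 within follow-up are flagged
#' `not_reached`.
#'
#' @param signature A [CoxSignature-class] (carries the baseline).
#' @param X Samples x features raw matrix, or `NULL` when `eta` is given.
#' @param eta Optional precomputed linear predictors (c-scores).
#' @return data.frame with `median_months` (NA when not reached) and
#'   `not_reached`.
#' @export
predictMedianTime <- function(signature, X = NULL, eta = NULL) {
  stopifnot(is(signature, "CoxSignature"))
  if (is.null(eta)) {
    if (is.null(X)) stop("provide X or eta")
    eta <- computeScores(signature, X)$c_score
  }
  H <- signature@baseline
  if (length(H@knots) == 0)
    return(data.frame(median_months = rep(NA_real_, length(eta)),
                      not_reached = rep(TRUE, length(eta))))
  res <- vapply(eta, function(e) {
    s <- exp(-H@values * exp(e))
    i <- which(s <= 0.5)
    if (length(i)) H@knots[i[1]] else NA_real_
  }, numeric(1))
  data.frame(median_months = res, not_reached = is.na(res))
}

.hazardRatioLowHigh <- function(time, event, strata) {
  keep <- strata %in% c("low", "high")
  if (sum(keep) == 0 || length(unique(strata[keep])) < 2)
    return(c(hr = NA_real_, lo = NA_real_, hi = NA_real_))
  x <- matrix(as.numeric(strata[keep] == "high"), ncol = 1,
              dimnames = list(NULL, "high"))
  fit <- tryCatch(fitCoxNewton(x, time[keep], event[keep]),
                  error = function(e) NULL)
  if (is.null(fit)) {
    warning("hazard ratio omitted: low-vs-high Cox fit failed")
    return(c(hr = NA_real_, lo = NA_real_, hi = NA_real_))
  }
  b <- unname(fit$beta[1])
  se <- unname(fit$se[1])
  c(hr = exp(b), lo = exp(b - 1.96 * se), hi = exp(b + 1.96 * se))
}

#' Evaluate a signature on a withheld test cohort
#'
#' Computes c- and t-scores on train and test, stratifies the test cohort by
#' training tertiles, and reports for each score type the 3-group and
#' low-vs-high log-rank p-values, the high-vs-low hazard ratio with Wald 95%
#' CI (unpenalized Cox on the group indicator), the outcome-validated
#' test-set concordance probability estimate ([cpeValidated()]) of the
#' scores, per-stratum Kaplan-Meier
#' curves and per-patient predicted median times. Degenerate stratifications
#' (identical scores, e.g. an empty signature) yield NA metrics with a
#' warning; the CPE is still reported (0.5 for a constant score).
#'
#' @param signature A [CoxSignature-class].
#' @param trainX,trainTime,trainEvent Training cohort (raw-feature matrix and
#'   outcome) used only for cutoffs.
#' @param testX,testTime,testEvent Withheld test cohort.
#' @param testIds Optional sample ids for the report.
#' @return A [PredictionReport-class].
#' @export
evaluateSignature <- function(signature, trainX, trainTime, trainEvent,
                              testX, testTime, testEvent, testIds = NULL) {
  stopifnot(is(signature, "CoxSignature"))
  .checkOutcome(testTime, testEvent, requireEvent = FALSE)
  trainScores <- computeScores(signature, trainX)
  testScores <- computeScores(signature, testX)
  if (is.null(testIds)) testIds <- testScores$sample_id

  km <- list()
  cutoffs <- list()
  strata <- list()
  metricRows <- list()
  for (sc in c("c_score", "t_score")) {
    tr <- trainScores[[sc]]
    te <- testScores[[sc]]
    cpeTest <- cpeValidated(te, testTime, testEvent)
    row <- data.frame(score = sub("_score", "-score", sc),
                      p_3group = NA_real_, p_low_high = NA_real_,
                      hr = NA_real_, hr_lo = NA_real_, hr_hi = NA_real_,
                      cpe_test = cpeTest, stringsAsFactors = FALSE)
    st <- tryCatch(stratifyRisk(tr, te), error = function(e) {
      warning("degenerate ", sc, " stratification: ", conditionMessage(e))
      NULL
    })
    if (!is.null(st)) {
      cutoffs[[sc]] <- st$cutoffs
      strata[[sc]] <- st$test
      present <- droplevels(st$test)
      if (nlevels(present) >= 2) {
        lr <- logrankTest(testTime, testEvent, present)
        row$p_3group <- lr$p
        lh <- st$test %in% c("low", "high")
        if (length(unique(st$test[lh])) >= 2) {
          lr2 <- logrankTest(testTime[lh], testEvent[lh],
                             droplevels(st$test[lh]))
          row$p_low_high <- lr2$p
        }
        hrci <- .hazardRatioLowHigh(testTime, testEvent, st$test)
        row$hr <- hrci["hr"]
        row$hr_lo <- hrci["lo"]
        row$hr_hi <- hrci["hi"]
      } else {
        warning("fewer than 2 nonempty test strata for ", sc,
                "; p-values omitted")
      }
      for (lv in levels(st$test)) {
        sel <- st$test == lv
        if (any(sel))
          km[[paste(sc, lv, sep = ".")]] <-
            kaplanMeier(testTime[sel], testEvent[sel])
      }
    }
    metricRows[[sc]] <- row
  }

  med <- predictMedianTime(signature, eta = testScores$c_score)
  patients <- data.frame(
    sample_id = testIds,
    c_score = testScores$c_score, t_score = testScores$t_score,
    c_stratum = if (!is.null(strata$c_score)) as.character(strata$c_score)
                else NA_character_,
    t_stratum = if (!is.null(strata$t_score)) as.character(strata$t_score)
                else NA_character_,
    predicted_median_months = med$median_months,
    not_reached = med$not_reached, stringsAsFactors = FALSE)

  metrics <- do.call(rbind, metricRows)
  rownames(metrics) <- NULL
  new("PredictionReport", patients = patients, metrics = metrics, km = km,
      cutoffs = cutoffs, signatureSize = nrow(signature@features))
}
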