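## Train/test splitting and repeated two-fold cross-validation of the
## penalty, scored by the held-fold concordance probability estimate.

#' Random train/test split of a cohort
#'
#' Simple random split, deterministic given the seed. The training size is
#' `floor(trainFraction * n)`, which reproduces an 80% split of 395 samples
#' as 316 and of 481 samples as 384. An optional event-stratified mode draws
#' the same fraction separately within events and censored samples.
#'
#' @param sampleIds Character vector of sample ids (unique).
#' @param trainFraction Fraction in (0, 1); default 0.8.
#' @param seed Integer seed.
#' @param stratifyEvent Stratify the draw by event status.
#' @param event 0/1 per sample; required for validation and stratified mode.
#' @return Named character vector (`"train"`/`"test"`) over `sampleIds`.
#' @export
trainTestSplit <- function(sampleIds, trainFraction = 0.8, seed = 1L,
                           stratifyEvent = FALSE, event = NULL) {
  if (anyDuplicated(sampleIds)) stop("sample ids must be unique")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie strictly between 0 and 1")
  n <- length(sampleIds)
  .withSeed(seed, {
    if (stratifyEvent) {
      if (is.null(event)) stop("stratified split needs event indicators")
      trainIds <- unlist(lapply(split(sampleIds, event), function(g) {
        sample(g, floor(trainFraction * length(g)))
      }), use.names = FALSE)
    } else {
      trainIds <- sample(sampleIds, floor(trainFraction * n))
    }
    lab <- setNames(ifelse(sampleIds %in% trainIds, "train", "test"),
                    sampleIds)
    if (!is.null(event)) {
      ev <- setNames(event, sampleIds)
      if (sum(ev[lab == "train"]) < 2 || sum(ev[lab == "test"]) < 2)
        stop("degenerate split: fewer than 2 events in train or test")
    }
    lab
  })
}

# penalty attaining the maximal mean cv.CPE; exact ties resolve to the
# largest penalty (sparsest model)
.selectLambda <- function(lambdas, meanCPE) {
  best <- max(meanCPE)
  max(lambdas[meanCPE >= best - 1e-12])
}

#' Repeated two-fold cross-validation of the penalty
#'
#' Fits the full path on all supplied (training) samples to fix the shared
#' penalty grid, then for each repeat splits the samples into `folds` random
#' folds; each fold is held out in turn, the path is refit on the remaining
#' samples (standardization refit in-fold), and the held-fold linear
#' predictors score the outcome-validated concordance probability estimate
#' ([cpeValidated()]) at every grid
#' penalty. The selected penalty maximizes the mean held-fold CPE; ties go
#' to the largest penalty (sparsest model). Folds with fewer than 2 events
#' are redrawn (bounded retries).
#'
#' @param X Samples x features matrix (raw scale).
#' @param time,event Right-censored outcome.
#' @param folds Number of folds (default 2).
#' @param repeats Number of repeats (default 10).
#' @param lambda2,nlambda,lambdaMinRatio Path-fitting controls, see
#'   [fitCoxPath()].
#' @param seed Integer seed for the fold draws.
#' @param foldEffort Effort caps `c(maxOuter, maxInner)` for the fold fits.
#'   Held-fold scoring needs only the ranking of the linear predictors, so
#'   fold paths run under lighter caps than the master fit; the master path
#'   (from which the signature is extracted) always uses the full defaults.
#' @return A [CVResult-class] carrying the master path.
#' @export
crossValidatePath <- function(X, time, event, folds = 2L, repeats = 10L,
                              lambda2 = 1e-5, nlambda = 100,
                              lambdaMinRatio = 0.001, seed = 1L,
                              foldEffort = c(8L, 40L)) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  .checkOutcome(time, event)
  folds <- as.integer(folds)
  repeats <- as.integer(repeats)
  if (folds < 2) stop("folds must be at least 2")
  if (repeats < 1) stop("repeats must be at least 1")

  master <- fitCoxPath(X, time, event, lambda2 = lambda2, nlambda = nlambda,
                       lambdaMinRatio = lambdaMinRatio)
  grid <- master@lambdas
  n <- nrow(X)

  cpeMat <- .withSeed(seed, {
    rows <- list()
    for (r in seq_len(repeats)) {
      assign <- NULL
      for (try in 1:100) {
        cand <- sample(rep_len(seq_len(folds), n))
        if (all(vapply(seq_len(folds),
                       function(f) sum(event[cand == f]) >= 2, logical(1)) &
                vapply(seq_len(folds),
                       function(f) sum(event[cand != f]) >= 2, logical(1)))) {
          assign <- cand
          break
        }
      }
      if (is.null(assign))
        stop("could not draw folds with at least 2 events each")
      for (f in seq_len(folds)) {
        inIdx <- assign != f
        fit <- fitCoxPath(X[inIdx, , drop = FALSE], time[inIdx],
                          event[inIdx], lambda2 = lambda2, lambdas = grid,
                          maxOuter = foldEffort[1], maxInner = foldEffort[2])
        Xh <- X[!inIdx, fit@featureIds, drop = FALSE]
        Xh <- sweep(sweep(Xh, 2, fit@center, "-"), 2, fit@scale, "/")
        etas <- Xh %*% fit@beta
        th <- time[!inIdx]
        eh <- event[!inIdx]
        rows[[length(rows) + 1L]] <-
          apply(etas, 2, function(e) cpeValidated(as.numeric(e), th, eh))
      }
    }
    do.call(rbind, rows)
  })

  meanCPE <- colMeans(cpeMat)
  sdCPE <- apply(cpeMat, 2, sd)
  lambdaStar <- .selectLambda(grid, meanCPE)
  new("CVResult", lambdas = grid, meanCPE = meanCPE, sdCPE = sdCPE,
      nonzero = as.integer(colSums(master@beta != 0)),
      lambdaOpt = lambdaStar, folds = folds, repeats = repeats,
      seed = as.integer(seed), path = master)
}
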