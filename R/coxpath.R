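## L1-regularized Cox regularization path with a small ridge stabilizer.
## Objective: -logPL(beta) + lambda * ||beta||_1 + lambda2 * ||beta||_2^2,
## solved by cyclic coordinate descent on the IRLS quadratic approximation,
## warm-started along a decreasing geometric lambda grid.

.dropDegenerate <- function(X) {
  sds <- apply(X, 2, sd)
  bad <- !is.finite(sds) | sds == 0
  if (any(bad))
    warning(sum(bad), " constant feature(s) dropped (unidentifiable): ",
            paste(head(colnames(X)[bad], 5), collapse = ", "),
            if (sum(bad) > 5) ", ..." else "")
  X[, !bad, drop = FALSE]
}

.standardizeTrain <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  Xs <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  list(X = Xs, center = ctr, scale = scl)
}

#' Entry penalty of the L1 path
#'
#' The largest penalty at which any coefficient becomes nonzero: the maximum
#' absolute component of the gradient of the negative log partial likelihood
#' at `beta = 0`. Fitting at any penalty at or above this value returns the
#' zero vector.
#'
#' @param X Samples x features matrix (standardized features expected; the
#'   value is scale-sensitive).
#' @param time,event Right-censored outcome with at least one event.
#' @return Scalar `lambda_max`.
#' @export
lambdaMax <- function(X, time, event) {
  g <- negLogPartialLik(numeric(ncol(X)), X, time, event)$gradient
  max(abs(g))
}

#' Fit the L1-penalized Cox regularization path
#'
#' Solves \deqn{\min_\beta\; -\log L(\beta) + \lambda \|\beta\|_1 +
#' \lambda_2 \|\beta\|_2^2} along a geometric grid of `nlambda` penalties
#' from `lambda_max` down to `lambdaMinRatio * lambda_max` (plus
#' `lambda = 0` when p < number of events), warm-starting each grid point
#' from the previous solution. Each grid point is iterated until the KKT
#' conditions of the penalized objective hold to `tolKKT`; points that do not
#' reach tolerance are flagged, and the path is still returned.
#'
#' Features are standardized to mean 0, unit variance on the fitting data by
#' default; coefficients are reported on the standardized scale and the
#' transform is stored for test-set application.
#'
#' @param X Samples x features matrix.
#' @param time,event Right-censored outcome with at least one event.
#' @param lambda2 Small nonnegative ridge constant (default `1e-5`).
#' @param nlambda Grid size (default 100).
#' @param lambdaMinRatio Smallest grid penalty as a fraction of
#'   `lambda_max` (default 0.001).
#' @param standardize Standardize features on the fitting data (default
#'   `TRUE`).
#' @param lambdas Optional explicit decreasing grid overriding the geometric
#'   construction (used by cross-validation to share one grid across folds).
#' @param tolKKT Absolute KKT tolerance (default `1e-6`).
#' @param maxOuter,maxInner Effort caps per grid point: outer quadratic
#'   re-approximations and coordinate-descent sweeps per quadratic. Grid
#'   points hitting the caps before `tolKKT` are flagged unconverged (this
#'   only occurs past model saturation, where the active set approaches the
#'   number of events).
#' @return A [CoxPathFit-class].
#' @export
fitCoxPath <- function(X, time, event, lambda2 = 1e-5, nlambda = 100,
                       lambdaMinRatio = 0.001, standardize = TRUE,
                       lambdas = NULL, tolKKT = 1e-6, maxOuter = 20L,
                       maxInner = 100L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  .checkOutcome(time, event)
  if (lambda2 < 0) stop("lambda2 must be nonnegative")
  X <- .dropDegenerate(X)
  if (ncol(X) == 0) stop("no identifiable features left")
  if (standardize) {
    st <- .standardizeTrain(X)
    Xs <- st$X
    ctr <- st$center
    scl <- st$scale
  } else {
    Xs <- X
    ctr <- setNames(rep(0, ncol(X)), colnames(X))
    scl <- setNames(rep(1, ncol(X)), colnames(X))
  }

  lmax <- lambdaMax(Xs, time, event)
  if (is.null(lambdas)) {
    lambdas <- exp(seq(log(lmax), log(lmax * lambdaMinRatio),
                       length.out = nlambda))
    if (ncol(Xs) < sum(event)) lambdas <- c(lambdas, 0)
  } else {
    if (any(diff(lambdas) >= 0)) stop("lambdas must be strictly decreasing")
  }

  rp <- .riskPrep(time, event)
  sol <- .cox_cd_path(Xs[rp$ord, , drop = FALSE], rp$event, rp$grpFirst,
                      rp$grpD, rp$nGrpLE, lambdas, lambda2,
                      numeric(ncol(Xs)), tolInner = 1e-8,
                      tolKKT = tolKKT, maxOuter = as.integer(maxOuter),
                      maxInner = as.integer(maxInner))
  beta <- sol$beta
  dimnames(beta) <- list(colnames(Xs), NULL)
  # the entry point is exactly zero by the KKT conditions; enforce against
  # coordinate-descent rounding
  beta[, lambdas >= lmax - 1e-12] <- 0
  new("CoxPathFit", lambdas = lambdas, lambdaEntry = lmax, beta = beta,
      lambda2 = lambda2,
      converged = as.logical(sol$converged), nloglik = as.numeric(sol$nloglik),
      featureIds = colnames(Xs), center = ctr, scale = scl, X = Xs,
      time = as.numeric(time), event = as.integer(event),
      standardized = standardize)
}

#' Coefficients of a path at a given penalty
#'
#' An exact grid hit returns the stored column bit-identically; any other
#' penalty in `[0, lambda_max]` is refit at that value, warm-started from the
#' nearest grid point (no interpolation).
#'
#' @param fit A [CoxPathFit-class].
#' @param lambda Penalty, nonnegative.
#' @return Named coefficient vector on the standardized scale.
#' @export
pathCoefficients <- function(fit, lambda) {
  stopifnot(is(fit, "CoxPathFit"))
  if (lambda < 0) stop("lambda must be nonnegative")
  hit <- which(fit@lambdas == lambda)
  if (length(hit))
    return(setNames(fit@beta[, hit[1]], fit@featureIds))
  if (lambda >= fit@lambdas[1])
    return(setNames(numeric(nrow(fit@beta)), fit@featureIds))
  near <- which.min(abs(fit@lambdas - lambda))
  rp <- .riskPrep(fit@time, fit@event)
  sol <- .cox_cd_path(fit@X[rp$ord, , drop = FALSE], rp$event, rp$grpFirst,
                      rp$grpD, rp$nGrpLE, lambda, fit@lambda2,
                      fit@beta[, near], tolInner = 1e-9, tolKKT = 1e-6,
                      maxOuter = 50L, maxInner = 500L)
  setNames(sol$beta[, 1], fit@featureIds)
}

#' Penalized objective of a path fit
#'
#' @param fit A [CoxPathFit-class].
#' @param beta Coefficient vector on the fit's standardized scale.
#' @param lambda Penalty at which to evaluate.
#' @return `-logPL + lambda*||beta||_1 + lambda2*||beta||_2^2`.
#' @export
pathObjective <- function(fit, beta, lambda) {
  nll <- negLogPartialLik(beta, fit@X, fit@time, fit@event)$value
  nll + lambda * sum(abs(beta)) + fit@lambda2 * sum(beta^2)
}

# KKT residual of the penalized objective at beta; used in tests and the
# convergence flags.
.kktResidual <- function(fit, beta, lambda) {
  g <- negLogPartialLik(beta, fit@X, fit@time, fit@event)$gradient
  act <- beta != 0
  v <- numeric(length(beta))
  v[act] <- abs(g[act] + 2 * fit@lambda2 * beta[act] + lambda * sign(beta[act]))
  v[!act] <- pmax(0, abs(g[!act]) - lambda)
  max(v)
}
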