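## Survival-analysis primitives. Partial likelihood, its gradient, the Newton
## fit and the Breslow baseline are authored here (they are the substrate of
## the penalized path solver); Kaplan-Meier and log-rank go through the
## survival package behind this module's interface.

.checkOutcome <- function(time, event, requireEvent = TRUE) {
  if (length(time) != length(event))
    stop("time and event must have equal length")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be positive and finite")
  if (!all(event %in% c(0, 1)))
    stop("event indicators must be 0/1")
  if (requireEvent && sum(event) == 0)
    stop("degenerate outcome: no events observed (all samples censored)")
  invisible(TRUE)
}

# Risk-set bookkeeping shared by the likelihood code and the C++ solver:
# samples sorted by ascending time; for each distinct event time, the suffix
# start of its risk set and its Breslow event count.
.riskPrep <- function(time, event) {
  ord <- order(time)
  ts <- time[ord]
  ev <- as.integer(event[ord])
  evTimes <- unique(ts[ev == 1L])
  grpFirst <- match(evTimes, ts) - 1L          # 0-based suffix starts
  grpD <- vapply(evTimes, function(t) sum(ev == 1L & ts == t), integer(1))
  nGrpLE <- findInterval(ts, evTimes)
  list(ord = ord, time = ts, event = ev, evTimes = evTimes,
       grpFirst = grpFirst, grpD = grpD, nGrpLE = nGrpLE)
}

#' Negative log partial likelihood and its gradient
#'
#' Cox's partial likelihood over risk sets at event times, with the Breslow
#' convention for tied event times:
#' \deqn{-\log L(\beta) = -\sum_{i:\delta_i=1}\left[x_i'\beta -
#'   \log \sum_{j \in R_i} e^{x_j'\beta}\right]}
#' where \eqn{R_i = \{j : y_j \ge y_i\}} is the risk set at time \eqn{y_i}.
#'
#' @param beta Coefficient vector (length = `ncol(X)`).
#' @param X Samples x features covariate matrix.
#' @param time Positive follow-up times (months).
#' @param event 0/1 event indicators; at least one event required.
#' @return list with `value` (scalar) and `gradient` (length-p vector).
#' @export
negLogPartialLik <- function(beta, X, time, event) {
  X <- as.matrix(X)
  .checkOutcome(time, event)
  if (length(beta) != ncol(X)) stop("beta length must match ncol(X)")
  rp <- .riskPrep(time, event)
  .cox_nll_grad(X[rp$ord, , drop = FALSE], as.numeric(beta), rp$event,
                rp$grpFirst, rp$grpD, rp$nGrpLE)
}

# Full observed information (p x p) at beta; used for Wald standard errors.
.coxInformation <- function(beta, X, time, event) {
  rp <- .riskPrep(time, event)
  Xs <- X[rp$ord, , drop = FALSE]
  eta <- as.numeric(Xs %*% beta)
  w <- exp(eta - max(eta))
  n <- length(w)
  p <- ncol(Xs)
  info <- matrix(0, p, p)
  # suffix accumulations over descending time
  S0 <- 0
  S1 <- numeric(p)
  S2 <- matrix(0, p, p)
  k <- length(rp$evTimes)
  for (j in n:1) {
    S0 <- S0 + w[j]
    S1 <- S1 + w[j] * Xs[j, ]
    S2 <- S2 + w[j] * tcrossprod(Xs[j, ])
    while (k >= 1 && rp$grpFirst[k] == j - 1L) {
      xbar <- S1 / S0
      info <- info + rp$grpD[k] * (S2 / S0 - tcrossprod(xbar))
      k <- k - 1L
    }
  }
  info
}

#' Fit an unpenalized Cox proportional hazards model by Newton iteration
#'
#' Newton-Raphson on the negative log partial likelihood (Breslow ties) with
#' step halving, to gradient norm `tol`. Standard errors come from the
#' inverse observed information. Monotone-likelihood (separation) and other
#' non-convergence is reported as an error, never returned silently.
#'
#' @param X Samples x features covariate matrix (no constant columns).
#' @param time,event Right-censored outcome.
#' @param tol Convergence tolerance on the max-norm of the gradient.
#' @param maxIter Maximum Newton iterations.
#' @return list of class `coxNewtonFit`: `beta`, `se`, `loglik` (log partial
#'   likelihood at the optimum), `iter`, `gradientNorm`.
#' @export
fitCoxNewton <- function(X, time, event, tol = 1e-8, maxIter = 50) {
  X <- as.matrix(X)
  .checkOutcome(time, event)
  if (ncol(X) > sum(event))
    stop("more features than events; unpenalized fit is not identifiable")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("constant columns are unidentifiable under the partial likelihood: ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  beta <- numeric(ncol(X))
  fb <- negLogPartialLik(beta, X, time, event)
  for (it in seq_len(maxIter)) {
    g <- fb$gradient
    if (max(abs(g)) <= tol) break
    info <- .coxInformation(beta, X, time, event)
    step <- tryCatch(solve(info, g), error = function(e)
      stop("singular information matrix; model not identifiable"))
    # step halving on the negative log partial likelihood
    alpha <- 1
    repeat {
      cand <- beta - alpha * step
      fc <- negLogPartialLik(cand, X, time, event)
      if (fc$value <= fb$value + 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    if (alpha < 1e-8 && fc$value > fb$value)
      stop("Newton iteration failed to decrease the objective")
    beta <- cand
    fb <- fc
    if (max(abs(beta)) > 50)
      stop("coefficients diverging; monotone likelihood (separation) suspected")
  }
  if (max(abs(fb$gradient)) > tol * max(1, abs(fb$value)))
    stop("Newton iteration did not converge in ", maxIter, " iterations")
  # a vanishing gradient at an extreme coefficient is the signature of a
  # monotone likelihood, not of an interior optimum
  if (max(abs(beta)) > 15)
    stop("coefficient escaping to infinity; ",
         "monotone likelihood (separation) suspected")
  info <- .coxInformation(beta, X, time, event)
  se <- sqrt(diag(solve(info)))
  structure(list(beta = setNames(beta, colnames(X)),
                 se = setNames(se, colnames(X)),
                 loglik = -fb$value, iter = it,
                 gradientNorm = max(abs(fb$gradient))),
            class = "coxNewtonFit")
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time,event Right-censored outcome (events not required; an
#'   all-censored input returns the constant curve 1).
#' @return A [StepCurve-class] with knots at the event times.
#' @export
kaplanMeier <- function(time, event) {
  .checkOutcome(time, event, requireEvent = FALSE)
  if (length(time) == 0) stop("empty outcome")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event > 0
  stepCurve(fit$time[keep], fit$surv[keep], start = 1, type = "survival")
}

#' k-sample log-rank test
#'
#' Standard log-rank chi-square statistic with `k - 1` degrees of freedom and
#' upper-tail p-value.
#'
#' @param time,event Right-censored outcome.
#' @param group Group labels with at least two levels; every level must be
#'   populated.
#' @return list with `chi2`, `df`, `p`.
#' @export
logrankTest <- function(time, event, group) {
  .checkOutcome(time, event, requireEvent = FALSE)
  group <- as.factor(group)
  if (nlevels(group) < 2) stop("log-rank test needs at least two groups")
  if (any(table(group) == 0))
    stop("empty group level: ",
         paste(levels(group)[table(group) == 0], collapse = ", "))
  sd0 <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(chi2 = as.numeric(sd0$chisq), df = df,
       p = pchisq(as.numeric(sd0$chisq), df = df, lower.tail = FALSE))
}

#' Breslow estimate of the cumulative baseline hazard
#'
#' \deqn{\hat H_0(t) = \sum_{t_i \le t} d_i / \sum_{j \in R_i} e^{x_j'\beta}}
#' with \eqn{d_i} events at each distinct event time. At `beta = 0` this is
#' the Nelson-Aalen estimator.
#'
#' @param beta Fitted coefficients.
#' @param X Samples x features matrix on the same scale as `beta`.
#' @param time,event Right-censored outcome.
#' @return A [StepCurve-class] cumulative hazard (nondecreasing, 0 before the
#'   first event time).
#' @export
breslowBaseline <- function(beta, X, time, event) {
  X <- as.matrix(X)
  .checkOutcome(time, event)
  if (!all(is.finite(beta))) stop("beta must be finite")
  rp <- .riskPrep(time, event)
  eta <- as.numeric(X[rp$ord, , drop = FALSE] %*% beta)
  mx <- max(eta)
  w <- exp(eta - mx)
  suff <- rev(cumsum(rev(w)))
  inc <- rp$grpD / (suff[rp$grpFirst + 1L] * exp(mx))
  stepCurve(rp$evTimes, cumsum(inc), start = 0, type = "cumhaz")
}
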