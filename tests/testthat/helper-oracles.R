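# Independent oracles, deliberately written as direct transcriptions of the
# definitions (double loops over risk sets, proximal gradient) so they share
# no code with the package implementations they check.

# negative log partial likelihood by explicit risk-set enumeration (Breslow)
naiveNegLogPL <- function(beta, X, time, event) {
  eta <- as.numeric(X %*% beta)
  val <- 0
  for (t in unique(time[event == 1])) {
    d <- sum(event == 1 & time == t)
    risk <- which(time >= t)
    val <- val - sum(eta[event == 1 & time == t]) +
      d * log(sum(exp(eta[risk])))
  }
  val
}

# gradient by the direct formula, again with explicit loops
naiveGradient <- function(beta, X, time, event) {
  eta <- as.numeric(X %*% beta)
  g <- numeric(ncol(X))
  for (t in unique(time[event == 1])) {
    d <- sum(event == 1 & time == t)
    risk <- which(time >= t)
    wr <- exp(eta[risk])
    xbar <- colSums(X[risk, , drop = FALSE] * wr) / sum(wr)
    g <- g - colSums(X[event == 1 & time == t, , drop = FALSE]) + d * xbar
  }
  g
}

# generic proximal-gradient (ISTA) minimizer of the penalized objective
# -logPL + lambda*||b||_1 + lambda2*||b||_2^2, with backtracking line search
istaCox <- function(X, time, event, lambda, lambda2, beta0 = NULL,
                    maxIter = 20000, tol = 1e-12) {
  p <- ncol(X)
  b <- if (is.null(beta0)) numeric(p) else beta0
  obj <- function(b) naiveNegLogPL(b, X, time, event) +
    lambda * sum(abs(b)) + lambda2 * sum(b^2)
  smoothGrad <- function(b) naiveGradient(b, X, time, event) + 2 * lambda2 * b
  s <- 1
  fPrev <- obj(b)
  for (i in seq_len(maxIter)) {
    g <- smoothGrad(b)
    repeat {
      cand <- sign(b - s * g) * pmax(abs(b - s * g) - s * lambda, 0)
      fCand <- obj(cand)
      # sufficient decrease wrt the proximal model
      fSmooth <- naiveNegLogPL(b, X, time, event) + lambda2 * sum(b^2)
      q <- fSmooth + sum(g * (cand - b)) + sum((cand - b)^2) / (2 * s) +
        lambda * sum(abs(cand))
      if (fCand <= q + 1e-12 || s < 1e-12) break
      s <- s / 2
    }
    if (abs(fPrev - fCand) < tol && i > 10) { b <- cand; break }
    b <- cand
    fPrev <- fCand
    s <- min(s * 1.5, 1)
  }
  list(beta = b, objective = obj(b))
}

# brute-force pairwise CPE (exact form), double loop
bruteCpe <- function(eta) {
  n <- length(eta)
  num <- 0
  cnt <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (eta[i] != eta[j]) {
      num <- num + 1 / (1 + exp(-abs(eta[i] - eta[j])))
      cnt <- cnt + 1
    }
  }
  if (cnt == 0) 0.5 else num / cnt
}

# small simulated instance used across solver tests
solverInstance <- function(n = 40, p = 8, seed = 11, censor = 0.3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  k <- min(3, p)
  eta <- as.numeric(X[, seq_len(k), drop = FALSE] %*%
                    c(0.8, -0.6, 0.4)[seq_len(k)])
  o <- simulateSurvival(eta, baselineScale = 40, censorTarget = censor,
                        seed = seed + 1)
  list(X = X, time = o$time, event = o$event)
}
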