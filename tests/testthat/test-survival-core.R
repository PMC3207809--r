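test_that("partial likelihood at zero equals the log risk-set sizes", {
  inst <- solverInstance(n = 25, p = 3, seed = 1)
  v <- negLogPartialLik(numeric(3), inst$X, inst$time, inst$event)
  rs <- sapply(inst$time[inst$event == 1],
               function(t) sum(inst$time >= t))
  expect_equal(v$value, sum(log(rs)), tolerance = 1e-12)
})

test_that("three-sample likelihood matches direct risk-set enumeration", {
  # times 1 < 2 < 3, all events, one covariate (1, 0, 0), beta = 1
  x <- matrix(c(1, 0, 0), ncol = 1)
  v <- negLogPartialLik(1, x, c(1, 2, 3), c(1, 1, 1))
  expected <- -(1 - log(exp(1) + 2)) - (0 - log(2)) - 0
  expect_equal(v$value, expected, tolerance = 1e-12)
  expect_equal(v$value, naiveNegLogPL(1, x, c(1, 2, 3), c(1, 1, 1)),
               tolerance = 1e-12)
})

test_that("analytic gradient matches central finite differences", {
  inst <- solverInstance(n = 30, p = 4, seed = 2)
  b <- c(0.4, -0.3, 0.2, 0)
  g <- negLogPartialLik(b, inst$X, inst$time, inst$event)$gradient
  h <- 1e-6
  fd <- sapply(1:4, function(k) {
    e <- numeric(4); e[k] <- h
    (negLogPartialLik(b + e, inst$X, inst$time, inst$event)$value -
     negLogPartialLik(b - e, inst$X, inst$time, inst$event)$value) / (2 * h)
  })
  expect_equal(g, fd, tolerance = 1e-5)
})

test_that("degenerate outcomes are rejected", {
  x <- matrix(rnorm(10), ncol = 1)
  expect_error(negLogPartialLik(0, x, 1:10, rep(0, 10)), "censored")
  expect_error(negLogPartialLik(0, x, c(-1, 2:10), rep(1, 10)), "positive")
})

test_that("Newton fit is symmetric under exchangeable groups", {
  # identical (tied) event patterns in both covariate groups
  x <- matrix(rep(c(0, 1), each = 5), ncol = 1, dimnames = list(NULL, "g"))
  time <- rep(c(1, 2, 3, 4, 5), 2)
  fit <- fitCoxNewton(x, time, rep(1L, 10))
  expect_lt(abs(fit$beta), 1e-8)
})

test_that("Newton fit recovers the generating coefficient at n = 1000", {
  set.seed(31)
  x <- matrix(rnorm(1000), ncol = 1, dimnames = list(NULL, "z"))
  o <- simulateSurvival(as.numeric(x) * 0.7, 50, 0.3, seed = 32)
  fit <- fitCoxNewton(x, o$time, o$event)
  expect_equal(unname(fit$beta), 0.7, tolerance = 0.1)
})

test_that("Newton fit agrees with survival::coxph on a 50 x 3 instance", {
  inst <- solverInstance(n = 50, p = 3, seed = 3)
  mine <- fitCoxNewton(inst$X, inst$time, inst$event)
  ref <- survival::coxph(survival::Surv(inst$time, inst$event) ~ inst$X,
                         ties = "breslow")
  expect_equal(unname(mine$beta), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(unname(mine$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-4)
})

test_that("Newton fit reports separation instead of silently returning", {
  # perfectly separating covariate: all early events in one group
  x <- matrix(c(rep(1, 5), rep(0, 5)), ncol = 1, dimnames = list(NULL, "s"))
  time <- c(1:5, 101:105)
  expect_error(fitCoxNewton(x, time, rep(1L, 10)))
  expect_error(fitCoxNewton(matrix(1, 10, 1), time, rep(1L, 10)), "constant")
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- kaplanMeier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km@knots, c(1, 2, 3))
  expect_equal(km@values, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  # the position of a censoring time after the last event is irrelevant
  km2a <- kaplanMeier(c(1, 2, 3, 4), c(1, 1, 1, 0))
  km2b <- kaplanMeier(c(1, 2, 3, 99), c(1, 1, 1, 0))
  expect_equal(km2a@knots, km2b@knots)
  expect_equal(km2a@values, km2b@values, tolerance = 1e-12)
  # no events: constant 1
  km3 <- kaplanMeier(c(1, 2), c(0, 0))
  expect_identical(length(km3@knots), 0L)
  expect_equal(evalStep(km3, c(0.5, 5)), c(1, 1))
})

test_that("log-rank is null on duplicated groups and df tracks levels", {
  time <- c(1, 2, 3, 4, 5)
  event <- c(1, 0, 1, 1, 0)
  lr <- logrankTest(c(time, time), c(event, event), rep(c("a", "b"), each = 5))
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)
  lr3 <- logrankTest(rep(time, 3), rep(event, 3), rep(c("a", "b", "c"), each = 5))
  expect_identical(lr3$df, 2L)
  expect_error(logrankTest(time, event, factor(rep("a", 5), levels = c("a", "b"))),
               "group")
})

test_that("two-group log-rank matches the hand observed-expected sums", {
  time <- c(1, 2, 3, 4)
  event <- c(1, 1, 1, 1)
  grp <- c("a", "b", "a", "b")
  # hand accumulation over the four event times
  oe <- 0; v <- 0
  for (t in time) {
    atRisk <- time >= t
    n1 <- sum(atRisk & grp == "a"); ntot <- sum(atRisk)
    d <- 1
    e1 <- d * n1 / ntot
    o1 <- as.numeric(grp[time == t] == "a")
    oe <- oe + o1 - e1
    if (ntot > 1)
      v <- v + d * (n1 / ntot) * (1 - n1 / ntot) * (ntot - d) / (ntot - 1)
  }
  lr <- logrankTest(time, event, grp)
  expect_equal(lr$chi2, oe^2 / v, tolerance = 1e-10)
})

test_that("log-rank is invariant under group relabeling", {
  inst <- solverInstance(n = 30, p = 2, seed = 4)
  g <- rep(c("x", "y", "z"), each = 10)
  a <- logrankTest(inst$time, inst$event, g)
  b <- logrankTest(inst$time, inst$event,
                   c(x = "z", y = "x", z = "y")[g])
  expect_equal(a$chi2, b$chi2, tolerance = 1e-12)
})

test_that("Breslow baseline at beta = 0 is the Nelson-Aalen estimator", {
  inst <- solverInstance(n = 20, p = 2, seed = 5)
  H <- breslowBaseline(c(0, 0), inst$X, inst$time, inst$event)
  evT <- sort(inst$time[inst$event == 1])
  na <- cumsum(sapply(evT, function(t) 1 / sum(inst$time >= t)))
  expect_equal(H@knots, evT)
  expect_equal(H@values, na, tolerance = 1e-12)
  expect_true(all(diff(H@values) >= 0))
})

test_that("Breslow survival tracks the generating exponential curve", {
  set.seed(41)
  x <- matrix(rnorm(1500), ncol = 1, dimnames = list(NULL, "z"))
  o <- simulateSurvival(as.numeric(x) * 0.5, 40, 0.3, seed = 42)
  fit <- fitCoxNewton(x, o$time, o$event)
  H <- breslowBaseline(fit$beta, x, o$time, o$event)
  grid <- seq(5, 60, by = 5)
  s0 <- exp(-evalStep(H, grid))
  expect_lt(max(abs(s0 - exp(-grid / 40))), 0.05)
})

test_that("KM and exp(-Breslow at zero) agree on tie-free data", {
  inst <- solverInstance(n = 60, p = 2, seed = 6)
  km <- kaplanMeier(inst$time, inst$event)
  H <- breslowBaseline(c(0, 0), inst$X, inst$time, inst$event)
  # product-limit vs exponentiated cumulative hazard differ at O(1/|R|^2)
  expect_lt(max(abs(km@values - exp(-H@values))), 0.05)
})
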