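# a small fitted pipeline reused across prognosis tests
prognosisFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    co <- simulateCohort(simConfig(nSamples = 200, nGenes = 20, nMirnas = 5,
                                   seed = 101))
    split <- trainTestSplit(sampleNames(co), 0.8, seed = 102,
                            event = clinicalData(co)$event)
    ds <- suppressMessages(integrateOmics(co, split, integrationConfig()))
    tro <- outcomeOf(ds, "train")
    cv <- crossValidatePath(trainMatrix(ds), tro$time, tro$event,
                            repeats = 2, nlambda = 40, seed = 103)
    sig <- extractSignature(cv@path, lambdaOpt(cv), featureMeta(ds))
    cache <<- list(co = co, ds = ds, cv = cv, sig = sig, tro = tro,
                   teo = outcomeOf(ds, "test"))
    cache
  }
})

test_that("c- and t-scores follow their defining arithmetic", {
  sig <- new("CoxSignature",
             features = data.frame(feature = c("mRNA:A", "mRNA:B"),
                                   platform = "mRNA", gene = c("A", "B"),
                                   beta = c(2, -1),
                                   direction = c("poor", "good")),
             center = setNames(c(0, 0), c("mRNA:A", "mRNA:B")),
             scale = setNames(c(1, 1), c("mRNA:A", "mRNA:B")),
             lambda = 1, lambda2 = 0,
             baseline = stepCurve(1, 0.1, start = 0, type = "cumhaz"))
  X <- matrix(c(1.5, 0.4), 1, 2, dimnames = list("s1", c("mRNA:A", "mRNA:B")))
  sc <- computeScores(sig, X)
  expect_equal(sc$c_score, 2 * 1.5 - 1 * 0.4, tolerance = 1e-12)
  expect_equal(sc$t_score, 1.5 - 0.4, tolerance = 1e-12)
  # single poor feature with beta 2 at standardized value 1.5 -> c = 3
  X2 <- matrix(c(1.5, 0), 1, 2, dimnames = list("s1", c("mRNA:A", "mRNA:B")))
  expect_equal(computeScores(sig, X2)$c_score, 3, tolerance = 1e-12)
  # missing columns are an error naming the features
  expect_error(computeScores(sig, X[, 1, drop = FALSE]), "mRNA:B")
  # adding a constant to one standardized feature shifts c-scores linearly
  X3 <- X; X3[, "mRNA:A"] <- X3[, "mRNA:A"] + 2
  expect_equal(computeScores(sig, X3)$c_score - sc$c_score, 4,
               tolerance = 1e-12)
})

test_that("tertile cutoffs follow interpolated quantiles with low ties", {
  st <- stratifyRisk(1:9, c(3.67, 6.34))
  expect_equal(st$cutoffs, c(11 / 3, 19 / 3), tolerance = 1e-10)
  expect_identical(as.character(table(st$train)), c("3", "3", "3"))
  # a test score exactly at the lower cutoff goes to the low stratum
  at <- stratifyRisk(1:9, st$cutoffs[1])
  expect_identical(as.character(at$test), "low")
  # training assignments are rank-based: monotone transforms preserve them
  st2 <- stratifyRisk(exp(1:9))
  expect_identical(as.character(st$train), as.character(st2$train))
  expect_error(stratifyRisk(rep(2, 5)), "identical")
  expect_error(stratifyRisk(1:2), "at least 3")
})

test_that("predicted medians honor the survival-curve closed form", {
  fx <- prognosisFixture()
  sig <- fx$sig
  expect_gt(nrow(signatureFeatures(sig)), 0)
  # very high risk: predicted median at or before the first event time
  hi <- predictMedianTime(sig, eta = 50)
  expect_equal(hi$median_months, sig@baseline@knots[1], tolerance = 1e-9)
  # very low risk: curve never reaches 0.5
  lo <- predictMedianTime(sig, eta = -50)
  expect_true(lo$not_reached)
  expect_true(is.na(lo$median_months))
})

test_that("median predictions reverse-order the c-scores", {
  fx <- prognosisFixture()
  expect_gt(nrow(signatureFeatures(fx$sig)), 0)
  sc <- computeScores(fx$sig, testMatrix(fx$ds))
  med <- predictMedianTime(fx$sig, eta = sc$c_score)
  m <- ifelse(med$not_reached, .Machine$double.xmax, med$median_months)
  ord <- order(sc$c_score)
  expect_true(all(diff(m[ord]) <= 0))
})

test_that("evaluation reports sensible directionality on real signal", {
  fx <- prognosisFixture()
  rep <- evaluateSignature(fx$sig, trainMatrix(fx$ds), fx$tro$time,
                           fx$tro$event, testMatrix(fx$ds), fx$teo$time,
                           fx$teo$event)
  m <- reportMetrics(rep)
  expect_identical(m$score, c("c-score", "t-score"))
  expect_true(all(m$cpe_test >= 0.5 & m$cpe_test <= 1))
  cRow <- m[m$score == "c-score", ]
  expect_gt(cRow$hr, 1)  # high-risk stratum must carry higher hazard
  expect_true(cRow$hr_lo < cRow$hr & cRow$hr < cRow$hr_hi)
  expect_true(all(m$p_3group >= 0 & m$p_3group <= 1))
  pt <- patientTable(rep)
  expect_identical(nrow(pt), sum(splitLabels(fx$ds) == "test"))
  # bit-reproducible report from a fixed signature and data
  rep2 <- evaluateSignature(fx$sig, trainMatrix(fx$ds), fx$tro$time,
                            fx$tro$event, testMatrix(fx$ds), fx$teo$time,
                            fx$teo$event)
  expect_identical(reportMetrics(rep), reportMetrics(rep2))
  expect_identical(patientTable(rep), patientTable(rep2))
})

test_that("identical outcomes across strata give null tests", {
  sig <- new("CoxSignature",
             features = data.frame(feature = "mRNA:A", platform = "mRNA",
                                   gene = "A", beta = 1, direction = "poor"),
             center = c("mRNA:A" = 0), scale = c("mRNA:A" = 1), lambda = 1,
             lambda2 = 0,
             baseline = stepCurve(1, 0.01, start = 0, type = "cumhaz"))
  # three score groups, outcomes duplicated across them
  time <- rep(c(1, 2, 3, 4, 5, 6), 3)
  event <- rep(c(1, 1, 0, 1, 1, 0), 3)
  Xte <- matrix(rep(c(-2, 0, 2), each = 6), ncol = 1,
                dimnames = list(NULL, "mRNA:A"))
  Xtr <- matrix(rep(c(-2, 0, 2), 4), ncol = 1,
                dimnames = list(NULL, "mRNA:A"))
  rep <- evaluateSignature(sig, Xtr, rep(c(2, 4), 6), rep(1L, 12),
                           Xte, time, event)
  m <- reportMetrics(rep)
  cRow <- m[m$score == "c-score", ]
  expect_equal(cRow$p_3group, 1, tolerance = 1e-9)
  expect_equal(cRow$hr, 1, tolerance = 0.05)
})

test_that("degenerate stratification yields NA metrics and CPE 0.5", {
  emptySig <- new("CoxSignature",
                  features = data.frame(feature = character(0),
                                        platform = character(0),
                                        gene = character(0),
                                        beta = numeric(0),
                                        direction = character(0)),
                  center = numeric(0), scale = numeric(0), lambda = 1,
                  lambda2 = 0,
                  baseline = stepCurve(numeric(0), numeric(0), start = 0,
                                       type = "cumhaz"))
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  o <- simulateSurvival(rep(0, 20), 40, 0.2, seed = 104)
  w <- capture_warnings(
    rep <- evaluateSignature(emptySig, X, o$time, o$event, X, o$time,
                             o$event))
  expect_true(any(grepl("degenerate", w)))
  m <- reportMetrics(rep)
  expect_true(all(is.na(m$p_3group)))
  expect_true(all(m$cpe_test == 0.5))
})
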