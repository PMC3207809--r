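test_that("config validation rejects impossible settings", {
  expect_error(simConfig(nSamples = 1), "at least 2")
  expect_error(simConfig(rhoCna = 1.2), "\\[-1, 1\\]")
  expect_error(simConfig(censorTarget = 1), "\\[0, 1\\)")
  expect_error(simConfig(causal = data.frame(platform = "CNA", index = 99,
                                             beta = 1), nGenes = 10),
               "out of platform bounds")
  expect_error(simulateSurvival(c(0, NA), 40, 0.3, seed = 1), "finite")
})

test_that("cross-platform Spearman correlations hit their signed targets", {
  co <- simulateCohort(simConfig(nSamples = 500, rhoCna = 0, rhoMeth = -0.8,
                                 rhoMirna = -0.4, seed = 1))
  m <- platformMatrix(co, "mRNA")
  rhoCna <- sapply(1:20, function(g)
    cor(m[g, ], platformMatrix(co, "CNA")[g, ], method = "spearman"))
  expect_lt(abs(rhoCna[1]), 0.1)        # independence case, single pair
  expect_lt(mean(abs(rhoCna)), 0.06)    # and in aggregate
  rhoMeth <- sapply(1:20, function(g)
    cor(m[g, ], platformMatrix(co, "METH")[g, ], method = "spearman"))
  expect_true(all(abs(rhoMeth - (-0.8)) < 0.07))
  pair <- mirnaPairing(co)
  rhoMir <- sapply(1:10, function(k)
    cor(platformMatrix(co, "miRNA")[pair$feature[k], ],
        m[pair$gene[k], ], method = "spearman"))
  expect_true(all(abs(rhoMir - (-0.4)) < 0.12))
})

test_that("methylation values stay in [0, 1] and platforms share samples", {
  co <- simulateCohort(simConfig(nSamples = 50, seed = 2))
  meth <- platformMatrix(co, "METH")
  expect_true(all(meth >= 0 & meth <= 1))
  ids <- sampleNames(co)
  for (pl in platformNames(co))
    expect_identical(colnames(platformMatrix(co, pl)), ids)
})

test_that("null effect sets give an identically-zero linear predictor", {
  co <- simulateCohort(simConfig(nSamples = 30, causal = NULL, seed = 3))
  expect_identical(unname(cohortTruth(co)$linear_predictor), rep(0, 30))
})

test_that("linear predictor equals standardized features times beta_true", {
  co <- simulateCohort(simConfig(nSamples = 120, seed = 4))
  tr <- cohortTruth(co)
  comb <- do.call(cbind, lapply(platformNames(co), function(pl)
    t(platformMatrix(co, pl))))
  key <- paste0(tr$beta_true$platform, ":", tr$beta_true$feature)
  colnames(comb) <- key
  lp <- as.numeric(scale(comb) %*% tr$beta_true$beta)
  expect_equal(unname(tr$linear_predictor), lp, tolerance = 1e-12)
})

test_that("identical configs reproduce the cohort bit-identically", {
  a <- simulateCohort(simConfig(nSamples = 40, seed = 9))
  b <- simulateCohort(simConfig(nSamples = 40, seed = 9))
  expect_identical(platformMatrix(a, "mRNA"), platformMatrix(b, "mRNA"))
  expect_identical(clinicalData(a), clinicalData(b))
  d <- simulateCohort(simConfig(nSamples = 40, seed = 10))
  expect_false(identical(clinicalData(a)$time_months,
                         clinicalData(d)$time_months))
})

test_that("omitting the microRNA platform is supported", {
  co <- simulateCohort(simConfig(nSamples = 20, nMirnas = 0,
                                 causal = NULL, seed = 5))
  expect_false("miRNA" %in% platformNames(co))
  expect_identical(nrow(mirnaPairing(co)), 0L)
})

test_that("exponential survival matches its closed-form median", {
  o <- simulateSurvival(rep(0, 2000), baselineScale = 40, censorTarget = 0,
                        seed = 6)
  expect_true(all(o$event == 1L))
  expect_equal(median(o$time), 40 * log(2), tolerance = 0.08)
})

test_that("adding log 2 to the linear predictor halves mean event time", {
  eta <- rnorm(3000, sd = 0.4)
  a <- simulateSurvival(eta, 40, 0, seed = 7)
  b <- simulateSurvival(eta + log(2), 40, 0, seed = 7)
  expect_equal(mean(b$time) / mean(a$time), 0.5, tolerance = 0.06)
})

test_that("censoring calibration lands near the target fraction", {
  for (s in 1:3) {
    o <- simulateSurvival(rnorm(500, sd = 0.8), 60, censorTarget = 0.45,
                          seed = 20 + s)
    expect_lt(abs(mean(o$event == 0) - 0.45), 0.05)
  }
  expect_error(simulateSurvival(rnorm(10), 60, censorTarget = 1, seed = 1),
               "\\[0, 1\\)")
})

test_that("a Cox fit on the true linear predictor recovers coefficient 1", {
  co <- simulateCohort(simConfig(nSamples = 1000, seed = 8))
  lp <- unname(cohortTruth(co)$linear_predictor)
  cl <- clinicalData(co)
  fit <- survival::coxph(survival::Surv(cl$time_months, cl$event) ~ lp,
                         ties = "breslow")
  expect_equal(unname(coef(fit)), 1, tolerance = 0.1)
})

test_that("cohorts round-trip through the plain-text writers", {
  co <- simulateCohort(simConfig(nSamples = 15, nGenes = 8, nMirnas = 3,
                                 causal = NULL, seed = 12))
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  back <- readCohort(dir)
  for (pl in platformNames(co))
    expect_equal(platformMatrix(back, pl), platformMatrix(co, pl),
                 tolerance = 1e-9)
  expect_equal(clinicalData(back)$time_months,
               clinicalData(co)$time_months, tolerance = 1e-9)
  expect_identical(clinicalData(back)$event, clinicalData(co)$event)
})
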