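test_that("Spearman pairing recovers copies, negations and hand values", {
  set.seed(61)
  s <- sprintf("S%02d", 1:10)
  g <- matrix(rnorm(10), 1, 10, dimnames = list("GENE1", s))
  other <- rbind(copy = g[1, ], neg = -g[1, ])
  colnames(other) <- s
  tab <- spearmanPairs(g, other,
                       pairing = data.frame(feature = c("copy", "neg"),
                                            gene = "GENE1"))
  expect_equal(tab$rho[tab$feature == "copy"], 1, tolerance = 1e-12)
  expect_equal(tab$rho[tab$feature == "neg"], -1, tolerance = 1e-12)
  # rank-then-Pearson by hand
  y <- rnorm(10)
  other2 <- matrix(y, 1, 10, dimnames = list("f", s))
  tab2 <- spearmanPairs(g, other2,
                        pairing = data.frame(feature = "f", gene = "GENE1"))
  expect_equal(tab2$rho, cor(rank(g[1, ]), rank(y)), tolerance = 1e-12)
})

test_that("unmapped features are excluded with a message", {
  s <- sprintf("S%02d", 1:8)
  g <- matrix(rnorm(8), 1, 8, dimnames = list("GENE1", s))
  other <- matrix(rnorm(16), 2, 8, dimnames = list(c("a", "orphan"), s))
  expect_message(
    tab <- spearmanPairs(g, other,
                         pairing = data.frame(feature = "a", gene = "GENE1")),
    "without an mRNA mapping")
  expect_identical(tab$feature, "a")
})

test_that("cutoff filtering keeps everything at 0 and respects signs", {
  tab <- data.frame(feature = c("a", "a", "b", "c"),
                    gene = c("g1", "g2", "g1", "g3"),
                    rho = c(0.2, -0.6, 0.4, -0.1))
  all0 <- filterFeatures(tab, 0)
  expect_true(all(all0$retained))
  # best match per feature is the max |rho|
  expect_equal(all0$rho[all0$feature == "a"], -0.6)
  f5 <- filterFeatures(tab, 0.5)
  expect_identical(f5$feature[f5$retained], "a")
  fpos <- filterFeatures(tab, 0.3, signPolicy = "positive")
  expect_identical(fpos$feature[fpos$retained], "b")
  f1 <- filterFeatures(tab, 1)
  expect_false(any(f1$retained))
})

test_that("strongly coupled causal features survive filtering", {
  hits <- 0
  for (s in 1:5) {
    co <- simulateCohort(simConfig(nSamples = 200, rhoCna = 0.9, seed = 70 + s))
    split <- trainTestSplit(sampleNames(co), 0.8, seed = s,
                            event = clinicalData(co)$event)
    ds <- suppressMessages(
      integrateOmics(co, split, integrationConfig(cutoffCna = 0.5)))
    causal <- cohortTruth(co)$beta_true
    cnaCausal <- causal$feature[causal$platform == "CNA" & causal$beta != 0]
    hits <- hits + mean(paste0("CNA:", cnaCausal) %in% colnames(ds@X))
  }
  expect_gt(hits / 5, 0.95)
})

test_that("assembly conserves counts and enforces the sample axis", {
  co <- simulateCohort(simConfig(nSamples = 40, nGenes = 10, nMirnas = 4,
                                 causal = NULL, seed = 62))
  split <- setNames(rep(c("train", "test"), c(30, 10)), sampleNames(co))
  ds <- suppressMessages(integrateOmics(co, split, integrationConfig(0, 0, 0)))
  expect_identical(ncol(ds@X), 10L + 10L + 10L + 4L)
  expect_identical(nrow(featureMeta(ds)), ncol(ds@X))
  bad <- split
  names(bad)[1] <- "NOPE"
  expect_error(assembleIntegrated(co, list(), bad), "offending ids")
})

test_that("single-platform assembly is an identity pass-through", {
  co <- simulateCohort(simConfig(nSamples = 20, nGenes = 6, nMirnas = 0,
                                 causal = NULL, seed = 63))
  co2 <- new("MultiOmicCohort",
             platforms = list(mRNA = platformMatrix(co, "mRNA")),
             clinical = clinicalData(co), pairing = mirnaPairing(co),
             truth = list())
  split <- setNames(rep(c("train", "test"), c(15, 5)), sampleNames(co2))
  ds <- assembleIntegrated(co2, list(), split)
  expect_equal(unname(ds@X), unname(t(platformMatrix(co2, "mRNA"))),
               tolerance = 1e-12)
})

test_that("retention and standardization never see test samples", {
  co <- simulateCohort(simConfig(nSamples = 100, seed = 64))
  split <- trainTestSplit(sampleNames(co), 0.8, seed = 65,
                          event = clinicalData(co)$event)
  ds1 <- suppressMessages(integrateOmics(co, split, integrationConfig()))
  # perturb every test-sample value on every platform
  testIds <- names(split)[split == "test"]
  pl2 <- co@platforms
  for (pl in names(pl2)) {
    v <- pl2[[pl]]
    v[, testIds] <- v[, sample(testIds), drop = FALSE]
    if (pl == "METH") v[, testIds] <- pmin(pmax(v[, testIds], 0), 1)
    pl2[[pl]] <- v
  }
  co2 <- new("MultiOmicCohort", platforms = pl2, clinical = clinicalData(co),
             pairing = mirnaPairing(co), truth = list())
  ds2 <- suppressMessages(integrateOmics(co2, split, integrationConfig()))
  expect_identical(colnames(ds1@X), colnames(ds2@X))
  expect_identical(ds1@center, ds2@center)
  expect_identical(ds1@scale, ds2@scale)
  expect_identical(trainMatrix(ds1), trainMatrix(ds2))
})

test_that("the retained feature set ignores feature order", {
  co <- simulateCohort(simConfig(nSamples = 60, seed = 66))
  split <- setNames(rep(c("train", "test"), c(48, 12)), sampleNames(co))
  ds1 <- suppressMessages(integrateOmics(co, split, integrationConfig()))
  set.seed(1)
  pl2 <- lapply(co@platforms, function(m) m[sample(nrow(m)), , drop = FALSE])
  co2 <- new("MultiOmicCohort", platforms = pl2, clinical = clinicalData(co),
             pairing = mirnaPairing(co), truth = list())
  ds2 <- suppressMessages(integrateOmics(co2, split, integrationConfig()))
  expect_setequal(colnames(ds1@X), colnames(ds2@X))
})
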