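#' Simulation configuration for a linked multi-omic cohort
#'
#' Defaults emulate a TCGA-scale serous ovarian carcinoma cohort: ~480
#' patients, four coupled platforms, ~44% censoring and an exponential
#' baseline whose median event time is on the order of the cohort's median
#' follow-up. Cross-platform coupling is specified as target Spearman
#' correlations between each gene's mRNA level and its matched copy-number
#' (positive), methylation (negative) and targeting microRNA (negative)
#' features.
#'
#' @param nSamples Number of patients.
#' @param nGenes Number of genes (mRNA/METH/CNA features each).
#' @param nMirnas Number of microRNAs (0 omits the platform).
#' @param causal data.frame with columns `platform`, `index`, `beta`: the
#'   sparse set of features acting on the log-hazard through the combined
#'   standardized feature space. `NULL` for a pure-noise cohort.
#' @param rhoCna,rhoMeth,rhoMirna Target Spearman correlations (signed, in
#'   \[-1, 1\]) between matched platform features and mRNA.
#' @param baselineScale Exponential baseline mean time-to-event in months
#'   (hazard `1/baselineScale` at linear predictor 0).
#' @param censorTarget Fraction of the cohort to censor, in \[0, 1).
#' @param seed Integer seed; the cohort is bit-reproducible given the
#'   full configuration.
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(nSamples = 480, nGenes = 60, nMirnas = 20,
                      causal = defaultCausalFeatures(),
                      rhoCna = 0.6, rhoMeth = -0.5, rhoMirna = -0.4,
                      baselineScale = 60, censorTarget = 0.443, seed = 1L) {
  cfg <- list(nSamples = as.integer(nSamples), nGenes = as.integer(nGenes),
              nMirnas = as.integer(nMirnas), causal = causal,
              rhoCna = rhoCna, rhoMeth = rhoMeth, rhoMirna = rhoMirna,
              baselineScale = baselineScale, censorTarget = censorTarget,
              seed = as.integer(seed))
  if (cfg$nSamples < 2) stop("nSamples must be at least 2")
  if (cfg$nGenes < 1) stop("nGenes must be at least 1")
  if (cfg$nMirnas < 0) stop("nMirnas must be nonnegative")
  for (r in c(cfg$rhoCna, cfg$rhoMeth, cfg$rhoMirna))
    if (!is.finite(r) || abs(r) > 1)
      stop("correlation targets must lie in [-1, 1]")
  if (cfg$censorTarget < 0 || cfg$censorTarget >= 1)
    stop("censorTarget must lie in [0, 1)")
  if (cfg$baselineScale <= 0) stop("baselineScale must be positive")
  if (!is.null(cfg$causal)) {
    stopifnot(all(c("platform", "index", "beta") %in% names(cfg$causal)))
    bound <- c(mRNA = cfg$nGenes, METH = cfg$nGenes, CNA = cfg$nGenes,
               miRNA = cfg$nMirnas)
    if (!all(cfg$causal$platform %in% names(bound)))
      stop("causal platforms must be among mRNA, METH, CNA, miRNA")
    if (any(cfg$causal$index < 1 |
            cfg$causal$index > bound[cfg$causal$platform]))
      stop("causal feature indices out of platform bounds")
  }
  class(cfg) <- "SimConfig"
  cfg
}

#' Default causal feature set
#'
#' Ten causal features of absolute effect 0.5 on the log-hazard (standardized
#' scale), spread across the four platforms with mixed signs.
#'
#' @return data.frame usable as the `causal` argument of [simConfig()].
#' @export
defaultCausalFeatures <- function() {
  data.frame(
    platform = c(rep("mRNA", 4), rep("METH", 3), rep("CNA", 2), "miRNA"),
    index = c(1:4, 1:3, 1:2, 1),
    beta = 0.5 * c(1, -1, 1, -1, 1, -1, 1, -1, 1, -1),
    stringsAsFactors = FALSE)
}

# Pearson correlation of the latent Gaussians that induces a target Spearman
# correlation under any monotone marginal transform (Gaussian copula).
.pearsonForSpearman <- function(rhoS) 2 * sin(pi * rhoS / 6)

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate a linked four-platform cohort with known ground truth
#'
#' mRNA levels are drawn per gene from a Gaussian with gene-specific mean and
#' spread; matched copy-number, methylation and microRNA features are
#' generated by Gaussian-copula mixing against the gene's latent mRNA score
#' so their Spearman correlations hit the signed targets. Methylation values
#' are mapped through a logistic squashing transform to (0, 1), which
#' preserves rank correlations. Event times follow a proportional-hazards
#' exponential model on the true linear predictor; censoring is uniform and
#' independent, calibrated by bisection so the expected censored fraction
#' matches `censorTarget`.
#'
#' @param config A [simConfig()] object.
#' @return A [MultiOmicCohort-class] whose `truth` slot carries `beta_true`,
#'   the per-sample true `linear_predictor`, and the generating config.
#' @export
simulateCohort <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimConfig"))
  .withSeed(config$seed, {
    n <- config$nSamples
    G <- config$nGenes
    M <- config$nMirnas
    ids <- sprintf("S%04d", seq_len(n))
    genes <- sprintf("GENE%03d", seq_len(G))

    # latent per-gene scores shared across platforms
    Z <- matrix(rnorm(n * G), n, G)

    mu <- rnorm(G, mean = 8, sd = 1.5)
    sdv <- runif(G, 0.5, 1.5)
    mrna <- sweep(sweep(Z, 2, sdv, "*"), 2, mu, "+")

    mix <- function(rhoS) {
      a <- .pearsonForSpearman(rhoS)
      a * Z + sqrt(max(0, 1 - a^2)) * matrix(rnorm(n * G), n, G)
    }
    cna <- 0.5 * mix(config$rhoCna)                      # log2-ratio-like
    methLatent <- mix(config$rhoMeth)
    meth <- plogis(sweep(methLatent, 2, rnorm(G), "+"))  # beta values

    platforms <- list(
      mRNA = t(`colnames<-`(mrna, genes)),
      METH = t(`colnames<-`(meth, genes)),
      CNA = t(`colnames<-`(cna, genes)))
    pairing <- data.frame(feature = character(0), gene = character(0))
    if (M > 0) {
      mirnas <- sprintf("miR-%03d", seq_len(M))
      target <- genes[((seq_len(M) - 1L) %% G) + 1L]
      aM <- .pearsonForSpearman(config$rhoMirna)
      mirna <- aM * Z[, match(target, genes), drop = FALSE] +
        sqrt(max(0, 1 - aM^2)) * matrix(rnorm(n * M), n, M)
      mirna <- sweep(mirna, 2, rnorm(M, mean = 6), "+")
      platforms$miRNA <- t(`colnames<-`(mirna, mirnas))
      pairing <- data.frame(feature = mirnas, gene = target,
                            stringsAsFactors = FALSE)
    }
    for (pl in names(platforms)) colnames(platforms[[pl]]) <- ids

    # combined standardized feature space and true linear predictor
    comb <- do.call(cbind, lapply(names(platforms), function(pl) {
      m <- t(platforms[[pl]])
      colnames(m) <- paste0(pl, ":", rownames(platforms[[pl]]))
      m
    }))
    Xs <- scale(comb)
    betaTrue <- setNames(numeric(ncol(comb)), colnames(comb))
    if (!is.null(config$causal) && nrow(config$causal)) {
      rn <- lapply(platforms, rownames)
      keys <- paste0(config$causal$platform, ":",
                     mapply(function(pl, i) rn[[pl]][i],
                            config$causal$platform, config$causal$index))
      betaTrue[keys] <- config$causal$beta
    }
    eta <- as.numeric(Xs %*% betaTrue)

    out <- simulateSurvival(eta, baselineScale = config$baselineScale,
                            censorTarget = config$censorTarget, seed = NULL)
    clinical <- data.frame(sample_id = ids, time_months = out$time,
                           event = out$event, stringsAsFactors = FALSE)
    truth <- list(
      beta_true = data.frame(
        platform = sub(":.*$", "", names(betaTrue)),
        feature = sub("^[^:]*:", "", names(betaTrue)),
        beta = as.numeric(betaTrue), stringsAsFactors = FALSE),
      linear_predictor = setNames(eta, ids),
      config = config)
    new("MultiOmicCohort", platforms = platforms, clinical = clinical,
        pairing = pairing, truth = truth)
  })
}

#' Simulate right-censored exponential survival under proportional hazards
#'
#' Event times are exponential with rate `exp(eta) / baselineScale`;
#' independent uniform censoring on `[0, tau]` with `tau` calibrated by
#' bisection so the expected censored fraction equals `censorTarget`. Tied
#' observed times are broken by a jitter of at most 1e-9 months.
#'
#' @param eta Per-sample linear predictor (finite).
#' @param baselineScale Baseline mean time-to-event, months.
#' @param censorTarget Target censored fraction in \[0, 1).
#' @param seed Integer seed, or `NULL` to consume the current RNG stream.
#' @return list with `time` (months, positive), `event` (integer 0/1) and
#'   `censor_horizon` (the calibrated tau, `Inf` when uncensored).
#' @export
simulateSurvival <- function(eta, baselineScale = 60, censorTarget = 0.443,
                             seed = NULL) {
  if (!all(is.finite(eta))) stop("linear predictors must be finite")
  if (censorTarget < 0 || censorTarget >= 1)
    stop("censorTarget must lie in [0, 1)")
  run <- function() {
    n <- length(eta)
    T <- rexp(n, rate = exp(eta) / baselineScale)
    if (censorTarget == 0) {
      time <- T
      event <- rep(1L, n)
      tau <- Inf
    } else {
      expectCensored <- function(tau) mean(pmin(T / tau, 1))
      lo <- min(T) * 1e-6
      hi <- max(T) * 1e6
      for (i in 1:200) {
        mid <- sqrt(lo * hi)
        if (expectCensored(mid) > censorTarget) lo <- mid else hi <- mid
      }
      tau <- sqrt(lo * hi)
      C <- runif(n, 0, tau)
      time <- pmin(T, C)
      event <- as.integer(T <= C)
    }
    dup <- duplicated(time)
    if (any(dup)) time[dup] <- time[dup] + runif(sum(dup), 0, 1e-9)
    list(time = time, event = event, censor_horizon = tau)
  }
  if (is.null(seed)) run() else .withSeed(seed, run())
}

#' Write a simulated cohort as plain-text artifacts
#'
#' One TSV per platform (features as rows, header of sample ids), a clinical
#' TSV, the microRNA-target pairing TSV and, when present, the ground-truth
#' coefficient TSV.
#'
#' @param cohort A [MultiOmicCohort-class].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "MultiOmicCohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (pl in platformNames(cohort)) {
    p <- file.path(dir, paste0(tolower(pl), ".tsv"))
    writeFeatureMatrix(platformMatrix(cohort, pl), p)
    paths <- c(paths, p)
  }
  pc <- file.path(dir, "clinical.tsv")
  writeClinical(clinicalData(cohort), pc)
  paths <- c(paths, pc)
  pp <- file.path(dir, "pairing.tsv")
  write.table(mirnaPairing(cohort), pp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, pp)
  tr <- cohortTruth(cohort)
  if (length(tr)) {
    pt <- file.path(dir, "ground_truth.tsv")
    write.table(tr$beta_true, pt, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, pt)
  }
  invisible(paths)
}
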