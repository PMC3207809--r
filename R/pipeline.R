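## End-to-end orchestration: simulate-or-load, integrate, split,
## cross-validated path fit, signature extraction, evaluation, artifacts.

.runConfigDefaults <- function() {
  list(
    # cohort source: either a simulation config or a directory of TSVs
    inputDir = NULL,
    nSamples = 480L, nGenes = 60L, nMirnas = 20L,
    causal = defaultCausalFeatures(),
    rhoCna = 0.6, rhoMeth = -0.5, rhoMirna = -0.4,
    baselineScale = 60, censorTarget = 0.443,
    # integration
    cutoffCna = 0.3, cutoffMeth = 0.3, cutoffMirna = 0.2,
    signPolicy = c(CNA = "any", METH = "any", miRNA = "any"),
    # split and model selection
    trainFraction = 0.8, stratifyEvent = FALSE,
    folds = 2L, repeats = 10L,
    lambda2 = 1e-5, nlambda = 100L, lambdaMinRatio = 0.001,
    # randomness and outputs
    seed = 1L, outDir = NULL)
}

#' Pipeline configuration
#'
#' A flat key-value configuration holding every tunable default of the
#' pipeline; unknown keys are rejected at construction so runs are
#' self-describing. See [simConfig()], [integrationConfig()],
#' [trainTestSplit()], [crossValidatePath()] for the meaning of each field.
#'
#' @param ... Named overrides of the defaults.
#' @return list of class `RunConfig` with every default materialized.
#' @export
runConfig <- function(...) {
  cfg <- .runConfigDefaults()
  dots <- list(...)
  if (length(dots) && (is.null(names(dots)) || any(names(dots) == "")))
    stop("all configuration entries must be named")
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "RunConfig"
  cfg
}

.configLines <- function(cfg) {
  flat <- lapply(cfg, function(v) {
    if (is.data.frame(v)) paste(apply(v, 1, paste, collapse = "/"),
                                collapse = ";")
    else paste(v, collapse = ",")
  })
  sprintf("# %s = %s", names(flat), unlist(flat))
}

#' Run the integrated-signature pipeline end to end
#'
#' Simulates (or loads) a multi-omic cohort, draws the train/test split,
#' integrates the platforms by Spearman filtering on training samples,
#' cross-validates the penalized Cox path, extracts the signature at the
#' selected penalty and evaluates it on the withheld test samples. Every
#' stage logs its feature counts; when `outDir` is set, the integrated
#' matrix, CV trace, signature, per-patient predictions and metrics are
#' written as TSV with the materialized configuration embedded as header
#' comments.
#'
#' @param config A [runConfig()].
#' @return list with `cohort`, `split`, `integrated`, `cv`, `signature`,
#'   `report` and the materialized `config`.
#' @export
runPipeline <- function(config = runConfig()) {
  stopifnot(inherits(config, "RunConfig"))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cohort <- stage("cohort", {
    if (!is.null(config$inputDir)) {
      message("pipeline: loading cohort from ", config$inputDir)
      readCohort(config$inputDir)
    } else {
      sc <- simConfig(nSamples = config$nSamples, nGenes = config$nGenes,
                      nMirnas = config$nMirnas, causal = config$causal,
                      rhoCna = config$rhoCna, rhoMeth = config$rhoMeth,
                      rhoMirna = config$rhoMirna,
                      baselineScale = config$baselineScale,
                      censorTarget = config$censorTarget,
                      seed = config$seed)
      message("pipeline: simulating cohort (n = ", sc$nSamples, ")")
      simulateCohort(sc)
    }
  })

  clin <- clinicalData(cohort)
  split <- stage("split",
    trainTestSplit(sampleNames(cohort), trainFraction = config$trainFraction,
                   seed = config$seed + 1L,
                   stratifyEvent = config$stratifyEvent,
                   event = clin$event))
  message("pipeline: split ", sum(split == "train"), " train / ",
          sum(split == "test"), " test")

  icfg <- integrationConfig(cutoffCna = config$cutoffCna,
                            cutoffMeth = config$cutoffMeth,
                            cutoffMirna = config$cutoffMirna,
                            signPolicy = config$signPolicy)
  integrated <- stage("integrate", integrateOmics(cohort, split, icfg))
  message("pipeline: integrated feature space has ", ncol(integrated@X),
          " features")

  trainOut <- outcomeOf(integrated, "train")
  cv <- stage("cross-validate",
    crossValidatePath(trainMatrix(integrated), trainOut$time, trainOut$event,
                      folds = config$folds, repeats = config$repeats,
                      lambda2 = config$lambda2, nlambda = config$nlambda,
                      lambdaMinRatio = config$lambdaMinRatio,
                      seed = config$seed + 2L))
  message(sprintf("pipeline: lambda* = %.4g (mean cv.CPE = %.3f)",
                  cv@lambdaOpt, max(cv@meanCPE)))

  signature <- stage("signature",
    extractSignature(cv@path, cv@lambdaOpt,
                     featureMeta = featureMeta(integrated)))
  message("pipeline: signature has ", nrow(signature@features), " features")

  testOut <- outcomeOf(integrated, "test")
  report <- stage("evaluate",
    evaluateSignature(signature,
                      trainMatrix(integrated), trainOut$time, trainOut$event,
                      testMatrix(integrated), testOut$time, testOut$event,
                      testIds = testOut$sample_id))

  if (!is.null(config$outDir))
    stage("write", .writeArtifacts(config, cohort, integrated, cv, signature,
                                   report))
  message(sprintf("pipeline: done in %.1f s",
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  list(cohort = cohort, split = split, integrated = integrated, cv = cv,
       signature = signature, report = report, config = config)
}

.writeArtifacts <- function(config, cohort, integrated, cv, signature,
                            report) {
  dir <- config$outDir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- .configLines(config)
  wTab <- function(d, file) {
    p <- file.path(dir, file)
    con <- file(p, "w")
    writeLines(hdr, con)
    write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  writeLines(hdr, file.path(dir, "config.txt"))
  writeCohort(cohort, file.path(dir, "cohort"))
  wTab(data.frame(feature = colnames(integrated@X),
                  t(integrated@X), check.names = FALSE),
       "integrated_matrix.tsv")
  ret <- attr(integrated, "retention")
  if (!is.null(ret))
    wTab(do.call(rbind, Map(cbind, platform = names(ret), ret)),
         "retention.tsv")
  wTab(cvTrace(cv), "cv_trace.tsv")
  wTab(signature@features, "signature.tsv")
  wTab(report@patients, "predictions.tsv")
  wTab(report@metrics, "metrics.tsv")
  invisible(dir)
}
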