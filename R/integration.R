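## Multi-platform integration: Spearman-correlation filtering of CNA,
## methylation and microRNA features against matched mRNA (computed on
## training samples only), then concatenation into one tagged feature space.

#' Integration configuration
#'
#' Absolute-Spearman retention cutoffs per platform pair and the per-platform
#' sign policy. The paper-scale defaults are moderate: a non-mRNA feature is
#' kept when its best-matching |rho| against mRNA reaches the cutoff.
#'
#' @param cutoffCna,cutoffMeth,cutoffMirna Cutoffs in \[0, 1\].
#' @param signPolicy Named character vector over `METH`, `CNA`, `miRNA`;
#'   each `"any"`, `"positive"` or `"negative"`. The signed mode additionally
#'   requires the expected correlation sign (CNA positive, METH/miRNA
#'   negative being the biological expectation).
#' @return list of class `IntegrationConfig`.
#' @export
integrationConfig <- function(cutoffCna = 0.3, cutoffMeth = 0.3,
                              cutoffMirna = 0.2,
                              signPolicy = c(CNA = "any", METH = "any",
                                             miRNA = "any")) {
  for (ct in c(cutoffCna, cutoffMeth, cutoffMirna))
    if (ct < 0 || ct > 1) stop("cutoffs must lie in [0, 1]")
  if (!all(signPolicy %in% c("any", "positive", "negative")))
    stop("signPolicy entries must be 'any', 'positive' or 'negative'")
  structure(list(cutoffs = c(CNA = cutoffCna, METH = cutoffMeth,
                             miRNA = cutoffMirna),
                 signPolicy = signPolicy),
            class = "IntegrationConfig")
}

#' Spearman correlations between paired features of two platforms
#'
#' Rank correlations (average ranks on ties) between each feature of a
#' platform and its mapped mRNA gene(s), computed on the given (training)
#' samples only. Features without any mapping are excluded with a logged
#' count.
#'
#' @param mrna mRNA matrix, features x samples, rownames = gene symbols.
#' @param other Other-platform matrix, features x samples (shared sample
#'   axis).
#' @param pairing data.frame with columns `feature`, `gene`; for gene-indexed
#'   platforms (CNA, METH) the identity mapping on shared rownames is the
#'   default (`NULL`).
#' @param samples Sample ids on which to compute (training samples);
#'   `NULL` uses all shared samples.
#' @return data.frame with `feature`, `gene`, `rho`, one row per mapped pair.
#' @export
spearmanPairs <- function(mrna, other, pairing = NULL, samples = NULL) {
  if (is.null(samples)) samples <- intersect(colnames(mrna), colnames(other))
  if (!all(samples %in% colnames(mrna)) || !all(samples %in% colnames(other)))
    stop("requested samples missing from a platform matrix")
  if (is.null(pairing)) {
    shared <- intersect(rownames(other), rownames(mrna))
    pairing <- data.frame(feature = shared, gene = shared,
                          stringsAsFactors = FALSE)
  }
  mapped <- pairing$feature %in% rownames(other) &
    pairing$gene %in% rownames(mrna)
  unmappedFeatures <- setdiff(rownames(other), pairing$feature[mapped])
  if (length(unmappedFeatures))
    message(length(unmappedFeatures),
            " feature(s) without an mRNA mapping excluded")
  pairing <- pairing[mapped, , drop = FALSE]
  if (nrow(pairing) == 0)
    return(data.frame(feature = character(0), gene = character(0),
                      rho = numeric(0)))
  rho <- vapply(seq_len(nrow(pairing)), function(i) {
    cor(other[pairing$feature[i], samples], mrna[pairing$gene[i], samples],
        method = "spearman")
  }, numeric(1))
  data.frame(feature = pairing$feature, gene = pairing$gene, rho = rho,
             stringsAsFactors = FALSE)
}

#' Filter features by their best-matching Spearman correlation
#'
#' A feature is retained iff the largest |rho| over its mapped genes reaches
#' the cutoff and, when a sign policy is set, that best-matching correlation
#' has the expected sign. Deterministic given the correlation table.
#'
#' @param rhoTable Output of [spearmanPairs()].
#' @param cutoff Absolute-Spearman threshold in \[0, 1\].
#' @param signPolicy `"any"`, `"positive"` or `"negative"`.
#' @return data.frame with `feature`, `gene` (best match), `rho` (best), and
#'   logical `retained`.
#' @export
filterFeatures <- function(rhoTable, cutoff, signPolicy = "any") {
  if (cutoff < 0 || cutoff > 1) stop("cutoff must lie in [0, 1]")
  if (nrow(rhoTable) == 0)
    return(cbind(rhoTable, retained = logical(0)))
  best <- do.call(rbind, lapply(split(rhoTable, rhoTable$feature), function(d) {
    d[which.max(abs(d$rho)), , drop = FALSE]
  }))
  best <- best[order(match(best$feature, unique(rhoTable$feature))), ,
               drop = FALSE]
  keep <- abs(best$rho) >= cutoff
  if (signPolicy == "positive") keep <- keep & best$rho > 0
  if (signPolicy == "negative") keep <- keep & best$rho < 0
  best$retained <- keep
  rownames(best) <- NULL
  best
}

#' Assemble the integrated feature space
#'
#' Column-binds the retained features of every platform (mRNA passes through
#' unfiltered) into one samples x features matrix with `platform:feature`
#' keys, attaches outcomes and split labels, and computes the per-feature
#' standardization transform on training samples only. Features with more
#' than 20% missing values are dropped; remaining missing entries are imputed
#' with the training-sample median.
#'
#' @param cohort A [MultiOmicCohort-class].
#' @param retained Named list of character vectors of retained feature ids
#'   per non-mRNA platform (see [filterFeatures()]); platforms absent from
#'   the list contribute nothing. mRNA is always fully included.
#' @param split Named character vector (`"train"`/`"test"`) over all cohort
#'   samples, as from [trainTestSplit()].
#' @param rhoTables Optional named list of [filterFeatures()] outputs used to
#'   annotate `featureMeta` with the best-matching correlations.
#' @return An [IntegratedDataset-class].
#' @export
assembleIntegrated <- function(cohort, retained = list(), split,
                               rhoTables = list()) {
  stopifnot(is(cohort, "MultiOmicCohort"))
  ids <- sampleNames(cohort)
  if (!setequal(names(split), ids))
    stop("split labels do not cover the cohort samples; offending ids: ",
         paste(head(c(setdiff(ids, names(split)),
                      setdiff(names(split), ids)), 5), collapse = ", "))
  split <- split[ids]
  trainIdx <- split == "train"

  blocks <- list()
  meta <- list()
  for (pl in platformNames(cohort)) {
    m <- platformMatrix(cohort, pl)
    keep <- if (pl == "mRNA") rownames(m)
            else intersect(retained[[pl]] %||% character(0), rownames(m))
    if (length(keep) == 0) next
    b <- t(m[keep, , drop = FALSE])
    colnames(b) <- paste0(pl, ":", keep)
    rt <- rhoTables[[pl]]
    rho <- if (!is.null(rt)) rt$rho[match(keep, rt$feature)]
           else rep(NA_real_, length(keep))
    gene <- if (!is.null(rt)) rt$gene[match(keep, rt$feature)]
            else if (pl == "miRNA") rep(NA_character_, length(keep))
            else keep
    blocks[[pl]] <- b
    meta[[pl]] <- data.frame(feature = keep, platform = pl, gene = gene,
                             rho = rho, stringsAsFactors = FALSE)
  }
  if (!length(blocks)) stop("no features retained on any platform")
  X <- do.call(cbind, blocks)
  fm <- do.call(rbind, meta)
  rownames(fm) <- NULL

  # missing-data policy: drop > 20% missing, train-median impute the rest
  frac <- colMeans(is.na(X))
  if (any(frac > 0.2)) {
    warning(sum(frac > 0.2), " feature(s) with >20% missing values dropped")
    fm <- fm[frac <= 0.2, , drop = FALSE]
    X <- X[, frac <= 0.2, drop = FALSE]
  }
  if (anyNA(X)) {
    med <- apply(X[trainIdx, , drop = FALSE], 2, median, na.rm = TRUE)
    for (j in which(colSums(is.na(X)) > 0))
      X[is.na(X[, j]), j] <- med[j]
  }

  ctr <- colMeans(X[trainIdx, , drop = FALSE])
  scl <- apply(X[trainIdx, , drop = FALSE], 2, sd)
  clin <- clinicalData(cohort)
  new("IntegratedDataset", X = X, featureMeta = fm, sampleIds = ids,
      time = as.numeric(clin$time_months), event = as.integer(clin$event),
      split = unname(split), center = ctr, scale = scl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Integrate a multi-omic cohort end to end
#'
#' Runs [spearmanPairs()] and [filterFeatures()] for each non-mRNA platform
#' against mRNA on the training samples only, then [assembleIntegrated()].
#' Test samples never influence retention or standardization.
#'
#' @param cohort A [MultiOmicCohort-class].
#' @param split Named `"train"`/`"test"` labels per sample.
#' @param config An [integrationConfig()].
#' @return An [IntegratedDataset-class]; the retention tables are attached as
#'   attribute `"retention"`.
#' @export
integrateOmics <- function(cohort, split, config = integrationConfig()) {
  stopifnot(is(cohort, "MultiOmicCohort"),
            inherits(config, "IntegrationConfig"))
  trainIds <- names(split)[split == "train"]
  mrna <- platformMatrix(cohort, "mRNA")
  retained <- list()
  tables <- list()
  for (pl in intersect(c("METH", "CNA", "miRNA"), platformNames(cohort))) {
    pairing <- if (pl == "miRNA") mirnaPairing(cohort) else NULL
    rt <- spearmanPairs(mrna, platformMatrix(cohort, pl), pairing = pairing,
                        samples = trainIds)
    ft <- filterFeatures(rt, cutoff = config$cutoffs[[pl]],
                         signPolicy = config$signPolicy[[pl]])
    retained[[pl]] <- ft$feature[ft$retained]
    tables[[pl]] <- ft
    message(sprintf("integration: %s retained %d / %d features (cutoff %.2f)",
                    pl, sum(ft$retained), nrow(ft), config$cutoffs[[pl]]))
  }
  ds <- assembleIntegrated(cohort, retained, split, rhoTables = tables)
  attr(ds, "retention") <- tables
  ds
}
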