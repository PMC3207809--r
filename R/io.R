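## Plain-text readers and writers: feature matrices (TSV, features as rows),
## clinical tables, microRNA pairings, signatures and reports.

#' Read a feature matrix from TSV
#'
#' Expects features as rows, the first column holding feature ids and the
#' header row holding sample ids. Ragged rows, duplicate feature ids and
#' non-numeric cells are rejected with the offending line/id named.
#'
#' @param path TSV file path.
#' @return Numeric matrix, features x samples.
#' @export
readFeatureMatrix <- function(path) {
  if (!file.size(path) > 0) stop("empty file: ", path)
  nf <- count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1)
    stop("ragged rows in ", path, " at line(s): ",
         paste(head(which(nf != nf[1]), 5), collapse = ", "))
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("no sample columns in ", path)
  ids <- as.character(d[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- d[, -1, drop = FALSE]
  nonNum <- !vapply(vals, is.numeric, logical(1))
  if (any(nonNum)) {
    for (j in which(nonNum)) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))) &
                   !is.na(vals[[j]]))
      if (length(bad))
        stop("non-numeric cell in ", path, ", column ", colnames(vals)[j],
             ", line ", bad[1] + 1L)
      vals[[j]] <- as.numeric(vals[[j]])
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' Write a feature matrix as TSV
#'
#' @param m Numeric matrix, features x samples.
#' @param path Output path.
#' @param idColumn Name of the feature-id column (default `"feature"`).
#' @return Invisibly, `path`.
#' @export
writeFeatureMatrix <- function(m, path, idColumn = "feature") {
  d <- data.frame(rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  colnames(d) <- c(idColumn, colnames(m))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a clinical table
#'
#' Requires columns `sample_id`, `time_months` (positive) and `event` (0/1);
#' optional annotation columns (`outcome_type`, `platinum_status`) are
#' carried through. When both `platinum_status` and a platinum-free interval
#' column `pfi_months` are present, the resistant/sensitive definitions are
#' checked (resistant requires a PFI below six months) and inconsistencies
#' raise a warning.
#'
#' @param path TSV file path.
#' @return Validated data.frame, row order preserved.
#' @export
readClinical <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sample_id", "time_months", "event")
  if (!all(req %in% names(d)))
    stop("clinical table must carry columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample id(s): ",
         paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "))
  if (any(!is.finite(d$time_months) | d$time_months <= 0))
    stop("nonpositive or non-finite time_months at row(s): ",
         paste(head(which(!is.finite(d$time_months) | d$time_months <= 0), 5),
               collapse = ", "))
  if (!all(d$event %in% c(0, 1)))
    stop("event must be 0/1; offending row(s): ",
         paste(head(which(!d$event %in% c(0, 1)), 5), collapse = ", "))
  d$event <- as.integer(d$event)
  if (all(c("platinum_status", "pfi_months") %in% names(d))) {
    bad <- d$platinum_status == "resistant" & d$pfi_months >= 6
    if (any(bad, na.rm = TRUE))
      warning("platinum_status 'resistant' with PFI >= 6 months at row(s): ",
              paste(head(which(bad), 5), collapse = ", "))
  }
  d
}

#' Write a clinical table as TSV
#'
#' @param clinical data.frame with at least `sample_id`, `time_months`,
#'   `event`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeClinical <- function(clinical, path) {
  write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a microRNA-to-gene pairing table
#'
#' @param path TSV with columns `feature` (microRNA id) and `gene`.
#' @return data.frame.
#' @export
readPairing <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("feature", "gene") %in% names(d)))
    stop("pairing table must carry columns feature, gene")
  d
}

#' Load a cohort from a directory of plain-text artifacts
#'
#' The inverse of [writeCohort()]: per-platform TSVs (`mrna.tsv`,
#' `meth.tsv`, `cna.tsv`, `mirna.tsv`; missing platforms are skipped),
#' `clinical.tsv` and `pairing.tsv`.
#'
#' @param dir Directory path.
#' @return A [MultiOmicCohort-class].
#' @export
readCohort <- function(dir) {
  clin <- readClinical(file.path(dir, "clinical.tsv"))
  platforms <- list()
  for (pl in PLATFORMS) {
    p <- file.path(dir, paste0(tolower(pl), ".tsv"))
    if (file.exists(p)) platforms[[pl]] <- readFeatureMatrix(p)
  }
  if (!length(platforms)) stop("no platform files found in ", dir)
  pp <- file.path(dir, "pairing.tsv")
  pairing <- if (file.exists(pp)) readPairing(pp)
             else data.frame(feature = character(0), gene = character(0))
  new("MultiOmicCohort", platforms = platforms, clinical = clin,
      pairing = pairing, truth = list())
}
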