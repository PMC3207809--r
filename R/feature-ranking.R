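## Ranking signature features by individual stratification power: a
## bottom-15% / top-15% three-way split per feature, scored by the 3-group
## log-rank statistic.

#' Three-way stratification of one feature's values
#'
#' Thresholds at the `lowQ` and `highQ` linear-interpolation quantiles of the
#' feature's distribution: `low` (bottom tail), `intermediate`, `high` (top
#' tail); ties go to the lower group.
#'
#' @param values Numeric feature values (>= 7 samples, not constant).
#' @param lowQ,highQ Tail quantiles (defaults 0.15 and 0.85).
#' @return Factor with levels `low`, `intermediate`, `high`; thresholds as
#'   attribute `"thresholds"`.
#' @export
stratifyByFeature <- function(values, lowQ = 0.15, highQ = 0.85) {
  if (length(values) < 7) stop("need at least 7 samples per tail split")
  if (lowQ <= 0 || highQ >= 1 || lowQ >= highQ)
    stop("require 0 < lowQ < highQ < 1")
  if (diff(range(values)) == 0)
    stop("degenerate feature: all values identical")
  th <- quantile(values, c(lowQ, highQ), names = FALSE, type = 7)
  lab <- factor(ifelse(values <= th[1], "low",
                       ifelse(values <= th[2], "intermediate", "high")),
                levels = c("low", "intermediate", "high"))
  attr(lab, "thresholds") <- th
  lab
}

#' Rank features by individual stratification power
#'
#' Each feature is split into low / intermediate / high groups by
#' [stratifyByFeature()] and scored with the 3-group log-rank statistic on
#' the provided cohort; features are ranked by descending chi-square (ties
#' broken by feature id). Degenerate features (constant, or with an empty
#' group) are skipped with a warning and excluded from the ranks.
#'
#' @param X Samples x features matrix (raw values).
#' @param time,event Right-censored outcome for the same samples.
#' @param features Feature columns to rank (default: all).
#' @param lowQ,highQ Tail quantiles of the split.
#' @return data.frame: `feature`, `low_threshold`, `high_threshold`, `chi2`,
#'   `df`, `p`, `rank`, ordered by rank.
#' @export
rankFeatures <- function(X, time, event, features = colnames(X),
                         lowQ = 0.15, highQ = 0.85) {
  .checkOutcome(time, event)
  missing <- setdiff(features, colnames(X))
  if (length(missing))
    stop("features not present: ", paste(missing, collapse = ", "))
  rows <- lapply(features, function(f) {
    lab <- tryCatch(stratifyByFeature(X[, f], lowQ, highQ),
                    error = function(e) NULL)
    if (is.null(lab) || nlevels(droplevels(lab)) < 2) {
      warning("feature ", f, " skipped (degenerate stratification)")
      return(NULL)
    }
    th <- attr(lab, "thresholds")
    lr <- logrankTest(time, event, droplevels(lab))
    data.frame(feature = f, low_threshold = th[1], high_threshold = th[2],
               chi2 = lr$chi2, df = lr$df, p = lr$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) stop("no rankable features")
  out <- out[order(-out$chi2, out$feature), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
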