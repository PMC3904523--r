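#' Rank-based area under the ROC curve
#'
#' Mann-Whitney formulation: the AUC equals the probability that a
#' randomly chosen positive outscores a randomly chosen negative, with
#' ties counting one half; computed from midranks.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels logical or two-level factor; `TRUE` / second level is
#'   positive.
#' @return AUC in \[0, 1\].
#' @export
aucRank <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels
         else factor(labels) == levels(factor(labels))[2L]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("AUC needs both classes present")
  r <- rank(scores)  # midranks handle ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Matthews correlation coefficient
#'
#' @param predicted,truth two-level factors or character vectors over the
#'   same label set.
#' @return MCC in \[-1, 1\]; 0 when a marginal is degenerate.
#' @export
mcc <- function(predicted, truth) {
  lev <- sort(unique(c(as.character(predicted), as.character(truth))))
  if (length(lev) > 2L) stop("MCC is defined for two classes")
  p <- factor(as.character(predicted), levels = lev)
  t <- factor(as.character(truth), levels = lev)
  tab <- base::table(p, t)
  tp <- as.numeric(tab[2L, 2L]); tn <- as.numeric(tab[1L, 1L])
  fp <- as.numeric(tab[2L, 1L]); fn <- as.numeric(tab[1L, 2L])
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Evaluation metrics over predictions
#'
#' Regression: Pearson's correlation coefficient rho and sigma, the
#' root-mean-square prediction error in kcal/mol (the error statistic
#' reported alongside rho; deliberately not the standard error of the
#' mean). Classification: accuracy, Matthews correlation coefficient, and
#' rank-based AUC. Zero-variance predictions make rho undefined and raise
#' an explicit error rather than yielding a silent NaN.
#'
#' @param predictions numeric (regression) or class labels
#'   (classification).
#' @param truth same-length ground truth.
#' @param task `"regression"` or `"classification"`.
#' @param scores numeric scores for AUC (classification; defaults to
#'   treating the predicted labels as scores is not meaningful, so
#'   required when AUC is wanted).
#' @return named list of metric values plus `n_used`.
#' @export
computeMetrics <- function(predictions, truth, task = "regression",
                           scores = NULL) {
  if (length(predictions) != length(truth))
    stop("predictions and truth differ in length")
  if (length(truth) < 2L) stop("need at least 2 observations")
  if (task == "regression") {
    if (sd(predictions) == 0)
      stop("Pearson's rho is undefined: predictions have zero variance")
    if (sd(truth) == 0)
      stop("Pearson's rho is undefined: truth has zero variance")
    list(pearson_rho = cor(predictions, truth),
         sigma = sqrt(mean((predictions - truth)^2)),
         n_used = length(truth))
  } else {
    acc <- mean(as.character(predictions) == as.character(truth))
    out <- list(accuracy = acc, mcc = mcc(predictions, truth),
                n_used = length(truth))
    if (!is.null(scores)) out$auc <- aucRank(scores, truth)
    out
  }
}

#' Post-hoc outlier removal
#'
#' Removes the `ceiling(fraction * n)` points with the largest absolute
#' residuals (ties broken by position) and returns the index set kept, so
#' that metrics can be recomputed on the remainder. Applied to residuals
#' after fitting; the model is not refitted.
#'
#' @param predictions,truth numeric vectors.
#' @param fraction fraction to remove, in \[0, 1).
#' @return list with `keep` (indices kept) and `removed` (indices
#'   removed, largest residual first).
#' @export
outlierRemoval <- function(predictions, truth, fraction = 0.10) {
  if (fraction < 0 || fraction >= 1)
    stop("fraction must be in [0, 1)")
  n <- length(truth)
  m <- ceiling(fraction * n)
  if (m == 0L) return(list(keep = seq_len(n), removed = integer(0)))
  ord <- order(-abs(predictions - truth), seq_len(n))
  removed <- ord[seq_len(m)]
  list(keep = sort(setdiff(seq_len(n), removed)), removed = removed)
}
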