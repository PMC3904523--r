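#' Construct a cross-validation protocol
#'
#' @param k number of folds; the study designs here use 5 (large
#'   stability sets), 10 (binding sets) or 20.
#' @param grouping `"mutation"` for plain record-level folds, or the
#'   low-redundancy modes `"protein"` / `"position"` in which all
#'   mutations of one structure (or one structure/chain/position) are
#'   confined to a single fold, so a protein never appears in both
#'   training and test.
#' @param seed integer seed for the fold assignment.
#' @return a [CVProtocol-class].
#' @examples
#' CVProtocol(10, "protein", seed = 7)
#' @export
CVProtocol <- function(k = 10L, grouping = "mutation", seed = 1L) {
  new("CVProtocol", k = as.integer(k), grouping = grouping,
      seed = as.integer(seed))
}

#' Assign records to cross-validation folds
#'
#' Record-level grouping shuffles records into balanced folds. Grouped
#' modes shuffle the groups, then assign each (largest first) to the
#' currently smallest fold, so no group ever spans folds.
#'
#' @param recordTable data.frame with `structureId`, `chainId`,
#'   `position`, `insert` columns (only needed for grouped modes).
#' @param protocol a [CVProtocol-class].
#' @return integer fold id per record, in 1..k.
#' @export
makeFolds <- function(recordTable, protocol) {
  n <- nrow(recordTable)
  k <- protocol@k
  if (protocol@grouping == "mutation") {
    if (n < k) stop("fewer records (", n, ") than folds (", k, ")")
    return(withr_seed(protocol@seed, sample(rep(seq_len(k),
                                               length.out = n))))
  }
  key <- if (protocol@grouping == "protein") recordTable$structureId
         else paste(recordTable$structureId, recordTable$chainId,
                    recordTable$position, recordTable$insert, sep = "\r")
  groups <- unique(key)
  if (length(groups) < k)
    stop("grouped protocol needs at least k=", k, " groups, found ",
         length(groups))
  sizes <- as.integer(base::table(key)[groups])
  ord <- withr_seed(protocol@seed, sample(seq_along(groups)))
  ord <- ord[order(-sizes[ord])]
  load <- numeric(k)
  fold <- integer(length(groups))
  for (g in ord) {
    f <- which.min(load)
    fold[g] <- f
    load[f] <- load[f] + sizes[g]
  }
  fold[match(key, groups)]
}

#' Cross-validate a predictive model over signatures
#'
#' Runs the chosen protocol: noise reduction, standardization and the
#' model are fitted on each training split and applied to the held-out
#' split; metrics are pooled over all held-out predictions (not averaged
#' per fold), matching a single truth-vs-prediction scatter. The full
#' held-out prediction table is kept in the report for audit, and the
#' fold map can be checked for grouping integrity.
#'
#' @param x numeric feature matrix, named columns.
#' @param y numeric targets (regression) or two-level labels
#'   (classification).
#' @param recordTable data.frame aligned with `x` rows carrying
#'   `structureId`, `chainId`, `position`, `insert` (used by grouped
#'   protocols and echoed into the audit table); may be `NULL` for
#'   record-level folds.
#' @param protocol a [CVProtocol-class].
#' @param spec a [modelSpec()].
#' @param outlierFraction if positive, metrics are additionally
#'   recomputed after removing that fraction of largest-residual points
#'   (regression only), reported as `pearson_rho_trimmed` /
#'   `sigma_trimmed`.
#' @return an [EvaluationReport-class].
#' @export
crossValidate <- function(x, y, recordTable = NULL,
                          protocol = CVProtocol(), spec = modelSpec(),
                          outlierFraction = 0) {
  n <- nrow(x)
  task <- if (is.numeric(y)) "regression" else "classification"
  if (is.null(recordTable))
    recordTable <- data.frame(structureId = NA_character_,
                              chainId = NA_character_,
                              position = NA_integer_, insert = "",
                              row = seq_len(n))
  if (nrow(recordTable) != n)
    stop("record table (", nrow(recordTable),
         " rows) does not align with signatures (", n, " rows)")
  fold <- makeFolds(recordTable, protocol)
  pred <- if (task == "regression") numeric(n) else character(n)
  score <- rep(NA_real_, n)
  for (f in seq_len(protocol@k)) {
    test <- which(fold == f)
    train <- which(fold != f)
    if (!length(test)) next
    if (task == "regression") {
      mod <- trainRegressor(x[train, , drop = FALSE], y[train], spec,
                            seed = protocol@seed + f)
      pred[test] <- predict(mod, x[test, , drop = FALSE])
    } else {
      mod <- trainClassifier(x[train, , drop = FALSE], y[train], spec,
                             seed = protocol@seed + f)
      pred[test] <- as.character(predict(mod, x[test, , drop = FALSE]))
      score[test] <- predict(mod, x[test, , drop = FALSE], type = "score")
    }
  }
  audit <- data.frame(id = seq_len(n),
                      structureId = recordTable$structureId,
                      fold = fold, truth = y, prediction = pred)
  if (task == "classification") audit$score <- score
  met <- if (task == "regression")
    computeMetrics(pred, y, "regression")
  else computeMetrics(pred, as.character(y), "classification",
                      scores = score)
  met$outlier_fraction_applied <- 0
  if (task == "regression" && outlierFraction > 0) {
    kept <- outlierRemoval(pred, y, outlierFraction)$keep
    trimmed <- computeMetrics(pred[kept], y[kept], "regression")
    met$pearson_rho_trimmed <- trimmed$pearson_rho
    met$sigma_trimmed <- trimmed$sigma
    met$outlier_fraction_applied <- outlierFraction
  }
  new("EvaluationReport", metrics = met, predictions = audit,
      protocol = protocol)
}

#' Write an evaluation report to disk
#'
#' Emits the metrics as JSON and human-readable text plus the held-out
#' prediction audit table (TSV: id, structure, fold, truth, prediction),
#' from which every reported metric can be recomputed.
#'
#' @param report an [EvaluationReport-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `"evaluation"`).
#' @return invisibly, the paths written.
#' @export
writeEvaluationReport <- function(report, dir, prefix = "evaluation") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonPath <- file.path(dir, paste0(prefix, "_metrics.json"))
  txtPath <- file.path(dir, paste0(prefix, "_report.txt"))
  auditPath <- file.path(dir, paste0(prefix, "_predictions.tsv"))
  jsonlite::write_json(reportMetrics(report), jsonPath, auto_unbox = TRUE,
                       digits = NA)
  m <- reportMetrics(report)
  lines <- c("Evaluation report",
             sprintf("  protocol: %d-fold, grouping=%s, seed=%d",
                     report@protocol@k, report@protocol@grouping,
                     report@protocol@seed),
             vapply(names(m), function(k)
               sprintf("  %-26s %s", k,
                       if (is.numeric(m[[k]])) format(m[[k]], digits = 6)
                       else as.character(m[[k]])), ""))
  writeLines(lines, txtPath)
  write.table(heldOutPredictions(report), auditPath, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(c(jsonPath, txtPath, auditPath))
}
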