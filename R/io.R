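#' Write and read signature tables
#'
#' Signatures are exchanged as delimited text with a mandatory header
#' row: record metadata columns (`structureId`, `chainId`, `mutation`,
#' `insert`, `ddG`) followed by the named feature columns, so that a
#' model can align features by name regardless of column order.
#'
#' @param features numeric matrix with named columns.
#' @param recordTable data.frame aligned with `features` rows (columns
#'   `structureId`, `chainId`, `wt`, `position`, `insert`, `mt`, `ddG`).
#' @param path TSV path.
#' @return `writeSignatureTable()`: invisibly, `path`.
#' @export
writeSignatureTable <- function(features, recordTable, path) {
  stopifnot(nrow(features) == nrow(recordTable))
  meta <- data.frame(structureId = recordTable$structureId,
                     chainId = recordTable$chainId,
                     mutation = paste0(recordTable$wt,
                                       recordTable$position,
                                       recordTable$mt),
                     insert = recordTable$insert,
                     ddG = recordTable$ddG, stringsAsFactors = FALSE)
  out <- cbind(meta, as.data.frame(features, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSignatureTable
#' @return `readSignatureTable()`: list with `features` (matrix) and
#'   `records` (metadata data.frame).
#' @export
readSignatureTable <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  metaCols <- c("structureId", "chainId", "mutation", "insert", "ddG")
  miss <- setdiff(metaCols, names(tab))
  if (length(miss))
    stop("signature table lacks columns: ", paste(miss, collapse = ", "))
  featCols <- setdiff(names(tab), metaCols)
  feat <- as.matrix(tab[, featCols, drop = FALSE])
  meta <- tab[, metaCols, drop = FALSE]
  meta$insert[is.na(meta$insert)] <- ""
  parsed <- lapply(meta$mutation, parseMutationCode)
  meta$wt <- vapply(parsed, `[[`, "", "wt")
  meta$position <- vapply(parsed, `[[`, 1L, "position")
  meta$mt <- vapply(parsed, `[[`, "", "mt")
  list(features = feat, records = meta)
}
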