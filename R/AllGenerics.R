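#' @name accessors
#' @title Accessors for csmpred classes
#' @description Slot accessors: `atoms()` and `structureId()` for
#'   [ProteinStructure-class]; `cutoffs()` and `scanCounts()` for
#'   [CutoffScan-class]; `features()` for [MutationSignature-class];
#'   `records()` for [MutationDataset-class]; `reportMetrics()` and
#'   `heldOutPredictions()` for [EvaluationReport-class].
#' @param x an object of the documented class.
#' @return the slot contents.
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))
#' @rdname accessors
#' @export
setGeneric("cutoffs", function(x) standardGeneric("cutoffs"))
#' @rdname accessors
#' @export
setGeneric("scanCounts", function(x) standardGeneric("scanCounts"))
#' @rdname accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))
#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("reportMetrics", function(x) standardGeneric("reportMetrics"))
#' @rdname accessors
#' @export
setGeneric("heldOutPredictions",
           function(x) standardGeneric("heldOutPredictions"))

#' @rdname accessors
#' @export
setMethod("atoms", "ProteinStructure", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("structureId", "ProteinStructure", function(x) x@structureId)
#' @rdname accessors
#' @export
setMethod("cutoffs", "CutoffScan", function(x) x@cutoffs)
#' @rdname accessors
#' @export
setMethod("scanCounts", "CutoffScan", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("features", "MutationSignature", function(x) x@features)
#' @rdname accessors
#' @export
setMethod("records", "MutationDataset", function(x) x@records)
#' @rdname accessors
#' @export
setMethod("reportMetrics", "EvaluationReport", function(x) x@metrics)
#' @rdname accessors
#' @export
setMethod("heldOutPredictions", "EvaluationReport",
          function(x) x@predictions)

setMethod("show", "ProteinStructure", function(object) {
  at <- object@atoms
  nres <- if (nrow(at)) nrow(unique(at[, c("chainId", "resNo", "insert")]))
          else 0L
  cat("ProteinStructure '", object@structureId, "': ", nrow(at),
      " heavy atoms, ", nres, " residues, chains: ",
      paste(sort(unique(at$chainId)), collapse = " "), "\n", sep = "")
  lab <- sum(!is.na(at$pharmacophore))
  cat("  pharmacophores assigned: ", lab, "/", nrow(at), "\n", sep = "")
})

setMethod("show", "SignatureParams", function(object) {
  cat("SignatureParams: r=", object@r, " A, cutoffs ", object@dMin, "..",
      object@dMax, " step ", object@dStep, " A, schemes: ",
      paste(object@schemes, collapse = "+"), "\n", sep = "")
})

setMethod("show", "CutoffScan", function(object) {
  cat("CutoffScan (", object@scheme, "): ", length(object@cutoffs),
      " cutoffs x ", ncol(object@counts), " pair classes\n", sep = "")
})

setMethod("show", "MutationSignature", function(object) {
  pv <- object@provenance
  cat("MutationSignature ", pv$structureId, " ", pv$mutation,
      " (chain ", pv$chainId, "): ", length(object@features),
      " features\n", sep = "")
})

setMethod("show", "MutationDataset", function(object) {
  cat("MutationDataset '", object@name, "' [", object@task, "]: ",
      nrow(object@records), " records, ",
      length(unique(object@records$structureId)), " structures\n", sep = "")
})

setMethod("show", "EvaluationReport", function(object) {
  m <- object@metrics
  cat("EvaluationReport (n=", m$n_used, ")\n", sep = "")
  for (k in setdiff(names(m), "n_used"))
    if (is.numeric(m[[k]]) && length(m[[k]]) == 1L)
      cat(sprintf("  %-26s %.4f\n", k, m[[k]]))
})

setMethod("show", "SignatureModel", function(object) {
  cat("SignatureModel [", object@family, ", ", object@task, "]: ",
      sum(object@mask), "/", length(object@mask),
      " features kept\n", sep = "")
})
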