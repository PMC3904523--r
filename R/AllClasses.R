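#' ProteinStructure: normalized heavy-atom model of a PDB entry
#'
#' Holds the heavy atoms of one structure (first model, one altloc conformer
#' per atom, waters removed) as a data frame, one row per atom, together
#' with the structure identifier. Hetero atoms other than water (nucleic
#' acids, ligands, ions) are retained and flagged so that environments at
#' protein-DNA interfaces include the nucleic-acid atoms.
#'
#' Columns of the atom table: `serial`, `atomName`, `element`, `resName`,
#' `resNo`, `insert` (insertion code, `""` if none), `chainId`, `x`, `y`,
#' `z` (Angstrom), `occupancy`, `hetero` (logical), `pharmacophore`
#' (character, `NA` until [assignPharmacophores()] is called).
#'
#' @slot structureId character scalar, e.g. a PDB code or file stem.
#' @slot atoms data.frame as described above.
#' @seealso [readPDB()], [atoms()], [residueKeys()]
#' @export
setClass("ProteinStructure",
  representation(structureId = "character", atoms = "data.frame"))

setValidity("ProteinStructure", function(object) {
  need <- c("serial", "atomName", "element", "resName", "resNo", "insert",
            "chainId", "x", "y", "z", "occupancy", "hetero", "pharmacophore")
  miss <- setdiff(need, names(object@atoms))
  if (length(miss))
    return(paste("atom table missing columns:", paste(miss, collapse = ", ")))
  if (length(object@structureId) != 1L)
    return("structureId must be a single string")
  xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
  if (nrow(xyz) && !all(is.finite(xyz)))
    return("atom coordinates must be finite")
  if (nrow(object@atoms) && any(!nzchar(object@atoms$element)))
    return("every atom needs a non-empty element symbol")
  TRUE
})

#' SignatureParams: parameters of the cutoff scan and environment
#'
#' @slot r environment radius in Angstrom; atoms within `r` of the mutated
#'   residue's geometric centre form the residue environment (default 10).
#' @slot dMin,dMax,dStep cutoff grid in Angstrom: cutoffs run from `dMin`
#'   to `dMax` inclusive in steps of `dStep` (defaults 0, 10, 0.5 giving 21
#'   cutoffs).
#' @slot schemes character subset of `c("one", "binary", "pharmacophore")`:
#'   which atom classifications segment the cumulative distribution
#'   (default all three, concatenated).
#' @slot centreMode `"all"` (geometric centre over all heavy atoms of the
#'   residue) or `"sidechain"` (side-chain atoms only, falling back to all
#'   atoms for glycine).
#' @slot includeSelfPairs logical; count atom pairs within the mutated
#'   residue itself (default TRUE).
#' @seealso [SignatureParams()]
#' @export
setClass("SignatureParams",
  representation(r = "numeric", dMin = "numeric", dMax = "numeric",
                 dStep = "numeric", schemes = "character",
                 centreMode = "character", includeSelfPairs = "logical"))

setValidity("SignatureParams", function(object) {
  if (object@r <= 0) return("r must be positive")
  if (object@dStep <= 0) return("dStep must be positive")
  if (!(object@dMin >= 0 && object@dMin < object@dMax))
    return("need 0 <= dMin < dMax")
  bad <- setdiff(object@schemes, c("one", "binary", "pharmacophore"))
  if (length(bad))
    return(paste("unknown scheme:", paste(bad, collapse = ", ")))
  if (!length(object@schemes)) return("at least one scheme required")
  if (!object@centreMode %in% c("all", "sidechain"))
    return("centreMode must be 'all' or 'sidechain'")
  TRUE
})

#' ResidueEnvironment: atoms around a mutation site
#'
#' The set of labelled heavy atoms (any chain, protein or retained hetero)
#' within radius `r` of the geometric centre of the wild-type residue at
#' the mutation site, the mutated residue's own atoms included.
#'
#' @slot centre numeric 3-vector, the geometric centre (Angstrom).
#' @slot atoms data.frame of member atoms (same columns as the structure's
#'   atom table).
#' @slot source list: `structureId`, `chainId`, `resNo`, `insert`, `r`.
#' @seealso [extractResidueEnvironment()]
#' @export
setClass("ResidueEnvironment",
  representation(centre = "numeric", atoms = "data.frame", source = "list"))

setValidity("ResidueEnvironment", function(object) {
  if (length(object@centre) != 3L) return("centre must be a 3-vector")
  r <- object@source$r
  if (!is.null(r) && nrow(object@atoms)) {
    d <- sqrt((object@atoms$x - object@centre[1L])^2 +
              (object@atoms$y - object@centre[2L])^2 +
              (object@atoms$z - object@centre[3L])^2)
    if (any(d > r + 1e-9))
      return("environment contains atoms beyond radius r")
  }
  TRUE
})

#' CutoffScan: class-segmented cumulative distance distribution
#'
#' Matrix of cumulative unordered atom-pair counts: rows are distance
#' cutoffs (ascending), columns are atom-class pairs under one
#' classification scheme. Entry `[k, c]` counts pairs at distance <=
#' cutoff k whose unordered class pair is c. Columns are non-decreasing
#' down the grid.
#'
#' @slot cutoffs numeric, ascending cutoff grid (Angstrom).
#' @slot counts integer matrix, `length(cutoffs)` x number of pair classes.
#' @slot scheme one of `"one"`, `"binary"`, `"pharmacophore"`.
#' @seealso [cutoffScan()]
#' @export
setClass("CutoffScan",
  representation(cutoffs = "numeric", counts = "matrix", scheme = "character"))

setValidity("CutoffScan", function(object) {
  if (is.unsorted(object@cutoffs, strictly = TRUE))
    return("cutoffs must be strictly ascending")
  if (nrow(object@counts) != length(object@cutoffs))
    return("counts rows must match cutoff grid")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (nrow(object@counts) > 1L &&
      any(apply(object@counts, 2L, function(co) any(diff(co) < 0))))
    return("cumulative counts must be non-decreasing in cutoff")
  TRUE
})

#' MutationSignature: the feature vector for one mutation
#'
#' Flat named numeric vector: per-scheme cutoff-scan counts flattened in
#' scheme -> pair-class -> cutoff order, then the 8 pharmacophore-change
#' entries (mutant minus wild-type residue atom-class counts), then pH,
#' temperature (degrees C) and relative solvent accessibility.
#'
#' @slot features named numeric vector.
#' @slot provenance list: `structureId`, `mutation`, `chainId`, `params`
#'   (the [SignatureParams-class] used), `imputed` (character vector naming
#'   conditions that were defaulted).
#' @seealso [computeSignature()], [assembleSignature()]
#' @export
setClass("MutationSignature",
  representation(features = "numeric", provenance = "list"))

setValidity("MutationSignature", function(object) {
  nm <- names(object@features)
  if (is.null(nm) || anyDuplicated(nm))
    return("features must have unique names")
  TRUE
})

#' MutationDataset: a table of experimental mutation records
#'
#' One row per experimental measurement. Columns: `structureId`, `chainId`,
#' `wt`, `position`, `insert`, `mt` (1-letter codes and author numbering),
#' `ddG` (kcal/mol, NA if derived from affinities), `kdWT`, `kdMT` (molar,
#' NA for stability data), `pH`, `temperature` (Kelvin), `source`.
#'
#' @slot records data.frame as above.
#' @slot name dataset label.
#' @slot task `"stability"`, `"protein-protein"` or `"protein-DNA"`.
#' @seealso [loadMutationTable()], [filterSinglePoint()]
#' @export
setClass("MutationDataset",
  representation(records = "data.frame", name = "character",
                 task = "character"))

setValidity("MutationDataset", function(object) {
  need <- c("structureId", "chainId", "wt", "position", "insert", "mt",
            "ddG", "kdWT", "kdMT", "pH", "temperature", "source")
  miss <- setdiff(need, names(object@records))
  if (length(miss))
    return(paste("records missing columns:", paste(miss, collapse = ", ")))
  if (!object@task %in% c("stability", "protein-protein", "protein-DNA"))
    return("task must be stability, protein-protein or protein-DNA")
  TRUE
})

#' CVProtocol: a cross-validation protocol
#'
#' @slot k number of folds (the study designs use 5, 10 or 20).
#' @slot grouping `"mutation"` (plain record-level folds), `"protein"` (all
#'   mutations of one structure confined to one fold) or `"position"` (all
#'   mutations at one structure/chain/position confined to one fold); the
#'   grouped modes are the low-redundancy protocols.
#' @slot seed integer seed for the fold assignment.
#' @export
setClass("CVProtocol",
  representation(k = "integer", grouping = "character", seed = "integer"))

setValidity("CVProtocol", function(object) {
  if (object@k < 2L) return("k must be >= 2")
  if (!object@grouping %in% c("mutation", "protein", "position"))
    return("grouping must be mutation, protein or position")
  TRUE
})

#' EvaluationReport: metrics over held-out predictions
#'
#' Metrics are pooled over all held-out predictions, not averaged per fold,
#' so the report corresponds to the single scatter of truth against
#' prediction. `sigma` is the root-mean-square held-out prediction error in
#' kcal/mol (the regression error statistic reported alongside Pearson's
#' rho; not the standard error of the mean).
#'
#' @slot metrics named list: `pearson_rho`, `sigma`, and for
#'   classification `accuracy`, `mcc`, `auc`; plus `n_used` and
#'   `outlier_fraction_applied`.
#' @slot predictions data.frame audit table: `id`, `fold`, `truth`,
#'   `prediction` (and `label`, `score` for classification).
#' @slot protocol the [CVProtocol-class] used (may be a placeholder for
#'   non-CV reports).
#' @export
setClass("EvaluationReport",
  representation(metrics = "list", predictions = "data.frame",
                 protocol = "CVProtocol"))

#' SignatureModel: a trained predictive model over signatures
#'
#' Wraps a fitted Gaussian-process (or alternative) model together with
#' everything needed to apply it to new signatures laid out by name: the
#' kept-feature mask from noise reduction, the feature scaling, and the
#' task type.
#'
#' @slot fit the underlying fitted model object.
#' @slot family model family label, e.g. `"gp"`.
#' @slot task `"regression"` or `"classification"`.
#' @slot featureNames character, the full input feature layout at training.
#' @slot mask logical, kept-feature mask (parallel to `featureNames`).
#' @slot center,scale numeric, per-kept-feature standardization applied
#'   before the kernel.
#' @slot levels class labels (classification only).
#' @slot seed integer seed used for training.
#' @export
setClass("SignatureModel",
  representation(fit = "ANY", family = "character", task = "character",
                 featureNames = "character", mask = "logical",
                 center = "numeric", scale = "numeric",
                 levels = "character", seed = "integer"))
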