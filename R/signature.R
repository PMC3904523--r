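#' Construct signature parameters
#'
#' @param r environment radius in Angstrom. The default 10 reflects the
#'   design emphasis on long-range distance patterns: the residue
#'   environment reaches up to 10 Angstrom from the residue centre.
#' @param dMin,dMax,dStep cutoff grid (Angstrom); defaults 0 to 10 in 0.5
#'   steps, i.e. 21 cutoffs.
#' @param schemes atom classification schemes segmenting the cumulative
#'   distribution: `"one"` (no distinction, 1 pair class), `"binary"`
#'   (polar/hydrophobic, 3 unordered pair classes) and `"pharmacophore"`
#'   (8 classes, 36 unordered pair classes). All three are concatenated by
#'   default.
#' @param centreMode `"all"` or `"sidechain"` (see
#'   [SignatureParams-class]).
#' @param includeSelfPairs count atom pairs within the mutated residue
#'   itself (default TRUE).
#' @return a [SignatureParams-class].
#' @examples
#' SignatureParams()
#' @export
SignatureParams <- function(r = 10, dMin = 0, dMax = 10, dStep = 0.5,
                            schemes = c("one", "binary", "pharmacophore"),
                            centreMode = "all", includeSelfPairs = TRUE) {
  new("SignatureParams", r = as.numeric(r), dMin = as.numeric(dMin),
      dMax = as.numeric(dMax), dStep = as.numeric(dStep),
      schemes = schemes, centreMode = centreMode,
      includeSelfPairs = includeSelfPairs)
}

#' @rdname SignatureParams
#' @param params a [SignatureParams-class].
#' @return `cutoffGrid()`: the ascending numeric cutoff grid.
#' @export
cutoffGrid <- function(params) {
  seq(params@dMin, params@dMax, by = params@dStep)
}

#' Geometric centre of a set of atoms
#'
#' Unweighted mean of heavy-atom coordinates.
#'
#' @param atomTable data.frame with `x`, `y`, `z` columns (or a numeric
#'   n x 3 matrix).
#' @return numeric 3-vector.
#' @examples
#' geometricCentre(cbind(x = c(0, 2), y = 0, z = 0))
#' @export
geometricCentre <- function(atomTable) {
  xyz <- if (is.matrix(atomTable)) atomTable
         else as.matrix(atomTable[, c("x", "y", "z")])
  if (!nrow(xyz)) stop("cannot take the centre of zero atoms")
  colMeans(xyz)
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# mutation-site centre per the centreMode policy
siteCentre <- function(resAtoms, centreMode = "all") {
  if (centreMode == "sidechain") {
    side <- resAtoms[!resAtoms$atomName %in% BACKBONE_ATOMS, , drop = FALSE]
    if (nrow(side)) resAtoms <- side  # glycine falls back to all atoms
  }
  geometricCentre(resAtoms)
}

#' Extract the residue environment around a mutation site
#'
#' Selects all heavy atoms of the structure (any chain, protein or
#' retained hetero) whose distance to the geometric centre of the given
#' residue is at most `r` (boundary inclusive). The residue's own atoms
#' always qualify.
#'
#' @param structure a labelled [ProteinStructure-class] (see
#'   [assignPharmacophores()]).
#' @param chainId,resNo,insert residue key.
#' @param r radius in Angstrom.
#' @param centreMode `"all"` or `"sidechain"`.
#' @return a [ResidueEnvironment-class].
#' @export
extractResidueEnvironment <- function(structure, chainId, resNo,
                                      insert = "", r = 10,
                                      centreMode = "all") {
  res <- residueAtoms(structure, chainId, resNo, insert)
  centre <- siteCentre(res, centreMode)
  df <- atoms(structure)
  d2 <- (df$x - centre[1L])^2 + (df$y - centre[2L])^2 +
        (df$z - centre[3L])^2
  env <- df[d2 <= r^2, , drop = FALSE]
  rownames(env) <- NULL
  new("ResidueEnvironment", centre = unname(centre), atoms = env,
      source = list(structureId = structureId(structure),
                    chainId = chainId, resNo = resNo, insert = insert,
                    r = r))
}

#' Pairwise Euclidean distance matrix of an environment
#'
#' @param env a [ResidueEnvironment-class] or a data.frame/matrix of
#'   coordinates.
#' @return symmetric matrix of distances in Angstrom with zero diagonal.
#' @export
pairwiseDistances <- function(env) {
  xyz <- if (is(env, "ResidueEnvironment"))
    as.matrix(env@atoms[, c("x", "y", "z")])
  else if (is.matrix(env)) env
  else as.matrix(env[, c("x", "y", "z")])
  as.matrix(stats::dist(xyz))
}

# polar/hydrophobic dichotomy over the 8 classes: charge and hydrogen
# bonding capability on one side, apolar carbon/sulphur/aromatic on the
# other
BINARY_MAP <- c(hydrophobic = "hydrophobic", aromatic = "hydrophobic",
                neutral = "hydrophobic", sulphur = "hydrophobic",
                positive = "polar", negative = "polar",
                donor = "polar", acceptor = "polar")

#' Atom-class pair labels of a scheme
#'
#' @param scheme `"one"`, `"binary"` or `"pharmacophore"`.
#' @return character vector of unordered pair labels (1, 3 or 36).
#' @examples
#' pairClassLabels("binary")
#' @export
pairClassLabels <- function(scheme) {
  cls <- switch(scheme,
    one = "all",
    binary = c("hydrophobic", "polar"),
    pharmacophore = pharmacophoreClasses(),
    stop("unknown scheme: ", scheme))
  if (scheme == "one") return("all:all")
  n <- length(cls)
  out <- character(0)
  for (i in seq_len(n))
    for (j in i:n)
      out <- c(out, paste(cls[i], cls[j], sep = ":"))
  out
}

# per-atom labels under a scheme, from 8-class pharmacophore labels
schemeAtomClasses <- function(pharm, scheme) {
  switch(scheme,
    one = rep("all", length(pharm)),
    binary = unname(BINARY_MAP[pharm]),
    pharmacophore = pharm,
    stop("unknown scheme: ", scheme))
}

# canonical unordered pair label for two class labels under a scheme
unorderedPairLabel <- function(a, b, scheme) {
  lev <- switch(scheme, one = "all",
                binary = c("hydrophobic", "polar"),
                pharmacophore = pharmacophoreClasses())
  ia <- match(a, lev); ib <- match(b, lev)
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  paste(lev[lo], lev[hi], sep = ":")
}

#' Cutoff scan: cumulative pair counts by atom-class pair
#'
#' Sweeps the edge-defining cutoff distance over the grid and counts, at
#' each cutoff and for each unordered atom-class pair, the unordered atom
#' pairs (i < j) at distance less than or equal to the cutoff. This is the
#' cumulative distance distribution of the environment's contact graph,
#' segmented by atomic category.
#'
#' @param dmatrix symmetric pairwise distance matrix.
#' @param classes per-atom 8-class pharmacophore labels, parallel to the
#'   matrix rows; the `"binary"` and `"one"` schemes derive their labels
#'   from these.
#' @param params a [SignatureParams-class] (supplies the cutoff grid).
#' @param scheme `"one"`, `"binary"` or `"pharmacophore"`.
#' @return a [CutoffScan-class].
#' @examples
#' xyz <- cbind(x = c(0, 3), y = 0, z = 0)
#' d <- pairwiseDistances(xyz)
#' cutoffScan(d, c("hydrophobic", "donor"), SignatureParams(), "one")
#' @export
cutoffScan <- function(dmatrix, classes, params = SignatureParams(),
                       scheme = "pharmacophore") {
  n <- nrow(dmatrix)
  if (length(classes) != n)
    stop("class labels (", length(classes),
         ") do not match distance matrix dimension (", n, ")")
  grid <- cutoffGrid(params)
  labels <- pairClassLabels(scheme)
  K <- length(grid)
  if (n < 2L) {
    counts <- matrix(0L, K, length(labels),
                     dimnames = list(NULL, labels))
    return(new("CutoffScan", cutoffs = grid, counts = counts,
               scheme = scheme))
  }
  atomCls <- schemeAtomClasses(classes, scheme)
  ut <- upper.tri(dmatrix)
  d <- dmatrix[ut]
  ij <- which(ut, arr.ind = TRUE)
  pairLab <- unorderedPairLabel(atomCls[ij[, 1L]], atomCls[ij[, 2L]],
                                scheme)
  # first grid index whose cutoff is >= d (ties inclusive: d <= cutoff)
  k0 <- findInterval(d, grid, left.open = TRUE) + 1L
  keep <- k0 <= K
  inc <- base::table(factor(k0[keep], levels = seq_len(K)),
                     factor(pairLab[keep], levels = labels))
  counts <- apply(unclass(inc), 2L, cumsum)
  if (K == 1L) counts <- matrix(counts, nrow = 1L,
                                dimnames = list(NULL, labels))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(NULL, labels)
  new("CutoffScan", cutoffs = grid, counts = counts, scheme = scheme)
}

#' Assemble the final signature vector
#'
#' Concatenates the cutoff scans (flattened scheme -> pair-class ->
#' cutoff), the 8-entry pharmacophore-change vector, and the experimental
#' conditions pH, temperature (degrees C) and RSA. Missing pH or
#' temperature are imputed with pH 7.0 / 25 degrees C and flagged in the
#' provenance.
#'
#' @param scans list of [CutoffScan-class] sharing one cutoff grid.
#' @param pChange named 8-vector from [pharmacophoreChange()].
#' @param pH,temperature experimental conditions (`NA` to impute).
#' @param rsa relative solvent accessibility fraction.
#' @param provenance list carried into the signature (structureId,
#'   mutation, chainId, params).
#' @return a [MutationSignature-class].
#' @export
assembleSignature <- function(scans, pChange, pH = NA, temperature = NA,
                              rsa, provenance = list()) {
  if (!length(scans)) stop("at least one cutoff scan required")
  grid <- cutoffs(scans[[1L]])
  for (s in scans)
    if (!isTRUE(all.equal(cutoffs(s), grid)))
      stop("cutoff scans use inconsistent cutoff grids")
  blocks <- lapply(scans, function(s) {
    co <- scanCounts(s)
    v <- as.vector(co)  # column-major: pair-class blocks of cutoffs
    names(v) <- paste0(s@scheme, ":",
                       rep(colnames(co), each = nrow(co)), ":",
                       format(rep(grid, ncol(co)), trim = TRUE))
    v
  })
  if (length(pChange) != 8L)
    stop("pharmacophore-change vector must have 8 entries")
  pc <- setNames(as.numeric(pChange),
                 paste0("pchange:", pharmacophoreClasses()))
  imputed <- character(0)
  if (is.na(pH)) { pH <- 7.0; imputed <- c(imputed, "pH") }
  if (is.na(temperature)) { temperature <- 25.0
                            imputed <- c(imputed, "temperature") }
  feat <- c(do.call(c, unname(blocks)), pc,
            pH = as.numeric(pH), temperature = as.numeric(temperature),
            rsa = as.numeric(rsa))
  provenance$imputed <- imputed
  new("MutationSignature", features = feat, provenance = provenance)
}

#' Compute the full signature for one mutation
#'
#' Orchestrates the whole calculation on the wild-type structure:
#' geometric centre of the mutated residue, residue-environment
#' extraction, pairwise distance matrix, one cutoff scan per enabled
#' classification scheme, pharmacophore-change vector, RSA, and assembly.
#' The wild-type residue stated in the mutation code is validated against
#' the structure; no mutant model is built.
#'
#' @param structure a [ProteinStructure-class]; pharmacophores are
#'   assigned on the fly if absent.
#' @param mutation mutation code like `"R282W"` (wild type, author
#'   position, mutant).
#' @param chainId chain of the mutation site.
#' @param insert insertion code, `""` if none.
#' @param params a [SignatureParams-class].
#' @param table pharmacophore table.
#' @param pH,temperature experimental conditions (temperature in degrees
#'   C; `NA` imputes the documented defaults).
#' @param asa optional precomputed per-atom ASA (see [shrakeRupley()]).
#' @return a [MutationSignature-class].
#' @examples
#' pdbtxt <- generateStructure(fixtureSpec("ideal-helix", nResidues = 8))
#' tf <- tempfile(fileext = ".pdb"); writeLines(pdbtxt, tf)
#' s <- assignPharmacophores(readPDB(tf))
#' sig <- computeSignature(s, "A4G", chainId = "A")
#' length(features(sig))
#' @export
computeSignature <- function(structure, mutation, chainId,
                             insert = "", params = SignatureParams(),
                             table = pharmacophoreTable(),
                             pH = NA, temperature = NA, asa = NULL) {
  mut <- parseMutationCode(mutation)
  df <- atoms(structure)
  if (all(is.na(df$pharmacophore)))
    structure <- assignPharmacophores(structure, table)
  res <- residueAtoms(structure, chainId, mut$position, insert)
  found <- res$resName[1L]
  expected <- aaThreeLetter(mut$wt)
  if (found != expected)
    stop("wild-type mismatch at ", chainId, ":", mut$position, insert,
         ": mutation states ", expected, " but structure has ", found)
  env <- extractResidueEnvironment(structure, chainId, mut$position,
                                   insert, r = params@r,
                                   centreMode = params@centreMode)
  envAtoms <- env@atoms
  dmat <- pairwiseDistances(env)
  if (!params@includeSelfPairs) {
    ownIdx <- which(envAtoms$chainId == chainId &
                    envAtoms$resNo == mut$position &
                    envAtoms$insert == insert)
    if (length(ownIdx) > 1L)
      dmat[ownIdx, ownIdx] <- Inf  # self-residue pairs fall beyond any cutoff
    diag(dmat) <- 0
  }
  scans <- lapply(params@schemes, function(sc)
    cutoffScan(dmat, envAtoms$pharmacophore, params, sc))
  pc <- pharmacophoreChange(mut$wt, mut$mt, table)
  rsa <- computeRSA(structure, chainId, mut$position, insert, asa = asa)
  assembleSignature(scans, pc, pH = pH, temperature = temperature,
                    rsa = rsa,
                    provenance = list(structureId = structureId(structure),
                                      mutation = mutation,
                                      chainId = chainId, insert = insert,
                                      params = params))
}

#' Compute signatures for every record of a dataset
#'
#' Batch application of [computeSignature()]. Per-record failures
#' (unresolvable structure, wild-type mismatch, non-standard residue) are
#' logged and skipped so one bad row does not abort a run; per-atom ASA is
#' computed once per structure and reused.
#'
#' @param structures named list of labelled [ProteinStructure-class]
#'   objects, keyed by `structureId`.
#' @param dataset a [MutationDataset-class].
#' @param params a [SignatureParams-class].
#' @param table pharmacophore table.
#' @return list with `features` (numeric matrix, one row per successful
#'   record, named columns), `records` (the successful records), and
#'   `failures` (data.frame of row index and reason).
#' @export
batchSignatures <- function(structures, dataset,
                            params = SignatureParams(),
                            table = pharmacophoreTable()) {
  recs <- records(dataset)
  asaCache <- list()
  rows <- list(); kept <- integer(0)
  failures <- data.frame(row = integer(0), reason = character(0))
  for (i in seq_len(nrow(recs))) {
    r <- recs[i, ]
    out <- tryCatch({
      st <- structures[[r$structureId]]
      if (is.null(st)) stop("structure not available: ", r$structureId)
      if (is.null(asaCache[[r$structureId]]))
        asaCache[[r$structureId]] <- shrakeRupley(st)
      code <- paste0(r$wt, r$position, r$mt)
      tempC <- if (is.na(r$temperature)) NA else r$temperature - 273.15
      computeSignature(st, code, chainId = r$chainId, insert = r$insert,
                       params = params, table = table, pH = r$pH,
                       temperature = tempC,
                       asa = asaCache[[r$structureId]])
    }, error = function(e) e)
    if (inherits(out, "error")) {
      failures <- rbind(failures,
                        data.frame(row = i, reason = conditionMessage(out)))
    } else {
      rows[[length(rows) + 1L]] <- features(out)
      kept <- c(kept, i)
    }
  }
  if (!length(rows))
    stop("no usable records: all ", nrow(recs), " rows failed")
  feat <- do.call(rbind, rows)
  rownames(feat) <- NULL
  list(features = feat, records = recs[kept, , drop = FALSE],
       failures = failures)
}
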