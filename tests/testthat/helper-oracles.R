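# Hand-crafted PDB fixtures and independent brute-force oracles used
# across the test files. The oracles deliberately re-derive every result
# with naive loops, not via the package's vectorized code paths.

glyPdbLines <- function() c(
  "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00  0.00           C",
  "ATOM      4  O   GLY A   1       1.251   2.390   0.000  1.00  0.00           O",
  "END")

altlocPdbLines <- function() c(
  "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA AGLY A   1       1.458   0.000   0.000  0.60  0.00           C",
  "ATOM      3  CA BGLY A   1       1.500   0.100   0.000  0.40  0.00           C",
  "ATOM      4  C   GLY A   1       2.009   1.420   0.000  1.00  0.00           C",
  "ATOM      5  O   GLY A   1       1.251   2.390   0.000  1.00  0.00           O",
  "END")

waterPdbLines <- function() c(
  glyPdbLines()[1:4],
  "HETATM    5  O   HOH A 101       8.000   8.000   8.000  1.00  0.00           O",
  "HETATM    6  O   HOH A 102       9.000   9.000   9.000  1.00  0.00           O",
  "END")

writeTempPdb <- function(lines) {
  tf <- tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  tf
}

structureFromFixture <- function(spec, id = "fix") {
  tf <- writeTempPdb(generateStructure(spec))
  on.exit(unlink(tf))
  assignPharmacophores(readPDB(tf, structureId = id))
}

labelledHelix <- local({
  cache <- list()
  function(n = 15L) {
    key <- as.character(n)
    if (is.null(cache[[key]]))
      cache[[key]] <<- structureFromFixture(
        fixtureSpec("ideal-helix", nResidues = n), id = "fixhelix")
    cache[[key]]
  }
})

# brute-force cumulative cutoff scan: explicit loop over pairs and cutoffs
bfCutoffScan <- function(xyz, classes8, grid, scheme) {
  lev <- switch(scheme, one = "all",
                binary = c("hydrophobic", "polar"),
                pharmacophore = pharmacophoreClasses())
  toScheme <- function(cl) switch(scheme,
    one = "all",
    binary = if (cl %in% c("positive", "negative", "donor", "acceptor"))
      "polar" else "hydrophobic",
    pharmacophore = cl)
  labels <- character(0)
  for (i in seq_along(lev)) for (j in i:length(lev))
    labels <- c(labels, paste(lev[i], lev[j], sep = ":"))
  n <- nrow(xyz)
  counts <- matrix(0L, length(grid), length(labels),
                   dimnames = list(NULL, labels))
  if (n < 2L) return(counts)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    a <- toScheme(classes8[i]); b <- toScheme(classes8[j])
    ia <- match(a, lev); ib <- match(b, lev)
    lab <- paste(lev[min(ia, ib)], lev[max(ia, ib)], sep = ":")
    for (k in seq_along(grid))
      if (d <= grid[k]) counts[k, lab] <- counts[k, lab] + 1L
  }
  counts
}

# independent end-to-end signature: own environment selection, own pair
# loops, own residue tallies; shares only the numeric ASA mesh (the
# package's shrakeRupley) for the rsa slot
bfSignature <- function(structure, mutation, chainId, params, asa = NULL) {
  mut <- parseMutationCode(mutation)
  at <- atoms(structure)
  own <- at$chainId == chainId & at$resNo == mut$position & at$insert == ""
  stopifnot(any(own))
  centre <- c(mean(at$x[own]), mean(at$y[own]), mean(at$z[own]))
  d2 <- (at$x - centre[1])^2 + (at$y - centre[2])^2 + (at$z - centre[3])^2
  env <- at[d2 <= params@r^2, , drop = FALSE]
  xyz <- as.matrix(env[, c("x", "y", "z")])
  grid <- seq(params@dMin, params@dMax, by = params@dStep)
  blocks <- c()
  for (sc in params@schemes) {
    counts <- bfCutoffScan(xyz, env$pharmacophore, grid, sc)
    for (colLab in colnames(counts))
      blocks <- c(blocks, setNames(
        as.numeric(counts[, colLab]),
        paste0(sc, ":", colLab, ":", format(grid, trim = TRUE))))
  }
  tab <- pharmacophoreTable()
  tally <- function(res3) {
    v <- setNames(numeric(8), pharmacophoreClasses())
    rows <- tab[tab$resName == res3 & tab$atomName != "OXT", ]
    for (cl in rows$class) v[cl] <- v[cl] + 1
    v
  }
  pc <- tally(aaThreeLetter(mut$mt)) - tally(aaThreeLetter(mut$wt))
  names(pc) <- paste0("pchange:", pharmacophoreClasses())
  if (is.null(asa)) asa <- shrakeRupley(structure)
  rsa <- min(1, sum(asa[own]) /
               maxAccessibility()[at$resName[own][1]])
  c(blocks, pc, pH = 7.0, temperature = 25.0, rsa = unname(rsa))
}

# all-pairs concordance AUC oracle
bfAUC <- function(scores, positive) {
  pos <- which(positive); neg <- which(!positive)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

randomRotation <- function() {
  m <- matrix(rnorm(9), 3)
  qr.Q(qr(m)) * sample(c(-1, 1), 1)
}

rotateStructure <- function(structure, R, shift = c(0, 0, 0)) {
  at <- atoms(structure)
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% R
  at$x <- xyz[, 1] + shift[1]
  at$y <- xyz[, 2] + shift[2]
  at$z <- xyz[, 3] + shift[3]
  methods::initialize(structure, atoms = at)
}
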