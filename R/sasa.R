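# van der Waals radii (Angstrom) by element, Bondi-style set as used by
# common accessibility programs; unlisted elements fall back to carbon
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
               ZN = 1.39, MG = 1.73, CA = 2.00, FE = 1.40, MN = 1.40,
               NA. = 2.27, K = 2.75)

vdwRadius <- function(element) {
  el <- toupper(element)
  el[el == "NA"] <- "NA."
  r <- unname(VDW_RADII[el])
  r[is.na(r)] <- 1.70
  r
}

# deterministic quasi-uniform points on the unit sphere (golden spiral)
spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom accessible surface area (rolling-probe method)
#'
#' Shrake-Rupley numerical accessible surface area: each atom is covered
#' with a deterministic quasi-uniform point mesh on its solvent-expanded
#' sphere (van der Waals radius + probe radius) and the accessible fraction
#' is the share of mesh points outside every neighbouring atom's expanded
#' sphere.
#'
#' @param structure a [ProteinStructure-class].
#' @param probe probe radius in Angstrom (default 1.4, a water molecule).
#' @param nPoints mesh points per atom (default 960).
#' @return numeric vector of per-atom ASA in square Angstrom, parallel to
#'   `atoms(structure)`.
#' @seealso [computeRSA()]
#' @export
shrakeRupley <- function(structure, probe = 1.4, nPoints = 960L) {
  df <- atoms(structure)
  n <- nrow(df)
  xyz <- as.matrix(df[, c("x", "y", "z")])
  rad <- vdwRadius(df$element) + probe
  mesh <- spherePoints(nPoints)
  asa <- numeric(n)
  maxReach <- max(rad)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1L] - xyz[i, 1L])^2 + (xyz[, 2L] - xyz[i, 2L])^2 +
          (xyz[, 3L] - xyz[i, 3L])^2
    nb <- which(d2 < (rad[i] + maxReach)^2 & d2 > 0)
    nb <- nb[sqrt(d2[nb]) < rad[i] + rad[nb]]
    pts <- mesh * rad[i]
    pts <- sweep(pts, 2L, xyz[i, ], "+")
    if (length(nb)) {
      free <- rep(TRUE, nPoints)
      for (j in nb) {
        dd <- (pts[, 1L] - xyz[j, 1L])^2 + (pts[, 2L] - xyz[j, 2L])^2 +
              (pts[, 3L] - xyz[j, 3L])^2
        free <- free & dd > rad[j]^2
        if (!any(free)) break
      }
      frac <- mean(free)
    } else frac <- 1
    asa[i] <- frac * 4 * pi * rad[i]^2
  }
  asa
}

#' Per-residue maximum accessibility reference
#'
#' Theoretical maximum accessible surface areas (square Angstrom) per
#' standard residue, used to normalize residue ASA into relative solvent
#' accessibility; shipped as `extdata/max_accessibility.tsv` (theoretical
#' Gly-X-Gly values of Tien et al. 2013).
#'
#' @return named numeric vector over the 20 standard residues.
#' @export
maxAccessibility <- function() {
  if (!is.null(.pkgEnv$maxASA)) return(.pkgEnv$maxASA)
  path <- system.file("extdata", "max_accessibility.tsv",
                      package = "csmpred", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  .pkgEnv$maxASA <- setNames(tab$maxASA, tab$resName)
  .pkgEnv$maxASA
}

#' Relative solvent accessibility of a residue
#'
#' Sums the per-atom accessible surface area of the residue (computed in
#' the context of the whole structure, probe 1.4 Angstrom) and divides by
#' the residue type's maximum-accessibility reference value; results
#' slightly above 1 (possible for exposed termini or distorted geometry)
#' are clipped to 1.
#'
#' @param structure a [ProteinStructure-class].
#' @param chainId,resNo,insert residue key (author numbering).
#' @param asa optional precomputed per-atom ASA from [shrakeRupley()], to
#'   avoid recomputation across many residues of one structure.
#' @param probe probe radius in Angstrom.
#' @return RSA fraction in \[0, 1\].
#' @export
computeRSA <- function(structure, chainId, resNo, insert = "", asa = NULL,
                       probe = 1.4) {
  res <- residueAtoms(structure, chainId, resNo, insert)
  if (is.null(asa)) asa <- shrakeRupley(structure, probe = probe)
  df <- atoms(structure)
  sel <- df$chainId == chainId & df$resNo == resNo & df$insert == insert
  resName <- res$resName[1L]
  ref <- maxAccessibility()[resName]
  if (is.na(ref)) {
    # non-standard residue: normalize against its own free-atom surface
    ref <- sum(4 * pi * (vdwRadius(res$element) + probe)^2)
  }
  min(1, sum(asa[sel]) / ref)
}
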