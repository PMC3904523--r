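#' Specify a deterministic toy structure
#'
#' Three fixture families cover the geometric regimes the signature code
#' must handle: `"point-cloud"` (random heavy atoms in a box, one
#' single-atom residue each — exercises raw pair counting),
#' `"ideal-helix"` (a poly-alanine alpha helix built from a canonical
#' backbone template on the standard helical screw, 100 degrees rotation
#' and 1.5 Angstrom rise per residue — a realistic dense protein
#' neighbourhood), and `"two-chain-contact"` (two 3x3x3 CA grids on
#' facing planes whose minimum inter-chain distance equals `gap`
#' exactly — a parameterized interface).
#'
#' @param kind one of `"point-cloud"`, `"ideal-helix"`,
#'   `"two-chain-contact"`.
#' @param nAtoms point-cloud size.
#' @param nResidues helix length in residues.
#' @param box point-cloud box edge (Angstrom).
#' @param gap interface gap (Angstrom).
#' @param spacing grid spacing of the contact fixture (Angstrom).
#' @param seed integer; fixed seed gives byte-identical output.
#' @return list of class `fixtureSpec`.
#' @export
fixtureSpec <- function(kind, nAtoms = 50L, nResidues = 15L, box = 20,
                        gap = 5, spacing = 3.8, seed = 1L) {
  if (!kind %in% c("point-cloud", "ideal-helix", "two-chain-contact"))
    stop("unknown fixture kind: ", kind)
  if (kind == "point-cloud" && nAtoms < 1L) stop("nAtoms must be >= 1")
  if (kind == "ideal-helix" && nResidues < 1L)
    stop("nResidues must be >= 1")
  if (kind == "two-chain-contact" && (gap <= 0 || spacing <= 0))
    stop("gap and spacing must be positive")
  structure(list(kind = kind, nAtoms = as.integer(nAtoms),
                 nResidues = as.integer(nResidues), box = box, gap = gap,
                 spacing = spacing, seed = as.integer(seed)),
            class = "fixtureSpec")
}

# canonical alanine template in local residue coordinates (Angstrom):
# CA at origin, standard bond geometry for N, C, O, CB
HELIX_TEMPLATE <- rbind(
  N  = c(-0.572,  1.337,  0.000),
  CA = c( 0.000,  0.000,  0.000),
  C  = c( 1.517,  0.000,  0.000),
  O  = c( 2.146,  1.057,  0.000),
  CB = c(-0.536, -0.776, -1.210))

helixCoordinates <- function(nResidues, rise = 1.5, twist = 100,
                             radius = 2.3) {
  out <- vector("list", nResidues)
  for (i in seq_len(nResidues)) {
    ang <- (i - 1L) * twist * pi / 180
    rot <- matrix(c(cos(ang), sin(ang), 0,
                    -sin(ang), cos(ang), 0,
                    0, 0, 1), 3L, 3L)
    base <- sweep(HELIX_TEMPLATE, 2L, c(radius, 0, 0), "+")
    xyz <- base %*% rot
    xyz[, 3L] <- xyz[, 3L] + (i - 1L) * rise
    out[[i]] <- xyz
  }
  out
}

#' Generate a toy structure as PDB text
#'
#' Deterministic for a fixed spec (point-cloud placement is seeded); the
#' output is syntactically valid PDB and round-trips through [readPDB()].
#'
#' @param spec a [fixtureSpec()].
#' @return character vector of PDB lines.
#' @examples
#' txt <- generateStructure(fixtureSpec("point-cloud", nAtoms = 3))
#' tf <- tempfile(fileext = ".pdb"); writeLines(txt, tf)
#' atoms(readPDB(tf))
#' @export
generateStructure <- function(spec) {
  stopifnot(inherits(spec, "fixtureSpec"))
  df <- switch(spec$kind,
    "point-cloud" = {
      xyz <- withr_seed(spec$seed,
                        matrix(runif(3L * spec$nAtoms, 0, spec$box),
                               ncol = 3L))
      el <- withr_seed(spec$seed + 1L,
                       sample(c("C", "N", "O", "S"), spec$nAtoms,
                              replace = TRUE,
                              prob = c(0.6, 0.15, 0.2, 0.05)))
      data.frame(serial = seq_len(spec$nAtoms),
                 atomName = el, element = el, resName = "LIG",
                 resNo = seq_len(spec$nAtoms), insert = "",
                 chainId = "X", x = round(xyz[, 1L], 3L),
                 y = round(xyz[, 2L], 3L), z = round(xyz[, 3L], 3L),
                 occupancy = 1, hetero = TRUE,
                 stringsAsFactors = FALSE)
    },
    "ideal-helix" = {
      res <- helixCoordinates(spec$nResidues)
      rows <- do.call(rbind, lapply(seq_along(res), function(i) {
        xyz <- res[[i]]
        data.frame(atomName = rownames(HELIX_TEMPLATE),
                   element = substr(rownames(HELIX_TEMPLATE), 1L, 1L),
                   resName = "ALA", resNo = i, insert = "",
                   chainId = "A", x = round(xyz[, 1L], 3L),
                   y = round(xyz[, 2L], 3L), z = round(xyz[, 3L], 3L),
                   occupancy = 1, hetero = FALSE,
                   stringsAsFactors = FALSE)
      }))
      cbind(serial = seq_len(nrow(rows)), rows)
    },
    "two-chain-contact" = {
      g <- expand.grid(dy = c(-1, 0, 1), dz = c(-1, 0, 1),
                       dx = c(0, 1, 2))
      s <- spec$spacing
      mk <- function(chain, x0, sign) {
        data.frame(atomName = "CA", element = "C", resName = "GLY",
                   resNo = seq_len(nrow(g)), insert = "",
                   chainId = chain,
                   x = x0 + sign * g$dx * s, y = g$dy * s, z = g$dz * s,
                   occupancy = 1, hetero = FALSE,
                   stringsAsFactors = FALSE)
      }
      rows <- rbind(mk("A", 0, -1), mk("B", spec$gap, +1))
      cbind(serial = seq_len(nrow(rows)), rows)
    })
  pdbLines(df)
}

#' Specify a synthetic mutation effect model
#'
#' Defines the generative truth for recovery experiments: the free-energy
#' change of a sampled mutation is `intercept + weights . signature +
#' Gaussian noise`, linear in a named subset of signature features so
#' recovery is analytically interpretable. The noise standard deviation
#' is stated relative to the signal: `noiseFrac = 0.5` (the default study
#' condition) draws noise with SD equal to half the SD of the noiseless
#' signal over the sampled mutations. An optional quadratic term in the
#' first selected feature adds mild nonlinearity.
#'
#' @param featurePatterns character regexes; the features carrying weight
#'   are those of the signature layout matching any pattern. The default
#'   loads the pharmacophore-change block, the relative solvent
#'   accessibility, and long-range one-class pair counts.
#' @param noiseFrac noise SD as a fraction of signal SD (default 0.5).
#' @param intercept baseline ddG in kcal/mol (default -1, typical mild
#'   destabilization).
#' @param quadratic weight of the quadratic term (default 0, linear).
#' @param seed seed for drawing the weights.
#' @return list of class `syntheticEffectModel`.
#' @export
syntheticEffectModel <- function(featurePatterns =
                                   c("^pchange:", "^rsa$",
                                     "^one:all:all:(8\\.0|9\\.0|10\\.0)$"),
                                 noiseFrac = 0.5, intercept = -1,
                                 quadratic = 0, seed = 1L) {
  stopifnot(noiseFrac >= 0)
  structure(list(featurePatterns = featurePatterns,
                 noiseFrac = noiseFrac, intercept = intercept,
                 quadratic = quadratic, seed = as.integer(seed)),
            class = "syntheticEffectModel")
}

#' Generate a synthetic mutation dataset with known generative truth
#'
#' Samples `n` distinct (site, mutant residue) combinations uniformly
#' over the standard-residue positions of the supplied structures,
#' computes their signatures, and draws free-energy changes from the
#' effect model. The generative truth (weights, intercept, noiseless
#' signal, injected noise SD) is returned so downstream recovery tests
#' can compare against it.
#'
#' @param structures named list of labelled [ProteinStructure-class]
#'   objects.
#' @param effect a [syntheticEffectModel()].
#' @param n number of mutations.
#' @param seed integer master seed (site sampling and noise).
#' @param params a [SignatureParams-class].
#' @return list: `dataset` (a [MutationDataset-class] in the stability
#'   task), `features` (signature matrix), `truth` (list with `weights`,
#'   `intercept`, `signal`, `noiseSD`, `noise`).
#' @export
generateMutationDataset <- function(structures, effect =
                                      syntheticEffectModel(), n = 500L,
                                    seed = 1L,
                                    params = SignatureParams()) {
  sites <- do.call(rbind, lapply(names(structures), function(id) {
    rk <- residueKeys(structures[[id]])
    rk <- rk[rk$resName %in% AA3, , drop = FALSE]
    if (nrow(rk)) cbind(structureId = id, rk) else NULL
  }))
  if (is.null(sites) || !nrow(sites))
    stop("no standard residues available for mutation")
  combos <- merge(sites, data.frame(mt = AA1), by = NULL)
  combos <- combos[aaOneLetter(combos$resName) != combos$mt, , drop = FALSE]
  if (nrow(combos) < n)
    stop("fixture too small: ", nrow(combos),
         " distinct site/mutant combinations available, ", n, " requested")
  pick <- withr_seed(seed, sample(nrow(combos), n))
  chosen <- combos[pick, , drop = FALSE]

  recs <- data.frame(structureId = chosen$structureId,
                     chainId = chosen$chainId,
                     wt = aaOneLetter(chosen$resName),
                     position = chosen$resNo, insert = chosen$insert,
                     mt = chosen$mt,
                     mutationStr = paste0(aaOneLetter(chosen$resName),
                                          chosen$resNo, chosen$mt),
                     ddG = NA_real_, kdWT = NA_real_, kdMT = NA_real_,
                     pH = 7.0, temperature = 298.15,
                     source = "synthetic", stringsAsFactors = FALSE)
  ds <- new("MutationDataset", records = recs, name = "synthetic",
            task = "stability")
  sig <- batchSignatures(structures, ds, params = params)
  if (nrow(sig$failures))
    stop("internal fixture error: ", nrow(sig$failures),
         " signature failures")
  feat <- sig$features

  hit <- Reduce(`|`, lapply(effect$featurePatterns, grepl,
                            x = colnames(feat)))
  wNames <- colnames(feat)[hit]
  active <- wNames[apply(feat[, wNames, drop = FALSE], 2L, sd) > 0]
  if (!length(active))
    stop("effect model selects no varying features")
  w <- withr_seed(effect$seed, setNames(rnorm(length(active)), active))
  xsub <- scale(feat[, active, drop = FALSE])
  signal <- effect$intercept + as.vector(xsub %*% w)
  if (effect$quadratic != 0)
    signal <- signal + effect$quadratic * xsub[, 1L]^2
  noiseSD <- effect$noiseFrac * sd(signal)
  noise <- if (noiseSD > 0) withr_seed(seed + 1L, rnorm(n, 0, noiseSD))
           else numeric(n)
  recs$ddG <- signal + noise
  list(dataset = new("MutationDataset", records = recs,
                     name = "synthetic", task = "stability"),
       features = feat,
       truth = list(weights = w, intercept = effect$intercept,
                    signal = signal, noiseSD = noiseSD, noise = noise))
}

#' SKEMPI-like fixture table with planted defects
#'
#' Writes a small protein-protein affinity table in the `skempi` dialect
#' with a documented composition: valid single-point rows plus planted
#' multi-point mutations, rows missing an affinity, a malformed mutation
#' code and a malformed (non-numeric) affinity. The sidecar manifest
#' (JSON) states the exact counts so filter tests can assert survivor
#' numbers; regeneration is deterministic.
#'
#' @param path output TSV path (manifest written alongside with suffix
#'   `.manifest.json`); defaults to a tempfile.
#' @param seed integer seed for the affinity draws.
#' @return list with `path`, `manifestPath` and `manifest` (named counts:
#'   `rows`, `valid`, `multi_point`, `missing_affinity`,
#'   `malformed_code`, `malformed_numeric`).
#' @export
skempiLikeFixture <- function(path = tempfile(fileext = ".tsv"),
                              seed = 1L) {
  nValid <- 13L
  kd <- withr_seed(seed, 10^runif(2L * nValid + 4L, -12, -3))
  mtPool <- c("G", "W", "D", "K", "F", "S", "V", "L", "E", "N", "Y", "T",
              "R")
  valid <- data.frame(
    pdb = "fixhelix", chain = "A",
    mutation = paste0("A", seq(2L, 1L + nValid), mtPool[seq_len(nValid)]),
    affinity_wt_M = signif(kd[seq_len(nValid)], 4L),
    affinity_mut_M = signif(kd[nValid + seq_len(nValid)], 4L),
    temperature_K = 298, pH = 7.4, stringsAsFactors = FALSE)
  multi <- valid[1:3, ]
  multi$mutation <- c("A2G,A5W", "A3D;A7K", "A4F/A9S")
  missingAff <- valid[4:5, ]
  missingAff$affinity_mut_M <- NA
  badCode <- valid[6, ]; badCode$mutation <- "X10G"
  badNum <- valid[7, ]
  badNum$affinity_wt_M <- "n/a"
  tab <- rbind(valid, multi, missingAff, badCode, badNum)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  manifest <- list(rows = nrow(tab), valid = nValid, multi_point = 3L,
                   missing_affinity = 2L, malformed_code = 1L,
                   malformed_numeric = 1L)
  manifestPath <- paste0(path, ".manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE)
  list(path = path, manifestPath = manifestPath, manifest = manifest)
}
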