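WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O", "DIS", "SOL")

#' Read and normalize a PDB structure
#'
#' Parses ATOM/HETATM records (wwPDB v3.3 fixed columns, via bio3d) and
#' applies the package's normalization policy: hydrogens (and deuteriums)
#' removed, waters removed, multi-model files reduced to the first model,
#' and for atoms with alternate locations only the highest-occupancy
#' conformer kept (ties broken by first encountered). Non-water hetero
#' atoms (nucleic acids, ligands, ions) are retained and flagged in the
#' `hetero` column so that environments at protein-nucleic-acid interfaces
#' see the nucleic-acid atoms.
#'
#' @param path path to a PDB file.
#' @param structureId identifier stored with the structure; defaults to the
#'   file stem.
#' @param keepHetero logical; retain non-water HETATM records (default
#'   TRUE).
#' @return a [ProteinStructure-class].
#' @examples
#' pdb <- generateStructure(fixtureSpec("ideal-helix", nResidues = 5))
#' tf <- tempfile(fileext = ".pdb"); writeLines(pdb, tf)
#' readPDB(tf)
#' @seealso [writePDB()], [assignPharmacophores()]
#' @export
readPDB <- function(path, structureId = NULL, keepHetero = TRUE) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  if (!any(grepl("^(ATOM  |HETATM)", raw)))
    stop("no ATOM/HETATM records in ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) {
      bad <- which(grepl("^(ATOM  |HETATM)", raw) & nchar(raw) < 54)
      where <- if (length(bad)) paste0(" (first malformed line: ", bad[1L], ")")
               else ""
      stop("failed to parse PDB file ", path, where, ": ",
           conditionMessage(e), call. = FALSE)
    })
  at <- pdb$atom
  if (is.null(structureId))
    structureId <- sub("\\.(pdb|ent)$", "", basename(path),
                       ignore.case = TRUE)

  element <- toupper(trimws(at$elesy))
  guess <- toupper(substr(gsub("[^A-Za-z].*$", "",
                               sub("^[0-9]+", "", trimws(at$elety))), 1L, 1L))
  element[is.na(element) | !nzchar(element)] <-
    guess[is.na(element) | !nzchar(element)]

  df <- data.frame(
    serial = at$eleno,
    atomName = trimws(at$elety),
    element = element,
    resName = trimws(at$resid),
    resNo = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    chainId = ifelse(is.na(at$chain), " ", at$chain),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    altLoc = ifelse(is.na(at$alt), "", at$alt),
    hetero = at$type == "HETATM",
    stringsAsFactors = FALSE)

  df <- df[!df$element %in% c("H", "D"), , drop = FALSE]
  df <- df[!df$resName %in% WATER_RESNAMES, , drop = FALSE]
  if (!keepHetero) df <- df[!df$hetero, , drop = FALSE]

  # altloc policy: per atom site keep the highest-occupancy conformer,
  # ties resolved in favour of the first encountered
  key <- paste(df$chainId, df$resNo, df$insert, df$resName, df$atomName,
               sep = "\r")
  if (anyDuplicated(key)) {
    ord <- order(match(key, unique(key)), -df$occupancy,
                 seq_len(nrow(df)))
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(paste(df$chainId, df$resNo, df$insert, df$resName,
                               df$atomName, sep = "\r")), , drop = FALSE]
    df <- df[order(match(df$serial, at$eleno)), , drop = FALSE]
  }
  df$altLoc <- NULL
  if (!nrow(df)) stop("structure ", structureId,
                      " contains no usable heavy atoms after normalization")
  df$pharmacophore <- NA_character_
  rownames(df) <- NULL
  new("ProteinStructure", structureId = structureId, atoms = df)
}

#' Write a structure back to PDB format
#'
#' Emits standard fixed-width ATOM/HETATM records for the atoms of a
#' [ProteinStructure-class]. Round-tripping through [readPDB()] recovers
#' the identical atom table (coordinates at 3 decimals).
#'
#' @param structure a [ProteinStructure-class].
#' @param path output file path; if `NULL`, the lines are returned
#'   invisibly instead of written.
#' @return invisibly, the character vector of PDB lines.
#' @export
writePDB <- function(structure, path = NULL) {
  lines <- pdbLines(atoms(structure))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

# format an atom table as PDB ATOM/HETATM records + END
pdbLines <- function(df) {
  recname <- ifelse(df$hetero, "HETATM", "ATOM  ")
  # PDB atom-name column quirk: names of 1-3 chars for 1-letter elements
  # start in column 14
  nm <- df$atomName
  pad <- nchar(df$element) == 1L & nchar(nm) < 4L
  nm[pad] <- sprintf(" %-3s", nm[pad])
  nm <- sprintf("%-4s", nm)
  body <- sprintf("%s%5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                  recname, df$serial %% 100000L, nm, df$resName,
                  df$chainId, df$resNo,
                  ifelse(nzchar(df$insert), df$insert, " "),
                  df$x, df$y, df$z, df$occupancy, 0,
                  sprintf("%2s", df$element))
  c(body, "END")
}

#' Enumerate residues of a structure
#'
#' @param structure a [ProteinStructure-class].
#' @param proteinOnly drop hetero residues (default TRUE).
#' @return data.frame with one row per residue: `chainId`, `resNo`,
#'   `insert`, `resName`, `nAtoms`.
#' @export
residueKeys <- function(structure, proteinOnly = TRUE) {
  df <- atoms(structure)
  if (proteinOnly) df <- df[!df$hetero, , drop = FALSE]
  key <- paste(df$chainId, df$resNo, df$insert, sep = "\r")
  first <- !duplicated(key)
  out <- df[first, c("chainId", "resNo", "insert", "resName")]
  out$nAtoms <- as.integer(table(key)[match(key[first], names(table(key)))])
  rownames(out) <- NULL
  out
}

# select the atom rows of one residue; errors if absent
residueAtoms <- function(structure, chainId, resNo, insert = "") {
  df <- atoms(structure)
  sel <- df$chainId == chainId & df$resNo == resNo & df$insert == insert
  if (!any(sel))
    stop("residue ", chainId, ":", resNo, insert, " not found in structure ",
         structureId(structure))
  df[sel, , drop = FALSE]
}
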