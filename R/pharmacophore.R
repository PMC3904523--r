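.pkgEnv <- new.env(parent = emptyenv())

#' The shipped pharmacophore atom-class table
#'
#' Maps every heavy atom of the 20 standard amino acids (plus the terminal
#' OXT) to exactly one of the eight pharmacophore classes (see
#' [pharmacophoreClasses()]). Atoms that could plausibly carry several
#' roles receive one class by the fixed priority order sulphur > positive >
#' negative > aromatic > donor > acceptor > hydrophobic > neutral; e.g.
#' histidine and tryptophan ring nitrogens are `aromatic`, hydroxyl oxygens
#' (which both donate and accept) are `donor`. The table ships as
#' human-readable TSV in `extdata/pharmacophore_classes.tsv`.
#'
#' @param path optional path to an alternative table with columns
#'   `resName`, `atomName`, `class`.
#' @return data.frame with columns `resName`, `atomName`, `class`.
#' @examples
#' head(pharmacophoreTable())
#' @export
pharmacophoreTable <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.pkgEnv$pharmTable)) return(.pkgEnv$pharmTable)
    path <- system.file("extdata", "pharmacophore_classes.tsv",
                        package = "csmpred", mustWork = TRUE)
    cache <- TRUE
  } else cache <- FALSE
  tab <- read.delim(path, stringsAsFactors = FALSE)
  bad <- setdiff(unique(tab$class), pharmacophoreClasses())
  if (length(bad))
    stop("pharmacophore table has unknown classes: ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(tab[, c("resName", "atomName")]))
    stop("pharmacophore table maps some atom twice")
  if (cache) .pkgEnv$pharmTable <- tab
  tab
}

# element-based fallback classes for atoms outside the residue table
# (nucleic acids, ligands, ions); phosphate P is negative, metals neutral
elementFallbackClass <- function(element) {
  map <- c(C = "hydrophobic", N = "donor", O = "acceptor",
           S = "sulphur", P = "negative", SE = "sulphur",
           F = "acceptor", CL = "acceptor", BR = "acceptor", I = "acceptor")
  cls <- unname(map[toupper(element)])
  cls[is.na(cls)] <- "neutral"
  cls
}

#' Assign a pharmacophore class to every atom
#'
#' Labels each heavy atom of the structure with one of the eight classes.
#' Standard-residue atoms are looked up in the table; atoms of non-standard
#' or hetero residues (and standard-residue atoms missing from the table,
#' e.g. nonstandard names) fall back to an element-based assignment unless
#' `strict = TRUE`.
#'
#' @param structure a [ProteinStructure-class].
#' @param table pharmacophore table as from [pharmacophoreTable()].
#' @param strict if TRUE, a standard-residue atom absent from the table is
#'   an error rather than falling back to the element class.
#' @return the structure with the `pharmacophore` atom column filled.
#' @export
assignPharmacophores <- function(structure, table = pharmacophoreTable(),
                                 strict = FALSE) {
  df <- atoms(structure)
  idx <- match(paste(df$resName, df$atomName),
               paste(table$resName, table$atomName))
  cls <- table$class[idx]
  missing <- is.na(cls)
  if (any(missing)) {
    standardMiss <- missing & df$resName %in% AA3 & !df$hetero
    if (strict && any(standardMiss)) {
      ex <- df[standardMiss, , drop = FALSE][1L, ]
      stop("atom not covered by pharmacophore table: ", ex$resName, " ",
           ex$atomName, " (chain ", ex$chainId, ", residue ", ex$resNo, ")")
    }
    cls[missing] <- elementFallbackClass(df$element[missing])
  }
  df$pharmacophore <- cls
  initialize(structure, atoms = df)
}

#' Pharmacophore count vector of a residue type
#'
#' Counts, per pharmacophore class, the heavy atoms of one standard amino
#' acid under the table's atom inventory (terminal OXT excluded). The
#' entries sum to the residue's heavy-atom count.
#'
#' @param resName 3-letter (or 1-letter) standard residue code.
#' @param table pharmacophore table.
#' @return named integer 8-vector in [pharmacophoreClasses()] order.
#' @examples
#' residuePharmacophoreVector("GLY")  # sums to 4
#' @export
residuePharmacophoreVector <- function(resName, table = pharmacophoreTable()) {
  resName <- toupper(resName)
  if (nchar(resName) == 1L) resName <- aaThreeLetter(resName)
  if (!resName %in% AA3)
    stop("unsupported residue: ", resName,
         " (pharmacophore vectors are defined for the 20 standard amino acids)")
  rows <- table[table$resName == resName & table$atomName != "OXT", ]
  cls <- factor(rows$class, levels = pharmacophoreClasses())
  setNames(as.integer(base::table(cls)), pharmacophoreClasses())
}

#' Pharmacophore-change vector of a mutation
#'
#' Component-wise difference between the mutant and wild-type residue
#' pharmacophore count vectors, `p_mt - p_wt`. Zero for an identity
#' mutation; swapping wild type and mutant negates the vector.
#'
#' @param wt,mt wild-type and mutant residue codes (1- or 3-letter).
#' @param table pharmacophore table.
#' @return named integer 8-vector.
#' @examples
#' pharmacophoreChange("G", "W")
#' @export
pharmacophoreChange <- function(wt, mt, table = pharmacophoreTable()) {
  residuePharmacophoreVector(mt, table) -
    residuePharmacophoreVector(wt, table)
}
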