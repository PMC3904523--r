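#' Parse a single-point mutation code
#'
#' Codes follow the conventional wild-type / author position / mutant
#' form, e.g. `"R282W"`. Both residues must be standard 1-letter codes and
#' must differ (a silent "mutation" has no signature target and is
#' rejected).
#'
#' @param code character scalar like `"R282W"`.
#' @return list with `wt`, `position` (integer), `mt`.
#' @examples
#' parseMutationCode("R282W")
#' @export
parseMutationCode <- function(code) {
  m <- regmatches(code, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", code))[[1L]]
  if (length(m) != 4L)
    stop("malformed mutation code: '", code,
         "' (expected <wt><position><mt>, e.g. R282W)")
  wt <- toupper(m[2L]); mt <- toupper(m[4L])
  if (!wt %in% AA1) stop("malformed mutation code: '", code, "': '", wt,
                         "' is not a standard residue")
  if (!mt %in% AA1) stop("malformed mutation code: '", code, "': '", mt,
                         "' is not a standard residue")
  if (wt == mt)
    stop("silent mutation '", code, "': wild type and mutant are identical")
  list(wt = wt, position = as.integer(m[3L]), mt = mt)
}

#' Gibbs free energy from a dissociation constant
#'
#' `dG = R T ln(KD)` with the gas constant R = 1.9872e-3 kcal/(mol K);
#' converts a molar dissociation constant at temperature T (Kelvin) into
#' kcal/mol. KD = 1 M gives exactly 0.
#'
#' @param kd dissociation constant in molar (> 0).
#' @param temperature temperature in Kelvin (> 0).
#' @return free energy in kcal/mol.
#' @examples
#' deltaGFromKd(1e-9, 298)
#' @export
deltaGFromKd <- function(kd, temperature = 298) {
  if (any(!is.finite(kd)) || any(kd <= 0))
    stop("KD must be positive and finite (molar)")
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    stop("temperature must be positive (Kelvin)")
  GAS_CONSTANT_KCAL * temperature * log(kd)
}

#' Binding free-energy change of a mutation
#'
#' `ddG = dG(mutant) - dG(wild type)` evaluated at a common temperature;
#' a mutant binding more weakly (larger KD) gives a positive value.
#' Antisymmetric under swapping wild type and mutant.
#'
#' @param kdWT,kdMT wild-type and mutant dissociation constants (molar).
#' @param temperature temperature in Kelvin; 298 is the standard-condition
#'   default used when a record lacks one.
#' @return kcal/mol.
#' @examples
#' ddgBinding(1e-9, 1e-8, 298)  # ten-fold weaker: about +1.36
#' @export
ddgBinding <- function(kdWT, kdMT, temperature = 298) {
  deltaGFromKd(kdMT, temperature) - deltaGFromKd(kdWT, temperature)
}

#' Direction-of-change class of a free-energy change
#'
#' Sign convention (documented here and applied uniformly): negative
#' values are destabilizing / affinity-reducing, positive values
#' stabilizing. Exactly zero is assigned to `"destabilizing"` and flagged
#' via the `"boundary"` attribute. Tables using the opposite convention
#' can be flipped at load time (`flipSign` of [loadMutationTable()]).
#'
#' @param ddG finite numeric vector, kcal/mol.
#' @return character vector of `"destabilizing"` / `"stabilizing"`, with
#'   attribute `boundary` marking exact zeros.
#' @examples
#' stabilityClass(c(-2, 1.5, 0))
#' @export
stabilityClass <- function(ddG) {
  if (any(!is.finite(ddG))) stop("ddG must be finite")
  out <- ifelse(ddG > 0, "stabilizing", "destabilizing")
  attr(out, "boundary") <- ddG == 0
  out
}

dialectConfig <- function(dialect) {
  path <- system.file("extdata", paste0("dialect_", dialect, ".yaml"),
                      package = "csmpred")
  if (!nzchar(path))
    stop("unknown dataset dialect: '", dialect,
         "' (shipped dialects: protherm, skempi, pronit, csmpred)")
  yaml::read_yaml(path)
}

numOrNA <- function(x) suppressWarnings(as.numeric(x))

#' Load a mutation/thermodynamics table
#'
#' Reads a delimited text table in one of the supported dialects
#' (ProTherm-style stability tables with measured ddG; SKEMPI- and
#' ProNIT-style affinity tables with wild-type and mutant KD). Column
#' mappings and temperature units are defined in editable YAML config
#' files shipped under `extdata/` (`dialect_*.yaml`), because database
#' exports vary across versions. Temperatures are normalized to Kelvin
#' internally. Rows whose mutation code or mapped numeric fields are
#' malformed (non-empty but unparseable) are skipped and logged, not
#' fatal; multi-point mutation rows are retained with `NA` mutation
#' fields so that [filterSinglePoint()] can count and exclude them.
#'
#' @param path delimited text file with a header row.
#' @param dialect `"protherm"`, `"skempi"`, `"pronit"` or `"csmpred"` (the
#'   package's canonical export format).
#' @param name dataset label (defaults to the file stem).
#' @param flipSign multiply ddG by -1 for tables using the opposite sign
#'   convention (see [stabilityClass()]).
#' @param returnLog if TRUE, return `list(dataset, skipped)` where
#'   `skipped` is a data.frame of dropped rows and reasons.
#' @return a [MutationDataset-class] (or a list, see `returnLog`).
#' @export
loadMutationTable <- function(path, dialect, name = NULL, flipSign = FALSE,
                              returnLog = FALSE) {
  cfg <- dialectConfig(dialect)
  raw <- read.delim(path, sep = cfg$sep %||% "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!nrow(raw)) stop("empty dataset: ", path)
  col <- function(key) {
    cn <- cfg$columns[[key]]
    if (is.null(cn) || !cn %in% names(raw)) return(rep(NA, nrow(raw)))
    raw[[cn]]
  }
  mutStr <- as.character(col("mutation"))
  skipped <- data.frame(row = integer(0), reason = character(0))
  skip <- rep(FALSE, nrow(raw))

  wt <- pos <- mt <- rep(NA_character_, nrow(raw))
  for (i in seq_len(nrow(raw))) {
    if (is.na(mutStr[i]) || grepl("[,;/]", mutStr[i])) next  # multi-point
    p <- tryCatch(parseMutationCode(mutStr[i]), error = function(e) NULL)
    if (!is.null(p)) { wt[i] <- p$wt; pos[i] <- p$position; mt[i] <- p$mt }
  }
  numField <- function(key, label) {
    v <- col(key)
    num <- numOrNA(v)
    bad <- !is.na(v) & is.na(num) & nzchar(trimws(as.character(v)))
    if (any(bad)) {
      skipped <<- rbind(skipped, data.frame(
        row = which(bad), reason = paste0("unparseable ", label)))
      skip[bad] <<- TRUE
    }
    num
  }
  ddG <- numField("ddG", "ddG")
  kdWT <- numField("kd_wt", "wild-type KD")
  kdMT <- numField("kd_mt", "mutant KD")
  pH <- numField("pH", "pH")
  temp <- numField("temperature", "temperature")
  if (identical(cfg$temperature_unit, "C")) temp <- temp + 273.15
  if (flipSign) ddG <- -ddG

  recs <- data.frame(
    structureId = as.character(col("structureId")),
    chainId = { ch <- as.character(col("chain")); ifelse(is.na(ch), "A", ch) },
    wt = wt, position = numOrNA(pos), insert = "",
    mt = mt, mutationStr = mutStr,
    ddG = ddG, kdWT = kdWT, kdMT = kdMT, pH = pH, temperature = temp,
    source = dialect, stringsAsFactors = FALSE)
  recs <- recs[!skip, , drop = FALSE]
  rownames(recs) <- NULL
  if (!nrow(recs)) stop("no parsable rows in ", path)
  ds <- new("MutationDataset", records = recs,
            name = name %||% sub("\\.[^.]*$", "", basename(path)),
            task = cfg$task %||% "stability")
  if (returnLog) list(dataset = ds, skipped = skipped) else ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a dataset in the package's canonical dialect
#'
#' @param dataset a [MutationDataset-class].
#' @param path output TSV path.
#' @return invisibly, `path`. Re-loading with
#'   `loadMutationTable(path, "csmpred")` recovers identical records.
#' @export
writeMutationTable <- function(dataset, path) {
  r <- records(dataset)
  out <- data.frame(pdb = r$structureId, chain = r$chainId,
                    mutation = ifelse(is.na(r$mutationStr) &
                                        !is.na(r$wt),
                                      paste0(r$wt, r$position, r$mt),
                                      r$mutationStr),
                    ddG = r$ddG, kd_wt = r$kdWT, kd_mt = r$kdMT,
                    pH = r$pH, temperature_K = r$temperature)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter to usable single-point mutation records
#'
#' Keeps records that are single substitutions with a resolvable structure
#' id and, depending on the task, either a measured ddG (stability) or
#' both wild-type and mutant affinities (binding). Every exclusion is
#' logged with a reason code; the filter is a pure function of the input
#' and idempotent.
#'
#' @param dataset a [MutationDataset-class].
#' @return list with `dataset` (filtered, order preserved) and
#'   `exclusions` (data.frame: `row`, `reason` in
#'   `c("multi_point_or_unparseable", "missing_structure", "missing_ddg",
#'   "missing_affinity")`).
#' @export
filterSinglePoint <- function(dataset) {
  r <- records(dataset)
  reason <- rep(NA_character_, nrow(r))
  notSingle <- is.na(r$wt) | is.na(r$mt) | is.na(r$position)
  reason[notSingle] <- "multi_point_or_unparseable"
  noStruct <- is.na(reason) &
    (is.na(r$structureId) | !nzchar(r$structureId))
  reason[noStruct] <- "missing_structure"
  if (dataset@task == "stability") {
    noTarget <- is.na(reason) & is.na(r$ddG)
    reason[noTarget] <- "missing_ddg"
  } else {
    noTarget <- is.na(reason) & (is.na(r$kdWT) | is.na(r$kdMT)) &
      is.na(r$ddG)
    reason[noTarget] <- "missing_affinity"
  }
  keep <- is.na(reason)
  excl <- data.frame(row = which(!keep), reason = reason[!keep])
  kept <- r[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(dataset = initialize(dataset, records = kept), exclusions = excl)
}

#' Fill binding ddG from affinities
#'
#' For records lacking a direct ddG but carrying both dissociation
#' constants, computes `ddG = dG(mutant) - dG(wild type)` via
#' [ddgBinding()] at the record's temperature (298 K when missing,
#' flagged in the `tempImputed` column).
#'
#' @param dataset a [MutationDataset-class].
#' @return the dataset with `ddG` filled and a `tempImputed` logical
#'   column added.
#' @export
deriveBindingDdg <- function(dataset) {
  r <- records(dataset)
  r$tempImputed <- FALSE
  todo <- is.na(r$ddG) & !is.na(r$kdWT) & !is.na(r$kdMT)
  if (any(todo)) {
    tK <- r$temperature[todo]
    imput <- is.na(tK)
    tK[imput] <- 298
    r$tempImputed[todo] <- imput
    r$ddG[todo] <- ddgBinding(r$kdWT[todo], r$kdMT[todo], tK)
  }
  initialize(dataset, records = r)
}

#' Collapse replicate measurements
#'
#' Optional deduplication: repeated measurements of the same mutation
#' (same structure, chain, position, mutant) under different conditions
#' are collapsed to their median ddG; pH and temperature collapse to their
#' medians over the non-missing replicates.
#'
#' @param dataset a [MutationDataset-class].
#' @return the collapsed dataset.
#' @export
collapseReplicates <- function(dataset) {
  r <- records(dataset)
  key <- paste(r$structureId, r$chainId, r$wt, r$position, r$insert, r$mt,
               sep = "\r")
  idx <- split(seq_len(nrow(r)), factor(key, levels = unique(key)))
  out <- do.call(rbind, lapply(idx, function(i) {
    row <- r[i[1L], , drop = FALSE]
    row$ddG <- stats::median(r$ddG[i], na.rm = TRUE)
    row$pH <- stats::median(r$pH[i], na.rm = TRUE)
    row$temperature <- stats::median(r$temperature[i], na.rm = TRUE)
    row
  }))
  rownames(out) <- NULL
  initialize(dataset, records = out)
}
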