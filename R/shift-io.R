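#' @include ShiftTable-methods.R
NULL

# dialect-independent atom-name normalization onto the canonical key space
.ATOM_MAP <- c(H = "HN", HN = "HN", N = "NH", NH = "NH", CA = "CA", CB = "CB")

.normalizeNucleus <- function(atom) {
  out <- .ATOM_MAP[toupper(atom)]
  unname(out)
}

.buildShiftTable <- function(entityId, num, name, nucleus, shift,
                             what = "table") {
  keep <- !is.na(nucleus)
  dropped <- unique(toupper(attr(nucleus, "raw")[!keep]))
  num <- num[keep]; name <- name[keep]
  nucleus <- nucleus[keep]; shift <- shift[keep]
  key <- paste(num, nucleus)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (residue, nucleus) row in ", what, ": ", d)
  }
  ures <- sort(unique(num))
  resName <- name[match(ures, num)]
  values <- matrix(NA_real_, length(ures), length(NUCLEI),
                   dimnames = list(as.character(ures), NUCLEI))
  values[cbind(match(num, ures), match(nucleus, NUCLEI))] <- shift
  ShiftTable(entityId, data.frame(number = ures, name = resName), values)
}

#' Read backbone chemical shifts from an NMR-STAR file
#'
#' Parses the assigned chemical-shift loop (\code{_Atom_chem_shift} tags) of
#' an NMR-STAR 3.1 file holding one entity, as deposited at the BMRB, and
#' returns the backbone shifts on the canonical nucleus set. Nuclei outside
#' \code{\link{NUCLEI}} (e.g. 13CO, HA) are dropped with a message;
#' ambiguity codes are ignored.
#'
#' @param path path to an NMR-STAR file with one chemical-shift loop.
#' @param entityId label for the returned table (default: the file name).
#' @return A \linkS4class{ShiftTable}.
#' @export
readNmrStarShifts <- function(path, entityId = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  loopStarts <- which(lines == "loop_")
  if (!length(loopStarts))
    stop("format error: no loop found in '", path, "'")
  for (ls in loopStarts) {
    i <- ls + 1L
    tags <- character()
    while (i <= length(lines) && startsWith(lines[i], "_")) {
      tags <- c(tags, lines[i])
      i <- i + 1L
    }
    if (!any(grepl("^_Atom_chem_shift\\.", tags))) next
    rows <- character()
    while (i <= length(lines) && lines[i] != "stop_") {
      if (nzchar(lines[i]) && !startsWith(lines[i], "#"))
        rows <- c(rows, lines[i])
      i <- i + 1L
    }
    fields <- strsplit(rows, "[[:space:]]+")
    ncolumns <- length(tags)
    bad <- which(lengths(fields) != ncolumns)
    if (length(bad))
      stop("format error: row ", bad[1L], " of the chemical-shift loop has ",
           lengths(fields)[bad[1L]], " fields, expected ", ncolumns)
    m <- do.call(rbind, fields)
    colnames(m) <- sub("^_Atom_chem_shift\\.", "", tags)
    seqCol <- intersect(c("Comp_index_ID", "Seq_ID"), colnames(m))[1L]
    need <- c(seqCol, "Comp_ID", "Atom_ID", "Val")
    if (any(is.na(need)) || !all(need %in% colnames(m)))
      stop("format error: chemical-shift loop lacks required tags")
    rawAtom <- m[, "Atom_ID"]
    nucleus <- .normalizeNucleus(rawAtom)
    attr(nucleus, "raw") <- rawAtom
    dropped <- unique(rawAtom[is.na(nucleus)])
    if (length(dropped))
      message("dropping nuclei outside the backbone set: ",
              paste(dropped, collapse = ", "))
    return(.buildShiftTable(entityId,
                            as.integer(m[, seqCol]), m[, "Comp_ID"],
                            nucleus, as.numeric(m[, "Val"]),
                            what = basename(path)))
  }
  stop("format error: no chemical-shift loop (_Atom_chem_shift) in '",
       path, "'")
}

#' Predictor table dialects
#'
#' Returns the column mappings used by [readPredictorTable()] for the
#' supported chemical-shift predictor output dialects, as read from the
#' packaged configuration file \code{extdata/predictor_dialects.yaml}.
#'
#' @return A named list of dialect descriptions.
#' @export
predictorDialects <- function() {
  yaml::read_yaml(system.file("extdata", "predictor_dialects.yaml",
                              package = "ShiftEnsemble", mustWork = TRUE))
}

#' Read a per-conformer predicted chemical-shift table
#'
#' Normalizes the output tables of the supported shift predictors into a
#' \linkS4class{ShiftTable}. Supported dialects: \code{"ucbshift"} (wide CSV
#' with one shift column per atom), \code{"shiftx2"} (long CSV with columns
#' NUM, RES, ATOMNAME, SHIFT), \code{"spartaplus"} (whitespace table with a
#' VARS header naming RESID, RESNAME, ATOMNAME and SHIFT columns) and
#' \code{"generic-csv"} (long CSV with columns residue_number, residue_name,
#' nucleus, shift). Atom names are mapped onto the canonical nucleus set;
#' atoms outside it are dropped.
#'
#' @param path path to the predictor output file.
#' @param dialect one of \code{"ucbshift"}, \code{"shiftx2"},
#'   \code{"spartaplus"}, \code{"generic-csv"}.
#' @param entityId label for the returned table (default: the file name).
#' @return A \linkS4class{ShiftTable}.
#' @export
readPredictorTable <- function(path,
                               dialect = c("generic-csv", "ucbshift",
                                           "shiftx2", "spartaplus"),
                               entityId = basename(path)) {
  dialect <- match.arg(dialect)
  if (file.size(path) == 0)
    stop("format error: empty file '", path, "'")
  if (dialect == "spartaplus") {
    lines <- readLines(path, warn = FALSE)
    varsLine <- grep("^VARS\\b", lines, value = TRUE)
    dataLines <- lines[grepl("^[[:space:]]*-?[0-9]", lines)]
    if (!length(dataLines))
      stop("format error: no data rows in '", path, "'")
    fields <- strsplit(trimws(dataLines), "[[:space:]]+")
    m <- do.call(rbind, fields)
    if (length(varsLine)) {
      vars <- strsplit(trimws(sub("^VARS", "", varsLine[1L])),
                       "[[:space:]]+")[[1L]]
      if (ncol(m) != length(vars))
        stop("format error: VARS header does not match data columns")
      colnames(m) <- vars
      cols <- c("RESID", "RESNAME", "ATOMNAME", "SHIFT")
    } else {
      # positional fallback: RESID RESNAME ATOMNAME ... SHIFT(5th)
      colnames(m) <- paste0("V", seq_len(ncol(m)))
      cols <- c("V1", "V2", "V3", "V5")
    }
    if (!all(cols %in% colnames(m)))
      stop("missing required column in sparta-plus table: ",
           paste(setdiff(cols, colnames(m)), collapse = ", "))
    df <- data.frame(residue_number = as.integer(m[, cols[1L]]),
                     residue_name = m[, cols[2L]],
                     nucleus = m[, cols[3L]],
                     shift = as.numeric(m[, cols[4L]]))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
    if (!nrow(df)) stop("format error: no data rows in '", path, "'")
    if (dialect == "generic-csv") {
      need <- c("residue_number", "residue_name", "nucleus", "shift")
      # normalized round-trip header is also accepted
      if ("shift_ppm" %in% names(df) && !"shift" %in% names(df))
        names(df)[names(df) == "shift_ppm"] <- "shift"
      if (!all(need %in% names(df)))
        stop("missing required column: ",
             paste(setdiff(need, names(df)), collapse = ", "))
      df <- df[need]
    } else if (dialect == "shiftx2") {
      need <- c("NUM", "RES", "ATOMNAME", "SHIFT")
      if (!all(need %in% names(df)))
        stop("missing required column: ",
             paste(setdiff(need, names(df)), collapse = ", "))
      df <- data.frame(residue_number = df$NUM, residue_name = df$RES,
                       nucleus = df$ATOMNAME, shift = df$SHIFT)
    } else { # ucbshift: wide, one column per atom
      numCol <- intersect(c("RESNUM", "NUM"), names(df))[1L]
      nameCol <- intersect(c("RESNAME", "RES"), names(df))[1L]
      if (is.na(numCol) || is.na(nameCol))
        stop("missing required column: RESNUM/RESNAME")
      atomCols <- intersect(names(.ATOM_MAP), names(df))
      if (!length(atomCols))
        stop("missing required column: no per-atom shift columns found")
      df <- do.call(rbind, lapply(atomCols, function(a)
        data.frame(residue_number = df[[numCol]],
                   residue_name = df[[nameCol]],
                   nucleus = a, shift = df[[a]])))
      df <- df[!is.na(df$shift), , drop = FALSE]
    }
  }
  raw <- as.character(df$nucleus)
  nucleus <- .normalizeNucleus(raw)
  attr(nucleus, "raw") <- raw
  .buildShiftTable(entityId, as.integer(df$residue_number),
                   as.character(df$residue_name), nucleus,
                   as.numeric(df$shift), what = basename(path))
}

#' Write / read the normalized chemical-shift table format
#'
#' The normalized interchange format is a CSV with header
#' \code{residue_number,residue_name,nucleus,shift_ppm} containing one row
#' per assigned entry. Values round-trip to better than 1e-6 ppm.
#'
#' @param table a \linkS4class{ShiftTable}.
#' @param path output (or input) file path.
#' @param entityId label for the table read back.
#' @return \code{writeShiftTable} returns \code{path} invisibly;
#'   \code{readShiftTable} returns a \linkS4class{ShiftTable}.
#' @export
writeShiftTable <- function(table, path) {
  v <- table@values
  idx <- which(!is.na(v), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  df <- data.frame(
    residue_number = table@residues$number[idx[, 1L]],
    residue_name = table@residues$name[idx[, 1L]],
    nucleus = NUCLEI[idx[, 2L]],
    shift_ppm = sprintf("%.8f", v[idx])
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeShiftTable
#' @export
readShiftTable <- function(path, entityId = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue_number", "residue_name", "nucleus", "shift_ppm")
  if (!all(need %in% names(df)))
    stop("missing required column: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  raw <- as.character(df$nucleus)
  nucleus <- .normalizeNucleus(raw)
  attr(nucleus, "raw") <- raw
  .buildShiftTable(entityId, as.integer(df$residue_number),
                   as.character(df$residue_name), nucleus,
                   as.numeric(df$shift_ppm), what = basename(path))
}

#' Apply the fully-assigned residue exclusion rule
#'
#' Restricts the library and the experimental reference to the residues
#' that are fully assigned for all four backbone nuclei in the reference
#' and present in every library table. Residues failing the rule — proline
#' (no amide proton) and glycine (no beta carbon) always among them — are
#' excluded and reported. Residue name mismatches between reference and
#' library are warned about, not fatal (author numbering drift between
#' depositions is common); the join is on residue number only.
#'
#' @param library a \linkS4class{ShiftLibrary}.
#' @param reference a \linkS4class{ShiftTable}.
#' @return A list with elements \code{library}, \code{reference} (both
#'   restricted to the retained residues) and \code{excluded} (integer
#'   residue numbers removed).
#' @export
applyExclusionMask <- function(library, reference) {
  refNum <- reference@residues$number
  libNum <- residueNumbers(library)
  common <- intersect(refNum, libNum)
  refName <- reference@residues$name[match(common, refNum)]
  libName <- library@tables[[1L]]@residues$name[match(common, libNum)]
  bad <- which(toupper(refName) != toupper(libName))
  if (length(bad))
    warning("residue name mismatch between reference and library at ",
            paste(common[bad], collapse = ", "))
  refOK <- refNum[rowSums(is.na(reference@values)) == 0L]
  libOK <- Reduce(intersect, lapply(library@tables, function(t)
    t@residues$number[rowSums(is.na(t@values)) == 0L]))
  keep <- intersect(intersect(refOK, libOK), common)
  excluded <- sort(union(setdiff(refNum, keep), setdiff(libNum, keep)))
  if (!length(keep))
    stop("no residues remain after the exclusion rule: reference has ",
         length(refOK), " fully assigned residues, library ",
         length(libOK), ", overlap 0")
  newRef <- subsetResidues(reference, keep)
  newTables <- lapply(library@tables, subsetResidues, numbers = keep)
  newLib <- ShiftLibrary(newTables, library@conformerIds, library@source)
  list(library = newLib, reference = newRef,
       excluded = as.integer(excluded))
}
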