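#' @include synthetic.R
NULL

#' Read a conformer ensemble from coordinates
#'
#' Reads backbone coordinates into a \linkS4class{ConformerEnsemble}.
#' \code{"pdb-multimodel"} reads a multi-model PDB through bio3d (one
#' conformer per MODEL); \code{"trajectory"} reads a DCD trajectory plus a
#' PDB topology, also through bio3d. Hydrogens are optional (the amide H is
#' needed only for order parameters); CA must be present for every residue.
#'
#' @param path coordinate file (multi-model PDB, or DCD trajectory).
#' @param format \code{"pdb-multimodel"} or \code{"trajectory"}.
#' @param topology PDB topology path (trajectory format only).
#' @return A \linkS4class{ConformerEnsemble}.
#' @export
readEnsemble <- function(path, format = c("pdb-multimodel", "trajectory"),
                         topology = NULL) {
  format <- match.arg(format)
  if (format == "pdb-multimodel") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    atom <- pdb$atom
  } else {
    if (is.null(topology))
      stop("trajectory format requires a PDB topology")
    pdb <- bio3d::read.pdb(topology, verbose = FALSE)
    atom <- pdb$atom
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    if (ncol(xyz) != nrow(atom) * 3L)
      stop("trajectory and topology atom counts differ")
  }
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nconf <- nrow(xyz)
  resno <- atom$resno
  ures <- unique(resno)
  nres <- length(ures)
  resname <- atom$resid[match(ures, resno)]
  dims <- c(nres, 3L, nconf)
  coords <- list(N = array(NA_real_, dims), H = array(NA_real_, dims),
                 CA = array(NA_real_, dims), CB = array(NA_real_, dims))
  pick <- list(N = "N", H = c("H", "HN"), CA = "CA", CB = "CB")
  for (nm in names(pick)) {
    idx <- which(atom$elety %in% pick[[nm]])
    if (!length(idx)) next
    rows <- match(resno[idx], ures)
    for (k in seq_len(nconf)) {
      m <- matrix(xyz[k, ], ncol = 3L, byrow = TRUE)
      coords[[nm]][rows, , k] <- m[idx, , drop = FALSE]
    }
  }
  if (anyNA(coords$CA))
    stop("missing CA coordinates for residue(s) ",
         paste(ures[apply(is.na(coords$CA[, 1L, , drop = FALSE]), 1L, any)],
               collapse = ", "))
  new("ConformerEnsemble",
      conformerIds = sprintf("model%d", seq_len(nconf)),
      residues = data.frame(number = as.integer(ures), name = resname),
      coords = coords, weights = numeric())
}

#' Write a conformer ensemble as a multi-model PDB
#'
#' Writes backbone atoms (N, H, CA, CB where present) of every conformer as
#' one MODEL each. Round-trips through [readEnsemble()] to coordinate
#' precision (1e-3 Angstrom, the PDB fixed-point format).
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeEnsemble <- function(ensemble, path) {
  res <- ensemble@residues
  nres <- nrow(res)
  nconf <- length(ensemble@conformerIds)
  atomOrder <- c("N", "H", "CA", "CB")
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nconf)) {
    writeLines(sprintf("MODEL     %4d", k), con)
    serial <- 0L
    for (i in seq_len(nres)) {
      for (nm in atomOrder) {
        xyz <- ensemble@coords[[nm]][i, , k]
        if (anyNA(xyz)) next
        serial <- serial + 1L
        elem <- substr(nm, 1L, 1L)
        writeLines(sprintf(
          "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", nm), " ", res$name[i], "A", res$number[i],
          " ", xyz[1], xyz[2], xyz[3], 1.0, 0.0, elem), con)
      }
    }
    writeLines(c("TER", "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

setMethod("show", "ConformerEnsemble", function(object) {
  cat("ConformerEnsemble: ", length(object@conformerIds), " conformers x ",
      nrow(object@residues), " residues",
      if (length(object@weights)) " (weighted)" else "", "\n", sep = "")
})

#' @rdname accessors
#' @export
setMethod("conformerIds", "ConformerEnsemble",
          function(object) object@conformerIds)

#' @rdname accessors
#' @export
setMethod("residueNumbers", "ConformerEnsemble",
          function(object) object@residues$number)

#' @rdname accessors
#' @export
setMethod("residueNames", "ConformerEnsemble",
          function(object) object@residues$name)

.SS_CODE_MAP <- c(H = "alpha-helix", G = "310-helix", E = "beta-sheet",
                  B = "beta-sheet", b = "beta-sheet", T = "turn",
                  C = "coil", S = "coil", I = "coil", "-" = "coil",
                  " " = "coil")

.mapSSCodes <- function(codes, map) {
  out <- map[codes]
  unknown <- unique(codes[is.na(out)])
  if (length(unknown)) {
    warning("unknown secondary-structure code(s) mapped to coil: ",
            paste(unknown, collapse = ", "))
    out[is.na(out)] <- "coil"
  }
  unname(out)
}

#' Read secondary-structure assignments (STRIDE / DSSP reports)
#'
#' Parses STRIDE or DSSP output into per-conformer residue labels on the
#' five-class alphabet \code{\link{SS_CLASSES}}. STRIDE: one \code{ASG}
#' line per residue; a new conformer block starts when the ordinal residue
#' counter restarts (or at a \code{MODEL} line). DSSP: the data section
#' after the \code{#  RESIDUE} header, summary code in column 17;
#' concatenated reports are split on repeated headers. The default code
#' mapping is H -> alpha-helix, G -> 310-helix, E/B -> beta-sheet,
#' T -> turn, everything else -> coil; unknown codes map to coil with a
#' warning. The mapping is configurable.
#'
#' @param path report file.
#' @param format \code{"stride"} or \code{"dssp"}.
#' @param map named character vector from one-letter codes to
#'   \code{SS_CLASSES}.
#' @return Character matrix (residues x conformers) of class labels with
#'   residue numbers as rownames.
#' @export
readSecondaryStructure <- function(path, format = c("stride", "dssp"),
                                   map = .SS_CODE_MAP) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  blocks <- list()
  if (format == "stride") {
    cur <- NULL
    lastOrd <- Inf
    for (ln in lines) {
      if (startsWith(ln, "MODEL")) {
        if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- cur
        cur <- NULL; lastOrd <- Inf
        next
      }
      if (!startsWith(ln, "ASG")) next
      f <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
      ord <- suppressWarnings(as.integer(f[5L]))
      if (!is.na(ord) && ord <= lastOrd && !is.null(cur) && nrow(cur) > 0) {
        blocks[[length(blocks) + 1L]] <- cur
        cur <- NULL
      }
      lastOrd <- if (is.na(ord)) lastOrd else ord
      cur <- rbind(cur, data.frame(number = as.integer(f[4L]),
                                   code = f[6L]))
    }
    if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- cur
  } else {
    headers <- grep("^\\s*#\\s+RESIDUE", lines)
    if (!length(headers)) stop("format error: no DSSP data header")
    bounds <- c(headers, length(lines) + 1L)
    for (b in seq_along(headers)) {
      rows <- lines[(bounds[b] + 1L):(bounds[b + 1L] - 1L)]
      rows <- rows[nchar(rows) >= 17]
      num <- suppressWarnings(as.integer(substr(rows, 6L, 10L)))
      code <- substr(rows, 17L, 17L)
      keep <- !is.na(num) & substr(rows, 14L, 14L) != "!"
      blocks[[length(blocks) + 1L]] <-
        data.frame(number = num[keep], code = code[keep])
    }
  }
  if (!length(blocks)) stop("format error: no assignments found")
  nres <- vapply(blocks, nrow, integer(1))
  if (length(unique(nres)) != 1L)
    stop("residue-count mismatch across conformer blocks: ",
         paste(unique(nres), collapse = ", "))
  labels <- vapply(blocks, function(b) .mapSSCodes(b$code, map),
                   character(nres[1L]))
  labels <- matrix(labels, nrow = nres[1L])
  rownames(labels) <- blocks[[1L]]$number
  labels
}
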