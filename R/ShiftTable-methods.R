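#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a ShiftTable
#'
#' @param entityId character(1) label for the entity.
#' @param residues data.frame with columns \code{number} and \code{name}.
#' @param values numeric matrix (residues x \code{NUCLEI}) of shifts in ppm;
#'   \code{NA} marks unassigned entries. Columns are reordered to the
#'   canonical nucleus order if named.
#' @return A \linkS4class{ShiftTable}.
#' @examples
#' st <- ShiftTable("toy",
#'   data.frame(number = 2:4, name = c("ALA", "LEU", "SER")),
#'   matrix(c(8.1, 8.2, 8.3, 118, 120, 122, 52, 54, 58, 19, 41, 63),
#'          nrow = 3, dimnames = list(NULL, c("HN", "NH", "CA", "CB"))))
#' assignedMask(st)
#' @export
ShiftTable <- function(entityId, residues, values) {
  residues <- data.frame(number = as.integer(residues$number),
                         name = as.character(residues$name),
                         stringsAsFactors = FALSE)
  values <- as.matrix(values)
  if (!is.null(colnames(values)))
    values <- values[, NUCLEI, drop = FALSE]
  else
    colnames(values) <- NUCLEI
  storage.mode(values) <- "double"
  rownames(values) <- as.character(residues$number)
  new("ShiftTable", entityId = as.character(entityId),
      residues = residues, values = values)
}

#' @rdname accessors
#' @export
setMethod("entityId", "ShiftTable", function(object) object@entityId)

#' @rdname accessors
#' @export
setMethod("residueNumbers", "ShiftTable",
          function(object) object@residues$number)

#' @rdname accessors
#' @export
setMethod("residueNames", "ShiftTable",
          function(object) object@residues$name)

#' @rdname accessors
#' @export
setMethod("shiftValues", "ShiftTable", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("assignedMask", "ShiftTable", function(object) !is.na(object@values))

setMethod("show", "ShiftTable", function(object) {
  cat("ShiftTable \"", object@entityId, "\": ",
      nrow(object@residues), " residues, ",
      sum(!is.na(object@values)), " assigned shifts\n", sep = "")
  if (nrow(object@residues)) {
    cat("  residues ", min(object@residues$number), "-",
        max(object@residues$number), "; assigned per nucleus: ",
        paste(sprintf("%s=%d", NUCLEI, colSums(!is.na(object@values))),
              collapse = ", "), "\n", sep = "")
  }
})

#' Subset a ShiftTable to a residue set
#'
#' @param table a \linkS4class{ShiftTable}.
#' @param numbers integer residue numbers to keep (order preserved from the
#'   table).
#' @return A \linkS4class{ShiftTable} restricted to \code{numbers}.
#' @export
subsetResidues <- function(table, numbers) {
  keep <- table@residues$number %in% numbers
  ShiftTable(table@entityId, table@residues[keep, , drop = FALSE],
             table@values[keep, , drop = FALSE])
}

#' Construct a ShiftLibrary
#'
#' @param tables list of \linkS4class{ShiftTable} objects sharing a residue
#'   list.
#' @param conformerIds character labels, one per table (defaults to the
#'   entity ids of the tables).
#' @param source character(1) free-text provenance.
#' @return A \linkS4class{ShiftLibrary}.
#' @export
ShiftLibrary <- function(tables, conformerIds = NULL, source = "unknown") {
  if (is.null(conformerIds))
    conformerIds <- vapply(tables, entityId, character(1))
  new("ShiftLibrary", conformerIds = as.character(conformerIds),
      tables = unname(tables), source = as.character(source))
}

#' @rdname accessors
#' @export
setMethod("conformerIds", "ShiftLibrary", function(object) object@conformerIds)

#' @rdname accessors
#' @export
setMethod("residueNumbers", "ShiftLibrary",
          function(object) object@tables[[1L]]@residues$number)

#' Library member access
#'
#' \code{[[} returns the \linkS4class{ShiftTable} of one conformer by index
#' or id; \code{length} the number of conformers.
#'
#' @param x a \linkS4class{ShiftLibrary}.
#' @param i integer index or conformer id.
#' @return A \linkS4class{ShiftTable}.
#' @rdname ShiftLibrary-access
#' @export
setMethod("[[", "ShiftLibrary", function(x, i) {
  if (is.character(i)) i <- match(i, x@conformerIds)
  x@tables[[i]]
})

#' @rdname ShiftLibrary-access
#' @export
setMethod("length", "ShiftLibrary", function(x) length(x@conformerIds))

setMethod("show", "ShiftLibrary", function(object) {
  cat("ShiftLibrary: ", length(object@conformerIds), " conformers x ",
      nrow(object@tables[[1L]]@residues), " residues (source: ",
      object@source, ")\n", sep = "")
})
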