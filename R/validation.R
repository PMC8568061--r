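#' @include order-parameters.R
NULL

#' Projection-space chemical-shift error
#'
#' Computes, per residue and nucleus, the scaled-space error
#' f(delta_reg) - f(delta_ref) between the regression-predicted and the
#' experimental chemical shifts, and combines the four nuclei into one
#' per-residue error. The default combination is the Euclidean
#' (root-sum-square) norm over nuclei; \code{norm = "sum"} uses the sum of
#' absolute per-nucleus errors instead (the literal summed form). A
#' nucleus missing on either side is dropped for that residue with a note.
#'
#' @param reg regression-predicted \linkS4class{ShiftTable} (delta_reg).
#' @param ref experimental reference \linkS4class{ShiftTable} (delta_ref).
#' @param model the \linkS4class{ScalingModel} fitted on the reference.
#' @param norm \code{"l2"} (default) or \code{"sum"}.
#' @return A \linkS4class{ValidationReport} (shift-error part; attach
#'   |dS2| with [attachDeltaS2()]).
#' @export
shiftError <- function(reg, ref, model, norm = c("l2", "sum")) {
  norm <- match.arg(norm)
  shared <- intersect(reg@residues$number, ref@residues$number)
  if (!length(shared)) stop("tables share no residues")
  vReg <- reg@values[match(shared, reg@residues$number), , drop = FALSE]
  vRef <- ref@values[match(shared, ref@residues$number), , drop = FALSE]
  err <- matrix(NA_real_, length(shared), length(NUCLEI),
                dimnames = list(shared, NUCLEI))
  for (nuc in NUCLEI) {
    both <- !is.na(vReg[, nuc]) & !is.na(vRef[, nuc])
    if (any(!both))
      message("nucleus ", nuc, " missing on one side for residue(s) ",
              paste(shared[!both], collapse = ", "))
    err[both, nuc] <- applyScaling(vReg[both, nuc], model, nuc) -
      applyScaling(vRef[both, nuc], model, nuc)
  }
  combined <- apply(err, 1L, function(e) {
    e <- e[!is.na(e)]
    if (!length(e)) return(NA_real_)
    if (norm == "l2") sqrt(sum(e^2)) else sum(abs(e))
  })
  new("ValidationReport", residues = as.integer(shared),
      perNucleusError = err, combinedError = as.numeric(combined),
      deltaS2 = numeric(), norm = norm)
}

#' Attach an order-parameter error track to a validation report
#'
#' @param report a \linkS4class{ValidationReport} from [shiftError()].
#' @param reg,ref \linkS4class{OrderParameterProfile}s, or a precomputed
#'   named |dS2| vector passed as \code{reg} (with \code{ref} missing).
#' @return The report with the \code{deltaS2} slot populated (NA on
#'   residues without an S2 value).
#' @export
attachDeltaS2 <- function(report, reg, ref) {
  d <- if (missing(ref)) reg else deltaS2(reg, ref)
  out <- rep(NA_real_, length(report@residues))
  idx <- match(names(d), as.character(report@residues))
  out[idx[!is.na(idx)]] <- d[!is.na(idx)]
  report@deltaS2 <- out
  validObject(report)
  report
}

#' Rank correlation between shift error and order-parameter error
#'
#' Spearman rank correlation between the per-residue combined
#' projection-space shift error and |dS2|, on the residues where both are
#' defined, together with the aligned per-residue table for plotting.
#'
#' @param report a \linkS4class{ValidationReport} with both tracks
#'   populated.
#' @return A list with \code{rho} (Spearman correlation) and \code{table}
#'   (data.frame: residue_number, shift_error, delta_s2).
#' @export
errorCorrelation <- function(report) {
  if (!length(report@deltaS2))
    stop("report has no order-parameter error track; see attachDeltaS2()")
  ok <- !is.na(report@combinedError) & !is.na(report@deltaS2)
  if (sum(ok) < 3L) stop("fewer than 3 residues with both error tracks")
  tab <- data.frame(residue_number = report@residues[ok],
                    shift_error = report@combinedError[ok],
                    delta_s2 = report@deltaS2[ok])
  rho <- stats::cor(tab$shift_error, tab$delta_s2, method = "spearman")
  list(rho = rho, table = tab)
}

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport (", object@norm, " combination): ",
      length(object@residues), " residues\n", sep = "")
  cat("  combined shift error: mean ",
      sprintf("%.4f", mean(object@combinedError, na.rm = TRUE)),
      ", max ", sprintf("%.4f", max(object@combinedError, na.rm = TRUE)),
      "\n", sep = "")
  if (length(object@deltaS2) && any(!is.na(object@deltaS2)))
    cat("  |dS2|: mean ",
        sprintf("%.4f", mean(object@deltaS2, na.rm = TRUE)), "\n",
        sep = "")
})

#' Export a validation report as CSV
#'
#' @param report a \linkS4class{ValidationReport}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeValidationReport <- function(report, path) {
  df <- data.frame(residue_number = report@residues,
                   report@perNucleusError,
                   combined_error = report@combinedError,
                   check.names = FALSE)
  if (length(report@deltaS2)) df$delta_s2 <- report@deltaS2
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
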