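#' @include structure-analysis.R
NULL

#' Largest-remainder apportionment of frame counts
#'
#' Apportions \code{total} integer copies among conformers in proportion to
#' their weights: each conformer first receives the floor of its quota
#' \code{total * w}, and the remaining copies go to the largest fractional
#' remainders (ties broken by index for determinism). Every supported
#' conformer with weight at least 1/(2 total) is guaranteed a copy.
#'
#' @param w numeric simplex weight vector.
#' @param total number of copies to distribute.
#' @return Integer vector of counts summing to \code{total}.
#' @export
apportionCounts <- function(w, total = 1000L) {
  quota <- total * w / sum(w)
  counts <- floor(quota)
  frac <- quota - counts
  left <- total - sum(counts)
  if (left > 0) {
    give <- order(frac, decreasing = TRUE)[seq_len(left)]
    counts[give] <- counts[give] + 1L
  }
  # floor guarantee for appreciably weighted conformers
  need <- which(w >= 1 / (2 * total) & counts == 0L)
  for (i in need) {
    donor <- which.max(counts)
    counts[donor] <- counts[donor] - 1L
    counts[i] <- 1L
  }
  as.integer(counts)
}

#' Expand a weighted ensemble to a fixed-size frame multiset
#'
#' Builds the input ensemble for order-parameter analysis by copying each
#' supported conformation in proportion to its regression coefficient
#' (largest-remainder apportionment), to a fixed total of frames (default
#' 1,000 structures).
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}.
#' @param weights an \linkS4class{EnsembleWeights} or named numeric vector
#'   over the ensemble's conformers.
#' @param total number of frames in the expansion.
#' @return An unweighted \linkS4class{ConformerEnsemble} with exactly
#'   \code{total} frames.
#' @export
expandEnsemble <- function(ensemble, weights, total = 1000L) {
  ids <- ensemble@conformerIds
  w <- .alignWeights(ensemble, weights)
  if (sum(w) <= 0) stop("support is empty")
  counts <- apportionCounts(w, total)
  rep_idx <- rep(seq_along(ids), counts)
  coords <- lapply(ensemble@coords, function(a)
    a[, , rep_idx, drop = FALSE])
  frameIds <- sprintf("%s.%d", ids[rep_idx],
                      sequence(counts[counts > 0]))
  new("ConformerEnsemble", conformerIds = frameIds,
      residues = ensemble@residues, coords = coords, weights = numeric())
}

#' Per-frame N-H unit vectors
#'
#' Extracts normalized N-to-H bond vectors for every residue and frame.
#' Prolines (no amide H) and residues missing N or H coordinates are
#' excluded and listed.
#'
#' @param ensemble a \linkS4class{ConformerEnsemble} with H coordinates.
#' @return A list with \code{vectors} (array: residues x 3 x frames, unit
#'   norm), \code{residues} (numbers retained) and \code{excluded}
#'   (numbers left out).
#' @export
nhVectors <- function(ensemble) {
  res <- ensemble@residues
  v <- ensemble@coords$H - ensemble@coords$N
  isPro <- res$name == "PRO"
  hasAll <- apply(!is.na(v), 1L, all)
  keep <- which(!isPro & hasAll)
  if (!length(keep)) stop("no residues with complete N-H vectors")
  v <- v[keep, , , drop = FALSE]
  nrm <- sqrt(colSums(aperm(v^2, c(2L, 1L, 3L))))
  for (d in 1:3) v[, d, ] <- v[, d, , drop = TRUE] / nrm
  list(vectors = v, residues = res$number[keep],
       excluded = res$number[-keep])
}

#' iRED order parameters from N-H vector ensembles
#'
#' Computes per-residue generalized order parameters S2 with the isotropic
#' reorientational eigenmode dynamics (iRED) approach: the matrix
#' M_ij = < P2(mu_i . mu_j) > of second-Legendre covariances over frames is
#' diagonalized, the five largest-eigenvalue modes are attributed to
#' overall reorientation, and S2_i = 1 - sum over the remaining modes of
#' lambda_m |m_i|^2. A rigid ensemble (all frames identical) gives M of
#' rank at most five, hence S2 = 1 exactly. Eigenvalues are sorted
#' descending with index tie-break for determinism; values are reported
#' raw unless clamped.
#'
#' @param vectors array (residues x 3 x frames) of unit vectors, or the
#'   list returned by [nhVectors()].
#' @param residues residue numbers (default from \code{vectors} when it is
#'   an [nhVectors()] result).
#' @param nDiscard number of overall-reorientation modes discarded
#'   (default 5).
#' @param clamp clamp S2 into [0, 1] (default FALSE: preserve diagnostic
#'   small negatives).
#' @return An \linkS4class{OrderParameterProfile} with source
#'   \code{"ensemble"}.
#' @export
iredOrderParameters <- function(vectors, residues = NULL, nDiscard = 5L,
                                clamp = FALSE) {
  excluded <- integer()
  if (is.list(vectors)) {
    if (is.null(residues)) residues <- vectors$residues
    excluded <- as.integer(vectors$excluded)
    vectors <- vectors$vectors
  }
  n <- dim(vectors)[1L]
  Tn <- dim(vectors)[3L]
  if (is.null(residues)) residues <- seq_len(n)
  if (n < nDiscard + 1L)
    stop("need more than ", nDiscard, " residues to separate internal ",
         "from overall modes; got ", n)
  if (Tn < 2L) stop("need at least 2 frames")
  M <- matrix(0, n, n)
  for (t in seq_len(Tn)) {
    V <- vectors[, , t, drop = TRUE]
    G <- tcrossprod(V)
    M <- M + 0.5 * (3 * G * G - 1)
  }
  M <- M / Tn
  eg <- eigen(M, symmetric = TRUE)   # eigenvalues descending
  keep <- seq_len(n) > nDiscard
  lam <- eg$values[keep]
  Vm <- eg$vectors[, keep, drop = FALSE]
  s2 <- 1 - as.vector(Vm^2 %*% lam)
  if (clamp) s2 <- pmin(pmax(s2, 0), 1)
  new("OrderParameterProfile", residues = as.integer(residues),
      s2 = s2, source = "ensemble", excluded = excluded)
}

#' Read an experimental order-parameter profile
#'
#' Reads a simple two-column CSV (residue_number, s2) of experimental S2
#' values, e.g. exported from chemical-shift-based predictors.
#'
#' @param path CSV file with columns \code{residue_number} and \code{s2}.
#' @return An \linkS4class{OrderParameterProfile} with source
#'   \code{"experimental"}.
#' @export
readOrderParameters <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("residue_number", "s2") %in% names(df)))
    stop("missing required column: residue_number, s2")
  new("OrderParameterProfile",
      residues = as.integer(df$residue_number),
      s2 = as.numeric(df$s2), source = "experimental",
      excluded = integer())
}

#' Write an order-parameter profile as CSV
#'
#' @param profile an \linkS4class{OrderParameterProfile}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeOrderParameters <- function(profile, path) {
  utils::write.csv(data.frame(residue_number = profile@residues,
                              s2 = profile@s2),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname accessors
#' @export
setMethod("s2Values", "OrderParameterProfile",
          function(object) stats::setNames(object@s2,
                                           object@residues))

#' @rdname accessors
#' @export
setMethod("residueNumbers", "OrderParameterProfile",
          function(object) object@residues)

setMethod("show", "OrderParameterProfile", function(object) {
  cat("OrderParameterProfile (", object@source, "): ",
      length(object@residues), " residues, mean S2 = ",
      sprintf("%.3f", mean(object@s2, na.rm = TRUE)), "\n", sep = "")
  if (length(object@excluded))
    cat("  excluded residues: ",
        paste(object@excluded, collapse = ", "), "\n", sep = "")
})

#' Absolute order-parameter difference
#'
#' |dS2| = |S2_reg - S2_ref| per residue, on the intersection of the two
#' profiles' residue sets; non-shared residues are reported in a message.
#'
#' @param reg ensemble-computed \linkS4class{OrderParameterProfile}.
#' @param ref reference \linkS4class{OrderParameterProfile}.
#' @return Named numeric vector of |dS2| over the shared residues.
#' @export
deltaS2 <- function(reg, ref) {
  shared <- intersect(reg@residues, ref@residues)
  if (!length(shared)) stop("profiles share no residues")
  mismatched <- union(setdiff(reg@residues, shared),
                      setdiff(ref@residues, shared))
  if (length(mismatched))
    message("residues present in only one profile dropped: ",
            paste(mismatched, collapse = ", "))
  d <- abs(reg@s2[match(shared, reg@residues)] -
           ref@s2[match(shared, ref@residues)])
  stats::setNames(d, shared)
}
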