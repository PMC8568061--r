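#' @include structure-io.R
NULL

# align a weight vector (EnsembleWeights or numeric) to an ensemble's
# conformers: by id when the names cover them, by position otherwise
.alignWeights <- function(ensemble, weights) {
  ids <- ensemble@conformerIds
  w <- if (is(weights, "EnsembleWeights")) weights@weights else weights
  if (!is.null(names(w)) && all(ids %in% names(w)))
    return(stats::setNames(w[ids], ids))
  if (length(w) == length(ids))
    return(stats::setNames(unname(w), ids))
  stop("weights do not cover the ensemble conformers: ",
       length(w), " weights for ", length(ids), " conformers")
}

.caCoords <- function(ensemble, conformer) {
  if (is.character(conformer))
    conformer <- match(conformer, ensemble@conformerIds)
  ensemble@coords$CA[, , conformer, drop = TRUE]
}

#' Compute a CA-CA contact map
#'
#' Boolean residue-pair matrix: TRUE iff the CA-CA distance is strictly
#' below the cutoff (default 7.5 Angstrom). Symmetric with TRUE diagonal,
#' and invariant under rigid-body motion of the coordinates.
#'
#' @param x a \linkS4class{ConformerEnsemble} or a numeric (residues x 3)
#'   CA coordinate matrix.
#' @param conformer conformer index or id (ensemble input only).
#' @param cutoff contact cutoff in Angstrom.
#' @return A \linkS4class{ContactMap}.
#' @export
contactMap <- function(x, conformer = 1L, cutoff = 7.5) {
  if (is(x, "ConformerEnsemble")) {
    ca <- .caCoords(x, conformer)
    resno <- x@residues$number
  } else {
    ca <- as.matrix(x)
    resno <- seq_len(nrow(ca))
  }
  d <- as.matrix(stats::dist(ca))
  m <- d < cutoff
  diag(m) <- TRUE
  dimnames(m) <- list(resno, resno)
  new("ContactMap", residues = as.integer(resno), map = m,
      cutoff = cutoff)
}

setMethod("show", "ContactMap", function(object) {
  n <- length(object@residues)
  cat("ContactMap: ", n, " residues, cutoff ", object@cutoff, " A, ",
      (sum(object@map) - n) / 2, " off-diagonal contacts\n", sep = "")
})

#' Geometry-based secondary-structure assignment
#'
#' A lightweight CA-geometry assigner in the DSSP tradition, used when no
#' external STRIDE/DSSP report is supplied. Helices are detected from
#' i,i+3 / i,i+4 CA distance windows (alpha and 310 parametrized
#' separately), strands from extended i-1,i+1 spacing, and beta-sheet
#' requires a partner strand within pairing distance (an isolated extended
#' chain is coil/turn only). Documented as approximate: it is not a
#' STRIDE re-implementation and is intended for synthetic backbones and
#' coarse summaries.
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}.
#' @param conformers conformer indices (default all).
#' @return Character matrix (residues x conformers) of \code{SS_CLASSES}
#'   labels, residue numbers as rownames.
#' @export
assignSecondaryStructure <- function(ensemble,
                                     conformers =
                                       seq_along(ensemble@conformerIds)) {
  nres <- nrow(ensemble@residues)
  assignOne <- function(ca) {
    lab <- rep("coil", nres)
    dk <- function(k) {
      i <- seq_len(nres - k)
      sqrt(rowSums((ca[i, , drop = FALSE] - ca[i + k, , drop = FALSE])^2))
    }
    d3 <- dk(3L); d4 <- if (nres > 4) dk(4L) else numeric()
    # alpha-helix window starting at i: d(i,i+3) ~ 5.05, d(i,i+4) ~ 6.2
    aStart <- which(d3 > 4.4 & d3 < 5.7 &
                    c(d4, Inf)[seq_along(d3)] > 5.5 &
                    c(d4, Inf)[seq_along(d3)] < 7.0)
    # 310 window: d(i,i+3) ~ 6.0, d(i,i+4) ~ 8.7
    gStart <- which(d3 >= 5.7 & d3 < 6.4 &
                    c(d4, Inf)[seq_along(d3)] > 7.8 &
                    c(d4, Inf)[seq_along(d3)] < 9.4)
    helix <- rep(FALSE, nres); g310 <- rep(FALSE, nres)
    for (s in aStart) helix[s:min(nres, s + 4L)] <- TRUE
    for (s in gStart) g310[s:min(nres, s + 3L)] <- TRUE
    # extended residues: centered i-1, i+1 span (~6.7 A for a strand)
    ext <- rep(FALSE, nres)
    if (nres >= 3) {
      i <- 2:(nres - 1)
      span <- sqrt(rowSums((ca[i - 1, , drop = FALSE] -
                            ca[i + 1, , drop = FALSE])^2))
      ext[i] <- span > 5.9 & span < 7.4
    }
    # beta-sheet: extended with an extended partner within pairing distance
    beta <- rep(FALSE, nres)
    extIdx <- which(ext)
    if (length(extIdx) >= 2) {
      d <- as.matrix(stats::dist(ca[extIdx, , drop = FALSE]))
      sep <- abs(outer(extIdx, extIdx, `-`))
      paired <- (d < 5.5) & (sep >= 3L)
      beta[extIdx[rowSums(paired) > 0]] <- TRUE
    }
    lab[beta] <- "beta-sheet"
    # chain-reversal turns among the remainder
    if (nres >= 5) {
      i <- 3:(nres - 2)
      rev <- sqrt(rowSums((ca[i - 2, , drop = FALSE] -
                           ca[i + 2, , drop = FALSE])^2))
      turn <- rep(FALSE, nres); turn[i] <- rev < 8.5
      lab[!beta & turn] <- "turn"
    }
    lab[g310] <- "310-helix"
    lab[helix] <- "alpha-helix"
    lab
  }
  out <- vapply(conformers, function(k)
    assignOne(ensemble@coords$CA[, , k, drop = TRUE]), character(nres))
  out <- matrix(out, nrow = nres)
  rownames(out) <- ensemble@residues$number
  colnames(out) <- ensemble@conformerIds[conformers]
  out
}

#' Secondary-structure proportion statistics
#'
#' From per-conformer residue labels, computes the per-residue class
#' proportions P_i(z) (each row sums to one), the beta-core residue set B
#' (strictly more than 50% beta-sheet), the per-conformer beta fraction
#' P_n = (beta count over B) / |B|, and ensemble-level class proportions.
#' When conformer weights are supplied, P_i and the ensemble-level
#' proportions are weight-averaged; B and P_n follow the same counting
#' definitions.
#'
#' @param assignments character matrix (residues x conformers) of
#'   \code{SS_CLASSES} labels (rownames = residue numbers).
#' @param weights optional per-conformer weights (normalized internally).
#' @param betaSubset optional residue numbers over which to compute the
#'   per-conformer beta fraction instead of the beta core B (e.g. one
#'   sheet's residues only).
#' @return A \linkS4class{SecondaryStructureProfile}.
#' @export
ssProportions <- function(assignments, weights = NULL, betaSubset = NULL) {
  if (is.null(rownames(assignments)))
    rownames(assignments) <- seq_len(nrow(assignments))
  resno <- as.integer(rownames(assignments))
  nconf <- ncol(assignments)
  w <- if (is.null(weights)) rep(1 / nconf, nconf) else weights / sum(weights)
  prop <- vapply(SS_CLASSES, function(z)
    as.vector((assignments == z) %*% w), numeric(nrow(assignments)))
  dimnames(prop) <- list(resno, SS_CLASSES)
  core <- resno[prop[, "beta-sheet"] > 0.5]
  subset <- if (is.null(betaSubset)) core else as.integer(betaSubset)
  rows <- match(subset, resno)
  if (length(rows) && !anyNA(rows)) {
    pn <- colSums(assignments[rows, , drop = FALSE] == "beta-sheet") /
      length(rows)
  } else {
    if (!is.null(betaSubset)) stop("betaSubset contains unknown residues")
    pn <- rep(NA_real_, nconf)
  }
  classProp <- colSums(prop) / nrow(prop)
  new("SecondaryStructureProfile", residues = resno, proportions = prop,
      betaCore = as.integer(core), perConformerBeta = as.numeric(pn),
      classProportions = classProp)
}

setMethod("show", "SecondaryStructureProfile", function(object) {
  cat("SecondaryStructureProfile: ", length(object@residues),
      " residues, beta core |B| = ", length(object@betaCore), "\n",
      sep = "")
  cat("  ensemble-level proportions: ",
      paste(sprintf("%s=%.3f", SS_CLASSES, object@classProportions),
            collapse = ", "), "\n", sep = "")
})

#' Marker-residue distance observable
#'
#' Euclidean distance between a chosen atom of two residues, per conformer
#' — the AB-loop-style observable (default CA of residues 17 and 24).
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}.
#' @param resA,resB residue numbers.
#' @param atom atom name (default \code{"CA"}).
#' @return Named numeric vector of distances (Angstrom), one per conformer.
#' @export
loopDistance <- function(ensemble, resA = 17L, resB = 24L, atom = "CA") {
  ia <- match(resA, ensemble@residues$number)
  ib <- match(resB, ensemble@residues$number)
  if (is.na(ia) || is.na(ib))
    stop("residue ", if (is.na(ia)) resA else resB, " not in the ensemble")
  arr <- ensemble@coords[[atom]]
  if (is.null(arr)) stop("unknown atom: ", atom)
  d <- sqrt(colSums((arr[ia, , ] - arr[ib, , ])^2))
  stats::setNames(d, ensemble@conformerIds)
}

#' PCA + k-means clustering of a weighted conformer ensemble
#'
#' Clusters the supported conformers of a weighted ensemble in contact-map
#' space: each conformer's CA-CA contact map (strict cutoff) is flattened
#' to its upper triangle, rows are weighted by the regression coefficients
#' (the clustered object is the predicted ensemble, whose members appear
#' with unequal probability), a weighted PCA provides the leading
#' components, and k-means (fixed seed) partitions the scores. Component
#' variances are non-increasing by construction.
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}.
#' @param weights optional \linkS4class{EnsembleWeights} or numeric vector;
#'   only conformers with positive weight are clustered (all, equally
#'   weighted, when NULL).
#' @param k number of clusters (user-chosen; no selection rule is
#'   auto-applied — see [silhouetteScores()]).
#' @param nComponents number of principal components fed to k-means.
#' @param cutoff contact cutoff in Angstrom.
#' @param seed integer seed for k-means.
#' @return A list with \code{labels} (named cluster assignment),
#'   \code{embedding} (conformers x components score matrix),
#'   \code{representatives} (highest-weight member per cluster),
#'   \code{variance} (component variances) and \code{conformers} (ids
#'   clustered).
#' @export
clusterEnsemble <- function(ensemble, weights = NULL, k, nComponents = 2L,
                            cutoff = 7.5, seed = 1L) {
  ids <- ensemble@conformerIds
  wv <- if (is.null(weights)) stats::setNames(rep(1, length(ids)), ids)
        else .alignWeights(ensemble, weights)
  sup <- which(wv > 0)
  if (k > length(sup))
    stop("k = ", k, " exceeds the ", length(sup), " supported conformers")
  w <- wv[sup] / sum(wv[sup])
  upper <- NULL
  X <- t(vapply(sup, function(i) {
    m <- contactMap(ensemble, i, cutoff)@map
    if (is.null(upper)) upper <<- upper.tri(m)
    as.numeric(m[upper])
  }, numeric(sum(upper.tri(diag(nrow(ensemble@residues)))))))
  mu <- as.vector(w %*% X)
  Xc <- sweep(X, 2L, mu)
  Xs <- Xc * sqrt(w)
  sv <- svd(Xs, nu = 0)
  nComponents <- min(nComponents, ncol(sv$v))
  V <- sv$v[, seq_len(nComponents), drop = FALSE]
  scores <- Xc %*% V
  rownames(scores) <- ids[sup]
  variance <- (sv$d^2)[seq_len(nComponents)]
  nDistinct <- nrow(unique(round(scores, 10)))
  if (nDistinct < k) {
    warning("only ", nDistinct, " distinct conformations in contact-map ",
            "space; reducing k")
    k <- nDistinct
  }
  set.seed(seed)
  km <- if (k == 1L)
    list(cluster = stats::setNames(rep(1L, nrow(scores)),
                                   rownames(scores)))
  else stats::kmeans(scores, centers = k, nstart = 25L, iter.max = 100L)
  labels <- stats::setNames(as.integer(km$cluster), ids[sup])
  reps <- vapply(seq_len(k), function(cl) {
    members <- names(labels)[labels == cl]
    members[which.max(wv[members])]
  }, character(1))
  list(labels = labels, embedding = scores, representatives = reps,
       variance = variance, conformers = ids[sup])
}

#' Average silhouette widths over a range of k
#'
#' Helper for choosing the cluster count: average silhouette width of the
#' [clusterEnsemble()] embedding for each candidate k. Advisory only —
#' the package never auto-selects k.
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}.
#' @param weights as in [clusterEnsemble()].
#' @param kRange integer vector of candidate cluster counts.
#' @param ... passed to [clusterEnsemble()].
#' @return Named numeric vector of average silhouette widths.
#' @export
silhouetteScores <- function(ensemble, weights = NULL, kRange = 2:5, ...) {
  out <- vapply(kRange, function(k) {
    cl <- clusterEnsemble(ensemble, weights, k = k, ...)
    if (length(unique(cl$labels)) < 2L) return(NA_real_)
    sil <- cluster::silhouette(cl$labels, stats::dist(cl$embedding))
    mean(sil[, "sil_width"])
  }, numeric(1))
  stats::setNames(out, kRange)
}
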