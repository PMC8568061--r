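#' @include scaling.R
NULL

#' Assemble the scaled regression problem
#'
#' Builds the design matrix and target of the constrained regression
#' y = sum_i w_i X_i + eps from a masked library and reference: every ppm
#' value is passed through the per-nucleus scaling function, and features
#' (rows) are ordered deterministically by residue number then canonical
#' nucleus order. The exclusion mask must already have been applied (no
#' missing entries are tolerated).
#'
#' @param library a masked \linkS4class{ShiftLibrary}.
#' @param reference the masked \linkS4class{ShiftTable} reference.
#' @param model a fitted \linkS4class{ScalingModel}.
#' @return A \linkS4class{RegressionProblem}.
#' @export
buildRegressionProblem <- function(library, reference, model) {
  if (length(library) < 1L) stop("empty library")
  if (!identical(residueNumbers(library), reference@residues$number))
    stop("dimension mismatch: library and reference residue lists differ; ",
         "run applyExclusionMask() first")
  if (anyNA(reference@values) ||
      any(vapply(library@tables, function(t) anyNA(t@values), logical(1))))
    stop("missing entries present; run applyExclusionMask() first")
  nres <- nrow(reference@residues)
  featureIndex <- data.frame(
    residue_number = rep(reference@residues$number, each = length(NUCLEI)),
    nucleus = rep(NUCLEI, nres),
    stringsAsFactors = FALSE
  )
  scaleTable <- function(tab) {
    s <- vapply(NUCLEI, function(n) {
      x <- tab@values[, n]
      names(x) <- rownames(tab@values)
      applyScaling(x, model, n)
    }, numeric(nres))
    as.vector(t(s))    # row-major: residue-major, nucleus-minor
  }
  design <- vapply(library@tables, scaleTable,
                   numeric(nres * length(NUCLEI)))
  colnames(design) <- library@conformerIds
  target <- scaleTable(reference)
  new("RegressionProblem", design = design, target = target,
      featureIndex = featureIndex, conformerIds = library@conformerIds)
}

# Active-set solver for min ||Xw - y||^2  s.t.  sum(w) = 1, w >= 0,
# working on the normal-equation form Q = X'X, c = X'y. Exact at
# convergence (KKT residual below tol); singular working-set systems are
# resolved by the minimum-norm solution, which also breaks ties among
# equal-residual optima.
.simplexActiveSet <- function(Q, cvec, wStart = NULL, tol = 1e-12,
                              maxIter = NULL) {
  n <- length(cvec)
  if (n == 1L) return(1)
  if (is.null(maxIter)) maxIter <- 50L * n + 100L
  if (is.null(wStart) || sum(wStart) <= 0) wStart <- rep(1 / n, n)
  w <- pmax(wStart, 0); w <- w / sum(w)
  free <- w > 0
  scaleQ <- max(abs(Q), 1)
  solveEq <- function(fr) {
    k <- sum(fr)
    K <- rbind(cbind(Q[fr, fr, drop = FALSE], 1), c(rep(1, k), 0))
    rhs <- c(cvec[fr], 1)
    sol <- tryCatch(solve(K, rhs), error = function(e)
      as.vector(MASS::ginv(K) %*% rhs))
    list(w = sol[seq_len(k)], lambda = sol[k + 1L])
  }
  for (iter in seq_len(maxIter)) {
    eq <- solveEq(free)
    wF <- eq$w
    if (min(wF) >= -1e-11) {
      wNew <- numeric(n)
      wNew[free] <- pmax(wF, 0)
      wNew <- wNew / sum(wNew)
      # stationarity on the free set gives g_F = -lambda * 1, so the
      # bound multipliers are mu_i = g_i + lambda
      g <- as.vector(Q %*% wNew) - cvec
      mu <- g + eq$lambda
      bound <- !free
      if (!any(bound) || min(mu[bound]) >= -1e-9 * scaleQ)
        return(wNew)
      j <- which(bound)[which.min(mu[bound])]
      free[j] <- TRUE
      w <- wNew
    } else {
      # step toward the equality solution until a bound blocks
      d <- numeric(n)
      d[free] <- wF - w[free]
      neg <- which(free)[wF < 0]
      alpha <- min(w[neg] / (w[neg] - wF[wF < 0]))
      blocked <- neg[w[neg] / (w[neg] - wF[wF < 0]) <= alpha + 1e-15]
      w <- pmax(w + alpha * d, 0)
      w[blocked] <- 0
      free[blocked] <- FALSE
      if (!any(free)) { free[which.max(cvec)] <- TRUE }
      w <- w / sum(w)
    }
  }
  warning("simplex active-set solver hit the iteration limit; ",
          "returning last iterate")
  w
}

.newEnsembleWeights <- function(w, ids, support, eps, residual) {
  names(w) <- ids
  new("EnsembleWeights", weights = w, support = support,
      thresholdEps = eps,
      perAtomR2 = stats::setNames(rep(NA_real_, 4), NUCLEI),
      totalR2 = NA_real_, residualNorm = residual)
}

#' Solve the simplex-constrained non-negative least-squares problem
#'
#' Minimizes ||y - Xw||^2 subject to w >= 0 and sum(w) = 1, the constraint
#' set under which coefficients are interpretable as conformer appearance
#' probabilities. The solve is two-stage: a Lawson-Hanson non-negative
#' least-squares pass (sum unconstrained) provides the warm start, and an
#' exact active-set quadratic program enforces the equality constraint to
#' KKT optimality. All-zero design columns are dropped with a warning
#' (their weight is reported as zero).
#'
#' @param problem a \linkS4class{RegressionProblem}.
#' @return An \linkS4class{EnsembleWeights} (pre-selection: the support is
#'   the set of strictly positive weights).
#' @seealso [selectFeatures()], [refitOnSupport()], [simplexGridSearch()]
#' @export
solveEnsembleWeights <- function(problem) {
  X <- problem@design
  y <- problem@target
  ids <- problem@conformerIds
  zero <- colSums(abs(X)) == 0
  if (any(zero)) {
    warning("dropping all-zero design column(s): ",
            paste(ids[zero], collapse = ", "))
    X <- X[, !zero, drop = FALSE]
  }
  keptIds <- ids[!zero]
  if (ncol(X) == 0L) stop("degenerate design: no usable columns")
  if (ncol(X) == 1L) {
    wk <- 1
  } else {
    nn <- tryCatch(pracma::lsqnonneg(X, y)$x, error = function(e) NULL)
    start <- if (!is.null(nn) && sum(nn) > 0) nn / sum(nn) else NULL
    Q <- crossprod(X)
    cvec <- as.vector(crossprod(X, y))
    wk <- .simplexActiveSet(Q, cvec, start)
  }
  w <- numeric(length(ids))
  w[!zero] <- wk
  residual <- sqrt(sum((y - as.vector(X %*% wk))^2))
  .newEnsembleWeights(w, ids, keptIds[wk > 0], 1e-5, residual)
}

#' Select the significant coefficient set
#'
#' Applies the relative selection rule S = \{j : w_j >= eps * max(w)\}
#' (inclusive comparison), with the default threshold eps = 1e-5. The
#' maximum-weight conformer is always selected, so S is never empty.
#'
#' @param weights an \linkS4class{EnsembleWeights}.
#' @param eps relative threshold (default 1e-5).
#' @return Character vector of selected conformer ids, in library order.
#' @export
selectFeatures <- function(weights, eps = 1e-5) {
  w <- weights@weights
  names(w)[w >= eps * max(w)]
}

#' Refit the constrained regression on the selected support
#'
#' Re-solves the simplex-constrained least-squares problem restricted to
#' the selected conformer set S; conformers outside S receive weight
#' exactly zero. Since S contains the maximum-weight conformer the
#' restricted simplex is always feasible.
#'
#' @param problem a \linkS4class{RegressionProblem}.
#' @param support character vector of selected conformer ids (from
#'   [selectFeatures()]).
#' @param eps the selection threshold to record (default 1e-5).
#' @return The final \linkS4class{EnsembleWeights}, supported on
#'   \code{support}.
#' @export
refitOnSupport <- function(problem, support, eps = 1e-5) {
  if (!length(support)) stop("support must be nonempty")
  idx <- match(support, problem@conformerIds)
  if (anyNA(idx)) stop("unknown conformer id in support")
  X <- problem@design[, idx, drop = FALSE]
  y <- problem@target
  if (length(idx) == 1L) {
    wk <- 1
  } else {
    Q <- crossprod(X)
    cvec <- as.vector(crossprod(X, y))
    wk <- .simplexActiveSet(Q, cvec)
  }
  w <- numeric(length(problem@conformerIds))
  w[idx] <- wk
  residual <- sqrt(sum((y - as.vector(X %*% wk))^2))
  .newEnsembleWeights(w, problem@conformerIds, support, eps, residual)
}

#' Score a weighted ensemble: per-nucleus and total R-squared
#'
#' Computes the coefficient of determination R^2 = 1 - RSS/TSS per nucleus
#' over that nucleus's residues, in original ppm space: the scaled-space
#' prediction Xw is mapped back through the inverse scaling function before
#' comparison with the ppm reference. The total score is the product of the
#' four per-nucleus scores. A nucleus with zero total sum of squares has an
#' undefined score, reported as NA with a warning.
#'
#' @param problem the \linkS4class{RegressionProblem} that was solved.
#' @param weights an \linkS4class{EnsembleWeights}.
#' @param model the \linkS4class{ScalingModel} used to build the problem.
#' @return \code{weights} with the \code{perAtomR2} and \code{totalR2}
#'   slots filled in.
#' @seealso [totalScore()]
#' @export
scoreEnsemble <- function(problem, weights, model) {
  w <- weights@weights[problem@conformerIds]
  pred <- as.vector(problem@design %*% w)
  r2 <- vapply(NUCLEI, function(nuc) {
    sel <- problem@featureIndex$nucleus == nuc
    yk <- invertScaling(problem@target[sel], model, nuc)
    yhat <- invertScaling(pred[sel], model, nuc)
    tss <- sum((yk - mean(yk))^2)
    if (tss == 0) return(NA_real_)
    1 - sum((yk - yhat)^2) / tss
  }, numeric(1))
  if (anyNA(r2))
    warning("undefined score (TSS = 0) for nucleus ",
            paste(NUCLEI[is.na(r2)], collapse = ", "))
  weights@perAtomR2 <- r2
  weights@totalR2 <- totalScore(r2)
  validObject(weights)
  weights
}

#' Total regression score
#'
#' The total score combining all backbone nuclei: the product of the four
#' per-nucleus coefficients of determination,
#' R2_total = prod over atoms in \{HN, NH, CA, CB\} of R2_atom.
#'
#' @param perAtom numeric vector of per-nucleus R^2 values.
#' @return numeric(1), the product (NA if any input is NA).
#' @examples
#' totalScore(c(0.8737, 0.9146, 0.9686, 0.9963))
#' @export
totalScore <- function(perAtom) {
  if (anyNA(perAtom)) return(NA_real_)
  prod(perAtom)
}

#' Predict the reference shifts from a weighted ensemble
#'
#' Returns the regression-predicted chemical-shift table delta_reg: the
#' per-(residue, nucleus) convex combination of the library tables in ppm
#' space under the final weights.
#'
#' @param weights an \linkS4class{EnsembleWeights}.
#' @param library the \linkS4class{ShiftLibrary} the weights refer to.
#' @param entityId label for the predicted table.
#' @return A \linkS4class{ShiftTable}.
#' @export
predictShifts <- function(weights, library, entityId = "regression") {
  w <- weights@weights[library@conformerIds]
  if (anyNA(w)) stop("weights and library conformer ids do not match")
  sup <- which(w > 0)
  vals <- Reduce(`+`, lapply(sup, function(i)
    w[i] * library@tables[[i]]@values))
  ShiftTable(entityId, library@tables[[1L]]@residues, vals)
}

#' @rdname accessors
#' @export
setMethod("ensembleWeights", "EnsembleWeights", function(object) object@weights)

#' @rdname accessors
#' @export
setMethod("supportSet", "EnsembleWeights", function(object) object@support)

#' @rdname accessors
#' @export
setMethod("perAtomR2", "EnsembleWeights", function(object) object@perAtomR2)

#' @rdname accessors
#' @export
setMethod("totalR2", "EnsembleWeights", function(object) object@totalR2)

#' @rdname accessors
#' @export
setMethod("residualNorm", "EnsembleWeights",
          function(object) object@residualNorm)

setMethod("show", "EnsembleWeights", function(object) {
  w <- object@weights
  cat("EnsembleWeights: ", length(w), " conformers, support ",
      length(object@support), " (eps = ", object@thresholdEps, ")\n",
      sep = "")
  top <- sort(w[w > 0], decreasing = TRUE)
  top <- utils::head(top, 5)
  cat("  top weights: ",
      paste(sprintf("%s=%.4f", names(top), top), collapse = ", "), "\n",
      sep = "")
  if (!anyNA(object@perAtomR2))
    cat("  per-atom R2: ",
        paste(sprintf("%s=%.4f", NUCLEI, object@perAtomR2),
              collapse = ", "),
        "; total ", sprintf("%.4f", object@totalR2), "\n", sep = "")
  cat("  scaled-space residual norm: ",
      format(object@residualNorm, digits = 6), "\n", sep = "")
})

#' Brute-force simplex grid search (validation oracle)
#'
#' Enumerates the probability simplex at a fixed step and returns the grid
#' point minimizing ||y - Xw||^2. Pure enumeration, independent of the
#' active-set solver; intended to validate solutions of small problems
#' (<= 4 conformers at step 0.001 is practical).
#'
#' @param X design matrix (features x conformers, at most a handful of
#'   columns).
#' @param y target vector.
#' @param step grid resolution on each coordinate (default 0.001).
#' @return A list with \code{w} (best grid point) and \code{objective}.
#' @export
simplexGridSearch <- function(X, y, step = 0.001) {
  n <- ncol(X)
  if (n > 5L) stop("grid enumeration is practical only for <= 5 columns")
  m <- as.integer(round(1 / step))
  Q <- crossprod(X)
  cvec <- as.vector(crossprod(X, y))
  res <- simplex_grid_search_cpp(Q, cvec, m)
  w <- res$w
  names(w) <- colnames(X)
  list(w = w, objective = res$objective + sum(y^2))
}
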