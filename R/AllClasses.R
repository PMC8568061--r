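#' @import methods
NULL

#' Canonical backbone nuclei
#'
#' The four backbone nuclei used throughout the package, in canonical order:
#' the amide proton (HN), the amide nitrogen (NH), the alpha carbon (CA) and
#' the beta carbon (CB). All dialect-specific atom names are mapped onto this
#' key space on read.
#'
#' @format Character vector of length 4.
#' @export
NUCLEI <- c("HN", "NH", "CA", "CB")

#' Secondary-structure classes
#'
#' The five-class secondary-structure alphabet used by the assignment parsers
#' and proportion statistics.
#'
#' @format Character vector of length 5.
#' @export
SS_CLASSES <- c("alpha-helix", "beta-sheet", "310-helix", "coil", "turn")

#' ShiftTable: per-residue backbone chemical shifts
#'
#' Holds backbone chemical shifts (ppm) for one entity: the experimental
#' reference or one library conformer. Values are stored as a residues x
#' nuclei matrix over the canonical nucleus set \code{\link{NUCLEI}}; an
#' unassigned (residue, nucleus) entry is \code{NA} (no sentinel numbers).
#'
#' @slot entityId character(1) free-text label.
#' @slot residues data.frame with columns \code{number} (integer, strictly
#'   increasing) and \code{name} (3-letter residue code).
#' @slot values numeric matrix, rows = residues, columns = \code{NUCLEI};
#'   \code{NA} marks unassigned entries.
#'
#' @seealso [ShiftTable()], [assignedMask()], [shiftValues()]
#' @export
setClass("ShiftTable",
  representation(
    entityId = "character",
    residues = "data.frame",
    values = "matrix"
  )
)

setValidity("ShiftTable", function(object) {
  msg <- character()
  res <- object@residues
  if (!all(c("number", "name") %in% names(res)))
    msg <- c(msg, "residues must have columns 'number' and 'name'")
  else {
    if (nrow(res) > 0 && any(diff(res$number) <= 0))
      msg <- c(msg, "residue numbers must be strictly increasing")
  }
  v <- object@values
  if (!identical(colnames(v), NUCLEI))
    msg <- c(msg, sprintf("value columns must be exactly {%s}",
                          paste(NUCLEI, collapse = ", ")))
  if (nrow(v) != nrow(res))
    msg <- c(msg, "values must have one row per residue")
  if (length(object@entityId) != 1L)
    msg <- c(msg, "entityId must be length 1")
  if (any(is.infinite(v)))
    msg <- c(msg, "shift values must be finite or NA")
  if (length(msg)) msg else TRUE
})

#' ShiftLibrary: a set of per-conformer shift tables
#'
#' An ordered collection of \linkS4class{ShiftTable} objects, one per
#' candidate conformer of the structural library. All member tables share
#' the same residue list and nucleus set.
#'
#' @slot conformerIds character vector of conformer labels (length n >= 1).
#' @slot tables list of \linkS4class{ShiftTable}, parallel to
#'   \code{conformerIds}.
#' @slot source character(1) free-text provenance (predictor name,
#'   trajectory name).
#'
#' @seealso [ShiftLibrary()], [applyExclusionMask()]
#' @export
setClass("ShiftLibrary",
  representation(
    conformerIds = "character",
    tables = "list",
    source = "character"
  )
)

setValidity("ShiftLibrary", function(object) {
  msg <- character()
  n <- length(object@conformerIds)
  if (n < 1L) msg <- c(msg, "library must contain at least one conformer")
  if (length(object@tables) != n)
    msg <- c(msg, "one table per conformer id required")
  if (anyDuplicated(object@conformerIds))
    msg <- c(msg, "conformer ids must be unique")
  if (n >= 1L && length(object@tables) == n) {
    if (!all(vapply(object@tables, is, logical(1), "ShiftTable")))
      msg <- c(msg, "all tables must be ShiftTable objects")
    else {
      ref <- object@tables[[1L]]@residues$number
      same <- vapply(object@tables, function(t)
        identical(t@residues$number, ref), logical(1))
      if (!all(same))
        msg <- c(msg, "all tables must share the same residue list")
    }
  }
  if (length(object@source) != 1L)
    msg <- c(msg, "source must be length 1")
  if (length(msg)) msg else TRUE
})

#' ScalingModel: per-nucleus log min-max scaling parameters
#'
#' Parameters of the per-nucleus scaling map
#' \deqn{f(x) = \log_a\!\left(\frac{x - y_{min}}{y_{max} - y_{min}} + 1\right) + \theta}
#' and its inverse. \code{ymin}/\code{ymax} are taken from the experimental
#' reference; \code{a} is the logarithm base (bounded to [1.1, 10]);
#' \code{theta} is an additive offset in scaled units, tuned for the amide
#' proton only and fixed at zero for the other nuclei.
#'
#' @slot params numeric matrix with rows \code{NUCLEI} and columns
#'   \code{a}, \code{theta}, \code{ymin}, \code{ymax}.
#'
#' @seealso [fitReferenceRange()], [applyScaling()], [invertScaling()],
#'   [tuneScaling()]
#' @export
setClass("ScalingModel", representation(params = "matrix"))

setValidity("ScalingModel", function(object) {
  p <- object@params
  msg <- character()
  if (!identical(rownames(p), NUCLEI) ||
      !identical(colnames(p), c("a", "theta", "ymin", "ymax")))
    return("params must be a NUCLEI x {a, theta, ymin, ymax} matrix")
  if (any(!is.finite(p)))
    msg <- c(msg, "all parameters must be finite")
  if (any(p[, "ymax"] <= p[, "ymin"]))
    msg <- c(msg, "ymax must exceed ymin for every nucleus")
  if (any(p[, "a"] < 1.1 - 1e-12 | p[, "a"] > 10 + 1e-12))
    msg <- c(msg, "base a must lie in [1.1, 10]")
  other <- setdiff(NUCLEI, "HN")
  if (any(p[other, "theta"] != 0))
    msg <- c(msg, "theta must be 0 for nuclei other than HN")
  if (length(msg)) msg else TRUE
})

#' RegressionProblem: assembled design for the simplex-constrained fit
#'
#' The scaled design matrix and target of the multiple linear regression
#' y = sum_i w_i X_i + eps. Rows are (residue, nucleus) features in a
#' deterministic order (by residue number, then canonical nucleus order);
#' columns are library conformers. The exclusion mask must already have been
#' applied, so no entry is missing.
#'
#' @slot design numeric matrix, features x conformers, of scaled shifts.
#' @slot target numeric vector of scaled reference shifts.
#' @slot featureIndex data.frame with columns \code{residue_number},
#'   \code{nucleus}, parallel to design rows.
#' @slot conformerIds character, parallel to design columns.
#'
#' @seealso [buildRegressionProblem()], [solveEnsembleWeights()]
#' @export
setClass("RegressionProblem",
  representation(
    design = "matrix",
    target = "numeric",
    featureIndex = "data.frame",
    conformerIds = "character"
  )
)

setValidity("RegressionProblem", function(object) {
  msg <- character()
  if (anyNA(object@design) || anyNA(object@target))
    msg <- c(msg, "design and target must contain no missing entries")
  if (nrow(object@design) != length(object@target))
    msg <- c(msg, "design rows must match target length")
  if (ncol(object@design) != length(object@conformerIds))
    msg <- c(msg, "design columns must match conformerIds")
  if (nrow(object@featureIndex) != nrow(object@design))
    msg <- c(msg, "featureIndex must have one row per feature")
  fi <- object@featureIndex
  if (all(c("residue_number", "nucleus") %in% names(fi)) && nrow(fi) > 1) {
    key <- order(fi$residue_number, match(fi$nucleus, NUCLEI))
    if (!identical(key, seq_len(nrow(fi))))
      msg <- c(msg, "features must be ordered by (residue_number, nucleus)")
  }
  if (length(msg)) msg else TRUE
})

#' EnsembleWeights: simplex-constrained conformer weights and scores
#'
#' The coefficient vector of the constrained regression: non-negative weights
#' over library conformers summing to one, together with the selected support,
#' the selection threshold, the residual norm of the scaled-space fit, and
#' (after scoring) per-nucleus and total coefficients of determination.
#'
#' @slot weights named numeric vector over all conformers; entries outside
#'   the support are exactly zero after refitting.
#' @slot support character vector of selected conformer ids.
#' @slot thresholdEps numeric(1), relative selection threshold (default 1e-5).
#' @slot perAtomR2 named numeric over \code{NUCLEI} (NA before scoring).
#' @slot totalR2 numeric(1), product of the per-nucleus scores.
#' @slot residualNorm numeric(1), 2-norm of the scaled-space residual.
#'
#' @seealso [solveEnsembleWeights()], [selectFeatures()], [refitOnSupport()],
#'   [scoreEnsemble()]
#' @export
setClass("EnsembleWeights",
  representation(
    weights = "numeric",
    support = "character",
    thresholdEps = "numeric",
    perAtomR2 = "numeric",
    totalR2 = "numeric",
    residualNorm = "numeric"
  )
)

setValidity("EnsembleWeights", function(object) {
  w <- object@weights
  msg <- character()
  if (is.null(names(w)))
    msg <- c(msg, "weights must be named by conformer id")
  if (any(w < 0))
    msg <- c(msg, "all weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-8)
    msg <- c(msg, "weights must sum to 1 within 1e-8")
  if (!all(object@support %in% names(w)))
    msg <- c(msg, "support must be a subset of conformer ids")
  off <- setdiff(names(w), object@support)
  if (length(off) && any(w[off] != 0))
    msg <- c(msg, "weights outside the support must be exactly zero")
  r2 <- object@perAtomR2
  if (!identical(names(r2), NUCLEI))
    msg <- c(msg, "perAtomR2 must be named by the canonical nuclei")
  if (!anyNA(r2) && length(object@totalR2) == 1 && !is.na(object@totalR2) &&
      abs(object@totalR2 - prod(r2)) > 1e-12)
    msg <- c(msg, "totalR2 must equal the product of perAtomR2 within 1e-12")
  if (length(msg)) msg else TRUE
})

#' ConformerEnsemble: backbone coordinates for an ordered conformer set
#'
#' Backbone coordinates (Angstrom) of an ordered set of conformers sharing
#' one residue list. Atoms N, H, CA, CB are stored as (residue, xyz,
#' conformer) arrays; CA must be present for every residue, H and CB may be
#' absent (NA) where chemistry dictates (proline has no amide H, glycine no
#' CB). Optionally carries per-conformer weights.
#'
#' @slot conformerIds character vector of frame/conformer labels.
#' @slot residues data.frame with columns \code{number}, \code{name}.
#' @slot coords named list of arrays \code{N}, \code{H}, \code{CA}, \code{CB},
#'   each of dim (n_residues, 3, n_conformers).
#' @slot weights numeric, per-conformer weight (length 0 when unweighted).
#'
#' @seealso [readEnsemble()], [makeToyEnsemble()], [expandEnsemble()]
#' @export
setClass("ConformerEnsemble",
  representation(
    conformerIds = "character",
    residues = "data.frame",
    coords = "list",
    weights = "numeric"
  )
)

setValidity("ConformerEnsemble", function(object) {
  msg <- character()
  nres <- nrow(object@residues)
  nconf <- length(object@conformerIds)
  if (nconf < 1L) msg <- c(msg, "at least one conformer required")
  if (!all(c("N", "H", "CA", "CB") %in% names(object@coords)))
    msg <- c(msg, "coords must contain arrays N, H, CA, CB")
  else {
    ok <- vapply(object@coords[c("N", "H", "CA", "CB")], function(a)
      is.array(a) && length(dim(a)) == 3 &&
        all(dim(a) == c(nres, 3L, nconf)), logical(1))
    if (!all(ok))
      msg <- c(msg, "each coords array must be (n_residues, 3, n_conformers)")
    else {
      if (anyNA(object@coords$CA) || any(is.infinite(object@coords$CA)))
        msg <- c(msg, "CA coordinates must be finite for every residue")
      if (any(vapply(object@coords, function(a) any(is.infinite(a)),
                     logical(1))))
        msg <- c(msg, "coordinates must be finite or NA")
    }
  }
  if (length(object@weights) &&
      length(object@weights) != nconf)
    msg <- c(msg, "weights, when present, must be one per conformer")
  if (length(msg)) msg else TRUE
})

#' ContactMap: boolean residue-residue contact matrix
#'
#' Symmetric boolean matrix of CA-CA contacts under a strict distance
#' cutoff (default 7.5 Angstrom); the diagonal is TRUE.
#'
#' @slot residues integer vector of residue numbers.
#' @slot map logical matrix, symmetric with TRUE diagonal.
#' @slot cutoff numeric(1) contact cutoff in Angstrom.
#'
#' @seealso [contactMap()]
#' @export
setClass("ContactMap",
  representation(residues = "integer", map = "matrix", cutoff = "numeric")
)

setValidity("ContactMap", function(object) {
  m <- object@map
  msg <- character()
  if (!is.logical(m)) msg <- c(msg, "map must be logical")
  if (nrow(m) != ncol(m) || nrow(m) != length(object@residues))
    msg <- c(msg, "map must be square over the residues")
  else {
    if (!isTRUE(all(m == t(m)))) msg <- c(msg, "map must be symmetric")
    if (!all(diag(m))) msg <- c(msg, "diagonal must be TRUE")
  }
  if (length(msg)) msg else TRUE
})

#' SecondaryStructureProfile: per-residue class proportions
#'
#' Per-residue proportions P_i(z) of the five secondary-structure classes
#' over an ensemble, the beta-core residue set B (residues with strictly
#' more than 50% beta-sheet), the per-conformer beta fraction P_n computed
#' over B, and ensemble-level class proportions.
#'
#' @slot residues integer residue numbers.
#' @slot proportions numeric matrix, residues x \code{SS_CLASSES}; rows sum
#'   to one.
#' @slot betaCore integer residue numbers with P_i(beta-sheet) > 0.5.
#' @slot perConformerBeta numeric, beta-sheet fraction of each conformer over
#'   the beta core (NA when the core is empty).
#' @slot classProportions named numeric over \code{SS_CLASSES}: ensemble-level
#'   class fractions (weight-averaged when conformer weights were supplied).
#'
#' @seealso [ssProportions()]
#' @export
setClass("SecondaryStructureProfile",
  representation(
    residues = "integer",
    proportions = "matrix",
    betaCore = "integer",
    perConformerBeta = "numeric",
    classProportions = "numeric"
  )
)

setValidity("SecondaryStructureProfile", function(object) {
  p <- object@proportions
  msg <- character()
  if (!identical(colnames(p), SS_CLASSES))
    msg <- c(msg, "proportion columns must be the canonical SS classes")
  if (nrow(p) != length(object@residues))
    msg <- c(msg, "one proportion row per residue required")
  if (nrow(p) > 0 && any(abs(rowSums(p) - 1) > 1e-12))
    msg <- c(msg, "per-residue proportions must sum to 1 within 1e-12")
  if (identical(colnames(p), SS_CLASSES)) {
    core <- object@residues[p[, "beta-sheet"] > 0.5]
    if (!identical(sort(object@betaCore), sort(as.integer(core))))
      msg <- c(msg, "betaCore must be exactly {i : P_i(beta-sheet) > 0.5}")
  }
  pn <- object@perConformerBeta
  if (length(pn) && any(!is.na(pn) & (pn < 0 | pn > 1)))
    msg <- c(msg, "per-conformer beta fractions must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' OrderParameterProfile: per-residue N-H order parameters
#'
#' Per-residue generalized order parameters S2 with provenance. Values are
#' reported raw (small negatives possible from finite sampling) and must lie
#' in [-0.1, 1 + 1e-6]; an optional clamp to [0, 1] is available at
#' computation time.
#'
#' @slot residues integer residue numbers.
#' @slot s2 numeric per-residue order parameters.
#' @slot source character(1), "experimental" or "ensemble".
#' @slot excluded integer residue numbers left out (prolines, missing H).
#'
#' @seealso [iredOrderParameters()], [deltaS2()]
#' @export
setClass("OrderParameterProfile",
  representation(
    residues = "integer",
    s2 = "numeric",
    source = "character",
    excluded = "integer"
  )
)

setValidity("OrderParameterProfile", function(object) {
  msg <- character()
  if (length(object@s2) != length(object@residues))
    msg <- c(msg, "one s2 value per residue required")
  if (any(!is.na(object@s2) &
          (object@s2 < -0.1 | object@s2 > 1 + 1e-6)))
    msg <- c(msg, "s2 values must lie in [-0.1, 1 + 1e-6]")
  if (length(object@source) != 1L ||
      !object@source %in% c("experimental", "ensemble"))
    msg <- c(msg, "source must be 'experimental' or 'ensemble'")
  if (length(msg)) msg else TRUE
})

#' ValidationReport: projection-space shift errors and S2 differences
#'
#' Per-residue, per-nucleus scaled chemical-shift errors f(delta_reg) -
#' f(delta_ref), their per-residue combined norm, and (optionally) the
#' per-residue absolute order-parameter difference |dS2| for correlation
#' analysis.
#'
#' @slot residues integer residue numbers.
#' @slot perNucleusError numeric matrix, residues x \code{NUCLEI}, of scaled
#'   errors (NA where a nucleus is missing on one side).
#' @slot combinedError numeric per-residue combined error (>= 0).
#' @slot deltaS2 numeric per-residue |dS2| (NA until attached).
#' @slot norm character(1), "l2" (root-sum-square over nuclei) or "sum"
#'   (sum of absolute per-nucleus errors).
#'
#' @seealso [shiftError()], [errorCorrelation()]
#' @export
setClass("ValidationReport",
  representation(
    residues = "integer",
    perNucleusError = "matrix",
    combinedError = "numeric",
    deltaS2 = "numeric",
    norm = "character"
  )
)

setValidity("ValidationReport", function(object) {
  msg <- character()
  n <- length(object@residues)
  if (nrow(object@perNucleusError) != n ||
      !identical(colnames(object@perNucleusError), NUCLEI))
    msg <- c(msg, "perNucleusError must be residues x canonical nuclei")
  if (length(object@combinedError) != n)
    msg <- c(msg, "one combined error per residue required")
  if (any(object@combinedError < 0, na.rm = TRUE))
    msg <- c(msg, "combined error must be non-negative")
  if (length(object@deltaS2) && length(object@deltaS2) != n)
    msg <- c(msg, "deltaS2, when present, must be one value per residue")
  if (!object@norm %in% c("l2", "sum"))
    msg <- c(msg, "norm must be 'l2' or 'sum'")
  if (length(msg)) msg else TRUE
})
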