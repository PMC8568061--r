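#' @include regression.R constants.R
NULL

.unit <- function(v) v / sqrt(sum(v^2))

.rotationFromQuaternion <- function(q) {
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(
    a*a + b*b - c*c - d*d, 2*(b*c - a*d),         2*(b*d + a*c),
    2*(b*c + a*d),         a*a - b*b + c*c - d*d, 2*(c*d - a*b),
    2*(b*d - a*c),         2*(c*d + a*b),         a*a - b*b - c*c + d*d
  ), 3, 3, byrow = TRUE)
}

.randomRotation <- function() .rotationFromQuaternion(stats::rnorm(4))

#' Specification for the synthetic fixture generators
#'
#' Bundles the study conditions the synthetic layer emulates: library size,
#' chain length, the ground-truth simplex weights of the reference mixture,
#' per-nucleus shift noise (the conformer-to-conformer spread a shift
#' predictor would produce), reference measurement noise, per-residue cone
#' motion amplitudes, and the seed. Defaults describe a transthyretin-like
#' problem at desk scale: a 127-residue chain, a 200-conformer library, a
#' three-state mixture (0.5/0.3/0.2) and predictor-scale shift noise.
#'
#' @param nConformers number of library conformers.
#' @param nResidues chain length.
#' @param activeWeights ground-truth simplex weight vector over conformers;
#'   either full length or a named sparse vector (names = conformer index).
#' @param noiseSigma named per-nucleus standard deviation (ppm) of the
#'   library shift noise.
#' @param referenceNoise per-nucleus sd (ppm) of noise added to the mixed
#'   reference (scalar recycled; default 0, a noiseless mixture).
#' @param motion per-residue cone semi-angle in degrees (recycled).
#' @param seed integer seed recorded in all outputs.
#' @return A validated list of class \code{"SyntheticSpec"}.
#' @export
syntheticSpec <- function(nConformers = 200, nResidues = 127,
                          activeWeights = c(`1` = 0.5, `2` = 0.3, `3` = 0.2),
                          noiseSigma = c(HN = 0.1, NH = 1.0,
                                         CA = 0.4, CB = 0.4),
                          referenceNoise = 0,
                          motion = 15,
                          seed = 1) {
  w <- numeric(nConformers)
  if (!is.null(names(activeWeights)) &&
      length(activeWeights) < nConformers) {
    w[as.integer(names(activeWeights))] <- activeWeights
  } else {
    if (length(activeWeights) != nConformers)
      stop("activeWeights must be full length or a named sparse vector")
    w <- activeWeights
  }
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("activeWeights must lie on the probability simplex")
  sigma <- noiseSigma[NUCLEI]
  if (anyNA(sigma) || any(sigma < 0))
    stop("noiseSigma must be named by the canonical nuclei and >= 0")
  structure(list(
    nConformers = as.integer(nConformers),
    nResidues = as.integer(nResidues),
    activeWeights = w,
    noiseSigma = sigma,
    referenceNoise = rep_len(as.numeric(referenceNoise), 4),
    motion = rep_len(as.numeric(motion), nResidues),
    seed = as.integer(seed)
  ), class = "SyntheticSpec")
}

.AA_POOL <- c("ALA", "ARG", "ASN", "ASP", "GLN", "GLU", "HIS", "ILE",
              "LEU", "LYS", "MET", "PHE", "SER", "THR", "TRP", "TYR", "VAL")

.randomSequence <- function(n) {
  seqs <- sample(.AA_POOL, n, replace = TRUE)
  # sprinkle in glycine and proline so the exclusion rule always has work
  nGly <- max(1L, round(0.07 * n))
  nPro <- max(1L, round(0.04 * n))
  pos <- sample(n, nGly + nPro)
  seqs[pos[seq_len(nGly)]] <- "GLY"
  seqs[pos[nGly + seq_len(nPro)]] <- "PRO"
  seqs
}

# segment builders: CA trace in a local frame, helix/strand axis along +z
.helixTrace <- function(L, r = 2.3, omega = 100 * pi / 180, rise = 1.5) {
  i <- seq_len(L) - 1
  cbind(r * cos(omega * i), r * sin(omega * i), rise * i)
}

.strandTrace <- function(L, amp = 0.95, rise = 3.35) {
  i <- seq_len(L) - 1
  cbind(amp * (-1)^i, 0, rise * i)
}

.coilTrace <- function(L, maxTurn = 40 * pi / 180) {
  p <- matrix(0, L, 3)
  dir <- c(0, 0, 1)
  for (i in 2:L) {
    ax <- .unit(stats::rnorm(3))
    ang <- stats::runif(1, 0, maxTurn)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    Rm <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    dir <- .unit(as.vector(Rm %*% dir))
    p[i, ] <- p[i - 1, ] + 3.8 * dir
  }
  p
}

.hairpinTrace <- function(L, sep = 4.8, rise = 3.35) {
  nTurn <- 3L
  n1 <- ceiling((L - nTurn) / 2)
  n2 <- L - nTurn - n1
  up <- .strandTrace(n1, rise = rise)
  top <- up[n1, 3]
  turn <- cbind(c(1.6, sep - 1.6, sep / 2),
                c(1.2, 1.2, 2.2),
                top + c(2.2, 2.2, 3.4))[seq_len(nTurn), , drop = FALSE]
  # phase-match the down-strand zigzag to the up strand so paired
  # residues sit at the sheet separation exactly
  j <- seq_len(n2)
  down <- cbind(sep + 0.95 * (-1)^(n1 - j), 0, top - rise * (j - 1))
  rbind(up, turn, down)
}

#' Generate a toy backbone conformer ensemble
#'
#' Builds backbone traces (CA, with N, H and CB placed consistently; the
#' N-H bond is 1.02 Angstrom) from ideal alpha-helix, beta-strand, coil and
#' beta-hairpin segments chained along a cursor, then perturbs each
#' conformer with Gaussian coordinate noise. A hinge rotation can be
#' applied to hit a requested CA-CA distance between two marker residues
#' (the AB-loop-style observable). Pure function of its arguments and the
#' seed; proline residues carry no amide H and glycines no CB.
#'
#' @param nConformers number of conformers to generate.
#' @param plan list of segments, each \code{list(type, length)} with type
#'   one of \code{"helix"}, \code{"strand"}, \code{"coil"},
#'   \code{"hairpin"}. Default: a hairpin-helix-coil plan of 36 residues.
#' @param sequence optional 3-letter residue codes (length = total plan
#'   length); default: a seeded random sequence with glycines and prolines.
#' @param coordNoise sd (Angstrom) of the per-conformer coordinate
#'   perturbation.
#' @param loopTarget optional \code{list(resA, resB, distance)}: rotate the
#'   chain about a hinge between the two residues so their CA-CA distance
#'   matches \code{distance}.
#' @param seed integer seed.
#' @return A \linkS4class{ConformerEnsemble}.
#' @export
makeToyEnsemble <- function(nConformers = 10,
                            plan = list(list(type = "hairpin", length = 17),
                                        list(type = "helix", length = 10),
                                        list(type = "coil", length = 9)),
                            sequence = NULL, coordNoise = 0.1,
                            loopTarget = NULL, seed = 1) {
  set.seed(seed)
  nres <- sum(vapply(plan, `[[`, numeric(1), "length"))
  if (is.null(sequence)) sequence <- .randomSequence(nres)
  if (length(sequence) != nres)
    stop("sequence length must match the segment plan")
  # chain template CA trace segment by segment
  ca <- matrix(NA_real_, nres, 3)
  pos <- c(0, 0, 0)
  Rm <- diag(3)
  at <- 0L
  for (seg in plan) {
    L <- seg$length
    local <- switch(seg$type,
      helix = .helixTrace(L),
      strand = .strandTrace(L),
      coil = .coilTrace(L),
      hairpin = .hairpinTrace(L),
      stop("unknown segment type: ", seg$type))
    world <- t(Rm %*% t(local)) +
      matrix(pos, L, 3, byrow = TRUE)
    ca[at + seq_len(L), ] <- world
    at <- at + L
    endDir <- .unit(world[L, ] - world[max(1, L - 1), ])
    pos <- world[L, ] + 3.8 * endDir
    # re-orient the next segment's axis along the current direction and
    # kick it sideways so consecutive segments do not overlap
    z <- endDir
    x <- .unit(pracma::cross(z, if (abs(z[1]) < 0.9) c(1, 0, 0)
                             else c(0, 1, 0)))
    y <- pracma::cross(z, x)
    Rm <- cbind(x, y, z)
  }
  if (!is.null(loopTarget)) {
    a <- loopTarget$resA; b <- loopTarget$resB
    h <- floor((a + b) / 2)
    axis <- .unit(pracma::cross(ca[b, ] - ca[h, ], ca[a, ] - ca[h, ]) +
                    c(1e-6, 2e-6, 3e-6))
    rotBy <- function(ang) {
      K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                    -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
      Rr <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
      tail <- ca[(h + 1):nres, , drop = FALSE]
      sweep(sweep(tail, 2, ca[h, ]) %*% t(Rr), 2, ca[h, ], `+`)
    }
    dist <- function(ang) {
      tail <- rotBy(ang)
      sqrt(sum((tail[b - h, ] - ca[a, ])^2))
    }
    target <- loopTarget$distance
    grid <- seq(0, pi, length.out = 181)
    dd <- vapply(grid, dist, numeric(1))
    if (target < min(dd) || target > max(dd)) {
      warning("loop target ", target, " A outside achievable range [",
              round(min(dd), 1), ", ", round(max(dd), 1), "]; using closest")
      ang <- grid[which.min(abs(dd - target))]
    } else {
      k <- which(diff(sign(dd - target)) != 0)[1L]
      ang <- stats::uniroot(function(x) dist(x) - target,
                            c(grid[k], grid[k + 1L]))$root
    }
    ca[(h + 1):nres, ] <- rotBy(ang)
  }
  buildAtoms <- function(caConf) {
    Nc <- Hc <- CBc <- matrix(NA_real_, nres, 3)
    for (i in seq_len(nres)) {
      prev <- if (i > 1) caConf[i - 1, ] else
        caConf[i, ] - (caConf[i + 1, ] - caConf[i, ])
      nxt <- if (i < nres) caConf[i + 1, ] else
        caConf[i, ] + (caConf[i, ] - caConf[i - 1, ])
      dPrev <- .unit(prev - caConf[i, ])
      dNext <- .unit(nxt - caConf[i, ])
      side <- pracma::cross(dNext, dPrev)
      if (sum(side^2) < 1e-8) side <- c(0, 1, 0) else side <- .unit(side)
      Nc[i, ] <- caConf[i, ] + 1.46 * .unit(dPrev + 0.35 * side)
      if (sequence[i] != "PRO") {
        u <- .unit(.unit(Nc[i, ] - caConf[i, ]) + 0.6 * side)
        Hc[i, ] <- Nc[i, ] + 1.02 * u
      }
      if (sequence[i] != "GLY") {
        v <- -(dPrev + dNext) + 1.1 * side
        CBc[i, ] <- caConf[i, ] + 1.53 * .unit(v)
      }
    }
    list(N = Nc, H = Hc, CA = caConf, CB = CBc)
  }
  dims <- c(nres, 3L, nConformers)
  coords <- list(N = array(NA_real_, dims), H = array(NA_real_, dims),
                 CA = array(NA_real_, dims), CB = array(NA_real_, dims))
  for (k in seq_len(nConformers)) {
    caK <- ca + matrix(stats::rnorm(nres * 3, sd = coordNoise), nres, 3)
    at <- buildAtoms(caK)
    for (nm in names(coords)) coords[[nm]][, , k] <- at[[nm]]
  }
  new("ConformerEnsemble",
      conformerIds = sprintf("conf%03d", seq_len(nConformers)),
      residues = data.frame(number = seq_len(nres), name = sequence),
      coords = coords, weights = numeric())
}

#' Generate a synthetic shift library from a conformer ensemble
#'
#' Emulates predictor output: for each conformer, the shift of each
#' (residue, nucleus) is a random-coil base value for the residue type,
#' plus a secondary-structure offset for the conformer's assigned class at
#' that residue (beta sheet lowers 13CA and raises 13CB, helix the
#' opposite), plus independent Gaussian noise of per-nucleus standard
#' deviation \code{noiseSigma} — the conformer-to-conformer spread a real
#' predictor produces. Prolines carry no HN, glycines no CB.
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}.
#' @param noiseSigma named per-nucleus sd in ppm.
#' @param seed integer seed.
#' @param source provenance string for the library.
#' @return A \linkS4class{ShiftLibrary} with one table per conformer.
#' @export
makeShiftLibrary <- function(ensemble,
                             noiseSigma = c(HN = 0.1, NH = 1.0,
                                            CA = 0.4, CB = 0.4),
                             seed = 1, source = "synthetic") {
  set.seed(seed)
  sigma <- noiseSigma[NUCLEI]
  ss <- assignSecondaryStructure(ensemble)
  res <- ensemble@residues
  nres <- nrow(res)
  base <- .RANDOM_COIL[res$name, , drop = FALSE]
  tables <- lapply(seq_along(ensemble@conformerIds), function(k) {
    off <- .SS_OFFSET[ss[, k], , drop = FALSE]
    noise <- matrix(stats::rnorm(nres * 4), nres, 4) *
      matrix(sigma, nres, 4, byrow = TRUE)
    v <- base + off + noise
    colnames(v) <- NUCLEI
    v[res$name == "PRO", "HN"] <- NA
    v[res$name == "GLY", "CB"] <- NA
    ShiftTable(ensemble@conformerIds[k], res, v)
  })
  ShiftLibrary(tables, ensemble@conformerIds, source)
}

#' Build a reference shift table as a known convex mixture
#'
#' Creates the regression target with a known answer: the reference is the
#' weighted ppm-space mixture of the library tables under ground-truth
#' simplex weights, optionally plus Gaussian measurement noise.
#'
#' @param library a \linkS4class{ShiftLibrary}.
#' @param weights ground-truth weights: full-length simplex vector or named
#'   sparse vector (names = conformer ids or indices).
#' @param noise per-nucleus measurement noise sd in ppm (scalar recycled;
#'   default 0 = noiseless mixture).
#' @param space space in which the convex mixture is exact:
#'   \code{"scaled"} (default) makes the ground truth exact in the
#'   regression's operating space — the scaled-space mixture is mapped back
#'   to ppm through a fixed-point construction so that ranges refitted on
#'   the resulting reference reproduce the generating scaling model;
#'   \code{"ppm"} mixes the raw tables (the log map's curvature then makes
#'   the ground truth only approximately recoverable).
#' @param seed integer seed.
#' @return A list with \code{reference} (\linkS4class{ShiftTable}) and
#'   \code{weights} (the full ground-truth vector, named by conformer id).
#' @export
makeReference <- function(library, weights, noise = 0,
                          space = c("scaled", "ppm"), seed = 1) {
  space <- match.arg(space)
  set.seed(seed)
  n <- length(library)
  w <- numeric(n)
  names(w) <- library@conformerIds
  if (!is.null(names(weights)) && length(weights) < n) {
    idx <- match(names(weights), library@conformerIds)
    if (anyNA(idx)) idx <- as.integer(names(weights))
    w[idx] <- weights
  } else {
    if (length(weights) != n)
      stop("weights must be full length or a named sparse vector")
    w[] <- weights
  }
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("ground-truth weights must lie on the probability simplex")
  sup <- which(w > 0)
  vals <- Reduce(`+`, lapply(sup, function(i)
    w[i] * library@tables[[i]]@values))
  res <- library@tables[[1L]]@residues
  if (space == "scaled") {
    # fixed point: find y with f_y(y) = sum_i w_i f_y(X_i) on the residues
    # the exclusion rule retains, where f_y uses ranges fitted on the
    # retained part of y itself (exactly what the pipeline refits), so the
    # scaled-space ground truth survives the downstream range fit
    libOK <- Reduce(intersect, lapply(library@tables, function(t)
      t@residues$number[rowSums(is.na(t@values)) == 0L]))
    keep <- which(rowSums(is.na(vals)) == 0L & res$number %in% libOK)
    for (it in seq_len(100L)) {
      model <- fitReferenceRange(
        ShiftTable("reference", res[keep, , drop = FALSE],
                   vals[keep, , drop = FALSE]))
      newVals <- vals
      for (nuc in NUCLEI) {
        mixScaled <- Reduce(`+`, lapply(sup, function(i)
          w[i] * applyScaling(library@tables[[i]]@values[keep, nuc],
                              model, nuc)))
        newVals[keep, nuc] <- invertScaling(mixScaled, model, nuc)
      }
      delta <- max(abs(newVals[keep, ] - vals[keep, ]))
      vals <- newVals
      if (delta < 1e-12) break
    }
  }
  noise <- rep_len(noise, 4)
  if (any(noise > 0)) {
    nres <- nrow(vals)
    vals <- vals + matrix(stats::rnorm(nres * 4), nres, 4) *
      matrix(noise, nres, 4, byrow = TRUE)
  }
  ref <- ShiftTable("reference", res, vals)
  list(reference = ref, weights = w)
}

#' Generate cone-motion N-H unit-vector ensembles
#'
#' Oracle input for the iRED order-parameter computation: each residue has
#' a fixed axis in a rigid molecular frame; per frame, its N-H vector is
#' drawn uniformly (in solid angle) within a cone of the given semi-angle
#' about that axis, and a uniformly random global rotation is applied to
#' the whole frame. For diffusion in a cone of semi-angle alpha the exact
#' order parameter is S2 = [cos(alpha) (1 + cos(alpha)) / 2]^2.
#'
#' @param nFrames number of frames.
#' @param semiAngles per-residue cone semi-angle in degrees (vector defines
#'   the number of residues).
#' @param seed integer seed.
#' @param globalRotation apply a random global rotation per frame
#'   (default TRUE).
#' @return numeric array (n_residues, 3, nFrames) of unit vectors.
#' @export
makeConeEnsemble <- function(nFrames, semiAngles, seed = 1,
                             globalRotation = TRUE) {
  set.seed(seed)
  nres <- length(semiAngles)
  axes <- t(apply(matrix(stats::rnorm(nres * 3), nres, 3), 1, .unit))
  alpha <- semiAngles * pi / 180
  out <- array(NA_real_, c(nres, 3L, nFrames))
  # per-residue orthonormal frames around each axis, stacked for
  # vectorized per-frame sampling
  frames <- lapply(seq_len(nres), function(i) {
    z <- axes[i, ]
    x <- .unit(pracma::cross(z, if (abs(z[1]) < 0.9) c(1, 0, 0)
                             else c(0, 1, 0)))
    y <- pracma::cross(z, x)
    cbind(x, y, z)
  })
  axisX <- t(vapply(frames, function(f) f[, 1L], numeric(3)))
  axisY <- t(vapply(frames, function(f) f[, 2L], numeric(3)))
  axisZ <- t(vapply(frames, function(f) f[, 3L], numeric(3)))
  for (t in seq_len(nFrames)) {
    G <- if (globalRotation) .randomRotation() else diag(3)
    cosT <- stats::runif(nres, cos(alpha), 1)
    sinT <- sqrt(pmax(0, 1 - cosT^2))
    phi <- stats::runif(nres, 0, 2 * pi)
    B <- axisX * (sinT * cos(phi)) + axisY * (sinT * sin(phi)) +
      axisZ * cosT
    out[, , t] <- B %*% t(G)
  }
  out
}

#' Closed-form cone-model order parameter
#'
#' S2 for diffusion in a cone of semi-angle alpha:
#' [cos(alpha) (1 + cos(alpha)) / 2]^2.
#'
#' @param alphaDeg cone semi-angle in degrees.
#' @return numeric order parameter in [0, 1].
#' @export
coneOrderParameter <- function(alphaDeg) {
  ca <- cos(alphaDeg * pi / 180)
  (ca * (1 + ca) / 2)^2
}
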