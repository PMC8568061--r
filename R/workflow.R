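#' @include validation.R
NULL

#' Assemble a run configuration
#'
#' Collects the workflow parameters with defaults matching the method's
#' stated constants: selection threshold eps = 1e-5, contact cutoff 7.5
#' Angstrom, 1,000-frame expansion, logarithm base bounded to [1.1, 10].
#' A YAML configuration file can supply any subset; explicit arguments
#' override file values.
#'
#' @param file optional YAML configuration file.
#' @param ... overrides for any configuration field (see Details).
#' @details Fields: \code{reference} (path), \code{referenceFormat}
#'   (\code{"nmrstar"}, \code{"csv"} or a predictor dialect),
#'   \code{library} (directory or vector of per-conformer table paths),
#'   \code{dialect}, \code{ensemble} (multi-model PDB path), \code{s2Ref}
#'   (experimental S2 CSV), \code{eps}, \code{aBounds}, \code{thetaBounds},
#'   \code{cutoff}, \code{k}, \code{nComponents}, \code{total},
#'   \code{norm}, \code{seed}, \code{outputDir}.
#' @return A named list of class \code{"RunConfig"}.
#' @export
runConfig <- function(file = NULL, ...) {
  cfg <- list(
    reference = NULL, referenceFormat = "nmrstar",
    library = NULL, dialect = "generic-csv",
    ensemble = NULL, s2Ref = NULL,
    eps = 1e-5, aBounds = c(1.1, 10), thetaBounds = c(-0.2, 0.2),
    tune = TRUE, cutoff = 7.5, k = 3L, nComponents = 2L,
    total = 1000L, norm = "l2", seed = 1L, outputDir = "."
  )
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    cfg[names(y)] <- y
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  stopifnot(cfg$eps > 0, cfg$total >= 1,
            length(cfg$aBounds) == 2, cfg$norm %in% c("l2", "sum"))
  structure(cfg, class = "RunConfig")
}

.writeManifest <- function(cfg, outDir, extra = list()) {
  manifest <- c(list(
    package = "ShiftEnsemble",
    version = as.character(utils::packageVersion("ShiftEnsemble")),
    config = unclass(cfg)
  ), extra)
  path <- file.path(outDir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

.loadReference <- function(cfg) {
  switch(cfg$referenceFormat,
         nmrstar = readNmrStarShifts(cfg$reference),
         csv = readShiftTable(cfg$reference),
         readPredictorTable(cfg$reference, cfg$referenceFormat))
}

.loadLibrary <- function(cfg) {
  paths <- cfg$library
  if (length(paths) == 1L && dir.exists(paths))
    paths <- sort(list.files(paths, full.names = TRUE,
                             pattern = "\\.(csv|tab|txt)$"))
  if (!length(paths)) stop("no library tables found")
  tables <- lapply(paths, readPredictorTable, dialect = cfg$dialect)
  ShiftLibrary(tables, sub("\\.[^.]*$", "", basename(paths)),
               source = cfg$dialect)
}

#' Run the full regression workflow
#'
#' Orchestrates the ensemble-selection pipeline: read the reference and
#' library, apply the fully-assigned exclusion rule, fit the reference
#' ranges, tune the scaling hyperparameters, solve the simplex-constrained
#' regression, select and refit the support, score, and back-predict the
#' reference shifts. All artifacts (weights, scores, residuals, scaling
#' model, predicted shifts, manifest) are written under the output
#' directory.
#'
#' @param cfg a \code{"RunConfig"} from [runConfig()].
#' @return Invisibly, a list with the fitted objects (\code{weights},
#'   \code{model}, \code{problem}, \code{predicted}, \code{excluded},
#'   \code{tuning}).
#' @export
runFit <- function(cfg) {
  outDir <- cfg$outputDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  reference <- .loadReference(cfg)
  library <- .loadLibrary(cfg)
  masked <- applyExclusionMask(library, reference)
  tuning <- if (isTRUE(cfg$tune))
    tuneScaling(masked$library, masked$reference,
                aBounds = cfg$aBounds, thetaBounds = cfg$thetaBounds)
  else
    list(a = 10, theta = 0, model = fitReferenceRange(masked$reference))
  model <- tuning$model
  problem <- buildRegressionProblem(masked$library, masked$reference, model)
  pre <- solveEnsembleWeights(problem)
  support <- selectFeatures(pre, eps = cfg$eps)
  final <- refitOnSupport(problem, support, eps = cfg$eps)
  final <- scoreEnsemble(problem, final, model)
  predicted <- predictShifts(final, masked$library)

  w <- final@weights
  utils::write.csv(data.frame(conformer_id = names(w), weight = w),
                   file.path(outDir, "weights.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(nucleus = c(NUCLEI, "total"),
                              r2 = c(final@perAtomR2, final@totalR2)),
                   file.path(outDir, "scores.csv"),
                   row.names = FALSE, quote = FALSE)
  resid <- problem@target -
    as.vector(problem@design %*% w[problem@conformerIds])
  utils::write.csv(cbind(problem@featureIndex, residual = resid),
                   file.path(outDir, "residuals.csv"),
                   row.names = FALSE, quote = FALSE)
  writeShiftTable(predicted, file.path(outDir, "predicted_shifts.csv"))
  writeScalingModel(model, file.path(outDir, "scaling_model.yaml"))
  .writeManifest(cfg, outDir, list(
    excluded_residues = masked$excluded,
    a = tuning$a, theta = tuning$theta,
    support_size = length(final@support),
    total_r2 = final@totalR2))
  invisible(list(weights = final, model = model, problem = problem,
                 predicted = predicted, excluded = masked$excluded,
                 tuning = tuning, masked = masked))
}

#' Run the structural analysis workflow
#'
#' Clusters the weighted ensemble in contact-map PCA space, computes
#' secondary-structure proportion statistics (built-in geometric assigner,
#' or a STRIDE/DSSP report when supplied) and the marker-residue loop
#' distances; writes cluster labels, the 2-D embedding, the
#' secondary-structure profile and the distances as CSV.
#'
#' @param cfg a \code{"RunConfig"}; \code{cfg$ensemble} names the
#'   multi-model PDB.
#' @param weights an \linkS4class{EnsembleWeights} (or NULL: unweighted).
#' @param ssReport optional STRIDE/DSSP report path.
#' @param ssFormat \code{"stride"} or \code{"dssp"}.
#' @return Invisibly, a list with \code{clusters}, \code{profile},
#'   \code{loopDistances} and the \code{ensemble}.
#' @export
runAnalyze <- function(cfg, weights = NULL, ssReport = NULL,
                       ssFormat = "stride") {
  outDir <- cfg$outputDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ensemble <- readEnsemble(cfg$ensemble)
  clusters <- clusterEnsemble(ensemble, weights, k = cfg$k,
                              nComponents = cfg$nComponents,
                              cutoff = cfg$cutoff, seed = cfg$seed)
  assignments <- if (is.null(ssReport))
    assignSecondaryStructure(ensemble)
  else
    readSecondaryStructure(ssReport, ssFormat)
  wv <- if (is.null(weights)) NULL else .alignWeights(ensemble, weights)
  profile <- ssProportions(assignments, weights = wv)
  ld <- loopDistance(ensemble)
  utils::write.csv(data.frame(conformer_id = clusters$conformers,
                              cluster = clusters$labels,
                              clusters$embedding, check.names = FALSE),
                   file.path(outDir, "clusters.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(residue_number = profile@residues,
                              profile@proportions, check.names = FALSE),
                   file.path(outDir, "ss_profile.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(conformer_id = names(ld),
                              loop_distance = ld),
                   file.path(outDir, "loop_distances.csv"),
                   row.names = FALSE, quote = FALSE)
  .writeManifest(cfg, outDir, list(beta_core = profile@betaCore))
  invisible(list(clusters = clusters, profile = profile,
                 loopDistances = ld, ensemble = ensemble))
}

#' Run the order-parameter workflow
#'
#' Expands the weighted ensemble to a fixed frame count, computes iRED N-H
#' order parameters, compares them to a reference profile (|dS2|), and —
#' when predicted and reference shift tables are available — assembles the
#' validation report linking projection-space shift error to |dS2|.
#'
#' @param cfg a \code{"RunConfig"}; \code{cfg$ensemble} names the
#'   multi-model PDB and \code{cfg$s2Ref} the reference S2 CSV (optional).
#' @param weights an \linkS4class{EnsembleWeights}.
#' @param predicted,reference optional \linkS4class{ShiftTable}s for the
#'   shift-error track.
#' @param model the \linkS4class{ScalingModel} (required with shift
#'   tables).
#' @return Invisibly, a list with \code{s2} (profile), \code{delta}
#'   (named |dS2| or NULL) and \code{report}
#'   (\linkS4class{ValidationReport} or NULL).
#' @export
runOrderParameters <- function(cfg, weights, predicted = NULL,
                               reference = NULL, model = NULL) {
  outDir <- cfg$outputDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ensemble <- readEnsemble(cfg$ensemble)
  expanded <- expandEnsemble(ensemble, weights, total = cfg$total)
  s2 <- iredOrderParameters(nhVectors(expanded))
  writeOrderParameters(s2, file.path(outDir, "s2_ensemble.csv"))
  delta <- NULL
  report <- NULL
  if (!is.null(cfg$s2Ref)) {
    ref <- readOrderParameters(cfg$s2Ref)
    delta <- deltaS2(s2, ref)
    utils::write.csv(data.frame(residue_number = names(delta),
                                abs_delta_s2 = delta),
                     file.path(outDir, "delta_s2.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(predicted) && !is.null(reference) && !is.null(model)) {
      report <- shiftError(predicted, reference, model, norm = cfg$norm)
      report <- attachDeltaS2(report, delta)
      writeValidationReport(report,
                            file.path(outDir, "validation_report.csv"))
    }
  }
  .writeManifest(cfg, outDir, list(frames = length(expanded@conformerIds)))
  invisible(list(s2 = s2, delta = delta, report = report,
                 expanded = expanded))
}

#' Generate a synthetic fixture bundle
#'
#' Writes, under the output directory, everything the pipeline consumes,
#' generated from a \code{\link{syntheticSpec}}: the toy conformer
#' ensemble (multi-model PDB), the per-conformer shift library (normalized
#' CSV, one file per conformer), the mixed reference table, the
#' ground-truth weights and a cone-model S2 reference.
#'
#' @param spec a \code{"SyntheticSpec"} (or YAML path understood by
#'   [syntheticSpec()] fields).
#' @param outDir output directory.
#' @return Invisibly, a list of the generated objects and file paths.
#' @export
runSimulate <- function(spec, outDir) {
  if (is.character(spec)) spec <- do.call(syntheticSpec,
                                          yaml::read_yaml(spec))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  nres <- spec$nResidues
  # segment plan covering the chain with mixed structure
  plan <- list(list(type = "hairpin", length = max(12L, nres %/% 3)),
               list(type = "helix", length = max(6L, nres %/% 5)),
               list(type = "coil", length = 0L))
  used <- sum(vapply(plan, `[[`, numeric(1), "length"))
  plan[[3L]]$length <- nres - used
  ensemble <- makeToyEnsemble(spec$nConformers, plan,
                              coordNoise = 0.15, seed = spec$seed)
  library <- makeShiftLibrary(ensemble, spec$noiseSigma,
                              seed = spec$seed + 1L)
  mix <- makeReference(library, spec$activeWeights,
                       noise = spec$referenceNoise, seed = spec$seed + 2L)
  cone <- makeConeEnsemble(500L, spec$motion, seed = spec$seed + 3L)
  s2 <- iredOrderParameters(cone, residues = seq_len(nres))
  pdbPath <- file.path(outDir, "ensemble.pdb")
  writeEnsemble(ensemble, pdbPath)
  libDir <- file.path(outDir, "library")
  dir.create(libDir, showWarnings = FALSE)
  for (i in seq_along(library@conformerIds))
    writeShiftTable(library@tables[[i]],
                    file.path(libDir, sprintf("%s.csv",
                                              library@conformerIds[i])))
  refPath <- file.path(outDir, "reference.csv")
  writeShiftTable(mix$reference, refPath)
  utils::write.csv(data.frame(conformer_id = names(mix$weights),
                              weight = mix$weights),
                   file.path(outDir, "truth_weights.csv"),
                   row.names = FALSE, quote = FALSE)
  writeOrderParameters(s2, file.path(outDir, "s2_reference.csv"))
  yaml::write_yaml(list(seed = spec$seed,
                        nConformers = spec$nConformers,
                        nResidues = spec$nResidues),
                   file.path(outDir, "spec_used.yaml"))
  invisible(list(ensemble = ensemble, library = library,
                 reference = mix$reference, weights = mix$weights,
                 paths = list(ensemble = pdbPath, library = libDir,
                              reference = refPath)))
}
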