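test_that("problem assembly scales elementwise with deterministic ordering", {
  fx <- mixtureFixture(nConformers = 3, nResidues = 20, seed = 41)
  prob <- fx$problem
  nres <- length(residueNumbers(fx$masked$reference))
  expect_identical(dim(prob@design), c(nres * 4L, 3L))
  # features ordered by residue then canonical nucleus order
  expect_identical(prob@featureIndex$nucleus, rep(NUCLEI, nres))
  expect_true(all(diff(prob@featureIndex$residue_number) >= 0))
  # entries equal elementwise application of f
  tab <- fx$masked$library[[2]]
  for (nuc in NUCLEI) {
    rows <- prob@featureIndex$nucleus == nuc
    expect_equal(prob@design[rows, 2],
                 applyScaling(shiftValues(tab)[, nuc], fx$model, nuc))
  }
  expect_error(buildRegressionProblem(fx$library, fx$mix$reference,
                                      fx$model),
               "applyExclusionMask|mismatch")
})

test_that("the constrained solver is exact on canonical cases", {
  fx <- mixtureFixture(nConformers = 12, nResidues = 20, seed = 43)
  # single column equal to the target
  refCol <- fx$masked$reference
  soloLib <- ShiftLibrary(list(refCol), "self")
  soloProb <- buildRegressionProblem(soloLib, fx$masked$reference,
                                     fx$model)
  solo <- solveEnsembleWeights(soloProb)
  expect_equal(unname(ensembleWeights(solo)), 1)
  expect_lt(residualNorm(solo), 1e-12)
  # known mixture, no noise: recovered to 1e-6
  w <- solveEnsembleWeights(fx$problem)
  expect_lt(max(abs(ensembleWeights(w) - fx$mix$weights)), 1e-6)
  expect_lt(residualNorm(w), 1e-9)
  # simplex constraints on the estimate
  expect_true(all(ensembleWeights(w) >= 0))
  expect_equal(sum(ensembleWeights(w)), 1, tolerance = 1e-10)
})

test_that("the solver matches the 0.001-step simplex-grid brute force", {
  set.seed(57)
  for (ncol in c(3L, 4L)) {
    X <- matrix(rnorm(40 * ncol), 40, ncol)
    y <- as.vector(X %*% randomSimplex(ncol)) + rnorm(40, sd = 0.4)
    grid <- simplexGridSearch(X, y, step = 0.001)
    w <- ShiftEnsemble:::.simplexActiveSet(crossprod(X),
                                           as.vector(crossprod(X, y)))
    expect_lt(max(abs(grid$w - w)), 0.001)
    # the grid optimum can never beat the exact solution
    expect_gte(grid$objective + 1e-10, sum((y - as.vector(X %*% w))^2))
  }
})

test_that("feature selection is an inclusive relative-threshold scan", {
  fx <- mixtureFixture(nConformers = 6, nResidues = 16, seed = 47)
  w <- solveEnsembleWeights(fx$problem)
  # direct scan oracle over 1,000 random weight vectors
  set.seed(7)
  for (rep in 1:1000) {
    wv <- randomSimplex(8)
    wv[sample(8, 3)] <- wv[sample(8, 3)] * 1e-7
    wv <- wv / sum(wv)
    names(wv) <- letters[1:8]
    ew <- new("EnsembleWeights", weights = wv, support = names(wv),
              thresholdEps = 1e-5,
              perAtomR2 = setNames(rep(NA_real_, 4), NUCLEI),
              totalR2 = NA_real_, residualNorm = 0)
    expect_identical(selectFeatures(ew),
                     names(wv)[wv >= 1e-5 * max(wv)])
  }
  # inclusive boundary and degenerate cases
  wv <- c(a = 1 - 1e-5 / (1 + 1e-5), b = 1e-5 / (1 + 1e-5))
  wv <- wv / sum(wv)
  ew <- new("EnsembleWeights", weights = wv, support = c("a", "b"),
            thresholdEps = 1e-5,
            perAtomR2 = setNames(rep(NA_real_, 4), NUCLEI),
            totalR2 = NA_real_, residualNorm = 0)
  expect_identical(selectFeatures(ew), c("a", "b"))   # w_b = eps * w_a
  uni <- new("EnsembleWeights",
             weights = setNames(rep(0.25, 4), letters[1:4]),
             support = letters[1:4], thresholdEps = 1e-5,
             perAtomR2 = setNames(rep(NA_real_, 4), NUCLEI),
             totalR2 = NA_real_, residualNorm = 0)
  expect_identical(selectFeatures(uni), letters[1:4])
})

test_that("refit on the support is feasible, sparse and never worse", {
  fx <- mixtureFixture(nConformers = 15, nResidues = 20, seed = 53,
                       noise = 0.1)
  pre <- solveEnsembleWeights(fx$problem)
  S <- selectFeatures(pre)
  final <- refitOnSupport(fx$problem, S)
  expect_true(all(ensembleWeights(final)[setdiff(
    conformerIds(fx$library), S)] == 0))
  expect_equal(sum(ensembleWeights(final)), 1, tolerance = 1e-10)
  # refit on the full support cannot increase the residual
  full <- refitOnSupport(fx$problem, supportSet(pre))
  expect_lte(residualNorm(full)^2, residualNorm(pre)^2 + 1e-9)
  # single-conformer support gets weight one
  one <- refitOnSupport(fx$problem, S[1])
  expect_equal(unname(ensembleWeights(one)[S[1]]), 1)
  # selection then refit still reproduces an exact mixture
  fx0 <- mixtureFixture(nConformers = 15, nResidues = 20, seed = 59)
  pre0 <- solveEnsembleWeights(fx0$problem)
  final0 <- refitOnSupport(fx0$problem, selectFeatures(pre0))
  expect_lt(max(abs(ensembleWeights(final0) - fx0$mix$weights)), 1e-6)
})

test_that("scores follow the R2 definition and multiply into the total", {
  fx <- mixtureFixture(nConformers = 10, nResidues = 20, seed = 61)
  w <- solveEnsembleWeights(fx$problem)
  scored <- scoreEnsemble(fx$problem, w, fx$model)
  # exact fit scores 1 per nucleus, total 1
  expect_equal(unname(perAtomR2(scored)), rep(1, 4), tolerance = 1e-9)
  expect_equal(totalR2(scored), 1, tolerance = 1e-9)
  expect_equal(totalR2(scored), prod(perAtomR2(scored)))
  # a constant prediction scores 0 by definition: R2 = 1 - RSS/TSS
  noisy <- mixtureFixture(nConformers = 10, nResidues = 20, seed = 67,
                          noise = 0.3)
  wN <- scoreEnsemble(noisy$problem, solveEnsembleWeights(noisy$problem),
                      noisy$model)
  hand <- vapply(NUCLEI, function(nuc) {
    rows <- noisy$problem@featureIndex$nucleus == nuc
    pred <- as.vector(noisy$problem@design %*%
                        ensembleWeights(wN)[conformerIds(noisy$library)])
    yk <- invertScaling(noisy$problem@target[rows], noisy$model, nuc)
    yh <- invertScaling(pred[rows], noisy$model, nuc)
    1 - sum((yk - yh)^2) / sum((yk - mean(yk))^2)
  }, numeric(1))
  expect_equal(perAtomR2(wN), hand)
  expect_equal(totalR2(wN), prod(hand))
})

test_that("predicted shift tables are ppm-space convex combinations", {
  fx <- mixtureFixture(nConformers = 5, nResidues = 16, seed = 71)
  ids <- conformerIds(fx$masked$library)
  point <- new("EnsembleWeights",
               weights = setNames(c(1, numeric(4)), ids),
               support = ids[1], thresholdEps = 1e-5,
               perAtomR2 = setNames(rep(NA_real_, 4), NUCLEI),
               totalR2 = NA_real_, residualNorm = 0)
  expect_equal(shiftValues(predictShifts(point, fx$masked$library)),
               shiftValues(fx$masked$library[[1]]))
  half <- new("EnsembleWeights",
              weights = setNames(c(0.5, 0.5, numeric(3)), ids),
              support = ids[1:2], thresholdEps = 1e-5,
              perAtomR2 = setNames(rep(NA_real_, 4), NUCLEI),
              totalR2 = NA_real_, residualNorm = 0)
  expect_equal(shiftValues(predictShifts(half, fx$masked$library)),
               (shiftValues(fx$masked$library[[1]]) +
                  shiftValues(fx$masked$library[[2]])) / 2)
  # general case equals the matrix-product oracle
  set.seed(5)
  wv <- randomSimplex(5)
  gen <- new("EnsembleWeights", weights = setNames(wv, ids),
             support = ids, thresholdEps = 1e-5,
             perAtomR2 = setNames(rep(NA_real_, 4), NUCLEI),
             totalR2 = NA_real_, residualNorm = 0)
  stack <- vapply(seq_along(ids), function(i)
    as.vector(shiftValues(fx$masked$library[[i]])),
    numeric(length(shiftValues(fx$masked$library[[1]]))))
  expect_equal(as.vector(shiftValues(predictShifts(gen,
                                                   fx$masked$library))),
               as.vector(stack %*% wv))
})

test_that("simplex constraints and recovery hold over random problems", {
  set.seed(83)
  for (rep in 1:10) {
    n <- sample(3:25, 1)
    X <- matrix(rnorm(60 * n), 60, n)
    y <- as.vector(X %*% randomSimplex(n)) + rnorm(60, sd = 0.5)
    w <- ShiftEnsemble:::.simplexActiveSet(crossprod(X),
                                           as.vector(crossprod(X, y)))
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-8)
  }
})
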