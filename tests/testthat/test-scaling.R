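test_that("reference ranges come from a direct min/max scan", {
  set.seed(3)
  vals <- matrix(rnorm(40, 80, 20), 10)
  tab <- quickTable(vals)
  model <- fitReferenceRange(tab)
  p <- scalingParams(model)
  for (k in seq_along(NUCLEI)) {
    expect_equal(p[NUCLEI[k], "ymin"], min(vals[, k]))
    expect_equal(p[NUCLEI[k], "ymax"], max(vals[, k]))
  }
  # 15N example: {105, 115, 130}
  v2 <- cbind(rnorm(3, 8, 0.5), c(105, 115, 130), rnorm(3, 55, 3),
              rnorm(3, 35, 3))
  p2 <- scalingParams(fitReferenceRange(quickTable(v2)))
  expect_equal(unname(p2["NH", c("ymin", "ymax")]), c(105, 130))

  # constant column is fatal
  vBad <- vals; vBad[, 2] <- 7
  expect_error(fitReferenceRange(quickTable(vBad)), "constant")
})

test_that("the scaling function obeys its closed forms and offsets", {
  vals <- matrix(c(7.5, 9.1, 8.2, 105, 130, 118, 50, 63, 55, 18, 70, 40),
                 3)
  model <- fitReferenceRange(quickTable(vals))
  p <- scalingParams(model)
  # f(y_min) = 0 and f(y_max) = log_a(2) for a = 10, theta = 0
  for (nuc in NUCLEI) {
    expect_equal(applyScaling(p[nuc, "ymin"], model, nuc), 0)
    expect_equal(applyScaling(p[nuc, "ymax"], model, nuc), log10(2))
  }
  # the amide-proton offset is purely additive: f(x; theta) - f(x; 0) = theta
  m2 <- setScalingHyperparameters(model, 10, 0.0661)
  expect_equal(applyScaling(p["HN", "ymin"], m2, "HN"), 0.0661)
  x <- seq(p["HN", "ymin"], p["HN", "ymax"], length.out = 11)
  expect_equal(applyScaling(x, m2, "HN") - applyScaling(x, model, "HN"),
               rep(0.0661, 11))
  # strict monotonicity on sorted random inputs, any valid base
  for (a in c(1.1, 2.7, 10)) {
    m3 <- setScalingHyperparameters(model, a, 0)
    xs <- sort(runif(200, p[1, "ymin"], p[1, "ymax"]))
    expect_true(all(diff(applyScaling(xs, m3, "HN")) > 0))
  }
  # domain error names the offender
  named <- c(r5 = p["CA", "ymin"] - 10 * (p["CA", "ymax"] - p["CA", "ymin"]))
  expect_error(applyScaling(named, model, "CA"), "r5")
})

test_that("inverse scaling round-trips to 1e-10 relative", {
  set.seed(9)
  vals <- matrix(rnorm(40, 70, 15), 10)
  model <- fitReferenceRange(quickTable(vals))
  p <- scalingParams(model)
  for (nuc in NUCLEI) {
    rng <- p[nuc, "ymax"] - p[nuc, "ymin"]
    x <- runif(1000, p[nuc, "ymin"] - 0.4 * rng, p[nuc, "ymax"] + rng)
    back <- invertScaling(applyScaling(x, model, nuc), model, nuc)
    expect_lt(max(abs(back - x)), 1e-10 * rng)
    expect_equal(invertScaling(0, model, nuc), unname(p[nuc, "ymin"]))
  }
  # s = theta maps back to y_min for HN
  m2 <- setScalingHyperparameters(model, 10, 0.05)
  expect_equal(invertScaling(0.05, m2, "HN"),
               unname(p["HN", "ymin"]))
})

test_that("weights are unchanged by the base and exact members tie-break to defaults", {
  fx <- mixtureFixture(nConformers = 8, nResidues = 20, seed = 21)
  # exact member: the reference itself is a library column
  libPlus <- ShiftLibrary(c(fx$masked$library@tables,
                            fx$masked$reference),
                          c(conformerIds(fx$masked$library), "self"))
  tuned <- tuneScaling(libPlus, fx$masked$reference)
  expect_equal(tuned$a, 10)
  expect_equal(tuned$theta, 0)
  expect_lt(tuned$objective, 1e-16)
  # the simplex solution is invariant under the base (an invertible map):
  # noiseless mixture recovered identically for different a
  ws <- lapply(c(2, 10), function(a) {
    m <- setScalingHyperparameters(fx$model, a, 0)
    prob <- buildRegressionProblem(fx$masked$library,
                                   fx$masked$reference, m)
    ensembleWeights(solveEnsembleWeights(prob))
  })
  expect_equal(ws[[1]], ws[[2]], tolerance = 1e-8)
})

test_that("optimizer and coarse grid agree on the tuned base", {
  fx <- mixtureFixture(nConformers = 2, nResidues = 16, seed = 31,
                       weights = c(`1` = 0.6, `2` = 0.4), noise = 0.05)
  obj <- function(a) {
    m <- setScalingHyperparameters(fx$model, a, 0)
    prob <- buildRegressionProblem(fx$masked$library,
                                   fx$masked$reference, m)
    residualNorm(solveEnsembleWeights(prob))^2
  }
  grid <- seq(1.1, 10, by = 0.1)
  bestGrid <- grid[which.min(vapply(grid, obj, numeric(1)))]
  tuned <- tuneScaling(fx$masked$library, fx$masked$reference)
  expect_lt(abs(tuned$a - bestGrid), 0.1 + 1e-3)
  expect_lte(tuned$objective, obj(bestGrid) + 1e-12)
})

test_that("scaling models serialize and restore exactly", {
  vals <- matrix(rnorm(40, 70, 15), 10)
  model <- setScalingHyperparameters(fitReferenceRange(quickTable(vals)),
                                     3.7, 0.041)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeScalingModel(model, path)
  expect_equal(scalingParams(readScalingModel(path)),
               scalingParams(model), tolerance = 1e-12)
})
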