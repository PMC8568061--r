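test_that("frame apportionment reproduces the weights within one count", {
  expect_identical(apportionCounts(c(1), 1000L), 1000L)
  expect_identical(apportionCounts(c(0.5, 0.5), 1000L), c(500L, 500L))
  set.seed(3)
  for (rep in 1:50) {
    n <- sample(2:40, 1)
    w <- randomSimplex(n)
    counts <- apportionCounts(w, 1000L)
    expect_identical(sum(counts), 1000L)
    expect_true(all(abs(counts - 1000 * w) <= 1))
    expect_true(all(counts[w >= 1 / 2000] >= 1L))
  }
})

test_that("expansion copies conformers in proportion to their weight", {
  ens <- makeToyEnsemble(4, seed = 37)
  w <- setNames(c(0.62, 0.25, 0.13, 0), conformerIds(ens))
  big <- expandEnsemble(ens, w, total = 1000L)
  expect_length(conformerIds(big), 1000L)
  src <- sub("\\.\\d+$", "", conformerIds(big))
  counts <- table(factor(src, levels = conformerIds(ens)))
  expect_true(all(abs(as.integer(counts) - 1000 * w) <= 1))
  # frames are verbatim copies of their source conformers
  first <- which(src == conformerIds(ens)[2])[1]
  expect_identical(big@coords$CA[, , first], ens@coords$CA[, , 2])
})

test_that("N-H vectors are unit length with prolines excluded", {
  ens <- makeToyEnsemble(3, seed = 41)
  nh <- nhVectors(ens)
  pro <- ens@residues$number[ens@residues$name == "PRO"]
  expect_true(length(pro) > 0)
  expect_true(all(pro %in% nh$excluded))
  expect_false(any(pro %in% nh$residues))
  norms <- sqrt(apply(nh$vectors^2, c(1, 3), sum))
  expect_lt(max(abs(norms - 1)), 1e-10)
  # hand-placed N and H along x give (1, 0, 0)
  one <- makeToyEnsemble(1, plan = list(list(type = "strand",
                                             length = 8)),
                         sequence = rep("ALA", 8), coordNoise = 0,
                         seed = 1)
  one@coords$H[3, , 1] <- one@coords$N[3, , 1] + c(1.02, 0, 0)
  nh1 <- nhVectors(one)
  expect_equal(nh1$vectors[match(3, nh1$residues), , 1], c(1, 0, 0))
})

test_that("iRED gives S2 = 1 for rigid ensembles, tumbling or not", {
  # identical frames: M has rank <= 5, internal modes vanish exactly
  v <- makeConeEnsemble(50, rep(0, 15), seed = 5, globalRotation = FALSE)
  s <- iredOrderParameters(v)
  expect_equal(unname(s2Values(s)), rep(1, 15), tolerance = 1e-12)
  # rigid body under uniformly random global rotations
  v2 <- makeConeEnsemble(5000, rep(0, 15), seed = 6)
  s2 <- iredOrderParameters(v2)
  expect_lt(max(abs(s2Values(s2) - 1)), 0.02)
  expect_error(iredOrderParameters(v[1:4, , , drop = FALSE]), "residues")
})

test_that("iRED is invariant under global rotation and frame permutation", {
  v <- makeConeEnsemble(400, rep(25, 20), seed = 8)
  base <- s2Values(iredOrderParameters(v))
  set.seed(9)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  vr <- v
  for (t in seq_len(dim(v)[3])) vr[, , t] <- v[, , t] %*% t(R)
  expect_equal(s2Values(iredOrderParameters(vr)), base,
               tolerance = 1e-10)
  perm <- sample(dim(v)[3])
  expect_equal(s2Values(iredOrderParameters(v[, , perm])), base,
               tolerance = 1e-12)
})

test_that("cone-motion ensembles approach the analytic order parameter", {
  means <- vapply(c(10, 30, 60), function(alpha) {
    v <- makeConeEnsemble(5000, rep(alpha, 120), seed = alpha)
    mean(s2Values(iredOrderParameters(v)))
  }, numeric(1))
  closed <- coneOrderParameter(c(10, 30, 60))
  expect_true(all(abs(means - closed) < 0.05))
  # larger cones are more mobile: S2 strictly decreases
  expect_true(all(diff(means) < 0))
})

test_that("order-parameter differences and CSV round trips are elementwise", {
  p1 <- new("OrderParameterProfile", residues = 1:6,
            s2 = c(1, 0.8, 0.6, 0.9, 0.5, 0.7), source = "ensemble",
            excluded = integer())
  p2 <- new("OrderParameterProfile", residues = 3:8,
            s2 = c(0.4, 0.9, 0.9, 0.2, 0.1, 0.3),
            source = "experimental", excluded = integer())
  expect_equal(unname(deltaS2(p1, p1)), rep(0, 6))
  expect_message(d <- deltaS2(p1, p2), "dropped")
  expect_identical(names(d), as.character(3:6))
  expect_equal(unname(d), abs(c(0.6 - 0.4, 0.9 - 0.9, 0.5 - 0.9,
                                0.7 - 0.2)))
  path <- withr::local_tempfile(fileext = ".csv")
  writeOrderParameters(p1, path)
  back <- readOrderParameters(path)
  expect_equal(s2Values(back), s2Values(p1))
  expect_identical(back@source, "experimental")
})
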