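test_that("multi-model PDB ensembles round-trip through disk", {
  ens <- makeToyEnsemble(4, seed = 13)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemble(ens, path)
  back <- readEnsemble(path)
  expect_length(conformerIds(back), 4L)
  expect_identical(residueNumbers(back), residueNumbers(ens))
  expect_lt(max(abs(back@coords$CA - ens@coords$CA)), 1e-3)
  # chemistry-driven absences survive: PRO has no H, GLY no CB
  expect_identical(is.na(back@coords$H), is.na(ens@coords$H))
  expect_identical(is.na(back@coords$CB), is.na(ens@coords$CB))
  # a CA-less residue is fatal on read
  lines <- readLines(path)
  lines <- lines[!grepl("^ATOM.* CA .* A   3 ", lines)]
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, bad)
  expect_error(readEnsemble(bad), "CA")
})

test_that("contact maps use a strict cutoff and match brute force", {
  # hand-placed geometry around the boundary
  ca <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(0, 7.6, 0), c(0, 0, 7.49))
  cm <- contactMap(ca)
  expect_true(cm@map[1, 2])        # 3.8 A: contact
  expect_false(cm@map[1, 3])       # 7.6 A: no contact
  expect_true(cm@map[1, 4])        # 7.49 A: strictly inside
  expect_true(all(diag(cm@map)))
  # random coordinates vs O(n^2) oracle, plus rigid-body invariance
  set.seed(17)
  for (rep in 1:5) {
    n <- 30
    xyz <- matrix(rnorm(n * 3, sd = 6), n, 3)
    cm <- contactMap(xyz)
    oracle <- matrix(FALSE, n, n)
    for (i in 1:n) for (j in 1:n)
      oracle[i, j] <- i == j || sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < 7.5
    expect_identical(unname(cm@map), oracle)
    expect_identical(cm@map, t(cm@map))
    th <- runif(1, 0, 2 * pi)
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    moved <- xyz %*% R + matrix(rnorm(3, sd = 50), n, 3, byrow = TRUE)
    expect_identical(contactMap(moved)@map, cm@map)
  }
})

test_that("STRIDE and DSSP reports map onto the same class alphabet", {
  codes <- cbind(c("H", "H", "H", "E", "E", "C", "T", "G"),
                 c("C", "G", "G", "B", "E", "C", "H", "H"))
  sf <- withr::local_tempfile(fileext = ".txt")
  writeLines(strideFixture(codes), sf)
  lab <- readSecondaryStructure(sf, "stride")
  expect_identical(dim(lab), c(8L, 2L))
  expect_identical(unname(lab[, 1]),
                   c("alpha-helix", "alpha-helix", "alpha-helix",
                     "beta-sheet", "beta-sheet", "coil", "turn",
                     "310-helix"))
  # same toy structure through the DSSP layout gives the same labels
  df <- withr::local_tempfile(fileext = ".dssp")
  writeLines(dsspFixture(codes[, 1]), df)
  expect_identical(unname(readSecondaryStructure(df, "dssp")[, 1]), unname(lab[, 1]))
  # unknown codes map to coil with a warning
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(strideFixture(cbind(c("H", "X", "E"))), bad)
  expect_warning(lab2 <- readSecondaryStructure(bad, "stride"), "unknown")
  expect_identical(unname(lab2[2, 1]), "coil")
})

test_that("the geometric assigner recognizes constructed structure", {
  helix <- makeToyEnsemble(2, plan = list(list(type = "helix",
                                               length = 14)),
                           coordNoise = 0.03, seed = 3)
  labH <- assignSecondaryStructure(helix)
  expect_true(all(labH[3:11, ] == "alpha-helix"))
  hairpin <- makeToyEnsemble(2, plan = list(list(type = "hairpin",
                                                 length = 19)),
                             coordNoise = 0.03, seed = 4)
  labB <- assignSecondaryStructure(hairpin)
  expect_gt(mean(labB == "beta-sheet"), 0.4)
  # an isolated extended chain can only be coil or turn
  lone <- makeToyEnsemble(2, plan = list(list(type = "strand",
                                              length = 14)),
                          coordNoise = 0.03, seed = 5)
  expect_true(all(assignSecondaryStructure(lone) %in% c("coil", "turn")))
})

test_that("proportion statistics follow the counting definitions", {
  set.seed(23)
  n <- 40; nconf <- 25
  lab <- matrix(sample(SS_CLASSES, n * nconf, replace = TRUE,
                       prob = c(0.15, 0.35, 0.05, 0.3, 0.15)), n, nconf)
  rownames(lab) <- seq_len(n) + 4L
  prof <- ssProportions(lab)
  expect_lt(max(abs(rowSums(prof@proportions) - 1)), 1e-12)
  # counting oracle
  for (z in SS_CLASSES)
    expect_equal(unname(prof@proportions[, z]),
                 unname(rowMeans(lab == z)))
  expect_identical(prof@betaCore,
                   as.integer(rownames(lab)[rowMeans(lab ==
                                                       "beta-sheet") > 0.5]))
  core <- match(prof@betaCore, as.integer(rownames(lab)))
  expect_equal(prof@perConformerBeta,
               colSums(lab[core, , drop = FALSE] == "beta-sheet") /
                 length(core))
  expect_true(all(prof@perConformerBeta >= 0 &
                    prof@perConformerBeta <= 1))

  # exactly 50% beta is NOT in the core (strictly more than half)
  lab2 <- matrix(rep(c("beta-sheet", "coil"), each = 2), 10, 4,
                 byrow = TRUE)
  prof2 <- ssProportions(lab2)
  expect_identical(prof2@betaCore, integer(0))
  # all-beta residue is
  lab3 <- rbind(rep("beta-sheet", 4), lab2[-1, ])
  prof3 <- ssProportions(lab3)
  expect_identical(prof3@betaCore, 1L)
  expect_equal(prof3@proportions[1, "beta-sheet"], 1)
  # a user-defined residue subset replaces the core for P_n
  profSub <- ssProportions(lab, betaSubset = as.integer(rownames(lab)[1:5]))
  expect_equal(profSub@perConformerBeta,
               colSums(lab[1:5, , drop = FALSE] == "beta-sheet") / 5)
})

test_that("marker distances equal direct norms and honor requested targets", {
  ens <- makeToyEnsemble(3, seed = 29)
  d <- loopDistance(ens, 5, 12)
  hand <- vapply(1:3, function(k)
    sqrt(sum((ens@coords$CA[5, , k] - ens@coords$CA[12, , k])^2)),
    numeric(1))
  expect_equal(unname(d), hand)
  expect_equal(unname(loopDistance(ens, 7, 7)), rep(0, 3))
  # hinge-rotated plan hits the requested AB-loop-style distance
  plan <- list(list(type = "coil", length = 9),
               list(type = "strand", length = 25),
               list(type = "coil", length = 6))
  for (target in c(20, 8)) {
    e <- makeToyEnsemble(3, plan = plan, coordNoise = 0.05,
                         loopTarget = list(resA = 17, resB = 24,
                                           distance = target),
                         seed = 31)
    expect_lt(max(abs(loopDistance(e) - target)), 0.5)
  }
})

test_that("contact-map clustering recovers planted partitions deterministically", {
  e1 <- makeToyEnsemble(6, plan = list(list(type = "hairpin",
                                            length = 20)),
                        coordNoise = 0.05, seed = 1)
  e2 <- makeToyEnsemble(6, plan = list(list(type = "helix",
                                            length = 20)),
                        coordNoise = 0.05, seed = 2)
  ens <- bindEnsembles(e1, e2)
  cl <- clusterEnsemble(ens, NULL, k = 2, seed = 101)
  truth <- rep(1:2, each = 6)
  # label-permutation-invariant comparison
  agree <- max(mean(cl$labels == truth), mean(cl$labels == 3 - truth))
  expect_equal(agree, 1)
  # deterministic under the seed
  cl2 <- clusterEnsemble(ens, NULL, k = 2, seed = 101)
  expect_identical(cl$labels, cl2$labels)
  expect_equal(cl$embedding, cl2$embedding)
  # component variances non-increasing
  expect_true(all(diff(cl$variance) <= 1e-12))
  # k larger than the support errors
  w <- setNames(c(rep(1 / 3, 3), rep(0, 9)), conformerIds(ens))
  expect_error(clusterEnsemble(ens, w, k = 5), "exceeds")
  # identical maps collapse to one effective cluster with zero variance
  same <- makeToyEnsemble(1, plan = list(list(type = "hairpin",
                                              length = 20)),
                          coordNoise = 0, seed = 7)
  dup <- bindEnsembles(same, same)
  expect_warning(cl3 <- clusterEnsemble(dup, NULL, k = 2, seed = 1),
                 "distinct")
  expect_identical(unname(cl3$labels), rep(1L, 2))
  expect_lt(max(abs(cl3$embedding)), 1e-9)
})
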