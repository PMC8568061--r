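test_that("NMR-STAR chemical-shift loops are parsed onto the backbone set", {
  path <- withr::local_tempfile(fileext = ".str")
  writeLines(starFixture(), path)
  st <- readNmrStarShifts(path)
  expect_s4_class(st, "ShiftTable")
  expect_identical(residueNumbers(st), 2:4)
  expect_equal(sum(assignedMask(st)), 12L)

  # a CO row is dropped without touching the backbone entries
  pathCO <- withr::local_tempfile(fileext = ".str")
  writeLines(starFixture(extraRows = "99 3 LEU C 176.20"), pathCO)
  expect_message(stCO <- readNmrStarShifts(pathCO), "outside the backbone")
  expect_equal(shiftValues(stCO), shiftValues(st))

  # missing loop and duplicate rows are hard errors
  pathBad <- withr::local_tempfile(fileext = ".str")
  writeLines(c("data_x", "loop_", "_Other.tag", "1", "stop_"), pathBad)
  expect_error(readNmrStarShifts(pathBad), "chemical-shift loop")
  pathDup <- withr::local_tempfile(fileext = ".str")
  writeLines(starFixture(extraRows = "99 3 LEU CA 55.00"), pathDup)
  expect_error(readNmrStarShifts(pathDup), "duplicate")
})

test_that("all predictor dialects normalize to the same ShiftTable", {
  df <- dialectFrame(5)
  gen <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, gen, row.names = FALSE)
  base <- readPredictorTable(gen, "generic-csv")
  expect_equal(sum(assignedMask(base)), 20L)

  sx2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(NUM = df$residue_number, RES = df$residue_name,
                       ATOMNAME = df$nucleus, SHIFT = df$shift),
            sx2, row.names = FALSE)
  expect_identical(shiftValues(readPredictorTable(sx2, "shiftx2")),
                   shiftValues(base))

  sp <- withr::local_tempfile(fileext = ".tab")
  writeLines(c("REMARK fixture",
               "VARS RESID RESNAME ATOMNAME SS_SHIFT SHIFT SIGMA",
               sprintf("%4d %4s %4s %9.3f %9.3f %9.3f", df$residue_number,
                       df$residue_name, df$nucleus, 0, df$shift, 0.2)),
             sp)
  expect_equal(shiftValues(readPredictorTable(sp, "spartaplus")),
               shiftValues(base))

  wide <- data.frame(RESNUM = unique(df$residue_number),
                     RESNAME = df$residue_name[df$nucleus == "H"],
                     H = df$shift[df$nucleus == "H"],
                     N = df$shift[df$nucleus == "N"],
                     CA = df$shift[df$nucleus == "CA"],
                     CB = df$shift[df$nucleus == "CB"])
  ub <- withr::local_tempfile(fileext = ".csv")
  write.csv(wide, ub, row.names = FALSE)
  expect_identical(shiftValues(readPredictorTable(ub, "ucbshift")),
                   shiftValues(base))

  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(readPredictorTable(empty, "generic-csv"), "empty|format")
})

test_that("the normalized table format round-trips to 1e-6 ppm", {
  set.seed(42)
  vals <- matrix(round(rnorm(20, 60, 25), 5), 5)
  vals[2, 1] <- NA  # an unassigned entry must survive as absent
  tab <- quickTable(vals, numbers = 11:15)
  path <- withr::local_tempfile(fileext = ".csv")
  writeShiftTable(tab, path)
  back <- readShiftTable(path)
  expect_identical(residueNumbers(back), 11:15)
  expect_identical(is.na(shiftValues(back)), is.na(shiftValues(tab)))
  expect_lt(max(abs(shiftValues(back) - shiftValues(tab)), na.rm = TRUE),
            1e-6)
})

test_that("the exclusion rule keeps exactly the fully assigned overlap", {
  fx <- mixtureFixture(nConformers = 5, seed = 11)
  lib <- fx$library
  ref <- fx$mix$reference
  masked <- applyExclusionMask(lib, ref)

  # prolines (no HN) and glycines (no CB) are always excluded
  proGly <- ref@residues$number[ref@residues$name %in% c("PRO", "GLY")]
  expect_true(all(proGly %in% masked$excluded))
  expect_false(any(proGly %in% residueNumbers(masked$reference)))

  # retained residues are fully assigned everywhere
  expect_false(anyNA(shiftValues(masked$reference)))
  for (i in seq_along(lib)) {
    expect_false(anyNA(shiftValues(masked$library[[i]])))
    expect_identical(residueNumbers(masked$library[[i]]),
                     residueNumbers(masked$reference))
  }

  # knocking out one CB in the reference excludes that residue
  vals <- shiftValues(ref)
  target <- residueNumbers(masked$reference)[3]
  vals[as.character(target), "CB"] <- NA
  ref2 <- ShiftTable("ref2", ref@residues, vals)
  masked2 <- applyExclusionMask(lib, ref2)
  expect_true(target %in% masked2$excluded)
  expect_identical(setdiff(residueNumbers(masked$reference),
                           residueNumbers(masked2$reference)),
                   target)

  # idempotence
  again <- applyExclusionMask(masked$library, masked$reference)
  expect_identical(residueNumbers(again$reference),
                   residueNumbers(masked$reference))
  expect_length(again$excluded, 0L)

  # fully assigned reference with no Pro/Gly excludes nothing
  full <- quickTable(matrix(rnorm(16, 50, 10), 4), numbers = 1:4)
  libFull <- ShiftLibrary(list(full, full), c("a", "b"))
  expect_length(applyExclusionMask(libFull, full)$excluded, 0L)
})
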