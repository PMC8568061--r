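# Fixture builders shared across the suite. Everything is generated in
# code; no external data files.

# hand-written NMR-STAR text for a residue range with all four nuclei
starFixture <- function(residues = 2:4,
                        names = c("ALA", "LEU", "SER"),
                        extraRows = character()) {
  rows <- character()
  id <- 0L
  for (k in seq_along(residues)) {
    for (atom in c("H", "N", "CA", "CB")) {
      id <- id + 1L
      val <- switch(atom, H = 8 + k / 10, N = 115 + k, CA = 50 + k,
                    CB = 20 + 3 * k)
      rows <- c(rows, sprintf("%d %d %s %s %.2f", id, residues[k],
                              names[k], atom, val))
    }
  }
  c("data_test", "save_assigned_chemical_shifts", "loop_",
    "_Atom_chem_shift.ID", "_Atom_chem_shift.Comp_index_ID",
    "_Atom_chem_shift.Comp_ID", "_Atom_chem_shift.Atom_ID",
    "_Atom_chem_shift.Val",
    rows, extraRows, "stop_", "save_")
}

# a long-format shift data.frame for dialect fixtures
dialectFrame <- function(n = 5, seed = 1) {
  set.seed(seed)
  data.frame(
    residue_number = rep(seq(2, length.out = n), each = 4),
    residue_name = rep(sample(c("ALA", "LEU", "SER", "VAL", "THR"), n,
                              replace = TRUE), each = 4),
    nucleus = rep(c("H", "N", "CA", "CB"), n),
    shift = round(rep(c(8.2, 120, 55, 35), n) + rnorm(4 * n), 3)
  )
}

# small ShiftTable straight from values
quickTable <- function(values, numbers = seq_len(nrow(values)),
                       names = rep("ALA", nrow(values)), id = "tab") {
  colnames(values) <- c("HN", "NH", "CA", "CB")
  ShiftTable(id, data.frame(number = numbers, name = names), values)
}

# random fully-assigned library + scaled-space mixture reference
mixtureFixture <- function(nConformers = 20, nResidues = 24, seed = 1,
                           weights = c(`1` = 0.5, `2` = 0.3, `3` = 0.2),
                           noise = 0, space = "scaled") {
  ens <- makeToyEnsemble(nConformers,
                         plan = list(list(type = "hairpin",
                                          length = nResidues %/% 2),
                                     list(type = "helix",
                                          length = nResidues %/% 4),
                                     list(type = "coil",
                                          length = nResidues -
                                            nResidues %/% 2 -
                                            nResidues %/% 4)),
                         seed = seed)
  lib <- makeShiftLibrary(ens, seed = seed + 1)
  mix <- makeReference(lib, weights, noise = noise, space = space,
                       seed = seed + 2)
  masked <- applyExclusionMask(lib, mix$reference)
  model <- fitReferenceRange(masked$reference)
  problem <- buildRegressionProblem(masked$library, masked$reference,
                                    model)
  list(ensemble = ens, library = lib, mix = mix, masked = masked,
       model = model, problem = problem)
}

# STRIDE report text from a matrix of one-letter codes (rows = residues,
# cols = conformers)
strideFixture <- function(codes) {
  lines <- character()
  for (k in seq_len(ncol(codes))) {
    lines <- c(lines, sprintf(
      "ASG  ALA A %4d %4d    %s    Label          -60.00    -40.00     20.0      ~~~~",
      seq_len(nrow(codes)), seq_len(nrow(codes)), codes[, k]))
  }
  c("REM stride fixture", lines)
}

# DSSP report text (single conformer) from one-letter codes
dsspFixture <- function(codes) {
  c("==== Secondary Structure Definition fixture ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    sprintf("%5d%5d A A  %s   0   0    0", seq_along(codes),
            seq_along(codes), codes))
}

# merge two ConformerEnsembles with the same residue list
bindEnsembles <- function(e1, e2) {
  n1 <- length(conformerIds(e1)); n2 <- length(conformerIds(e2))
  nres <- nrow(e1@residues)
  co <- lapply(names(e1@coords), function(nm) {
    a <- array(NA_real_, c(nres, 3L, n1 + n2))
    a[, , seq_len(n1)] <- e1@coords[[nm]]
    a[, , n1 + seq_len(n2)] <- e2@coords[[nm]]
    a
  })
  names(co) <- names(e1@coords)
  new("ConformerEnsemble",
      conformerIds = sprintf("m%03d", seq_len(n1 + n2)),
      residues = e1@residues, coords = co, weights = numeric())
}

# random simplex vector
randomSimplex <- function(n) {
  w <- stats::rexp(n)
  w / sum(w)
}
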