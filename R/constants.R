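# Random-coil backbone chemical shifts (ppm) and secondary-structure
# offsets used by the synthetic shift generator. Values are rounded
# literature-style random-coil shifts; the generator's tests rely on the
# relative structure (offset signs, per-nucleus scale), not the absolute
# numbers.
.RANDOM_COIL <- matrix(c(
  # HN,    NH,    CA,   CB
  8.24, 123.8, 52.5, 19.1,  # ALA
  8.23, 120.5, 56.0, 30.9,  # ARG
  8.40, 118.7, 53.1, 38.9,  # ASN
  8.34, 120.4, 54.2, 41.1,  # ASP
  8.32, 118.8, 58.2, 28.0,  # CYS
  8.32, 119.8, 55.7, 29.4,  # GLN
  8.42, 120.2, 56.6, 29.9,  # GLU
  8.33, 108.8, 45.1, NA,    # GLY (no CB)
  8.42, 118.2, 55.0, 29.0,  # HIS
  8.00, 119.9, 61.1, 38.8,  # ILE
  8.16, 121.8, 55.1, 42.4,  # LEU
  8.29, 120.4, 56.2, 33.1,  # LYS
  8.28, 119.6, 55.4, 32.9,  # MET
  8.30, 120.3, 57.7, 39.6,  # PHE
  NA,   137.0, 63.3, 32.1,  # PRO (no amide H)
  8.31, 115.7, 58.3, 63.8,  # SER
  8.15, 113.6, 61.8, 69.8,  # THR
  8.25, 121.3, 57.5, 29.6,  # TRP
  8.12, 120.3, 57.9, 38.8,  # TYR
  8.03, 119.2, 62.2, 32.9   # VAL
), ncol = 4, byrow = TRUE, dimnames = list(
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"),
  c("HN", "NH", "CA", "CB")))

# Secondary-structure shift offsets (ppm): helix raises CA and lowers CB,
# sheet does the opposite; amide shifts move up in sheets.
.SS_OFFSET <- matrix(c(
  # HN,    NH,   CA,   CB
  -0.25, -1.5,  2.6, -0.4,  # alpha-helix
   0.35,  2.0, -1.5,  2.2,  # beta-sheet
  -0.15, -1.0,  1.5, -0.2,  # 310-helix
   0.00,  0.0,  0.0,  0.0,  # coil
   0.00,  0.0,  0.0,  0.0   # turn
), ncol = 4, byrow = TRUE, dimnames = list(
  c("alpha-helix", "beta-sheet", "310-helix", "coil", "turn"),
  c("HN", "NH", "CA", "CB")))
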