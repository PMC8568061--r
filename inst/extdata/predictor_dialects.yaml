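# Column mappings for the supported chemical-shift predictor output dialects.
# Atom names in every dialect are normalized onto the canonical nucleus set
# {HN, NH, CA, CB}: H/HN -> HN, N/NH -> NH, CA -> CA, CB -> CB; any other
# atom (CO, HA, sidechain) is dropped on read.
generic-csv:
  layout: long
  columns:
    residue_number: residue_number
    residue_name: residue_name
    nucleus: nucleus
    shift: shift        # header shift_ppm (normalized format) also accepted
ucbshift:
  layout: wide
  columns:
    residue_number: RESNUM
    residue_name: RESNAME
  atom_columns: [H, HN, N, NH, CA, CB]   # one shift column per atom
shiftx2:
  layout: long
  columns:
    residue_number: NUM
    residue_name: RES
    nucleus: ATOMNAME
    shift: SHIFT
spartaplus:
  layout: whitespace
  header: VARS          # VARS line names the columns; positional fallback
  columns:
    residue_number: RESID
    residue_name: RESNAME
    nucleus: ATOMNAME
    shift: SHIFT
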