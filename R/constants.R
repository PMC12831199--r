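# Shared residue-code tables.
# One- from three-letter codes; MSE (selenomethionine) maps to M, anything
# else without a standard parent maps to 'X' and never matches a motif.
AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M")

AA_123 <- stats::setNames(names(AA_321)[1:20], unname(AA_321)[1:20])

STANDARD_AA <- unname(AA_321[1:20])

WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")
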