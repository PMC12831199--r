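# Fixtures built in code at test time; nothing binary on disk.

# minimal hand-written PDB text: ALA + GLY, backbone only
two_residue_pdb <- function() {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 90.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 90.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00 90.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00 90.00           O",
    "ATOM      5  N   GLY A   2       3.332   1.536   0.000  1.00 90.00           N",
    "ATOM      6  CA  GLY A   2       3.988   2.831   0.000  1.00 90.00           C",
    "ATOM      7  C   GLY A   2       5.504   2.705   0.000  1.00 90.00           C",
    "ATOM      8  O   GLY A   2       6.030   1.593   0.000  1.00 90.00           O",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# a PDB with altloc A and B copies of one atom, plus a water and an MSE
altloc_mse_pdb <- function() {
  lines <- c(
    "ATOM      1  N   MSE A   1       0.000   0.000   0.000  1.00 90.00           N",
    "ATOM      2  CA AMSE A   1       1.458   0.000   0.000  0.60 90.00           C",
    "ATOM      3  CA BMSE A   1       1.470   0.100   0.000  0.40 90.00           C",
    "ATOM      4  C   MSE A   1       2.009   1.420   0.000  1.00 90.00           C",
    "ATOM      5  O   MSE A   1       1.251   2.390   0.000  1.00 90.00           O",
    "HETATM    6  O   HOH A 101      9.000    9.000   9.000  1.00  0.00           O",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

helix_model <- function(n = 20, seq = strrep("A", n), id = "helix") {
  build_backbone(seq, dihedrals_preset(nchar(seq), "helix"), model_id = id)
}

hairpin_model <- function(strand_len = 6, id = "hairpin") {
  n <- 2 * strand_len + 2
  build_backbone(strrep("A", n), dihedrals_hairpin(strand_len), model_id = id)
}

# deterministic benchmark shared by several test files (generated once per
# test run)
benchmark_fixture <- local({
  cache <- NULL
  function(seed = 42) {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), paste0("funnel_bench_", seed))
      cache <<- generate_funnel_benchmark(dir, seed = seed)
    }
    cache
  }
})
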