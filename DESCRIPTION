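Package: slimscan
Title: Structural-Context Discovery of Short Linear Motifs in Predicted Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scans proteomes of predicted protein structures for degenerate
    five-residue short linear motifs (SLiMs) and filters the matches by
    structural context. Provides PDB/mmCIF structure input and output,
    per-residue secondary-structure assignment from backbone hydrogen bonding
    (Kabsch-Sander energies with turn and bridge rules), degenerate motif
    pattern compilation and scanning, evaluation of two-chain complex
    predictions (interface contacts, motif helicity, hydrogen-bond orientation,
    predicted-aligned-error and ipTM evidence), a staged candidate-filtering
    funnel with machine-readable reports, and a synthetic-structure generator
    that builds ideal-geometry backbones, toy proteomes with planted motifs,
    localization tables and binder/non-binder complex bundles for ground-truth
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
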