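---
title: "Structural-context discovery of a five-residue SHD1-binding motif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural-context discovery of a five-residue SHD1-binding motif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimscan)
```

## The problem

Short linear motifs (SLiMs) are compact interaction elements, typically
3–10 residues, that live in intrinsically disordered protein regions and are
recognised by folded domains. The motif this package targets is a
five-residue element with consensus (V/I)-(I/L)-(D/S)-(L/A)-Y that binds the
hydrophobic groove of the SHD1 domain of the fungal polarisome scaffold
Spa2 (GIT1/2 in mammals). Positions are labelled −2, −1, 0, +1, +2, with the
Asp/Ser anchor at 0 and the conserved Tyr at +2. On binding, the motif folds
from disorder into a short α-helix inside the groove; the Tyr(+2) hydroxyl
hydrogen-bonds one of two symmetry-related aspartates on the receptor
(Asp112 in the canonical helix orientation, Asp62 in the flipped one).

A degenerate five-position pattern matches often by chance in any proteome,
so raw sequence hits are filtered by structural context and by complex-level
evidence. `slimscan` implements that funnel as five computational stages:

1. pattern match over a proteome of predicted structures;
2. structural context: no motif residue in β-strand (the motif must lie in
   unfolded or helical regions, mixtures included);
3. cytosolic localization;
4. a predicted two-chain complex in which the motif is helical *and*
   contacts the receptor's hydrophobic groove;
5. interface confidence: complex ipTM at least that of a reference complex
   (the weakest experimentally validated binder).

A sixth, experimental stage (an in-vivo competition assay) exists in the
underlying screening strategy; the report echoes it as
`experimental_validation: pending` and never computes it.

## Secondary structure from backbone hydrogen bonds

Per-residue labels come from a Kabsch–Sander-style assignment implemented in
the package (`assign_secondary_structure()`). Amide hydrogens are placed on
each N, 1.01 Å opposite the preceding carbonyl C→O direction; prolines,
chain-initial residues and residues after a chain break get none. The
electrostatic bond energy between a donor (N–H) and an acceptor (C=O) is

E = 0.084 · 332 · (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol,

with distances in Å; a bond is accepted below −0.5 kcal/mol. Two consecutive
n-turns (a bond from residue i+n back to i, n ∈ {3, 4, 5}) define helices;
parallel/antiparallel bridge patterns define strand; everything else —
including turns and bends — is loop. The 8-class alphabet is simplified to
{H, E, C} for the context filter: {H, G, I} → H, {E, B} → E, rest → C.

Two choices here were genuinely open:

* The original screen annotated structures with a molecular-viewer's
  built-in assigner whose algorithm is unpublished. We implement
  Kabsch–Sander energies with standard turn/bridge rules instead: it is
  reproducible, documentable, and agrees with any such assigner on regular
  elements. The method tag is recorded in every annotation. Small
  disagreements on irregular boundaries are possible and acknowledged.
* Whether "loop" includes turns and bends was not stated; we count them as
  loop, consistent with a filter that only excludes strand.

Chain breaks (consecutive Cα–Cα above 4.5 Å) split a chain into segments;
hydrogen bonds are not evaluated across a break. A consequence worth noting:
a planted β-strand context must be a genuinely connected hairpin, not two
disconnected segments.

## Motif scanning

Patterns are compiled from bracket notation (`"[VI][IL][DS][LA]Y"`) into
five position-wise allowed sets. Scanning reports every window, overlapping
windows included, whose residues all belong to their position's set; `X`
(unknown residue) matches nothing. Protein-level funnel counts deduplicate
proteins with several occurrences — the stage counts are counts of
proteins, not of matches. Sequences are extracted from the structure files
themselves, mirroring a structure-file scan; strict-pattern matches are
provably a subset of relaxed-pattern matches.

## Complex evidence

For each candidate, a prediction bundle (two-chain model, PAE matrix JSON,
ipTM) is consumed, never computed. The package derives:

* **Groove contact** — any heavy-atom pair between the five motif residues
  and the receptor's hydrophobic patch {48, 51, 59, 98, 101, 109} within
  4.5 Å. The minimum distance is reported even without contact.
* **Motif helicity in the complex** — at least 4 of the 5 motif residues
  labelled H on the ligand chain in its bound conformation.
* **Orientation** — canonical_D112 when the Tyr(+2) hydroxyl is within the
  3.5 Å hydrogen-bond cutoff of Asp112's carboxylate and closer to it than
  to Asp62; flipped_D62 symmetrically; otherwise indeterminate. A non-Tyr
  at +2 is "not applicable", which is distinct from indeterminate. An
  orientation claim additionally requires groove contact.
* **Interface PAE** — mean and minimum over *both* off-diagonal blocks of
  the PAE matrix (PAE is asymmetric) restricted to motif × receptor pairs.

The 4.5 Å heavy-atom and 3.5 Å hydrogen-bond cutoffs are standard
structural-biology conventions; the screen itself published no numeric
criterion for "binds the groove", so the contact rule is a declared,
configurable operationalisation (`groove_definition()`). Groove numbering
follows the full-length receptor; a `numbering_offset` maps fragment chains.
The stage-5 comparison is inclusive (≥): a candidate whose ipTM exactly
equals the reference survives.

## What the synthetic generator emulates

`generate_funnel_benchmark()` builds ground-truth inputs for every stage
with no downloads:

* **Backbones** are built by NeRF internal-to-Cartesian extension with ideal
  bond lengths/angles (N–CA 1.458, CA–C 1.525, C–N 1.329 Å; trans peptide),
  dihedral presets helix (−57°, −47°) and strand (−139°, 135°), carbonyl O
  in the peptide plane and a tetrahedral Cβ. Consecutive Cα–Cα distances
  come out at 3.80 Å and ideal helices hydrogen-bond i→i+4, so the
  assigner labels them H without any circular calibration.
* **Strand context** uses a β-hairpin: two ideal antiparallel strands joined
  by a two-residue turn whose torsions were derived once by numerically
  optimising the Kabsch–Sander energies of the intended cross-strand bonds
  under ideal geometry, then frozen as a named preset. The five residues
  entering the turn register as E at any strand length.
* **Coil** torsions are drawn uniformly from a broad φ ∈ (−140°, −60°),
  ψ ∈ (−50°, 110°) window that avoids the narrow strand/polyproline band;
  the spread prevents regular ladders. Planted windows are verified against
  the intended context and re-drawn (bounded retries) if an accidental
  regular element forms, so the truth table stays exact.
* **Background sequences** use the 19 standard letters without Tyr: since
  the motif requires Tyr at +2, every motif occurrence in a toy proteome is
  a planted one and the truth table is exhaustive. An internal oracle
  re-scan nevertheless records any accidental match. This is the one
  deliberate unrealism of the sequence model.
* **The mock receptor** is a generated five-helix bundle renumbered so the
  groove residues exist with the expected side-chain atom names (Leu patch,
  Lys97, Asp62/Asp112 with OD1/OD2). Side chains beyond Cβ are coarse
  stubs along the Cα→Cβ direction — enough geometry for contacts and
  hydrogen-bond distances, explicitly not a rotamer model. Binder ligands
  are helical peptides rigidly placed so the Tyr(+2) hydroxyl sits 2.8 Å
  from the chosen aspartate; non-binders violate exactly their designed
  failure criterion (chains separated by 100 Å, an extended motif, or an
  ipTM below reference with intact geometry).
* **PAE matrices** have small within-chain values and cross-chain blocks
  drawn from a truncated normal (mean 4.5 Å for confident interfaces,
  18 Å otherwise, clamped to [0.2, 31.75]); **ipTM** draws 0.10–0.30 above
  the reference for binders and 0.05–0.20 below for stage-5 failures. The
  reference value defaults to 0.50 — the screen reports only that its
  reference complex scores lowest among the validated binders, so the value
  was fixed once at a plausible weak-complex confidence and is a parameter
  of every generator.

All generators are pure functions of (parameters, seed); identical calls
produce byte-identical files.

Because geometry is ideal and noise-free, passing the benchmark shows the
*logic* of every stage is correct — it does not show robustness to the
conformational heterogeneity, low-confidence regions, or annotation noise
of real predicted proteomes. On the real archive the strand/loop boundary
cases are where assigner choice can shift a handful of proteins between
stages 1 and 2.

## Numerical choices and degenerate inputs

* Bond acceptance −0.5 kcal/mol; chain-break threshold 4.5 Å Cα–Cα.
* Missing atoms make a hydrogen bond "not evaluable", never silently zero;
  residues without labels exclude a candidate with reason `unannotated`.
* Chains shorter than 3 residues are all loop; a 3-residue ligand fragment
  is "not evaluable" for helicity.
* Altloc handling keeps blank/'A' copies only; first model of multi-model
  files; MSE maps to Met, other non-standard residues to X.
* Unknown-localization policy defaults to keep-and-flag (strict mode
  drops); the published stage counts cannot disambiguate the two, so the
  permissive reading is the default and both are exposed.
* Proteome iteration is lexicographic by entry name, making runs
  deterministic; unparseable entries are skipped with a logged reason, and
  "no files" is distinguished from "all files failed".

## Problem sizes

The shipped benchmark uses 25 proteins (19 with one planted motif each:
4 binders, 1 reference, 4 strand-context, 3 non-cytosolic, 4 groove/helicity
failures, 3 ipTM failures) of 40–90 residues, and 12 complex bundles of
~137 residues — sizes chosen so the whole suite, including the
1000-sequence scanner/oracle comparison and the brute-force secondary-
structure oracle on chains up to 30 residues, runs in well under five
minutes on one CPU. The same pipeline runs unchanged on a full predicted
proteome archive (a directory or tar of AlphaFold-DB-style files); that run
is not part of the test suite because it requires a multi-gigabyte
download.

## Known limitations

* The secondary-structure assigner reproduces standard turn/bridge rules
  but is not guaranteed to match any specific third-party assigner
  residue-for-residue on irregular elements.
* Side-chain geometry in synthetic complexes is stub-level; contact counts
  on real models will differ in magnitude (the boolean criteria are what
  the funnel uses).
* PAE/ipTM are consumed, not validated: garbage confidence values in,
  garbage stage-5 decisions out.
* The localization stage is as good as the user-supplied table; no
  annotation database is bundled.
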