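#!/usr/bin/env Rscript
# Step 3: interface evidence for every complex-prediction bundle.
#
# For each candidate bundle: does the motif contact the hydrophobic groove,
# is it helical in the complex, which way does the Tyr(+2) hydroxyl point
# (Asp112 = canonical, Asp62 = flipped), and how confident is the interface
# (mean cross-chain PAE, ipTM)?

suppressMessages(library(slimscan))

bench_dir <- "scratch/funnel-benchmark"
bundles <- list.dirs(file.path(bench_dir, "bundles"), recursive = FALSE)
if (length(bundles) == 0) stop("run analysis/01_simulate.R first")

g <- groove_definition()
rows <- lapply(sort(bundles), function(b) {
  pred <- read_complex_bundle(b)
  # the ligand is a fragment; locate its motif by scanning its sequence
  lig <- chain_ids(pred$model)[2]
  hit <- scan_sequence(extract_sequence(pred$model, lig),
                       frm_pattern("relaxed"))
  ev <- evaluate_complex(pred, g, motif_start = hit$start[1])
  data.frame(candidate = pred$candidate_id,
             groove_contact = ev$groove_contact,
             n_contacts = ev$n_contact_pairs,
             min_dist = round(ev$min_dist, 2),
             helical = ev$motif_helical,
             orientation = ev$orientation,
             mean_pae = round(ev$mean_interface_pae, 2),
             iptm = ev$iptm)
})
evidence <- do.call(rbind, rows)
print(evidence, row.names = FALSE)
write.table(evidence, "results/03_interface_evidence.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nEvidence table -> results/03_interface_evidence.tsv\n")
cat("Binders show groove contact + helical motif + low PAE;",
    "designed non-binders each violate exactly one criterion.\n")
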