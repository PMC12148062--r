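#!/usr/bin/env Rscript
# Step 1 — simulate the study.
#
# Generates the labeled single-cell reference (6 NVU cell types, planted
# marker and enriched-gene tiers, the endothelium-restricted Pdyn ligand and
# the broadly expressed Oprk1 receptor) and the 132-segment ROI cohort
# (12 mice, genotype x sex balanced, 11 ROIs each) with full ground truth:
# mixing fractions on the neurovascular gradient, the +0.05 APP+ microglia
# shift, 2-fold genotype effects in the endothelial contribution, and the
# correlated Pdyn -> Oprk1 pair. Writes the on-disk bundle and caches the
# objects for the later steps.

suppressPackageStartupMessages(library(nvudeconv))

seed <- 1
out <- "results"
dir.create(file.path(out, "cache"), recursive = TRUE, showWarnings = FALSE)
dir.create(file.path(out, "data"), recursive = TRUE, showWarnings = FALSE)
dir.create(file.path(out, "truth"), recursive = TRUE, showWarnings = FALSE)

message("simulating single-cell reference and ROI cohort (seed ", seed, ")")
ref <- generate_reference_scrna(seed = seed)
sim <- generate_roi_dataset(ref, seed = seed)

write_geomx_bundle(sim$expr, sim$annot, file.path(out, "data"))
write_single_cell(ref$sc, file.path(out, "data", "single_cell"))
write_gmt(ref$signatures, file.path(out, "data", "marker_signatures.gmt"))
lr_tab <- data.frame(lr_pair = "Pdyn_Oprk1",
                     ligand_gene_symbol = "Pdyn",
                     receptor_gene_symbol = "Oprk1")
write.table(lr_tab, file.path(out, "data", "lr_pairs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

write_tables(list(fractions_truth = data.frame(
  segment_id = rownames(sim$truth$fractions), sim$truth$fractions,
  check.names = FALSE),
  de_truth = sim$truth$de,
  lr_truth = sim$truth$lr), file.path(out, "truth"))

saveRDS(ref, file.path(out, "cache", "ref.rds"))
saveRDS(sim, file.path(out, "cache", "sim.rds"))

message(sprintf("wrote %d segments x %d genes (%d negative probes); %d cells",
                ncol(sim$expr$counts), sum(!sim$expr$negative),
                sum(sim$expr$negative), nrow(ref$sc$counts)))
pos <- sim$annot$genotype == "APP+"
message(sprintf("ground truth: microglia shift %+0.3f; endothelial-neuron Spearman %0.2f",
                mean(sim$truth$fractions[pos, "Microglia"]) -
                  mean(sim$truth$fractions[!pos, "Microglia"]),
                cor(sim$truth$fractions[, "Endothelial"],
                    sim$truth$fractions[, "Neuron"], method = "spearman")))
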