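#!/usr/bin/env Rscript
# Step 3 — signature scoring and the deconvolution reference.
#
# Scores each single-cell cluster against the marker signatures (rank-based
# Mann-Whitney U score), consolidates clusters into cellular units
# (here the 6 generated types map to themselves; with a real 14-cluster
# reference this is where the hierarchy is cut), selects the cells closest
# to each unit centroid and the most unit-specific genes, and builds the
# genes x units reference.

suppressPackageStartupMessages(library(nvudeconv))
out <- "results"

ref <- readRDS(file.path(out, "cache", "ref.rds"))
sigs <- ref$signatures

rb <- build_reference_pipeline(ref$sc, sigs, min_cells = 100, k_units = 6,
                               n_per_unit = 1500, n_genes = 1500)

write_tables(data.frame(cluster = rownames(rb$scores), rb$scores,
                        check.names = FALSE), out, name = "cluster_scores")
write_tables(rb$mapping$mapping, out, name = "unit_mapping")
write_tables(data.frame(gene = rownames(rb$reference), rb$reference,
                        check.names = FALSE), out, name = "reference_matrix")
saveRDS(rb, file.path(out, "cache", "reference.rds"))

message(sprintf("reference: %d genes x %d units from %d selected cells",
                nrow(rb$reference), ncol(rb$reference),
                nrow(rb$cells$counts)))
message("per-cluster argmax signature: ",
        paste(rownames(rb$scores),
              colnames(rb$scores)[apply(rb$scores, 1, which.max)],
              sep = "->", collapse = ", "))
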