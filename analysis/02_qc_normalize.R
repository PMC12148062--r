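#!/usr/bin/env Rscript
# Step 2 — negative-probe QC and normalization.
#
# Computes each segment's limit of quantification (geometric mean of the
# negative probes times geoSD^1.5), filters target genes to those detected
# above the LOQ in at least 10% of segments, and applies Q3 (upper-quartile)
# between-segment normalization.

suppressPackageStartupMessages(library(nvudeconv))
out <- "results"

bundle <- load_geomx_bundle(file.path(out, "data", "counts.tsv"),
                            file.path(out, "data", "segments.tsv"))
expr <- bundle$expr

loq <- loq_table(expr, exponent = 1.5)
filtered <- filter_by_loq(expr, loq, min_rate = 0.1)
norm_lin <- q3_normalize(filtered, log2_out = FALSE)
norm_log <- nvu_expr(log2(norm_lin$counts + 1), negative = norm_lin$negative,
                     stage = "log2")

write_tables(data.frame(segment_id = names(loq$loq), loq = loq$loq),
             out, name = "loq")
write_tables(norm_log, out, name = "expression_normalized_log2")
saveRDS(list(loq = loq, filtered = filtered, norm_lin = norm_lin,
             norm_log = norm_log),
        file.path(out, "cache", "qc.rds"))

message(sprintf("LOQ median %0.1f counts; %d of %d target genes pass the 10%% detection gate",
                median(loq$loq), nrow(filtered$counts),
                sum(!expr$negative)))
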