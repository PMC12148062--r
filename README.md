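# nvudeconv

Cell-type deconvolution analysis of GeoMx-style digital spatial profiling
(DSP) data from the neurovascular unit (NVU) — the endothelium, pericytes,
astrocytes, neurons, microglia and oligodendroglia that maintain the
blood–brain barrier. DSP regions of interest (ROIs) drawn over CD31-stained
vasculature are still cellular mixtures; this package implements the full
chain from raw ROI count matrices to cell-type-resolved biology:

1. **QC and normalization** — per-segment limit of quantification from
   negative probes, `LOQ = geomean(neg) × geoSD(neg)^1.5`; genes kept when
   detected above the LOQ in ≥ 10 % of segments; Q3 (upper-quartile)
   between-segment normalization.
2. **Signature scoring and reference construction** — rank-based
   (Mann–Whitney U) signature scores in [0, 1] for cells and segments;
   hierarchical consolidation of single-cell clusters into cellular units
   (clusters with ≤ 100 cells dropped); per-unit selection of the 1,500
   cells closest to the unit centroid (Spearman to the mean log1p profile)
   and of unit-specific genes (non-zero prevalence × mean non-zero
   expression, specificity-ratio ranked); the genes × units reference is the
   per-cell CP10K mean.
3. **Deconvolution** — per-segment unit fractions by non-negative least
   squares of the linear profile on the reference columns (gene-wise
   precision weights, simplex renormalization); Wilcoxon rank-sum tests of
   unit abundance between APP+ and APP− genotypes.
4. **Knockoff purification** — 30 SVD-based knockoff pseudo-replicates per
   segment (rank-r signal preserved exactly, residual rotated by a seeded
   orthogonal transform); fractions re-estimated on every replicate; a
   collated per-gene NNLS over the whole replicate ensemble gives
   cohort-level unit expression (reference-support constrained,
   genotype-adjusted, with a proportional-allocation fallback where
   attribution is unidentifiable), which allocates each segment's observed
   expression into per-segment, per-unit expression levels. Segments with
   ≥ 2 missing units are removed as unstable.
5. **Cell-type differential expression** — sex-adjusted moderated-t
   (empirical-Bayes variance shrinkage) contrasts of APP+ vs APP− at ROI
   level and within each unit, after the published sample filters
   (log2(median) < 4; 1.5×IQR boxplot outliers on PC1/PC2); diffusion-map
   (Lafon) embedding of the DE genes from sample Spearman correlations.
6. **Enrichment and ligand–receptor networks** — hypergeometric
   over-representation with BH-FDR; directed LR edges where the ligand is
   up-regulated in the source unit, the receptor in the target unit, and
   their purified expressions correlate (Spearman > 0.35), including
   autocrine edges; chord-diagram data export.

Because real NVU DSP cohorts are rarely public, the package ships a
first-class synthetic-data generator with complete ground truth (negative
binomial counts, Dirichlet × neurovascular-gradient mixing fractions, a
genotype-linked microglia shift, planted endothelial 2-fold effects, a
planted correlated `Pdyn → Oprk1` pair, sex as a nuisance covariate,
negative probes), so every stage has a recovery test.

## Worked example

The analysis is organised as numbered drivers under `analysis/`
(`01_simulate.R` … `06_lr_networks.R`), each a thin script over the
package's functions that prints what it found and writes its tables under
`results/`. Running them in order on the default study conditions
(132 segments, 6 units, 2,000 genes, seed 1) prints, among other things:

```
fraction recovery r by unit: Astrocyte=0.964, Endothelial=0.983,
  Microglia=0.943, Neuron=0.986, Oligodendrocyte=0.945, OPC=0.945
median |error| 0.0152; microglia Wilcoxon p = 1.77e-08
endothelial DE: 146 genes p<0.05 (72 up / 59 down); planted-gene AUC 0.917
diffusion embedding: 129 components; |cor(Phi1, genotype)| = 0.85
ORA: 2 of 12 gene sets FDR-significant; top set Endothelial_enriched (odds ratio 51.1)
network: 6 edges over 6 units
planted edges recovered: 4 of 4 (autocrine yes); reverse-direction false edges: 0
```

Reading: estimated unit fractions track the generator's truth (per-unit
Pearson r ≥ 0.94, median absolute error 0.015), the planted +0.05 APP+
microglia abundance shift is detected, the planted endothelial 2-fold genes
are recovered from the purified endothelial expression (AUC 0.917), the
first diffusion coordinate separates the genotypes, over-representation
flags the endothelium-enriched gene tier the effects were planted in, and
the `Pdyn → Oprk1` edges — including the autocrine vasculature edge — are
recovered with no reverse-direction false edge.

The same chain in code:

```r
library(nvudeconv)
ref <- generate_reference_scrna(seed = 1)   # 1,200 cells, 6 types, truth known
sim <- generate_roi_dataset(ref, seed = 1)  # 132 ROIs + annotations + truth
res <- run_nvu_pipeline(sim$expr, sim$annot, ref$sc, ref$signatures,
                        lr_pairs = data.frame(ligand = "Pdyn",
                                              receptor = "Oprk1"),
                        n_genes = 1500, seed = 1)
res$fractions            # segments x units, rows on the simplex
res$abundance$Microglia  # Wilcoxon test of the genotype abundance shift
res$de_by_unit$Endothelial
res$network$edges
```

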