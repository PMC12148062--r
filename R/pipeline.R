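#' @title End-to-end analysis orchestration
#' @description One call from a raw ROI bundle plus a labeled single-cell
#'   reference to fractions, abundance tests, purified cell-type expression,
#'   per-unit differential expression, and the ligand-receptor network — the
#'   chain the numbered analysis scripts drive step by step.
#' @name pipeline
NULL

#' Run the deconvolution analysis end to end
#'
#' QC (LOQ filter, Q3 normalization), reference construction from the labeled
#' single cells, per-segment fraction estimation, knockoff pseudo-replicates,
#' purification, stability filtering, per-unit DE, and (optionally) the
#' ligand-receptor network.
#'
#' @param expr raw ROI \code{\link{nvu_expr}} (with negative probes).
#' @param annot segment annotation.
#' @param sc labeled single-cell reference (\code{\link{nvu_sc}}).
#' @param sigs gene-set collection for consolidation scoring.
#' @param lr_pairs optional ligand-receptor pair table.
#' @param geosd LOQ geometric-SD exponent (default 1.5).
#' @param min_rate LOQ detection-rate gate (default 0.10).
#' @param min_cells,k_units,n_per_unit,n_genes reference-builder settings.
#' @param n_reps,energy knockoff settings (default 30 replicates, 0.90
#'   energy).
#' @param max_missing stability-filter threshold (default 2).
#' @param min_log2_median per-unit sample filter threshold (default 4).
#' @param rho_min,p_cut ligand-receptor gates (default 0.35, 0.05).
#' @param seed integer seed for the knockoff construction.
#' @return list with every intermediate: \code{loq}, \code{filtered},
#'   \code{normalized} (log2), \code{refbuild}, \code{fractions},
#'   \code{abundance} (per-unit Wilcoxon), \code{knockoffs}, \code{purified},
#'   \code{stable}, \code{de_roi}, \code{de_by_unit}, \code{network}.
#' @export
run_nvu_pipeline <- function(expr, annot, sc, sigs, lr_pairs = NULL,
                             geosd = 1.5, min_rate = 0.1,
                             min_cells = 100, k_units = 6,
                             n_per_unit = 1500, n_genes = 3000,
                             n_reps = 30, energy = 0.9, max_missing = 2,
                             min_log2_median = 4, rho_min = 0.35,
                             p_cut = 0.05, seed = 1) {
  loq <- loq_table(expr, exponent = geosd)
  filtered <- filter_by_loq(expr, loq, min_rate = min_rate)
  norm_lin <- q3_normalize(filtered, log2_out = FALSE)
  norm_log <- nvu_expr(log2(norm_lin$counts + 1), negative = norm_lin$negative,
                       stage = "log2")

  refbuild <- build_reference_pipeline(
    sc, sigs, min_cells = min_cells, k_units = k_units,
    n_per_unit = n_per_unit,
    n_genes = min(n_genes, ncol(sc$counts)))

  fractions <- estimate_fractions(norm_lin, refbuild$reference)
  units <- colnames(fractions)
  abundance <- lapply(setNames(units, units), function(u)
    test_abundance_shift(fractions, annot, u))

  knock <- make_knockoffs(norm_lin, n_reps = n_reps, energy = energy,
                          seed = seed)
  purified <- purify_expression(knock, refbuild$reference,
                                covariate = setNames(annot$genotype,
                                                     annot$segment_id))
  stable <- stability_filter(purified, max_missing = max_missing)

  de_roi <- fit_de(norm_log, annot)
  de_by_unit <- fit_de_by_unit(stable, annot,
                               min_log2_median = min_log2_median)
  network <- if (!is.null(lr_pairs))
    build_lr_network(de_by_unit, stable, lr_pairs, rho_min = rho_min,
                     p_cut = p_cut) else NULL

  list(loq = loq, filtered = filtered, normalized = norm_log,
       refbuild = refbuild, fractions = fractions, abundance = abundance,
       knockoffs = knock, purified = purified, stable = stable,
       de_roi = de_roi, de_by_unit = de_by_unit, network = network)
}

#' Area under the ROC curve from scores and binary labels
#'
#' Rank-sum (Mann-Whitney) AUC: probability that a random positive outscores
#' a random negative, with average ranks for ties. Used to quantify recovery
#' of planted DE genes.
#'
#' @param score numeric vector (larger = more positive call).
#' @param positive logical vector, same length.
#' @return AUC in [0, 1].
#' @export
rank_auc <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  ok <- is.finite(score)
  score <- score[ok]; positive <- as.logical(positive)[ok]
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
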