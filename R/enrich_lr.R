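#' @title Over-representation analysis and ligand-receptor networks
#' @description One-sided hypergeometric over-representation of DE gene lists
#'   in gene sets, and construction of the directed ligand-receptor network
#'   over the deconvolved cellular units: an edge (source, target) carries an
#'   annotated (ligand, receptor) pair when the ligand is up-regulated in the
#'   source unit, the receptor is up-regulated in the target unit, and their
#'   purified expressions correlate (Spearman) above the threshold.
#' @name enrich_lr
NULL

#' Hypergeometric over-representation test for one gene set
#'
#' One-sided upper-tail p on the 2x2 overlap table. The odds ratio is
#' (a d) / (b c), with the Haldane 0.5 correction applied only when a zero
#' cell exists.
#'
#' @param de_genes character vector, the gene list (subset of universe).
#' @param gene_set character vector, the set (subset of universe).
#' @param universe character vector of all measured genes.
#' @return one-row data.frame: \code{overlap}, \code{set_size},
#'   \code{universe_size}, \code{list_size}, \code{odds_ratio}, \code{p}.
#' @export
ora_test <- function(de_genes, gene_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  de_genes <- unique(intersect(de_genes, universe))
  gene_set <- unique(intersect(gene_set, universe))
  a <- length(intersect(de_genes, gene_set))
  b <- length(de_genes) - a
  cc <- length(gene_set) - a
  d <- length(universe) - a - b - cc
  p <- phyper(a - 1, length(gene_set), length(universe) - length(gene_set),
              length(de_genes), lower.tail = FALSE)
  if (a == 0 || b == 0 || cc == 0 || d == 0) {
    orr <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    orr <- (a * d) / (b * cc)
  }
  data.frame(overlap = a, set_size = length(gene_set),
             universe_size = length(universe), list_size = length(de_genes),
             odds_ratio = orr, p = p)
}

#' Over-representation across a gene-set collection
#'
#' @param de_genes gene list.
#' @param gsc gene-set collection (\code{\link{load_gmt}} layout).
#' @param universe all measured genes.
#' @return data.frame, one row per set, with BH-FDR column \code{q}; rows
#'   ordered by p.
#' @export
ora_collection <- function(de_genes, gsc, universe) {
  rows <- lapply(names(gsc$sets), function(nm)
    cbind(data.frame(set = nm, stringsAsFactors = FALSE),
          ora_test(de_genes, gsc$sets[[nm]], universe)))
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, "BH")
  out[order(out$p), , drop = FALSE]
}

#' Build the directed ligand-receptor network over cellular units
#'
#' For every ordered unit pair (source, target) — including source = target,
#' the autocrine case — and every annotated (ligand, receptor) pair: the edge
#' carries the pair iff the ligand is up-regulated in the source unit
#' (p < \code{p_cut} and logFC > \code{lfc_min}), the receptor is
#' up-regulated in the target unit, and the Spearman correlation between the
#' ligand's purified expression in the source and the receptor's purified
#' expression in the target — across segments valid for both units — is
#' strictly greater than \code{rho_min}. Pairs whose genes are absent from the
#' purified matrix are skipped and logged, not errors.
#'
#' @param de_by_unit named list of \code{nvu_de} tables
#'   (\code{\link{fit_de_by_unit}}).
#' @param cts an \code{nvu_ctexpr} (post stability filter), segments aligned
#'   across units.
#' @param pairs ligand-receptor table (\code{\link{load_lr_pairs}} layout).
#' @param rho_min Spearman threshold (the study used 0.35, strict >).
#' @param p_cut significance gate on raw p (default 0.05).
#' @param lfc_min up-regulation gate on logFC (default 0: any positive
#'   fold change; the study's |logFC| > 0.25 gate is not applied here).
#' @return list of class \code{nvu_lrnet}: \code{edges} (data.frame source,
#'   target, ligand, receptor, ligand_p, receptor_p, rho), \code{tally}
#'   (units x units matrix of per-edge pair counts), \code{skipped}
#'   (data.frame of pairs missing from the purified matrix).
#' @export
build_lr_network <- function(de_by_unit, cts, pairs, rho_min = 0.35,
                             p_cut = 0.05, lfc_min = 0) {
  stopifnot(inherits(cts, "nvu_ctexpr"))
  units <- names(de_by_unit)
  if (!all(units %in% dimnames(cts$expr)[[3]]))
    stop("DE units absent from the purified expression set")
  genes <- dimnames(cts$expr)[[2]]

  up <- lapply(de_by_unit, function(de)
    de$gene[de$p < p_cut & de$logFC > lfc_min])
  edges <- list()
  skipped <- list()
  tally <- matrix(0L, length(units), length(units),
                  dimnames = list(units, units))
  for (s in units) for (t in units) {
    for (k in seq_len(nrow(pairs))) {
      L <- pairs$ligand[k]; R <- pairs$receptor[k]
      if (!(L %in% genes) || !(R %in% genes)) {
        skipped[[paste(L, R)]] <- data.frame(ligand = L, receptor = R,
                                             stringsAsFactors = FALSE)
        next
      }
      if (!(L %in% up[[s]]) || !(R %in% up[[t]])) next
      ok <- cts$valid[, s] & cts$valid[, t]
      if (sum(ok) < 3) next
      x <- cts$expr[ok, L, s]
      y <- cts$expr[ok, R, t]
      if (sd(x) == 0 || sd(y) == 0) next
      rho <- cor(x, y, method = "spearman")
      if (is.finite(rho) && rho > rho_min) {
        de_s <- de_by_unit[[s]]; de_t <- de_by_unit[[t]]
        edges[[length(edges) + 1]] <- data.frame(
          source = s, target = t, ligand = L, receptor = R,
          ligand_p = de_s$p[de_s$gene == L],
          receptor_p = de_t$p[de_t$gene == R],
          rho = rho, stringsAsFactors = FALSE)
        tally[s, t] <- tally[s, t] + 1L
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(), target = character(),
               ligand = character(), receptor = character(),
               ligand_p = numeric(), receptor_p = numeric(),
               rho = numeric(), stringsAsFactors = FALSE)
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(ligand = character(), receptor = character())
  rownames(edges) <- rownames(skipped) <- NULL
  structure(list(edges = edges, tally = tally, skipped = skipped,
                 rho_min = rho_min, p_cut = p_cut),
            class = "nvu_lrnet")
}

#' @export
print.nvu_lrnet <- function(x, ...) {
  cat(sprintf("<nvu_lrnet> %d edges over %d units (rho > %g)\n",
              nrow(x$edges), nrow(x$tally), x$rho_min))
  invisible(x)
}

#' Export chord-diagram data for one focus unit
#'
#' Long-format table of every stored (source, target, pair, rho) touching the
#' focus unit, ordered by per-edge tally then correlation — the data behind a
#' chord rendering, without the rendering.
#'
#' @param net an \code{nvu_lrnet}.
#' @param focus_unit unit label.
#' @return data.frame: \code{source}, \code{target}, \code{ligand},
#'   \code{receptor}, \code{rho}, \code{tally}.
#' @export
export_chord_data <- function(net, focus_unit) {
  stopifnot(inherits(net, "nvu_lrnet"))
  if (!focus_unit %in% rownames(net$tally))
    stop("unknown unit: ", focus_unit)
  e <- net$edges
  e <- e[e$source == focus_unit | e$target == focus_unit, , drop = FALSE]
  if (!nrow(e))
    return(data.frame(source = character(), target = character(),
                      ligand = character(), receptor = character(),
                      rho = numeric(), tally = integer()))
  e$tally <- net$tally[cbind(e$source, e$target)]
  e <- e[order(-e$tally, -e$rho), c("source", "target", "ligand", "receptor",
                                    "rho", "tally")]
  rownames(e) <- NULL
  e
}

#' Write an LR network as edge-list TSV plus a JSON adjacency document
#'
#' @param net an \code{nvu_lrnet}.
#' @param out_dir output directory.
#' @return manifest data.frame (as \code{\link{write_tables}}).
#' @export
write_lr_network <- function(net, out_dir) {
  man <- write_tables(net$edges, out_dir, name = "lr_edges")
  adj <- list(units = rownames(net$tally), tally = net$tally,
              rho_min = net$rho_min, p_cut = net$p_cut)
  path <- file.path(out_dir, "lr_adjacency.json")
  jsonlite::write_json(adj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  rbind(man, data.frame(file = path, rows = nrow(net$tally)))
}
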