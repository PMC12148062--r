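#' @title Deconvolution reference construction
#' @description Builds the genes x cellular-units mean-expression reference
#'   from labeled single cells: per-unit selection of the cells closest to the
#'   unit centroid, specificity-driven feature selection combining non-zero
#'   prevalence with mean non-zero expression, and depth-normalized averaging.
#' @name reference_builder
NULL

# cells of one unit according to a consolidation mapping
.unit_cells <- function(sc, mapping, unit) {
  cl <- mapping$mapping$cluster[mapping$mapping$unit == unit]
  which(sc$cluster %in% cl)
}

#' Select the cells closest to each unit centroid
#'
#' Closeness is the Spearman correlation between a cell's log1p count profile
#' and the unit's mean log1p profile (robust to sequencing depth). Per unit
#' the top \code{n_per_unit} cells are kept; units with fewer cells keep all
#' of them (the study's astrocyte case: 1032 of a requested 1500). Ties are
#' broken by cell id so selection is reproducible.
#'
#' @param sc an \code{\link{nvu_sc}}.
#' @param mapping an \code{nvu_mapping} from \code{\link{consolidate_types}}.
#' @param n_per_unit cells requested per unit (the study used 1500).
#' @return an \code{\link{nvu_sc}} restricted to the selected cells, with
#'   cluster labels replaced by unit labels.
#' @export
select_cells <- function(sc, mapping, n_per_unit = 1500) {
  stopifnot(inherits(sc, "nvu_sc"), inherits(mapping, "nvu_mapping"),
            n_per_unit >= 1)
  units <- unique(mapping$mapping$unit)
  lg <- log1p(sc$counts)
  picked <- integer(0)
  unit_lab <- character(0)
  for (u in units) {
    idx <- .unit_cells(sc, mapping, u)
    if (!length(idx)) stop("unit has no cells after mapping: ", u)
    centroid <- colMeans(lg[idx, , drop = FALSE])
    rho <- suppressWarnings(
      cor(t(lg[idx, , drop = FALSE]), centroid, method = "spearman"))[, 1]
    rho[!is.finite(rho)] <- -Inf
    ord <- idx[order(-rho, rownames(sc$counts)[idx])]
    take <- ord[seq_len(min(n_per_unit, length(ord)))]
    picked <- c(picked, take)
    unit_lab <- c(unit_lab, rep(u, length(take)))
  }
  nvu_sc(sc$counts[picked, , drop = FALSE], cluster = unit_lab,
         animal = sc$animal[picked])
}

#' Specificity-driven feature selection for the reference
#'
#' Per unit u and gene g, score(g, u) = (fraction of unit-u cells with a
#' non-zero count) x (mean log1p count over those non-zero cells). Genes are
#' ranked within each unit by the specificity ratio
#' score(g, u) / max over other units of score(g, .), capped at 1e6 when no
#' other unit expresses the gene, and the per-unit rankings are merged
#' round-robin until \code{n_genes} unique genes are collected.
#'
#' @param sc_subset cell-selected \code{\link{nvu_sc}} whose cluster labels
#'   are unit labels (\code{\link{select_cells}} output).
#' @param mapping an \code{nvu_mapping} (identity over unit labels accepted).
#' @param n_genes reference size (the study used 3000); must be at least the
#'   number of units and at most the measured genes.
#' @return character vector of \code{n_genes} gene symbols, with the
#'   per-gene-per-unit score matrix as attribute \code{"score"}.
#' @export
select_features <- function(sc_subset, mapping, n_genes = 3000) {
  stopifnot(inherits(sc_subset, "nvu_sc"))
  units <- sort(unique(sc_subset$cluster))
  if (n_genes < length(units))
    stop("n_genes must be >= number of units")
  if (n_genes > ncol(sc_subset$counts))
    stop("n_genes exceeds measured genes")
  genes <- colnames(sc_subset$counts)

  score <- matrix(0, length(genes), length(units),
                  dimnames = list(genes, units))
  for (u in units) {
    m <- sc_subset$counts[sc_subset$cluster == u, , drop = FALSE]
    nz <- m > 0
    prev <- colMeans(nz)
    lg <- log1p(m)
    lg[!nz] <- 0
    nnz <- colSums(nz)
    mean_nz <- ifelse(nnz > 0, colSums(lg) / pmax(nnz, 1), 0)
    score[, u] <- prev * mean_nz
  }

  ranked <- lapply(units, function(u) {
    others <- apply(score[, setdiff(units, u), drop = FALSE], 1, max)
    ratio <- ifelse(others > 0, score[, u] / others,
                    ifelse(score[, u] > 0, 1e6, 0))
    genes[order(-ratio, -score[, u], genes)]
  })

  sel <- character(0)
  pos <- rep(1L, length(units))
  while (length(sel) < n_genes) {
    for (k in seq_along(units)) {
      while (pos[k] <= length(genes) && ranked[[k]][pos[k]] %in% sel)
        pos[k] <- pos[k] + 1L
      if (pos[k] <= length(genes) && length(sel) < n_genes) {
        sel <- c(sel, ranked[[k]][pos[k]])
        pos[k] <- pos[k] + 1L
      }
    }
  }
  structure(sel, score = score)
}

#' Build the genes x units deconvolution reference
#'
#' Each cell is library-size scaled to 10,000 total counts (removing depth as
#' a confound), then entry (g, u) is the mean scaled count of gene g over the
#' unit's cells.
#'
#' @param sc_subset cell-selected \code{\link{nvu_sc}} with unit labels.
#' @param mapping an \code{nvu_mapping} (accepted for interface symmetry; the
#'   subset's labels are already units).
#' @param genes reference gene list (subset of measured genes).
#' @return genes x units numeric matrix of class \code{nvu_reference} with
#'   attribute \code{cells_used} (named per-unit cell counts).
#' @export
build_reference <- function(sc_subset, mapping = NULL, genes) {
  stopifnot(inherits(sc_subset, "nvu_sc"))
  miss <- setdiff(genes, colnames(sc_subset$counts))
  if (length(miss)) stop("reference genes not measured: ",
                         paste(head(miss, 5), collapse = ", "))
  if (anyDuplicated(genes)) stop("duplicate genes in reference gene list")
  units <- sort(unique(sc_subset$cluster))
  scaled <- sc_subset$counts / pmax(rowSums(sc_subset$counts), 1) * 1e4
  ref <- vapply(units, function(u)
    colMeans(scaled[sc_subset$cluster == u, genes, drop = FALSE]),
    numeric(length(genes)))
  rownames(ref) <- genes
  structure(ref, class = c("nvu_reference", "matrix"),
            cells_used = vapply(units, function(u)
              sum(sc_subset$cluster == u), integer(1)))
}

#' End-to-end reference construction from a labeled single-cell matrix
#'
#' Convenience chain: score clusters against signatures, consolidate into
#' units, select cells and features, and build the reference.
#'
#' @param sc an \code{\link{nvu_sc}}.
#' @param sigs gene-set collection used for consolidation scoring.
#' @param min_cells,k_units consolidation parameters.
#' @param n_per_unit,n_genes cell- and feature-selection sizes.
#' @param r_max signature rank truncation.
#' @return list with \code{scores}, \code{mapping}, \code{cells}
#'   (selected subset), \code{genes}, \code{reference}.
#' @export
build_reference_pipeline <- function(sc, sigs, min_cells = 100, k_units = 6,
                                     n_per_unit = 1500, n_genes = 3000,
                                     r_max = 1500) {
  scores <- score_cell_types(sc, sigs, r_max = r_max)
  mapping <- consolidate_types(scores, min_cells = min_cells,
                               k_units = k_units)
  cells <- select_cells(sc, mapping, n_per_unit = n_per_unit)
  id_map <- structure(list(mapping = data.frame(
    cluster = sort(unique(cells$cluster)),
    unit = sort(unique(cells$cluster)), stringsAsFactors = FALSE),
    dropped = data.frame(cluster = character(), reason = character())),
    class = "nvu_mapping")
  genes <- select_features(cells, id_map, n_genes = n_genes)
  list(scores = scores, mapping = mapping, cells = cells,
       genes = as.character(genes),
       reference = build_reference(cells, id_map, as.character(genes)))
}
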