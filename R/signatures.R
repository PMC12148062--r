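#' @title Rank-based signature scoring and cluster consolidation
#' @description Mann-Whitney-U-based signature scores in [0, 1] (the UCell
#'   statistic) for segments and single cells, and deterministic consolidation
#'   of single-cell clusters into cellular units by hierarchical clustering of
#'   their signature-score profiles.
#' @name signatures
NULL

#' Rank-based signature score for one sample
#'
#' Genes are ranked descending by expression with average-rank ties; ranks
#' beyond \code{r_max} are truncated to \code{r_max + 1}. With n signature
#' genes present, U = (sum of signature ranks) - n(n+1)/2 and the score is
#' max(0, 1 - U / (n * r_max)). The score depends on ranks only, so it is
#' invariant to any monotone transform of the expression vector.
#'
#' @param expr_row named numeric vector: one sample's gene values.
#' @param signature character vector of gene symbols; must satisfy
#'   \code{r_max >= length(signature)}.
#' @param r_max rank truncation (default 1500, the scoring convention).
#' @return score in [0, 1], or \code{NA} (flagged, not zero) when no
#'   signature gene is measured.
#' @export
ucell_score <- function(expr_row, signature, r_max = 1500) {
  if (r_max < length(signature))
    stop("r_max must be >= signature size")
  sig <- intersect(signature, names(expr_row))
  if (!length(sig)) return(NA_real_)
  r <- rank(-expr_row, ties.method = "average")
  r[r > r_max] <- r_max + 1
  n <- length(sig)
  u <- sum(r[sig]) - n * (n + 1) / 2
  max(0, 1 - u / (n * r_max))
}

# score every column of a genes x samples matrix against every signature
.score_matrix <- function(mat, sets, r_max) {
  out <- matrix(NA_real_, ncol(mat), length(sets),
                dimnames = list(colnames(mat), names(sets)))
  for (j in seq_len(ncol(mat))) {
    v <- mat[, j]
    names(v) <- rownames(mat)
    r <- rank(-v, ties.method = "average")
    r[r > r_max] <- r_max + 1
    for (s in seq_along(sets)) {
      sig <- intersect(sets[[s]], rownames(mat))
      if (!length(sig)) next
      n <- length(sig)
      u <- sum(r[sig]) - n * (n + 1) / 2
      out[j, s] <- max(0, 1 - u / (n * r_max))
    }
  }
  out
}

#' Signature scores for ROI segments
#'
#' @param expr an \code{\link{nvu_expr}} (any stage; scores are rank-based).
#' @param sigs a gene-set collection (\code{\link{load_gmt}} layout).
#' @param r_max rank truncation.
#' @return segments x signatures score matrix with attribute \code{r_max}.
#' @export
score_segments <- function(expr, sigs, r_max = 1500) {
  stopifnot(inherits(expr, "nvu_expr"))
  out <- .score_matrix(target_counts(expr), sigs$sets, r_max)
  attr(out, "r_max") <- r_max
  out
}

#' Per-cluster signature scores for single cells
#'
#' Scores every cell, then averages within cluster.
#'
#' @param sc an \code{\link{nvu_sc}}.
#' @param sigs a gene-set collection.
#' @param r_max rank truncation.
#' @return clusters x signatures matrix of mean scores, attribute
#'   \code{cluster_sizes}.
#' @export
score_cell_types <- function(sc, sigs, r_max = 1500) {
  stopifnot(inherits(sc, "nvu_sc"))
  if (!length(sigs$sets)) stop("need at least one signature")
  per_cell <- .score_matrix(t(sc$counts), sigs$sets, r_max)
  cl <- sort(unique(sc$cluster))
  out <- t(vapply(cl, function(u)
    colMeans(per_cell[sc$cluster == u, , drop = FALSE]),
    numeric(ncol(per_cell))))
  rownames(out) <- cl
  attr(out, "cluster_sizes") <- vapply(cl, function(u) sum(sc$cluster == u),
                                       integer(1))
  attr(out, "r_max") <- r_max
  out
}

#' Consolidate single-cell clusters into cellular units
#'
#' Clusters that do not exceed \code{min_cells} cells are dropped as
#' under-represented (the study required > 100 cells). The remaining clusters
#' are hierarchically clustered (average linkage on 1 - Pearson correlation of
#' their signature-score rows) and cut at \code{k_units}; each unit is labeled
#' by the sorted concatenation of its member cluster labels. Deterministic
#' given scores and sizes. An optional manual mapping overrides the automatic
#' assignment to reproduce judgment calls.
#'
#' @param scores clusters x signatures score matrix
#'   (\code{\link{score_cell_types}}).
#' @param cluster_sizes named integer vector (defaults to the matrix's
#'   \code{cluster_sizes} attribute).
#' @param min_cells retention threshold; a cluster is kept iff its size is
#'   strictly greater (default 100).
#' @param k_units number of cellular units (default 6).
#' @param manual optional named character vector cluster -> unit; entries with
#'   value \code{NA} drop the cluster with reason \code{"manual"}.
#' @return list of class \code{nvu_mapping}: \code{mapping} (data.frame
#'   cluster, unit) and \code{dropped} (data.frame cluster, reason).
#' @export
consolidate_types <- function(scores, cluster_sizes = NULL, min_cells = 100,
                              k_units = 6, manual = NULL) {
  if (is.null(cluster_sizes)) cluster_sizes <- attr(scores, "cluster_sizes")
  if (is.null(cluster_sizes))
    stop("cluster_sizes required (attribute missing)")
  cl <- rownames(scores)
  stopifnot(!is.null(cl), all(cl %in% names(cluster_sizes)))

  dropped <- data.frame(cluster = character(), reason = character(),
                        stringsAsFactors = FALSE)
  small <- cl[cluster_sizes[cl] <= min_cells]
  if (length(small))
    dropped <- rbind(dropped, data.frame(cluster = small,
                                         reason = "under-represented",
                                         stringsAsFactors = FALSE))
  if (!is.null(manual)) {
    man_drop <- names(manual)[is.na(manual)]
    man_drop <- setdiff(intersect(man_drop, cl), dropped$cluster)
    if (length(man_drop))
      dropped <- rbind(dropped, data.frame(cluster = man_drop,
                                           reason = "manual",
                                           stringsAsFactors = FALSE))
  }
  keep <- setdiff(cl, dropped$cluster)
  if (k_units > length(keep))
    stop("k_units (", k_units, ") exceeds retained clusters (",
         length(keep), ")")

  s <- scores[keep, , drop = FALSE]
  if (length(keep) == k_units) {
    grp <- seq_along(keep)
  } else {
    cc <- suppressWarnings(cor(t(s)))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 1
    hc <- hclust(as.dist(1 - cc), method = "average")
    grp <- cutree(hc, k = k_units)
  }
  unit_of <- vapply(seq_len(k_units), function(g)
    paste(sort(keep[grp == g]), collapse = "+"), character(1))
  mapping <- data.frame(cluster = keep, unit = unit_of[grp],
                        stringsAsFactors = FALSE)
  if (!is.null(manual)) {
    ov <- intersect(names(manual)[!is.na(manual)], mapping$cluster)
    mapping$unit[match(ov, mapping$cluster)] <- manual[ov]
  }
  structure(list(mapping = mapping, dropped = dropped),
            class = "nvu_mapping")
}

#' @export
print.nvu_mapping <- function(x, ...) {
  cat(sprintf("<nvu_mapping> %d clusters -> %d units (%d dropped)\n",
              nrow(x$mapping), length(unique(x$mapping$unit)),
              nrow(x$dropped)))
  invisible(x)
}
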