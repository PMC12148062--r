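#' @useDynLib nvudeconv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor sd median quantile prcomp p.adjust pt phyper rnorm
#'   rnbinom rlnorm runif var wilcox.test ks.test rgamma hclust cutree
#'   as.dist model.matrix setNames
#' @importFrom utils read.delim write.table head
NULL

#' ROI expression matrix with probe-class flags
#'
#' Genes-by-segments numeric matrix carrying, per gene, a target/negative-probe
#' flag, and a stage tag recording what scale the values are on.
#'
#' @param counts numeric matrix, genes in rows (rownames = gene symbols),
#'   segments in columns (colnames = segment ids).
#' @param negative logical vector, one entry per gene row; \code{TRUE} marks a
#'   negative (no-target background) probe.
#' @param stage one of \code{"raw"}, \code{"normalized"}, \code{"log2"}.
#' @return an object of class \code{nvu_expr}.
#' @export
nvu_expr <- function(counts, negative = rep(FALSE, nrow(counts)),
                     stage = c("raw", "normalized", "log2")) {
  stage <- match.arg(stage)
  stopifnot(is.matrix(counts), is.numeric(counts))
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and segment colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene symbols in counts")
  if (length(negative) != nrow(counts))
    stop("negative flag length must equal gene count")
  if (stage == "raw" && any(counts < 0))
    stop("negative counts in raw expression matrix")
  structure(list(counts = counts, negative = as.logical(negative),
                 stage = stage),
            class = "nvu_expr")
}

#' @export
print.nvu_expr <- function(x, ...) {
  cat(sprintf("<nvu_expr> %d genes (%d negative probes) x %d segments [%s]\n",
              nrow(x$counts), sum(x$negative), ncol(x$counts), x$stage))
  invisible(x)
}

#' @export
dim.nvu_expr <- function(x) dim(x$counts)

#' Target-gene submatrix of an expression object
#' @param x an \code{nvu_expr}.
#' @return numeric matrix restricted to non-negative-probe rows.
#' @export
target_counts <- function(x) {
  stopifnot(inherits(x, "nvu_expr"))
  x$counts[!x$negative, , drop = FALSE]
}

#' Negative-probe submatrix of an expression object
#' @param x an \code{nvu_expr}.
#' @return numeric matrix restricted to negative-probe rows.
#' @export
negative_counts <- function(x) {
  stopifnot(inherits(x, "nvu_expr"))
  x$counts[x$negative, , drop = FALSE]
}

#' Single-cell count matrix with cluster and animal labels
#'
#' @param counts cells-by-genes numeric matrix of non-negative integers
#'   (rownames = cell ids, colnames = gene symbols).
#' @param cluster character vector, one cluster label per cell.
#' @param animal character vector, one animal id per cell.
#' @return an object of class \code{nvu_sc}.
#' @export
nvu_sc <- function(counts, cluster, animal = rep("a1", nrow(counts))) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop("single-cell counts must be non-negative")
  if (length(cluster) != nrow(counts) || length(animal) != nrow(counts))
    stop("cluster/animal labels must have one entry per cell")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("cell%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) stop("counts must carry gene colnames")
  if (any(table(cluster) < 1)) stop("every cluster must have at least one cell")
  structure(list(counts = counts, cluster = as.character(cluster),
                 animal = as.character(animal)),
            class = "nvu_sc")
}

#' @export
print.nvu_sc <- function(x, ...) {
  cat(sprintf("<nvu_sc> %d cells x %d genes, %d clusters\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cluster))))
  invisible(x)
}

#' Validate a segment annotation table
#'
#' Required columns: \code{segment_id}, \code{roi_id}, \code{mouse_id},
#' \code{genotype} (values \code{"APP+"} / \code{"APP-"}), \code{sex}.
#'
#' @param annot a data.frame.
#' @return the validated data.frame (invisibly usable downstream).
#' @export
validate_annotation <- function(annot) {
  need <- c("segment_id", "roi_id", "mouse_id", "genotype", "sex")
  miss <- setdiff(need, names(annot))
  if (length(miss))
    stop("annotation missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(annot$segment_id))
    stop("duplicate segment ids in annotation")
  bad <- setdiff(unique(annot$genotype), c("APP+", "APP-"))
  if (length(bad))
    stop("unrecognized genotype labels: ", paste(bad, collapse = ", "))
  annot
}

# internal: geometric mean on a positive vector
geomean <- function(x) exp(mean(log(x)))

# internal: stable check that rows sit on the probability simplex
assert_simplex <- function(m, tol = 1e-9) {
  if (any(m < -tol)) stop("negative entries in fraction matrix")
  if (any(abs(rowSums(m) - 1) > tol)) stop("fraction rows must sum to 1")
  invisible(TRUE)
}
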