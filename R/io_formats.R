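#' @title On-disk formats
#' @description Readers and writers for every artifact the pipeline touches:
#'   TSV/CSV count bundles, MatrixMarket single-cell triplets, GMT gene sets,
#'   and CellTalkDB-layout ligand-receptor tables. All writers emit UTF-8,
#'   LF-terminated, tab-separated text with deterministic column order so that
#'   reader/writer pairs are lossless round trips.
#' @name io_formats
NULL

# delimiter by extension; ambiguous extensions default to TSV
.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.read_table <- function(path) {
  read.delim(path, sep = .delim_for(path), check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Load a GeoMx-style ROI count bundle
#'
#' Reads a genes-by-segments count table (first column = gene symbol) and the
#' matching per-segment annotation, flags negative probes by symbol prefix, and
#' returns the pair with segments and genes in canonical (sorted) order so that
#' loading is insensitive to input row/column permutations.
#'
#' @param counts_path TSV/CSV file; gene rows, segment columns.
#' @param annot_path TSV/CSV with one row per segment; must contain
#'   \code{segment_id}, \code{roi_id}, \code{mouse_id}, \code{genotype},
#'   \code{sex}.
#' @param neg_prefix gene-symbol prefix marking negative probes
#'   (default \code{"NegProbe"}; the platform's encoding is configurable).
#' @return list with \code{expr} (\code{\link{nvu_expr}}) and \code{annot}
#'   (data.frame), segment keys identical and ordered.
#' @export
load_geomx_bundle <- function(counts_path, annot_path, neg_prefix = "NegProbe") {
  tab <- .read_table(counts_path)
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  keep <- !duplicated(genes)
  m <- m[keep, , drop = FALSE]
  rownames(m) <- genes[keep]

  annot <- validate_annotation(.read_table(annot_path))
  only_counts <- setdiff(colnames(m), annot$segment_id)
  only_annot <- setdiff(annot$segment_id, colnames(m))
  if (length(only_counts) || length(only_annot))
    stop("segment keys differ between counts and annotation; ",
         "counts-only: {", paste(only_counts, collapse = ", "), "} ",
         "annotation-only: {", paste(only_annot, collapse = ", "), "}")
  if (any(m < 0)) stop("negative counts in ", counts_path)

  ord_seg <- order(colnames(m))
  ord_gene <- order(rownames(m))
  m <- m[ord_gene, ord_seg, drop = FALSE]
  annot <- annot[match(colnames(m), annot$segment_id), , drop = FALSE]
  rownames(annot) <- NULL
  neg <- startsWith(rownames(m), neg_prefix)
  list(expr = nvu_expr(m, negative = neg, stage = "raw"), annot = annot)
}

#' Write a GeoMx-style ROI count bundle
#'
#' @param expr an \code{\link{nvu_expr}} (raw counts).
#' @param annot matching segment annotation.
#' @param dir output directory (created if needed).
#' @return character vector of the two file paths written.
#' @export
write_geomx_bundle <- function(expr, annot, dir) {
  stopifnot(inherits(expr, "nvu_expr"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts_path <- file.path(dir, "counts.tsv")
  annot_path <- file.path(dir, "segments.tsv")
  df <- data.frame(gene = rownames(expr$counts), expr$counts,
                   check.names = FALSE)
  .write_tsv(df, counts_path)
  .write_tsv(annot, annot_path)
  c(counts_path, annot_path)
}

#' Load a labeled single-cell count matrix (MatrixMarket layout)
#'
#' @param mtx_path MatrixMarket sparse counts, genes in rows, cells in columns.
#' @param genes_path one gene symbol per line (first column of a TSV).
#' @param labels_path TSV with columns \code{cell_id}, \code{cluster},
#'   \code{animal}; one row per cell, in MTX column order.
#' @return an \code{\link{nvu_sc}}; duplicate gene symbols are dropped keeping
#'   the first occurrence.
#' @export
load_single_cell <- function(mtx_path, genes_path, labels_path) {
  m <- Matrix::readMM(mtx_path)
  genes <- .read_table(genes_path)[[1]]
  lab <- .read_table(labels_path)
  if (nrow(m) != length(genes))
    stop(sprintf("MTX declares %d gene rows but gene file has %d",
                 nrow(m), length(genes)))
  if (ncol(m) != nrow(lab))
    stop(sprintf("MTX declares %d cells but label file has %d rows",
                 ncol(m), nrow(lab)))
  need <- c("cell_id", "cluster")
  miss <- setdiff(need, names(lab))
  if (length(miss)) stop("label file missing columns: ",
                         paste(miss, collapse = ", "))
  counts <- t(as.matrix(m))
  colnames(counts) <- as.character(genes)
  rownames(counts) <- as.character(lab$cell_id)
  keep <- !duplicated(colnames(counts))
  counts <- counts[, keep, drop = FALSE]
  animal <- if ("animal" %in% names(lab)) lab$animal else rep("a1", nrow(lab))
  nvu_sc(counts, cluster = lab$cluster, animal = animal)
}

#' Write a single-cell matrix in MatrixMarket layout
#' @param sc an \code{\link{nvu_sc}}.
#' @param dir output directory.
#' @return character vector of the three file paths written.
#' @export
write_single_cell <- function(sc, dir) {
  stopifnot(inherits(sc, "nvu_sc"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(dir, "counts.mtx")
  genes <- file.path(dir, "genes.tsv")
  labels <- file.path(dir, "labels.tsv")
  Matrix::writeMM(Matrix::Matrix(t(sc$counts), sparse = TRUE), mtx)
  .write_tsv(data.frame(gene = colnames(sc$counts)), genes)
  .write_tsv(data.frame(cell_id = rownames(sc$counts), cluster = sc$cluster,
                        animal = sc$animal), labels)
  c(mtx, genes, labels)
}

#' Load a GMT gene-set collection
#'
#' Standard GMT dialect: \code{name<TAB>description<TAB>gene1<TAB>...} per
#' line. Lines with fewer than three fields are skipped with a warning; sets
#' that end up empty are dropped with a warning; duplicate symbols within a set
#' are collapsed.
#'
#' @param path GMT file.
#' @return list with \code{name} (file basename) and \code{sets} (named list of
#'   unique gene-symbol vectors).
#' @export
load_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3) {
      warning("skipping GMT line with <3 fields: ", substr(ln, 1, 40))
      next
    }
    sets[[f[1]]] <- unique(f[-(1:2)])
  }
  if (anyDuplicated(names(sets))) stop("duplicate set names in ", path)
  list(name = basename(path), sets = sets)
}

#' Write a gene-set collection as GMT
#' @param gsc a gene-set collection as returned by \code{\link{load_gmt}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(nm)
    paste(c(nm, "na", gsc$sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Load a ligand-receptor pair table (CellTalkDB layout)
#'
#' @param path TSV with a header naming the ligand and receptor symbol columns.
#' @param ligand_col,receptor_col column names holding the gene symbols.
#' @return data.frame with columns \code{ligand}, \code{receptor};
#'   duplicate (ligand, receptor) rows removed, symbol case preserved.
#' @export
load_lr_pairs <- function(path, ligand_col = "ligand_gene_symbol",
                          receptor_col = "receptor_gene_symbol") {
  tab <- .read_table(path)
  miss <- setdiff(c(ligand_col, receptor_col), names(tab))
  if (length(miss))
    stop("ligand-receptor table missing columns: ",
         paste(miss, collapse = ", "))
  out <- data.frame(ligand = as.character(tab[[ligand_col]]),
                    receptor = as.character(tab[[receptor_col]]),
                    stringsAsFactors = FALSE)
  out[!duplicated(out), , drop = FALSE]
}

.write_tsv <- function(df, path) {
  con <- file(path, open = "wb")  # binary connection pins LF endings
  on.exit(close(con))
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  path
}

#' Write any tabular pipeline product to a directory
#'
#' Dispatches on the product type (DE tables, fraction matrices, LOQ tables,
#' ORA tables, LR edge lists, plain data.frames / matrices), writes
#' deterministic tab-separated text, and returns a manifest of the files
#' written with their data row counts. Fraction-matrix rows are re-validated
#' against the simplex invariant on write.
#'
#' @param results a pipeline product or a named list of them.
#' @param out_dir output directory (created if needed).
#' @param name file stem used for a single product (default from the class).
#' @return data.frame manifest with columns \code{file}, \code{rows}.
#' @export
write_tables <- function(results, out_dir, name = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create directory ", out_dir)
  }
  if (file.access(out_dir, mode = 2) != 0)
    stop("directory not writable: ", out_dir)
  if (is.list(results) && !is.data.frame(results) &&
      !inherits(results, c("nvu_expr", "nvu_fractions")) &&
      !is.null(names(results))) {
    man <- do.call(rbind, lapply(names(results), function(nm)
      write_tables(results[[nm]], out_dir, name = nm)))
    rownames(man) <- NULL
    return(man)
  }
  df <- .as_table(results)
  stem <- if (is.null(name)) attr(df, "nvu_stem") %||% "table" else name
  path <- file.path(out_dir, paste0(stem, ".tsv"))
  .write_tsv(df, path)
  data.frame(file = path, rows = nrow(df), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.as_table <- function(x) {
  if (inherits(x, "nvu_fractions")) {
    assert_simplex(unclass(x)[, , drop = FALSE])
    df <- data.frame(segment_id = rownames(x), unclass(x),
                     residual = attr(x, "residual"), check.names = FALSE)
    attr(df, "nvu_stem") <- "fractions"
    return(df)
  }
  if (inherits(x, "nvu_expr")) {
    df <- data.frame(gene = rownames(x$counts), negative = x$negative,
                     x$counts, check.names = FALSE)
    attr(df, "nvu_stem") <- paste0("expression_", x$stage)
    return(df)
  }
  if (is.matrix(x)) {
    df <- data.frame(id = rownames(x) %||% seq_len(nrow(x)), x,
                     check.names = FALSE)
    attr(df, "nvu_stem") <- "matrix"
    return(df)
  }
  if (is.data.frame(x)) {
    attr(x, "nvu_stem") <- if (all(c("logFC", "p") %in% names(x)))
      "de_result" else "table"
    return(x)
  }
  stop("no table writer for class ", paste(class(x), collapse = "/"))
}
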