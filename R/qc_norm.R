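#' @title Negative-probe QC and normalization
#' @description Limit-of-quantification (LOQ) computation from negative
#'   probes, detection-rate gene filtering, and third-quartile (Q3)
#'   between-segment normalization — the standard GeoMx segment processing
#'   chain, with the LOQ geometric-SD exponent exposed (1.5 in this study).
#' @name qc_norm
NULL

#' Limit of quantification for one segment
#'
#' LOQ = geometric mean of the segment's negative-probe counts times the
#' geometric SD raised to \code{exponent}. The geometric SD uses the sample
#' (n-1) standard deviation of natural-log counts; zero counts are floored at
#' 0.5 before taking logs (geometric statistics are undefined at zero).
#'
#' @param expr an \code{\link{nvu_expr}} with raw counts.
#' @param exponent geometric-SD exponent (the study used 1.5).
#' @param seg segment id (column name).
#' @return the LOQ, a positive count value.
#' @export
compute_loq <- function(expr, exponent = 1.5, seg) {
  stopifnot(inherits(expr, "nvu_expr"))
  if (!seg %in% colnames(expr$counts)) stop("unknown segment: ", seg)
  neg <- negative_counts(expr)[, seg]
  if (length(neg) < 2)
    stop("insufficient negative probes in segment ", seg,
         " (need >= 2, have ", length(neg), ")")
  lx <- log(pmax(neg, 0.5))
  geomean <- exp(mean(lx))
  geosd <- exp(sd(lx))
  geomean * geosd^exponent
}

#' Per-segment LOQ table with per-gene detection flags
#'
#' @param expr an \code{\link{nvu_expr}} with raw counts.
#' @param exponent geometric-SD exponent.
#' @return list of class \code{nvu_loq}: \code{loq} (named per-segment LOQ),
#'   \code{exponent}, and \code{detected} (target genes x segments logical,
#'   \code{TRUE} where count > segment LOQ).
#' @export
loq_table <- function(expr, exponent = 1.5) {
  loq <- vapply(colnames(expr$counts),
                function(s) compute_loq(expr, exponent, s), numeric(1))
  tg <- target_counts(expr)
  detected <- sweep(tg, 2, loq, ">")
  structure(list(loq = loq, exponent = exponent, detected = detected),
            class = "nvu_loq")
}

#' Filter target genes by LOQ detection rate
#'
#' Retains target genes whose count exceeds the segment LOQ in at least
#' \code{min_rate} of segments. Negative probes are always dropped from the
#' output; the result is idempotent under re-filtering.
#'
#' @param expr an \code{\link{nvu_expr}} with raw counts.
#' @param loq an \code{nvu_loq} from \code{\link{loq_table}}.
#' @param min_rate minimum detection rate in [0, 1] (default 0.10, the
#'   platform convention).
#' @return an \code{\link{nvu_expr}} restricted to passing target genes.
#' @export
filter_by_loq <- function(expr, loq, min_rate = 0.1) {
  stopifnot(inherits(expr, "nvu_expr"), inherits(loq, "nvu_loq"),
            min_rate >= 0, min_rate <= 1)
  tg <- target_counts(expr)
  det <- loq$detected[rownames(tg), colnames(tg), drop = FALSE]
  rate <- rowMeans(det)
  keep <- rate >= min_rate & rate > 0
  if (!any(keep))
    stop("all target genes fall below the LOQ detection gate (min_rate = ",
         min_rate, ")")
  nvu_expr(tg[keep, , drop = FALSE], negative = rep(FALSE, sum(keep)),
           stage = expr$stage)
}

#' Q3 (upper-quartile) between-segment normalization
#'
#' Each segment is scaled by (geometric mean of all segments' 75th-percentile
#' counts) / (that segment's 75th percentile); quantiles use R's default
#' linear interpolation (type 7) so results are bit-stable. Optionally the
#' matrix is then put on the log2(x + 1) scale.
#'
#' @param expr a filtered target-gene \code{\link{nvu_expr}} (>= 4 genes).
#' @param log2_out return log2(x + 1) values (default TRUE).
#' @return an \code{\link{nvu_expr}} with stage \code{"log2"} (or
#'   \code{"normalized"}); the per-segment scale factors are attached as the
#'   \code{"q3_factors"} attribute.
#' @export
q3_normalize <- function(expr, log2_out = TRUE) {
  stopifnot(inherits(expr, "nvu_expr"))
  if (any(expr$negative)) stop("normalize the filtered target matrix")
  m <- expr$counts
  if (nrow(m) < 4) stop("need >= 4 genes for Q3 normalization")
  q3 <- apply(m, 2, quantile, probs = 0.75, names = FALSE, type = 7)
  zero <- q3 <= 0
  if (any(zero))
    stop("zero 75th-percentile count in segment(s): ",
         paste(colnames(m)[zero], collapse = ", "))
  factors <- geomean(q3) / q3
  norm <- sweep(m, 2, factors, "*")
  out <- if (log2_out)
    nvu_expr(log2(norm + 1), negative = expr$negative, stage = "log2")
  else nvu_expr(norm, negative = expr$negative, stage = "normalized")
  attr(out, "q3_factors") <- factors
  out
}
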