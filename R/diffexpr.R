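#' @title Covariate-adjusted differential expression and diffusion embedding
#' @description Per-gene ordinary least squares on log2 expression with
#'   empirical-Bayes variance moderation (moment-matched scaled-F prior on the
#'   gene-wise variances), the study's per-unit sample filters (low-median
#'   exclusion and principal-component boxplot outliers), significance
#'   classification at the published gates, and the diffusion-map (Lafon)
#'   embedding of sample Spearman correlations.
#' @name diffexpr
NULL

# Newton inversion of the trigamma function (for the variance-prior df)
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

# moment-match the scaled-F distribution of gene-wise variances on the log
# scale; returns the prior df d0 and prior variance s0^2
.squeeze_var <- function(s2, df) {
  s2 <- pmax(s2, 1e-300)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0)
    return(list(df_prior = Inf, s2_prior = exp(mean(e))))
  df_prior <- 2 * .trigamma_inverse(evar)
  s2_prior <- exp(mean(e) + digamma(df_prior / 2) - log(df_prior / 2))
  list(df_prior = df_prior, s2_prior = s2_prior)
}

#' Differential expression between APP genotypes with sex adjustment
#'
#' Fits, per gene, ordinary least squares of log2 expression on
#' (intercept, genotype, sex); the genotype coefficient is APP+ minus APP-.
#' With \code{moderated = TRUE} the residual variances are shrunk toward a
#' common prior: posterior variance (d0 s0^2 + d s^2) / (d0 + d) with d0 and
#' s0^2 moment-matched to the scaled-F distribution of the gene-wise
#' variances, and the moderated t is referred to d0 + d degrees of freedom.
#' P-values are two-sided; q is Benjamini-Hochberg across genes.
#'
#' @param expr genes x segments log2 matrix, or an \code{\link{nvu_expr}} with
#'   stage \code{"log2"}.
#' @param annot segment annotation covering the matrix columns.
#' @param covariates additional annotation columns modeled as fixed effects
#'   (default \code{"sex"}).
#' @param moderated empirical-Bayes moderation (default TRUE); FALSE gives
#'   plain OLS t-statistics for oracle checks.
#' @return data.frame of class \code{nvu_de}: \code{gene}, \code{logFC},
#'   \code{t}, \code{p}, \code{q}; contrast metadata in attributes.
#' @export
fit_de <- function(expr, annot, covariates = "sex", moderated = TRUE) {
  Y <- if (inherits(expr, "nvu_expr")) {
    if (expr$stage != "log2") stop("fit_de expects log2-scale expression")
    target_counts(expr)
  } else expr
  annot <- validate_annotation(annot)
  annot <- annot[match(colnames(Y), annot$segment_id), , drop = FALSE]
  if (anyNA(annot$segment_id))
    stop("annotation does not cover all segments")
  for (g in unique(annot$genotype)) {}
  if (min(table(factor(annot$genotype, c("APP-", "APP+")))) < 2)
    stop("need >= 2 segments per genotype")

  annot$genotype <- factor(annot$genotype, levels = c("APP-", "APP+"))
  fml <- stats::as.formula(paste(
    "~ genotype",
    if (length(covariates)) paste("+", paste(covariates, collapse = " + "))
    else ""))
  X <- model.matrix(fml, data = annot)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank-deficient; confounded column(s): ",
         paste(bad, collapse = ", "))
  }
  n <- nrow(X); p <- ncol(X); df <- n - p
  if (df < 1) stop("no residual degrees of freedom")

  coef <- t(qr.coef(qrX, t(Y)))                 # genes x p
  fitted <- coef %*% t(X)
  res <- Y - fitted
  s2 <- rowSums(res^2) / df
  xtxi <- chol2inv(qr.R(qrX)[seq_len(p), seq_len(p), drop = FALSE])
  j <- which(colnames(X) == "genotypeAPP+")
  unscaled <- sqrt(xtxi[j, j])
  lfc <- coef[, j]

  if (moderated) {
    sq <- .squeeze_var(s2, df)
    s2_post <- if (is.infinite(sq$df_prior)) rep(sq$s2_prior, length(s2))
      else (sq$df_prior * sq$s2_prior + df * s2) / (sq$df_prior + df)
    df_total <- min(sq$df_prior + df, 1e7)
  } else {
    sq <- list(df_prior = 0, s2_prior = NA_real_)
    s2_post <- s2
    df_total <- df
  }
  se <- unscaled * sqrt(s2_post)
  tstat <- ifelse(se > 0, lfc / se, 0)
  pval <- 2 * pt(-abs(tstat), df_total)
  out <- data.frame(gene = rownames(Y), logFC = unname(lfc),
                    t = unname(tstat), p = unname(pval),
                    q = p.adjust(pval, "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("nvu_de", "data.frame")
  attr(out, "contrast") <- "APP+ vs APP-"
  attr(out, "covariates") <- covariates
  attr(out, "df_prior") <- sq$df_prior
  attr(out, "s2_prior") <- sq$s2_prior
  attr(out, "df_residual") <- df
  out
}

#' Per-unit sample filtering before cell-type DE
#'
#' Stage 1 drops segments whose log2 median linear expression is strictly
#' below \code{min_log2_median} (the study used 4). Stage 2 computes
#' principal components of the remaining segments (genes centered) and drops
#' segments falling outside the boxplot whiskers
#' [Q1 - 1.5 IQR, Q3 + 1.5 IQR] on PC1 or PC2.
#'
#' @param cts_unit genes x segments log2(x + 1) matrix for one unit.
#' @param min_log2_median stage-1 threshold (log2 units).
#' @return list: \code{matrix} (surviving columns), \code{log} (data.frame
#'   segment, stage, reason for every exclusion).
#' @export
filter_unit_samples <- function(cts_unit, min_log2_median = 4) {
  stopifnot(is.matrix(cts_unit))
  if (ncol(cts_unit) < 4) stop("need >= 4 segments")
  lin_med <- apply(pmax(2^cts_unit - 1, 0), 2, median)
  thr <- 2^min_log2_median
  # strict inequality with a relative guard so log-scale round-trips cannot
  # flip a median sitting exactly on the threshold
  low <- lin_med < thr * (1 - 1e-9)
  log_df <- if (any(low))
    data.frame(segment = colnames(cts_unit)[low], stage = "median",
               reason = sprintf("log2(median)=%.3f < %g",
                                log2(pmax(lin_med[low], 1e-300)),
                                min_log2_median),
               stringsAsFactors = FALSE)
  else data.frame(segment = character(), stage = character(),
                  reason = character(), stringsAsFactors = FALSE)
  m <- cts_unit[, !low, drop = FALSE]
  if (ncol(m) < 4) stop("fewer than 4 segments survive the median filter")

  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  flags <- rep(FALSE, ncol(m))
  for (k in 1:min(2, ncol(pc$x))) {
    v <- pc$x[, k]
    qs <- quantile(v, c(0.25, 0.75), names = FALSE)
    iqr <- qs[2] - qs[1]
    flags <- flags | v < qs[1] - 1.5 * iqr | v > qs[2] + 1.5 * iqr
  }
  if (any(flags))
    log_df <- rbind(log_df,
                    data.frame(segment = colnames(m)[flags], stage = "pca",
                               reason = "outside 1.5*IQR whiskers on PC1/PC2",
                               stringsAsFactors = FALSE))
  out <- m[, !flags, drop = FALSE]
  if (ncol(out) < 4) stop("fewer than 4 segments survive the outlier filter")
  list(matrix = out, log = log_df)
}

#' Classify DE genes at the published gates
#'
#' Strict inequalities throughout: up requires p < \code{p_cut} and
#' logFC > \code{lfc_cut}; down requires p < \code{p_cut} and
#' logFC < -\code{lfc_cut}.
#'
#' @param de an \code{nvu_de}.
#' @param p_cut significance gate on raw p (default 0.05; set
#'   \code{use_q = TRUE} to gate on BH-FDR instead).
#' @param lfc_cut absolute log2-fold-change gate (default 0.25).
#' @param use_q gate on the q column instead of raw p.
#' @return list: \code{up}, \code{down}, \code{ns} (gene vectors),
#'   \code{counts} (named integer vector incl. \code{significant} =
#'   p < p_cut regardless of logFC).
#' @export
classify_de <- function(de, p_cut = 0.05, lfc_cut = 0.25, use_q = FALSE) {
  stopifnot(p_cut > 0, lfc_cut > 0)
  pv <- if (use_q) de$q else de$p
  sig <- pv < p_cut
  up <- sig & de$logFC > lfc_cut
  down <- sig & de$logFC < -lfc_cut
  list(up = de$gene[up], down = de$gene[down],
       ns = de$gene[!(up | down)],
       counts = c(up = sum(up), down = sum(down),
                  significant = sum(sig), total = nrow(de)))
}

# diffusion-map core on a precomputed affinity matrix (alpha = 1
# density normalization, then row-normalization to a Markov operator)
.lafon_core <- function(K, t_steps = 1, tol = 1e-10) {
  d <- rowSums(K)
  K1 <- K / (d %o% d)
  d2 <- rowSums(K1)
  Ms <- K1 / sqrt(d2 %o% d2)        # symmetric conjugate of the Markov matrix
  eg <- eigen(Ms, symmetric = TRUE)
  lambda <- eg$values
  psi <- eg$vectors / sqrt(d2)      # right eigenvectors of the Markov matrix
  keep <- which(seq_along(lambda) > 1 & lambda > tol)
  if (!length(keep)) {
    warning("no non-trivial diffusion components; embedding is empty")
    return(list(phi = matrix(0, nrow(K), 0), eigenvalues = numeric(0)))
  }
  phi <- sweep(psi[, keep, drop = FALSE], 2, lambda[keep]^t_steps, "*")
  # deterministic sign: largest-magnitude coordinate positive
  for (k in seq_len(ncol(phi))) {
    s <- sign(phi[which.max(abs(phi[, k])), k])
    if (s != 0) phi[, k] <- phi[, k] * s
  }
  colnames(phi) <- paste0("Phi", seq_len(ncol(phi)))
  rownames(phi) <- rownames(K)
  list(phi = phi, eigenvalues = lambda[keep])
}

#' Diffusion-map (Lafon) embedding of samples
#'
#' Sample-sample Spearman correlations are mapped to the affinity
#' (1 + rho) / 2, density-normalized with alpha = 1, row-normalized to a
#' Markov operator, and eigendecomposed; the embedding coordinates are
#' Phi_k = lambda_k^t psi_k for k >= 1 (the trivial constant eigenvector is
#' discarded). Components are ordered by decreasing eigenvalue.
#'
#' @param expr_sub samples x genes log2 matrix (typically restricted to the
#'   DE genes); >= 3 samples, >= 2 genes.
#' @param t_steps diffusion time (default 1).
#' @return list of class \code{nvu_diffusion}: \code{phi} (samples x
#'   components), \code{eigenvalues}, \code{genes}.
#' @export
lafon_embedding <- function(expr_sub, t_steps = 1) {
  stopifnot(is.matrix(expr_sub))
  if (nrow(expr_sub) < 3) stop("need >= 3 samples")
  if (ncol(expr_sub) < 2) stop("need >= 2 genes")
  sds <- apply(expr_sub, 1, sd)
  if (any(sds == 0))
    stop("constant sample vector (Spearman undefined): ",
         paste(rownames(expr_sub)[sds == 0], collapse = ", "))
  rho <- cor(t(expr_sub), method = "spearman")
  K <- (1 + rho) / 2
  out <- .lafon_core(K, t_steps)
  structure(list(phi = out$phi, eigenvalues = out$eigenvalues,
                 genes = colnames(expr_sub)),
            class = "nvu_diffusion")
}

#' Per-unit differential expression over purified expression
#'
#' Applies \code{\link{filter_unit_samples}} then \code{\link{fit_de}} to each
#' unit's purified genes x segments matrix (valid segments only).
#'
#' After the sample filters, each unit's surviving matrix is Q3-normalized
#' across segments (75th-percentile scaling on the linear scale) before the
#' fit: the purified expression level of a segment-unit carries an arbitrary
#' per-segment scale from the estimated fraction it was divided by, and the
#' upper-quartile rescaling removes that compositional scale noise without
#' touching gene-specific contrasts.
#'
#' @param cts an \code{nvu_ctexpr} (post \code{\link{stability_filter}}).
#' @param annot segment annotation.
#' @param min_log2_median stage-1 filter threshold.
#' @param covariates fixed-effect covariates for \code{\link{fit_de}}.
#' @param moderated use variance moderation.
#' @param normalize Q3-normalize each unit's filtered matrix before the fit.
#' @param min_fraction segments whose estimated fraction of the unit is
#'   below this are excluded from that unit's contrast (default 0.05): the
#'   expression of a unit constituting less than ~5 percent of a bulk
#'   mixture is not recoverable, and such segments contribute heavy-tailed
#'   noise. Requires the purified set to carry its fraction table.
#' @return named list (per unit) of \code{nvu_de} tables; each carries the
#'   exclusion log as attribute \code{"filter_log"}.
#' @export
fit_de_by_unit <- function(cts, annot, min_log2_median = 4,
                           covariates = "sex", moderated = TRUE,
                           normalize = TRUE, min_fraction = 0.05) {
  stopifnot(inherits(cts, "nvu_ctexpr"))
  units <- dimnames(cts$expr)[[3]]
  out <- list()
  for (u in units) {
    m <- t(cts$expr[, , u])                 # genes x segments
    keep <- cts$valid[, u]
    if (!is.null(cts$fractions))
      keep <- keep & cts$fractions[, u] >= min_fraction
    m <- m[, keep, drop = FALSE]
    if (ncol(m) < 4) next
    flt <- filter_unit_samples(m, min_log2_median = min_log2_median)
    fit_mat <- flt$matrix
    if (normalize) {
      lin <- pmax(2^fit_mat - 1, 0)
      q3 <- apply(lin, 2, quantile, probs = 0.75, names = FALSE)
      if (all(q3 > 0))
        fit_mat <- log2(sweep(lin, 2, geomean(q3) / q3, "*") + 1)
    }
    de <- fit_de(fit_mat, annot, covariates = covariates,
                 moderated = moderated)
    attr(de, "filter_log") <- flt$log
    attr(de, "unit") <- u
    out[[u]] <- de
  }
  out
}
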