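#' @title Fraction estimation, knockoff pseudo-replicates, and purification
#' @description The deconvolution core: per-segment non-negative least-squares
#'   (NNLS) estimation of cell-unit fractions against the reference,
#'   SVD-based knockoff pseudo-replicates that preserve each segment's fitted
#'   low-rank structure while randomizing residual structure, per-segment
#'   per-gene purification of cell-type expression from the replicate
#'   ensemble, the instability filter on missing units, and the Wilcoxon
#'   abundance test.
#' @name deconv
NULL

# NNLS of y on the columns of S. Both sides are scaled by per-gene weights
# (same scaling left and right, so the mixing coefficients are untouched),
# then y is unit-variance scaled for conditioning and the coefficients mapped
# back before simplex renormalization, so fractions are not biased by scale.
.nnls_fractions <- function(y, S, w = NULL) {
  if (!is.null(w)) {
    y <- y * w
    S <- S * w
  }
  sy <- sd(y)
  if (!is.finite(sy) || sy == 0) sy <- 1
  fit <- .nnls_multi(S, matrix(y / sy, ncol = 1))
  beta <- fit$coef[, 1] * sy
  total <- sum(beta)
  frac <- if (total > 0) beta / total else rep(1 / ncol(S), ncol(S))
  list(fractions = frac, residual = fit$resid[1] * sy)
}

# per-gene precision weights: inverse empirical SD across segments, which
# for negative-binomial counts tracks 1/sqrt(mu + phi mu^2) and keeps the
# high-abundance genes from dominating the least-squares fit
.gene_weights <- function(m) {
  s <- apply(m, 1, sd)
  med <- median(s[s > 0])
  if (!is.finite(med) || med == 0) med <- 1
  1 / pmax(s, 1e-3 * med)
}

#' Estimate per-segment cell-unit fractions
#'
#' For each segment, solves non-negative least squares of the (linear-scale)
#' segment profile on the reference columns over the shared genes, and
#' renormalizes the coefficients to the simplex. Both sides are scaled
#' gene-wise by inverse empirical SD across segments (a precision weight that
#' keeps overdispersed high-abundance genes from dominating the fit; applied
#' identically to profile and reference, it leaves the mixing coefficients
#' unbiased) and the profile is unit-variance scaled for conditioning.
#' Invariant to global scaling of the segment profile.
#'
#' @param expr an \code{\link{nvu_expr}} on the linear scale (raw or
#'   normalized), or a genes x segments matrix.
#' @param ref an \code{nvu_reference} (genes x units).
#' @param weights optional per-gene weights (named or in shared-gene order);
#'   by default the inverse per-gene SD across segments (unit weights when
#'   fewer than 3 segments).
#' @return segments x units matrix of class \code{nvu_fractions}; rows on the
#'   simplex, per-row fit residual in attribute \code{"residual"}.
#' @export
estimate_fractions <- function(expr, ref, weights = NULL) {
  m <- if (inherits(expr, "nvu_expr")) {
    if (expr$stage == "log2") stop("fractions are estimated on the linear scale")
    target_counts(expr)
  } else expr
  shared <- intersect(rownames(m), rownames(ref))
  if (length(shared) < 50)
    stop("need >= 50 genes shared with the reference, have ", length(shared))
  S <- ref[shared, , drop = FALSE]
  class(S) <- "matrix"
  w <- if (!is.null(weights)) {
    if (!is.null(names(weights))) unname(weights[shared]) else weights
  } else if (ncol(m) >= 3) .gene_weights(m[shared, , drop = FALSE]) else NULL
  fr <- matrix(0, ncol(m), ncol(S),
               dimnames = list(colnames(m), colnames(S)))
  resid <- numeric(ncol(m))
  for (i in seq_len(ncol(m))) {
    fit <- .nnls_fractions(m[shared, i], S, w)
    fr[i, ] <- fit$fractions
    resid[i] <- fit$residual
  }
  structure(fr, class = c("nvu_fractions", "matrix"), residual = resid)
}

# deterministic random orthogonal matrix (QR with positive diagonal)
.rand_orthogonal <- function(q) {
  z <- matrix(rnorm(q * q), q, q)
  qr_ <- qr(z)
  Q <- qr.Q(qr_)
  Q %*% diag(sign(diag(qr.R(qr_))), q, q)
}

#' SVD-based knockoff pseudo-replicates
#'
#' The segments x genes linear-scale matrix is gene-wise precision-scaled
#' (inverse per-gene SD; a diagonal scaling commutes with mixing, so scaled
#' profiles are still exact mixtures of the scaled reference) and centered;
#' its SVD splits each segment into a rank-r "signal" reconstruction (r =
#' smallest rank capturing at least \code{energy} of the squared singular
#' values) and a residual lying in the complementary right-singular subspace.
#' Each pseudo-replicate keeps the segment's signal part exactly and rotates
#' its residual coordinates by a seeded random orthogonal transform,
#' preserving the (scaled) residual norm exactly; replicates are returned in
#' the original linear units. Working on the linear scale is essential: a
#' rotation applied to log-transformed mixtures no longer yields valid
#' mixtures, which destroys the downstream purification geometry. When no
#' residual subspace exists the replicates fall back to the original profile
#' plus seeded Gaussian noise at the smallest residual scale (with a
#' warning).
#'
#' @param expr an \code{\link{nvu_expr}} on the linear scale (raw or
#'   normalized), or a genes x segments linear-scale matrix.
#' @param n_reps pseudo-replicates per segment (the study used 30).
#' @param energy proportion of squared-singular-value energy defining the
#'   signal rank, in (0, 1] (default 0.90).
#' @param seed integer seed; identical seeds give byte-identical ensembles.
#' @return list of class \code{nvu_knockoffs}: \code{replicates} (per segment,
#'   an n_reps x genes matrix, linear scale, clipped at zero), \code{rank},
#'   \code{seed}, \code{genes}, \code{segments}.
#' @export
make_knockoffs <- function(expr, n_reps = 30, energy = 0.9, seed = 1) {
  m <- if (inherits(expr, "nvu_expr")) {
    if (expr$stage == "log2")
      stop("knockoffs are constructed on the linear scale")
    target_counts(expr)
  } else expr
  stopifnot(energy > 0, energy <= 1)
  X <- t(m)                      # segments x genes
  n <- nrow(X)
  if (n < 3) stop("need >= 3 segments for knockoff construction")
  w <- if (n >= 3) .gene_weights(m) else rep(1, nrow(m))
  X <- sweep(X, 2, w, "*")       # precision-scaled working space
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d) * 1e-12
  d <- sv$d[pos]
  cum <- cumsum(d^2) / sum(d^2)
  r <- which(cum >= energy)[1]
  q <- length(d) - r             # residual-subspace dimension

  U <- sv$u[, pos, drop = FALSE]
  V <- sv$v[, pos, drop = FALSE]
  signal <- U[, seq_len(r), drop = FALSE] %*%
    (d[seq_len(r)] * t(V[, seq_len(r), drop = FALSE]))

  reps <- withr::with_seed(seed, {
    if (q == 0) {
      warning("no residual subspace (signal rank = matrix rank); ",
              "falling back to Gaussian perturbation")
      scale <- min(d) / sqrt(n * ncol(X))
      lapply(seq_len(n), function(i) {
        out <- matrix(rnorm(n_reps * ncol(X), sd = scale), n_reps, ncol(X))
        out <- sweep(out, 2, X[i, ], "+")
        out <- sweep(out, 2, w, "/")
        colnames(out) <- colnames(X)
        out
      })
    } else {
      Vr <- V[, (r + 1):length(d), drop = FALSE]
      C <- U[, (r + 1):length(d), drop = FALSE] %*%
        diag(d[(r + 1):length(d)], q, q)     # residual coordinates (n x q)
      Qs <- lapply(seq_len(n_reps), function(k) .rand_orthogonal(q))
      lapply(seq_len(n), function(i) {
        base <- mu + signal[i, ]
        out <- matrix(0, n_reps, ncol(X), dimnames = list(NULL, colnames(X)))
        for (k in seq_len(n_reps))
          out[k, ] <- base + as.vector(Vr %*% (Qs[[k]] %*% C[i, ]))
        out <- sweep(out, 2, w, "/")         # back to original linear units
        out
      })
    }
  })
  names(reps) <- rownames(X)
  structure(list(replicates = reps, rank = r, seed = seed,
                 genes = colnames(X), segments = rownames(X),
                 n_reps = n_reps, weights = w, original = m),
            class = "nvu_knockoffs")
}

#' @export
print.nvu_knockoffs <- function(x, ...) {
  cat(sprintf("<nvu_knockoffs> %d segments x %d replicates x %d genes, rank %d\n",
              length(x$replicates), x$n_reps, length(x$genes), x$rank))
  invisible(x)
}

#' Purify per-segment per-unit expression from a knockoff ensemble
#'
#' Two-stage estimator. Stage 1 (collated regression): unit fractions are
#' re-estimated on every pseudo-replicate of every segment; the collated
#' ensemble — all replicates of all segments, whose fraction rows vary
#' genuinely across segments — forms the design of one non-negative
#' least-squares regression per gene, giving the cohort-level per-unit
#' expression of each gene. Stage 2 (per-segment allocation): each segment's
#' replicate-mean expression of gene g is allocated across units in
#' proportion to fraction times cohort-level unit expression, and the
#' allocated signal is divided by the unit's fraction, yielding the unit's
#' expression level (not its contribution to the mixture). A unit therefore
#' receives signal only where both its estimated fraction and its
#' cohort-level expression of the gene are non-zero; genes the cohort
#' regression attributes to other units are exactly zero. On noiseless
#' mixtures the estimator is exact: the purified profile of every present
#' unit equals its reference column up to the segment's library scale.
#'
#' Units whose estimated fraction is (numerically) zero in every replicate
#' of a segment are flagged invalid for that segment, as is the whole
#' segment when its replicate design has rank < 2.
#'
#' @param ens an \code{nvu_knockoffs} (linear-scale replicates).
#' @param ref an \code{nvu_reference}.
#' @param support_min cohort support threshold (default 0.01). Two roles:
#'   for genes the reference measures, a unit may receive cohort expression
#'   only where its reference value is at least \code{support_min} of the
#'   gene's maximum reference value (the regression respects the
#'   reference's expression support); and cohort estimates below
#'   \code{support_min} of the gene's maximum unit value are zeroed
#'   (denoising the non-negative least-squares support).
#' @param covariate optional per-segment contrast covariate (e.g. the
#'   genotype indicator; named by segment id or in ensemble order). It
#'   enters the stage-1 regression as a free main-effect column, so that a
#'   condition-linked expression shift — which co-varies with any
#'   condition-linked abundance shift — is not misattributed to the units
#'   whose abundances track the condition.
#' @return list of class \code{nvu_ctexpr}: \code{expr} (segments x genes x
#'   units array of log2(x + 1) values, \code{NA} where invalid),
#'   \code{valid} (segments x units logical), and \code{cohort} (genes x
#'   units cohort-level expression from stage 1).
#' @export
purify_expression <- function(ens, ref, support_min = 0.01,
                              covariate = NULL) {
  stopifnot(inherits(ens, "nvu_knockoffs"))
  units <- colnames(ref)
  shared <- intersect(ens$genes, rownames(ref))
  if (length(shared) < 50)
    stop("ensemble and reference share too few genes (", length(shared), ")")
  S <- ref[shared, , drop = FALSE]
  class(S) <- "matrix"
  segs <- ens$segments
  genes <- ens$genes
  n_reps <- ens$n_reps
  expr <- array(NA_real_, dim = c(length(segs), length(genes), length(units)),
                dimnames = list(segs, genes, units))
  valid <- matrix(TRUE, length(segs), length(units),
                  dimnames = list(segs, units))

  # per-gene precision weights across segments (replicate means)
  seg_means <- vapply(ens$replicates, function(R)
    colMeans(pmax(R[, shared, drop = FALSE], 0)), numeric(length(shared)))
  w <- if (length(segs) >= 3) .gene_weights(seg_means) else NULL

  # stage 1: per-replicate fractions, collated design
  D_all <- matrix(0, length(segs) * n_reps, length(units),
                  dimnames = list(NULL, units))
  Y_all <- matrix(0, length(segs) * n_reps, length(genes))
  D_bar <- matrix(0, length(segs), length(units),
                  dimnames = list(segs, units))
  for (i in seq_along(segs)) {
    R <- pmax(ens$replicates[[i]], 0)
    rows <- (i - 1) * n_reps + seq_len(n_reps)
    for (k in seq_len(n_reps))
      D_all[rows[k], ] <- .nnls_fractions(R[k, shared], S, w)$fractions
    Y_all[rows, ] <- R
    D_bar[i, ] <- colMeans(D_all[rows, , drop = FALSE])
  }
  ww <- if (is.null(w)) rep(1, length(shared)) else w
  wfull <- setNames(rep(median(ww), length(genes)), genes)
  wfull[shared] <- ww
  design <- D_all
  n_extra <- 0L
  if (!is.null(covariate)) {
    cv <- if (!is.null(names(covariate))) unname(covariate[segs])
      else covariate
    if (length(cv) != length(segs) || anyNA(cv))
      stop("covariate must cover every ensemble segment")
    cv <- as.numeric(as.factor(cv)) - 1
    cv_rows <- rep(cv, each = n_reps)
    # +/- split makes the covariate coefficient sign-free under NNLS
    design <- cbind(D_all, cv_rows, -cv_rows)
    n_extra <- 2L
  }

  # per-gene unit support: where the reference measures the gene, only units
  # that express it in the reference may receive cohort-level expression
  supp <- matrix(TRUE, length(genes), length(units),
                 dimnames = list(genes, units))
  ref_max <- apply(S, 1, max)
  supp[shared, ] <- S >= pmax(support_min * ref_max, 1e-12)
  supp[shared, ][ref_max == 0, ] <- TRUE

  Yw <- sweep(Y_all, 2, wfull, "*")
  cohort <- matrix(0, length(genes), length(units),
                   dimnames = list(genes, units))
  pattern <- apply(supp, 1, function(z) paste(as.integer(z), collapse = ""))
  # Per-gene attribution is only identifiable where expression covaries with
  # composition; for a uniformly expressed gene the likelihood is nearly flat
  # along the simplex-null direction and the NNLS support is an arbitrary
  # vertex. Guard by model comparison: keep the structured fit only when it
  # improves on proportional allocation (every allowed unit at the gene's
  # mean level) by a meaningful margin, otherwise allocate proportionally.
  y_mean <- colMeans(Yw)
  for (pat in unique(pattern)) {
    gs <- which(pattern == pat)
    cols <- which(supp[gs[1], ])
    A <- design[, c(cols, length(units) + seq_len(n_extra)), drop = FALSE]
    fit <- .nnls_multi(A, Yw[, gs, drop = FALSE])
    rss_s <- fit$resid^2
    # proportional model: fraction-sum times mean level, covariate refit
    rs <- rowSums(design[, cols, drop = FALSE])
    R0 <- Yw[, gs, drop = FALSE] - outer(rs, y_mean[gs])
    if (n_extra > 0) {
      gv <- design[, length(units) + 1]
      R0 <- R0 - outer(gv, colSums(gv * R0) / max(sum(gv^2), 1e-12))
    }
    rss_p <- colSums(R0^2)
    # structured attribution must beat proportional by a clear margin;
    # per-segment random effects make small RSS gains pure noise-chasing
    use_prop <- rss_p <= rss_s * 1.25
    co_t <- t(fit$coef[seq_along(cols), , drop = FALSE])
    if (any(use_prop))
      co_t[use_prop, ] <- matrix(y_mean[gs][use_prop],
                                 sum(use_prop), length(cols))
    cohort[gs, cols] <- co_t
  }
  # genes the reference does not measure carry no support knowledge: an
  # exact zero from the collinear fit is an artifact there, so their unit
  # values are floored at a quarter of the gene's mean level
  nonref <- !(genes %in% shared)
  if (any(nonref))
    cohort[nonref, ] <- pmax(cohort[nonref, , drop = FALSE],
                             0.25 * y_mean[nonref])
  cohort <- sweep(cohort, 1, wfull, "/")      # genes x units, linear scale
  cohort[cohort < support_min * apply(cohort, 1, max)] <- 0

  # stage 2: fraction-weighted allocation, reported as expression levels
  for (i in seq_along(segs)) {
    R <- pmax(ens$replicates[[i]], 0)
    rows <- (i - 1) * n_reps + seq_len(n_reps)
    D_i <- D_all[rows, , drop = FALSE]
    absent <- apply(D_i, 2, max) < 1e-6
    if (qr(D_i)$rank < 2) {
      valid[i, ] <- FALSE
      next
    }
    valid[i, absent] <- FALSE
    # allocate the observed profile (the replicates stabilize the fractions
    # and the cohort fit; the segment's own expression carries the
    # gene-level covariation the rotations scramble)
    y_bar <- if (!is.null(ens$original)) ens$original[, segs[i]]
      else colMeans(R)
    load <- sweep(cohort, 2, D_bar[i, ], "*") # genes x units
    denom <- rowSums(load)
    share <- load / ifelse(denom > 0, denom, 1)
    if (any(denom <= 0))
      share[denom <= 0, ] <- matrix(D_bar[i, ] / sum(D_bar[i, ]),
                                    sum(denom <= 0), length(units),
                                    byrow = TRUE)
    x <- share * y_bar
    # floor the divisor at 1%: dividing by a vanishing fraction estimate
    # would explode the level of a unit that is barely present anyway
    x <- sweep(x, 2, pmax(D_bar[i, ], 0.01), "/")  # contribution -> level
    x[, absent] <- NA_real_
    expr[i, , ] <- log2(pmax(x, 0) + 1)
  }
  structure(list(expr = expr, valid = valid, cohort = cohort,
                 fractions = D_bar),
            class = "nvu_ctexpr")
}

#' @export
print.nvu_ctexpr <- function(x, ...) {
  d <- dim(x$expr)
  cat(sprintf("<nvu_ctexpr> %d segments x %d genes x %d units (%d invalid flags)\n",
              d[1], d[2], d[3], sum(!x$valid)))
  invisible(x)
}

#' Remove segments with unstable deconvolution
#'
#' Segments with \code{max_missing} or more invalid units are removed
#' entirely (the study observed instability when 2 or more NVU cell types
#' were missing and excluded those ROIs).
#'
#' @param cts an \code{nvu_ctexpr}.
#' @param max_missing removal threshold (a segment is removed when its
#'   invalid-unit count is >= this; default 2).
#' @return filtered \code{nvu_ctexpr} with attribute \code{"removed"}
#'   (named invalid-unit counts of the removed segments).
#' @export
stability_filter <- function(cts, max_missing = 2) {
  stopifnot(inherits(cts, "nvu_ctexpr"), max_missing >= 1)
  miss <- rowSums(!cts$valid)
  drop <- miss >= max_missing
  if (all(drop)) stop("all segments removed by the stability filter")
  if (any(drop))
    message(sum(drop), " segment(s) removed by the stability filter (",
            "missing-unit counts: ",
            paste(miss[drop], collapse = ", "), ")")
  out <- structure(list(expr = cts$expr[!drop, , , drop = FALSE],
                        valid = cts$valid[!drop, , drop = FALSE],
                        cohort = cts$cohort,
                        fractions = cts$fractions[!drop, , drop = FALSE]),
                   class = "nvu_ctexpr")
  attr(out, "removed") <- miss[drop]
  out
}

#' Wilcoxon rank-sum test on one unit's abundances by genotype
#'
#' Exact two-sided distribution when both groups have at most 25 segments and
#' there are no ties; otherwise the normal approximation with continuity
#' correction.
#'
#' @param fr an \code{nvu_fractions}.
#' @param annot segment annotation (genotype column used).
#' @param unit unit label (column of \code{fr}).
#' @return list with \code{statistic} (W), \code{p.value}, \code{method}.
#' @export
test_abundance_shift <- function(fr, annot, unit) {
  if (!unit %in% colnames(fr)) stop("unknown unit: ", unit)
  annot <- validate_annotation(annot)
  x <- unclass(fr)[match(annot$segment_id, rownames(fr)), unit]
  g_pos <- x[annot$genotype == "APP+"]
  g_neg <- x[annot$genotype == "APP-"]
  if (!length(g_pos) || !length(g_neg))
    stop("both genotype groups must be non-empty")
  ties <- anyDuplicated(c(g_pos, g_neg)) > 0
  exact <- length(g_pos) <= 25 && length(g_neg) <= 25 && !ties
  ht <- wilcox.test(g_pos, g_neg, exact = exact, correct = TRUE)
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       method = ht$method)
}
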