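.toy_ref <- function() {
  # two disjoint-support (orthogonal) columns plus shared genes
  S <- cbind(U1 = c(rep(10, 30), rep(0, 30), rep(5, 40)),
             U2 = c(rep(0, 30), rep(8, 30), rep(5, 40)))
  rownames(S) <- sprintf("g%03d", 1:100)
  structure(S, class = c("nvu_reference", "matrix"),
            cells_used = c(U1 = 1L, U2 = 1L))
}

test_that("fraction estimation recovers pure and mixed profiles exactly", {
  S <- .toy_ref()
  y <- matrix(S[, "U1"], ncol = 1, dimnames = list(rownames(S), "seg1"))
  fr <- estimate_fractions(y, S)
  expect_equal(unname(fr[1, ]), c(1, 0), tolerance = 1e-9)

  ortho <- structure(unclass(S)[1:60, ], class = c("nvu_reference", "matrix"))
  mix <- matrix(0.5 * ortho[, 1] + 0.5 * ortho[, 2], ncol = 1,
                dimnames = list(rownames(ortho), "seg1"))
  fr2 <- estimate_fractions(mix, ortho)
  expect_equal(unname(fr2[1, ]), c(0.5, 0.5), tolerance = 1e-6)
  expect_lt(attr(fr2, "residual")[1], 1e-9)
})

test_that("fraction estimation is scale-invariant and validates inputs", {
  S <- .toy_ref()
  set.seed(51)
  y <- matrix(as.vector(S %*% c(0.3, 0.7)) + rexp(100), 100, 1,
              dimnames = list(rownames(S), "seg1"))
  f1 <- estimate_fractions(y, S)
  f2 <- estimate_fractions(y * 1e4, S)
  expect_equal(unclass(f1), unclass(f2), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_simplex(unclass(f1))
  short <- y[1:40, , drop = FALSE]
  expect_error(estimate_fractions(short, S), ">= 50 genes")
})

test_that("the NNLS solver agrees with an independent implementation", {
  skip_if_not_installed("pracma")
  set.seed(52)
  for (i in 1:20) {
    A <- matrix(rnorm(30 * 4), 30, 4)
    b <- rnorm(30)
    ours <- nvudeconv:::.nnls_multi(A, matrix(b, ncol = 1))
    oracle <- pracma::lsqnonneg(A, b)
    expect_equal(ours$coef[, 1], oracle$x, tolerance = 1e-8)
    expect_equal(ours$resid[1]^2, oracle$resid.norm, tolerance = 1e-8)
  }
})

test_that("knockoffs preserve signal and residual geometry exactly", {
  set.seed(53)
  n <- 12; p <- 80
  m <- matrix(rexp(n * p, 1 / 50), p, n,
              dimnames = list(sprintf("g%02d", 1:p), sprintf("S%02d", 1:n)))
  ens <- make_knockoffs(m, n_reps = 5, energy = 0.6, seed = 7)
  w <- ens$weights
  X <- sweep(t(m), 2, w, "*")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  r <- ens$rank
  Vs <- sv$v[, seq_len(r), drop = FALSE]
  recon <- sv$u[, 1:r, drop = FALSE] %*% (sv$d[1:r] * t(Vs))
  for (i in c(1, 5, 12)) for (k in c(1, 3)) {
    rep_w <- ens$replicates[[i]][k, ] * w - mu
    # signal projection identical to the original's
    expect_equal(as.vector(rep_w %*% Vs), as.vector(Xc[i, ] %*% Vs),
                 tolerance = 1e-9)
    # residual norm preserved
    expect_equal(sqrt(sum((rep_w - recon[i, ])^2)),
                 sqrt(sum((Xc[i, ] - recon[i, ])^2)), tolerance = 1e-9)
  }
})

test_that("knockoffs are seeded and the zero-residual case degenerates", {
  set.seed(54)
  m <- matrix(rexp(10 * 60, 1 / 30), 60, 10,
              dimnames = list(sprintf("g%02d", 1:60), sprintf("S%02d", 1:10)))
  a <- make_knockoffs(m, n_reps = 4, energy = 0.5, seed = 1)
  b <- make_knockoffs(m, n_reps = 4, energy = 0.5, seed = 1)
  expect_identical(a$replicates, b$replicates)
  c3 <- make_knockoffs(m, n_reps = 4, energy = 0.5, seed = 2)
  expect_false(identical(a$replicates, c3$replicates))

  # near-zero residual beyond the selected rank: replicates = original
  u <- matrix(rnorm(10 * 2), 10, 2); v <- matrix(rnorm(2 * 60), 2, 60)
  low <- t(u %*% diag(c(40, 20)) %*% v)
  low <- low - min(low) + 1
  low <- low + 1e-9 * matrix(rnorm(600), 60, 10)  # tiny third component
  dimnames(low) <- dimnames(m)
  ens <- make_knockoffs(low, n_reps = 3, energy = 0.95, seed = 1)
  for (i in 1:3)
    expect_equal(ens$replicates[[i]][1, ], low[, i], tolerance = 1e-5,
                 ignore_attr = TRUE)

  expect_error(make_knockoffs(m[, 1:2, drop = FALSE]), ">= 3 segments")
  ll <- matrix(rexp(12), 4, 3, dimnames = list(letters[1:4], LETTERS[1:3]))
  log_in <- nvu_expr(log2(ll + 1), negative = rep(FALSE, 4), stage = "log2")
  expect_error(make_knockoffs(log_in), "linear scale")
})

test_that("noiseless mixtures purify back to the reference columns", {
  ref <- fixture_ref()
  rb <- build_reference_pipeline(ref$sc, ref$signatures, n_genes = 800)
  S <- rb$reference; class(S) <- "matrix"
  set.seed(55)
  fr <- t(replicate(30, { x <- rgamma(6, c(5, 4, 4, 2, 2, 2)); x / sum(x) }))
  colnames(fr) <- colnames(S)
  mix <- S %*% t(fr)
  colnames(mix) <- sprintf("S%02d", 1:30)
  ens <- suppressWarnings(make_knockoffs(mix, n_reps = 30, energy = 0.9,
                                         seed = 1))
  pu <- suppressWarnings(purify_expression(ens, rb$reference))
  for (u in colnames(S)) {
    cors <- vapply(1:30, function(i) {
      if (!pu$valid[i, u]) return(NA_real_)
      suppressWarnings(cor(2^pu$expr[i, , u] - 1, S[, u]))
    }, numeric(1))
    expect_gte(min(cors, na.rm = TRUE), 0.99)
  }
})

test_that("absent units and rank-deficient designs are flagged invalid", {
  ref <- fixture_ref()
  rb <- build_reference_pipeline(ref$sc, ref$signatures, n_genes = 600)
  S <- rb$reference; class(S) <- "matrix"
  set.seed(56)
  segs <- sprintf("S%02d", 1:10)
  # hand-built ensemble: every replicate is an exact mixture of units 1-5,
  # with the sixth unit's fraction exactly zero
  reps <- lapply(seq_along(segs), function(i) {
    R <- t(vapply(1:8, function(k) {
      w <- c(rgamma(5, c(5, 4, 4, 2, 2)), 0)
      as.vector(S %*% (w / sum(w)))
    }, numeric(nrow(S))))
    colnames(R) <- rownames(S)
    R
  })
  names(reps) <- segs
  # degenerate segment: all replicates share one fraction row (design rank 1)
  w_fix <- c(2, 1, 1, 1, 1, 1); w_fix <- w_fix / sum(w_fix)
  reps[[10]] <- matrix(rep(as.vector(S %*% w_fix), each = 8), 8, nrow(S))
  colnames(reps[[10]]) <- rownames(S)
  ens <- structure(list(replicates = reps, rank = 2, seed = 1,
                        genes = rownames(S), segments = segs, n_reps = 8,
                        weights = NULL, original = NULL),
                   class = "nvu_knockoffs")
  pu <- purify_expression(ens, rb$reference)
  absent_unit <- colnames(S)[6]
  expect_true(all(!pu$valid[1:9, absent_unit]))
  expect_true(all(is.na(pu$expr[1:9, , absent_unit])))
  expect_true(all(pu$valid[1:9, colnames(S)[1]]))
  # the degenerate segment is invalid for every unit
  expect_true(all(!pu$valid[10, ]))
})

test_that("the stability filter removes segments at the missing-unit gate", {
  segs <- sprintf("S%02d", 1:6)
  units <- c("A", "B", "C")
  arr <- array(5, c(6, 4, 3), dimnames = list(segs, paste0("g", 1:4), units))
  valid <- matrix(TRUE, 6, 3, dimnames = list(segs, units))
  valid["S01", c("A", "B")] <- FALSE   # 2 missing -> removed
  valid["S02", "A"] <- FALSE           # 1 missing -> retained
  cts <- manual_ctexpr(arr, valid)
  out <- suppressMessages(stability_filter(cts, max_missing = 2))
  expect_equal(dimnames(out$expr)[[1]], segs[-1])
  expect_equal(unname(attr(out, "removed")), 2)
  # brute-force count agrees
  expect_equal(sum(rowSums(!valid) >= 2), 1)
  all_bad <- manual_ctexpr(arr, matrix(FALSE, 6, 3,
                                       dimnames = list(segs, units)))
  expect_error(suppressMessages(stability_filter(all_bad, 1)), "all segments")
})

test_that("the abundance test matches the exact Wilcoxon distribution", {
  fr <- structure(matrix(c(1, 2, 3, 4, 5, 6) / 10, 6, 1,
                         dimnames = list(sprintf("S%d", 1:6), "Microglia")),
                  class = c("nvu_fractions", "matrix"),
                  residual = rep(0, 6))
  annot <- data.frame(segment_id = sprintf("S%d", 1:6),
                      roi_id = sprintf("R%d", 1:6), mouse_id = "m1",
                      genotype = rep(c("APP-", "APP+"), each = 3), sex = "F")
  out <- test_abundance_shift(fr, annot, "Microglia")
  expect_equal(out$p.value, 0.1)       # 2 / choose(6, 3)

  same <- fr; same[4:6, 1] <- same[1:3, 1]
  expect_equal(test_abundance_shift(same, annot, "Microglia")$p.value, 1)

  bad <- annot; bad$genotype <- "APP-"
  expect_error(test_abundance_shift(fr, bad, "Microglia"), "non-empty")
  expect_error(test_abundance_shift(fr, annot, "Elf"), "unknown unit")
})
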