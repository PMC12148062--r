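.de_annot <- function(n, genotype = rep(c("APP-", "APP+"), each = n / 2),
                      sex = rep(c("F", "M"), length.out = n)) {
  data.frame(segment_id = sprintf("S%02d", 1:n),
             roi_id = sprintf("R%02d", 1:n), mouse_id = "m1",
             genotype = genotype, sex = sex, stringsAsFactors = FALSE)
}

test_that("identical genotype groups give zero logFC and p = 1", {
  set.seed(61)
  half <- matrix(rnorm(50 * 4, 8), 50, 4)
  Y <- cbind(half, half)   # APP+ columns copy APP- columns
  dimnames(Y) <- list(sprintf("g%02d", 1:50), sprintf("S%02d", 1:8))
  annot <- .de_annot(8, genotype = rep(c("APP-", "APP+"), each = 4),
                     sex = rep(c("F", "M", "F", "M"), 2))
  de <- fit_de(Y, annot)
  expect_equal(de$logFC, rep(0, 50), tolerance = 1e-12)
  expect_equal(de$p, rep(1, 50), tolerance = 1e-12)
})

test_that("unmoderated fit reproduces the closed-form OLS oracle", {
  Y <- matrix(c(1, 2, 3, 4), 1, 4,
              dimnames = list("g1", sprintf("S%02d", 1:4)))
  annot <- .de_annot(4, sex = rep("F", 4))
  de <- fit_de(Y, annot, covariates = character(0), moderated = FALSE)
  expect_equal(de$logFC, 2)
  expect_equal(de$t, 2.828427, tolerance = 1e-6)
  expect_equal(de$p, 0.1055728, tolerance = 1e-6)
  expect_equal(attr(de, "df_residual"), 2)
})

test_that("moderated statistics match the established empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(62)
  n <- 24
  Y <- matrix(rnorm(300 * n, sd = rep(sqrt(rchisq(300, 4) / 4), n)), 300, n)
  Y[1:20, 13:24] <- Y[1:20, 13:24] + 1
  dimnames(Y) <- list(sprintf("g%03d", 1:300), sprintf("S%02d", 1:n))
  annot <- .de_annot(n)
  de <- fit_de(Y, annot)

  design <- model.matrix(~ genotype + sex,
                         data = transform(annot,
                                          genotype = factor(genotype,
                                                            c("APP-", "APP+"))))
  fit <- limma::eBayes(limma::lmFit(Y, design))
  expect_equal(de$logFC, unname(fit$coefficients[, 2]), tolerance = 1e-9)
  expect_equal(de$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(de$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
  expect_equal(attr(de, "df_prior"), unname(fit$df.prior), tolerance = 1e-4)
  expect_equal(attr(de, "s2_prior"), unname(fit$s2.prior), tolerance = 1e-4)
})

test_that("swapping genotype labels flips logFC and keeps p-values", {
  set.seed(63)
  Y <- matrix(rnorm(100 * 12, 8), 100, 12,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("S%02d", 1:12)))
  annot <- .de_annot(12)
  sw <- annot
  sw$genotype <- ifelse(annot$genotype == "APP+", "APP-", "APP+")
  a <- fit_de(Y, annot)
  b <- fit_de(Y, sw)
  expect_equal(a$logFC, -b$logFC, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  # BH monotonicity: q-ordering preserves p-ordering
  expect_equal(order(a$q, a$p), order(a$p))
  expect_true(all(a$q >= a$p))
})

test_that("a rank-deficient design errors naming the confounded column", {
  set.seed(64)
  Y <- matrix(rnorm(40), 10, 4,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("S%02d", 1:4)))
  annot <- .de_annot(4, sex = c("F", "F", "M", "M"))  # sex == genotype
  expect_error(fit_de(Y, annot), "sex")
})

test_that("unit sample filtering applies the median and whisker rules", {
  set.seed(65)
  n <- 20
  base <- matrix(rnorm(200 * n, 4, 0.3), 200, n,
                 dimnames = list(sprintf("g%03d", 1:200), sprintf("S%02d", 1:n)))
  # rescale columns to controlled linear medians: 15 (dropped, log2 < 4),
  # exactly 16 (log2(median) == 4, retained by the strict inequality), and
  # comparable values just above the gate for the remaining segments
  targets <- c(15, 16, round(runif(n - 2, 16.5, 19), 1))
  for (j in seq_len(n)) {
    lin <- 2^base[, j] - 1
    base[, j] <- log2(lin * (targets[j] / median(lin)) + 1)
  }
  out <- filter_unit_samples(base, min_log2_median = 4)
  expect_false("S01" %in% colnames(out$matrix))
  expect_true("S02" %in% colnames(out$matrix))
  expect_true(any(out$log$segment == "S01" & out$log$stage == "median"))

  # displaced segment flagged by the PC whiskers, matching brute force
  m2 <- matrix(rnorm(100 * n, 8, 0.5), 100, n,
               dimnames = list(sprintf("g%03d", 1:100), sprintf("S%02d", 1:n)))
  pc1_dir <- rnorm(100); pc1_dir <- pc1_dir / sqrt(sum(pc1_dir^2))
  m2[, 5] <- m2[, 5] + 10 * pc1_dir      # ~10 SD along one axis
  out2 <- filter_unit_samples(m2, min_log2_median = 0)
  pc <- prcomp(t(m2), center = TRUE)
  flags <- rep(FALSE, n)
  for (k in 1:2) {
    v <- pc$x[, k]; qs <- quantile(v, c(0.25, 0.75)); iqr <- diff(qs)
    flags <- flags | v < qs[1] - 1.5 * iqr | v > qs[2] + 1.5 * iqr
  }
  expect_equal(setdiff(colnames(m2), colnames(out2$matrix)),
               colnames(m2)[flags])
  expect_true("S05" %in% out2$log$segment)

  expect_error(filter_unit_samples(m2[, 1:3]), ">= 4 segments")
})

test_that("DE classification applies strict gates and exhaustive counts", {
  de <- data.frame(gene = paste0("g", 1:6),
                   logFC = c(0.3, 0.25, -0.3, -0.2, 1, 0.4),
                   t = 1:6,
                   p = c(0.04, 0.04, 0.04, 0.01, 0.2, 0.049),
                   q = c(0.1, 0.1, 0.1, 0.05, 0.3, 0.12))
  class(de) <- c("nvu_de", "data.frame")
  out <- classify_de(de, p_cut = 0.05, lfc_cut = 0.25)
  expect_equal(out$up, c("g1", "g6"))          # g2 at the boundary is ns
  expect_equal(out$down, "g3")                 # g4 below the lfc gate
  expect_equal(unname(out$counts["significant"]), 5L)
  expect_equal(unname(out$counts["up"] + out$counts["down"]), 3L)
  # brute force
  manual_up <- with(de, gene[p < 0.05 & logFC > 0.25])
  expect_equal(out$up, manual_up)
  # q-gated variant
  outq <- classify_de(de, p_cut = 0.05, lfc_cut = 0.25, use_q = TRUE)
  expect_equal(outq$down, "g4"[de$q[4] < 0.05 & de$logFC[4] < -0.25])
})

test_that("diffusion embedding separates two correlation blocks", {
  set.seed(66)
  n_half <- 5; p <- 60
  f1 <- rnorm(p); f2 <- rnorm(p)
  mk <- function(f) t(replicate(n_half, f * 3 + rnorm(p)))
  X <- rbind(mk(f1), mk(f2))
  rownames(X) <- sprintf("S%02d", 1:10)
  emb <- lafon_embedding(X, t_steps = 1)
  s <- sign(emb$phi[, 1])
  expect_true(all(s[1:5] == s[1]) && all(s[6:10] == -s[1]))
  expect_true(all(diff(emb$eigenvalues) <= 1e-12))
  expect_true(all(emb$eigenvalues <= 1 + 1e-9))

  # independent dense-eigensolver oracle on the same affinity matrix
  rho <- cor(t(X), method = "spearman")
  K <- (1 + rho) / 2
  d <- rowSums(K); K1 <- K / outer(d, d); d2 <- rowSums(K1)
  M <- K1 / d2                        # row-stochastic Markov operator
  eg <- eigen(M)
  lam <- Re(eg$values)
  expect_equal(sort(emb$eigenvalues, decreasing = TRUE),
               sort(lam[lam > 1e-10 & abs(lam - 1) > 1e-10],
                    decreasing = TRUE)[seq_along(emb$eigenvalues)],
               tolerance = 1e-8)
})

test_that("degenerate samples are handled per contract", {
  X <- matrix(rnorm(30), 3, 10,
              dimnames = list(c("A", "B", "C"), paste0("g", 1:10)))
  X[2, ] <- 5                         # constant sample: Spearman undefined
  expect_error(lafon_embedding(X), "B")

  same <- matrix(rep(rnorm(10), each = 4), 4, 10,
                 dimnames = list(paste0("S", 1:4), paste0("g", 1:10)))
  expect_warning(emb <- lafon_embedding(same), "empty")
  expect_equal(ncol(emb$phi), 0)
})
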