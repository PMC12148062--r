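test_that("the rank-based score matches hand-worked examples", {
  v <- c(a = 50, b = 40, c = 30, d = 20, e = 10)
  # signature = the n top-ranked genes -> U = 0, score 1
  expect_equal(ucell_score(v, c("a", "b"), r_max = 5), 1)
  # 1-gene signature at rank 3, r_max 5: U = 2, score 1 - 2/5
  expect_equal(ucell_score(v, "c", r_max = 5), 0.6)
  # a signature gene beyond r_max scores at the truncation floor
  v2 <- setNames(seq(100, 1, length.out = 100), paste0("g", 1:100))
  expect_equal(ucell_score(v2, "g100", r_max = 5), 0)
  # multi-gene truncated signatures sit at the formula's (n-1)/(2 r_max)
  expect_equal(ucell_score(v2, c("g99", "g100"), r_max = 5), 1 / 10)
  # empty intersection is flagged missing, not zero
  expect_true(is.na(ucell_score(v, "zz", r_max = 5)))
  expect_error(ucell_score(v, c("a", "b", "c"), r_max = 2), "r_max")
})

test_that("the score depends on ranks only (monotone invariance)", {
  set.seed(31)
  v <- setNames(rexp(200), paste0("g", 1:200))
  sig <- sample(names(v), 8)
  s1 <- ucell_score(v, sig, r_max = 150)
  expect_equal(ucell_score(log1p(v), sig, r_max = 150), s1)
  expect_equal(ucell_score(v^3, sig, r_max = 150), s1)
  expect_equal(ucell_score(rank(v) * 2, sig, r_max = 150), s1)
})

test_that("random signatures on shuffled data score near one half", {
  set.seed(32)
  n_genes <- 1500
  scores <- replicate(500, {
    v <- setNames(sample(n_genes), paste0("g", seq_len(n_genes)))
    ucell_score(v, sample(names(v), 5), r_max = 1500)
  })
  expect_gt(mean(scores), 0.4)
  expect_lt(mean(scores), 0.6)
})

test_that("per-cluster scoring identifies each type by its own markers", {
  ref <- small_ref()
  scores <- score_cell_types(ref$sc, ref$signatures, r_max = 300)
  expect_equal(dim(scores), c(3, 3))
  for (u in rownames(scores))
    expect_equal(names(which.max(scores[u, ])), u)

  # permutation invariance of the cluster means
  sc <- ref$sc
  perm <- sample(nrow(sc$counts))
  sc_p <- nvu_sc(sc$counts[perm, ], cluster = sc$cluster[perm],
                 animal = sc$animal[perm])
  expect_equal(score_cell_types(sc_p, ref$signatures, r_max = 300),
               scores, ignore_attr = TRUE)

  # one cell per cluster: aggregation is the identity
  idx <- match(unique(sc$cluster), sc$cluster)
  sc_1 <- nvu_sc(sc$counts[idx, ], cluster = sc$cluster[idx],
                 animal = sc$animal[idx])
  per_cell <- score_cell_types(sc_1, ref$signatures, r_max = 300)
  expect_equal(rownames(per_cell), sort(unique(sc$cluster)))
})

test_that("consolidation drops small clusters and cuts deterministically", {
  set.seed(33)
  scores <- rbind(small = runif(3), big = runif(3))
  colnames(scores) <- paste0("sig", 1:3)
  out <- consolidate_types(scores, cluster_sizes = c(small = 50, big = 500),
                           min_cells = 100, k_units = 1)
  expect_equal(out$dropped$cluster, "small")
  expect_equal(out$dropped$reason, "under-represented")
  expect_equal(out$mapping$cluster, "big")

  # a cluster of exactly min_cells cells does not survive
  out2 <- consolidate_types(scores, cluster_sizes = c(small = 100, big = 500),
                            min_cells = 100, k_units = 1)
  expect_true("small" %in% out2$dropped$cluster)

  expect_error(consolidate_types(scores,
                                 cluster_sizes = c(small = 500, big = 500),
                                 min_cells = 100, k_units = 3),
               "exceeds retained clusters")
})

test_that("identical score rows share a unit at any cut", {
  scores <- rbind(a = c(0.9, 0.1, 0.2), b = c(0.9, 0.1, 0.2),
                  c = c(0.1, 0.8, 0.3), d = c(0.2, 0.2, 0.9))
  colnames(scores) <- paste0("sig", 1:3)
  sizes <- setNames(rep(500, 4), rownames(scores))
  for (k in 1:3) {
    out <- consolidate_types(scores, sizes, min_cells = 100, k_units = k)
    map <- setNames(out$mapping$unit, out$mapping$cluster)
    expect_equal(map[["a"]], map[["b"]], info = paste("k =", k))
  }
})

test_that("a 14-cluster fixture built from 6 latent profiles is recovered", {
  set.seed(34)
  latent <- matrix(runif(6 * 5), 6, 5)
  assign <- rep(1:6, length.out = 14)
  scores <- latent[assign, ] + matrix(rnorm(14 * 5, sd = 0.01), 14, 5)
  rownames(scores) <- sprintf("cl%02d", 1:14)
  colnames(scores) <- paste0("sig", 1:5)
  sizes <- setNames(rep(1000, 14), rownames(scores))
  out <- consolidate_types(scores, sizes, min_cells = 100, k_units = 6)
  grp <- setNames(out$mapping$unit, out$mapping$cluster)
  # same latent profile -> same unit; different -> different
  for (i in 1:13) for (j in (i + 1):14) {
    same <- assign[i] == assign[j]
    expect_equal(grp[[rownames(scores)[i]]] == grp[[rownames(scores)[j]]],
                 same)
  }
  # manual override can relabel or drop
  man <- consolidate_types(scores, sizes, min_cells = 100, k_units = 6,
                           manual = c(cl01 = NA, cl02 = "Custom"))
  expect_true("cl01" %in% man$dropped$cluster)
  expect_equal(man$dropped$reason[man$dropped$cluster == "cl01"], "manual")
  expect_equal(man$mapping$unit[man$mapping$cluster == "cl02"], "Custom")
})
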