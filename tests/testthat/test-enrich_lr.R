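test_that("the over-representation test matches known hypergeometric values", {
  uni <- paste0("g", 1:10)
  row <- ora_test(uni[1:5], uni[1:5], uni)
  expect_equal(row$p, 1 / choose(10, 5))
  expect_equal(row$overlap, 5)

  # overlap at its independence expectation on a symmetric table -> p > 0.5
  uni2 <- paste0("g", 1:20)
  row2 <- ora_test(uni2[1:10], uni2[c(1:5, 11:15)], uni2)
  expect_gt(row2$p, 0.5)

  # zero overlap: p at the far tail, odds ratio corrected and finite
  row3 <- ora_test(uni2[1:5], uni2[6:10], uni2)
  expect_equal(row3$overlap, 0)
  expect_true(is.finite(row3$odds_ratio))
  expect_gt(row3$p, 0.9)

  expect_error(ora_test("a", "a", character(0)), "empty universe")
})

test_that("the hypergeometric tail equals exhaustive enumeration", {
  for (N in c(6, 9, 12)) {
    uni <- paste0("g", seq_len(N))
    for (set_n in c(2, 4)) for (list_n in c(2, 5)) {
      gene_set <- uni[seq_len(set_n)]
      de <- uni[N - seq_len(list_n) + 1]
      a <- length(intersect(de, gene_set))
      # enumerate: P(overlap >= a) over all C(N, list_n) draws
      draws <- combn(N, list_n)
      hits <- colSums(matrix(draws %in% seq_len(set_n), nrow = list_n))
      want <- mean(hits >= a)
      expect_equal(ora_test(de, gene_set, uni)$p, want, tolerance = 1e-12,
                   info = sprintf("N=%d set=%d list=%d", N, set_n, list_n))
    }
  }
})

test_that("collection-level ORA orders by p and applies BH", {
  set.seed(71)
  uni <- paste0("g", 1:50)
  gsc <- list(name = "toy",
              sets = list(A = uni[1:10], B = uni[41:50], C = uni[11:25]))
  res <- ora_collection(uni[1:12], gsc, uni)
  expect_equal(nrow(res), 3)
  expect_equal(res$q, p.adjust(res$p, "BH"), tolerance = 1e-12)
  expect_true(!is.unsorted(res$p))
  expect_equal(res$set[1], "A")
})

# scaffolding for network tests: two units, controlled DE and correlations
.net_fixture <- function(rho_ab = 0.9) {
  segs <- sprintf("S%02d", 1:30)
  set.seed(72)
  f <- rnorm(30)
  lig_src <- 5 + f                      # ligand tracks the shared factor
  rec_tgt <- 5 + rho_ab * f + sqrt(1 - rho_ab^2) * rnorm(30)
  arr <- array(rnorm(30 * 3 * 2, 5, 1), c(30, 3, 2),
               dimnames = list(segs, c("L", "R", "x"), c("src", "tgt")))
  arr[, "L", "src"] <- lig_src
  arr[, "R", "tgt"] <- rec_tgt
  cts <- manual_ctexpr(arr)
  de_up <- function(genes) {
    d <- data.frame(gene = c("L", "R", "x"), logFC = 0, t = 0, p = 1, q = 1)
    d$logFC[d$gene %in% genes] <- 1
    d$p[d$gene %in% genes] <- 0.001
    class(d) <- c("nvu_de", "data.frame")
    d
  }
  list(cts = cts, de_up = de_up)
}

test_that("network edges require both up-gates and the correlation gate", {
  fx <- .net_fixture()
  pairs <- data.frame(ligand = "L", receptor = "R")
  # ligand up in src, receptor up in tgt -> one directed edge
  de <- list(src = fx$de_up("L"), tgt = fx$de_up("R"))
  net <- build_lr_network(de, fx$cts, pairs, rho_min = 0.35)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$source, "src")
  expect_equal(net$edges$target, "tgt")
  expect_equal(net$tally["src", "tgt"], 1L)

  # no up-regulated ligand anywhere -> empty network
  de0 <- list(src = fx$de_up(character(0)), tgt = fx$de_up("R"))
  expect_equal(nrow(build_lr_network(de0, fx$cts, pairs)$edges), 0)

  # directionality: roles reversed do not create the forward edge
  de_rev <- list(src = fx$de_up("R"), tgt = fx$de_up("L"))
  net_rev <- build_lr_network(de_rev, fx$cts, pairs, rho_min = 0.35)
  expect_equal(nrow(net_rev$edges), 0)

  # genes absent from the purified matrix are skipped, not errors
  pairs2 <- rbind(pairs, data.frame(ligand = "Zz", receptor = "R"))
  net2 <- build_lr_network(de, fx$cts, pairs2)
  expect_equal(nrow(net2$skipped), 1)
  expect_equal(net2$skipped$ligand, "Zz")
})

test_that("the correlation gate is strictly greater-than", {
  segs <- sprintf("S%02d", 1:8)
  arr <- array(5, c(8, 2, 2),
               dimnames = list(segs, c("L", "R"), c("src", "tgt")))
  # construct vectors whose Spearman correlation is exactly 0.35 is awkward;
  # instead check the boundary through the gate itself on rho = 1 and the
  # threshold set to 1 (edge requires rho > 1: impossible)
  x <- 1:8
  arr[, "L", "src"] <- x
  arr[, "R", "tgt"] <- x                # rho exactly 1
  cts <- manual_ctexpr(arr)
  d <- data.frame(gene = c("L", "R"), logFC = 1, t = 1, p = 0.001, q = 0.01)
  class(d) <- c("nvu_de", "data.frame")
  de <- list(src = d, tgt = d)
  pairs <- data.frame(ligand = "L", receptor = "R")
  expect_equal(nrow(build_lr_network(de, cts, pairs, rho_min = 1)$edges), 0)
  expect_gt(nrow(build_lr_network(de, cts, pairs, rho_min = 0.999)$edges), 0)
})

test_that("chord export restricts to the focus unit and orders by tally", {
  fx <- .net_fixture()
  pairs <- data.frame(ligand = c("L", "L"), receptor = c("R", "x"))
  de <- list(src = fx$de_up(c("L")), tgt = fx$de_up(c("R", "x")))
  # make x in tgt correlate with L too
  fx$cts$expr[, "x", "tgt"] <- fx$cts$expr[, "L", "src"] + rnorm(30, 0, 0.1)
  net <- build_lr_network(de, fx$cts, pairs, rho_min = 0.35)
  tab <- export_chord_data(net, "src")
  expect_equal(nrow(tab), sum(net$edges$source == "src" |
                                net$edges$target == "src"))
  expect_true(all(diff(tab$tally) <= 0))
  # row count equals the sum of tallies on matching edges
  touching <- net$tally["src", ] + net$tally[, "src"]
  touching["src"] <- net$tally["src", "src"]
  expect_equal(nrow(tab), sum(net$tally["src", ]) + sum(net$tally[, "src"]) -
                 net$tally["src", "src"])
  expect_error(export_chord_data(net, "nope"), "unknown unit")
  empty <- build_lr_network(list(src = fx$de_up(character(0)),
                                 tgt = fx$de_up(character(0))),
                            fx$cts, pairs)
  expect_equal(nrow(export_chord_data(empty, "src")), 0)
})
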