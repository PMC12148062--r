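# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

# full-size synthetic reference (the default study conditions), cached
fixture_ref <- function() {
  if (is.null(.fixture_env$ref))
    .fixture_env$ref <- generate_reference_scrna(seed = 1)
  .fixture_env$ref
}

# default ROI dataset at seed 1, cached
fixture_sim <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- generate_roi_dataset(fixture_ref(), seed = 1)
  .fixture_env$sim
}

# reduced-scale reference for fast unit tests
small_ref <- function(seed = 3) {
  generate_reference_scrna(n_types = 3, cells_per_type = 40, n_genes = 300,
                           markers_per_type = 10, enriched_per_type = 10,
                           seed = seed)
}

# a tiny expression object with negative probes
tiny_expr <- function() {
  m <- rbind(
    g1 = c(10, 20, 30, 40),
    g2 = c(5, 5, 5, 5),
    g3 = c(100, 80, 60, 40),
    `NegProbe-A` = c(4, 4, 4, 4),
    `NegProbe-B` = c(2, 8, 4, 4),
    `NegProbe-C` = c(8, 2, 4, 4))
  colnames(m) <- paste0("S", 1:4)
  nvu_expr(m, negative = startsWith(rownames(m), "NegProbe"), stage = "raw")
}

tiny_annot <- function(n = 4) {
  data.frame(segment_id = paste0("S", seq_len(n)),
             roi_id = paste0("R", seq_len(n)),
             mouse_id = paste0("m", rep(1:2, length.out = n)),
             genotype = rep(c("APP-", "APP+"), each = ceiling(n / 2))[seq_len(n)],
             sex = rep(c("F", "M"), length.out = n),
             stringsAsFactors = FALSE)
}

# hand-built cell-type expression set for filter/network tests
manual_ctexpr <- function(expr_array, valid = NULL) {
  if (is.null(valid))
    valid <- matrix(TRUE, dim(expr_array)[1], dim(expr_array)[3],
                    dimnames = dimnames(expr_array)[c(1, 3)])
  structure(list(expr = expr_array, valid = valid), class = "nvu_ctexpr")
}

expect_simplex <- function(m, tol = 1e-9) {
  expect_true(all(m >= -tol))
  expect_true(all(abs(rowSums(m) - 1) < tol))
}
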