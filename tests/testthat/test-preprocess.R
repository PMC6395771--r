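make_counts <- function(values, n_genes, n_samples) {
  matrix(values, n_genes, n_samples,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

test_that("compute_cpm scales by library size", {
  counts <- make_counts(c(30, 999970, 500000, 500000), 2, 2)
  cpm <- compute_cpm(counts)
  expect_equal(colSums(cpm), c(s01 = 1e6, s02 = 1e6))
  expect_equal(cpm["g001", "s01"], 30)     # unit-size library: CPM == counts
  counts2 <- make_counts(c(30, 1e7 - 30), 2, 1)
  expect_equal(compute_cpm(counts2)["g001", 1], 3)
  counts3 <- counts
  counts3[, 1] <- 0
  expect_error(compute_cpm(counts3), "s01")
})

test_that("filter_expressed applies the group-wise CPM rule", {
  # gene passing in 100% of cases only, gene failing everywhere
  counts <- rbind(
    g1 = c(4, 4, 0, 0),
    g2 = c(2, 2, 2, 2),
    g3 = c(1e5, 1e5, 1e5, 1e5)
  )
  colnames(counts) <- c("c1", "c2", "k1", "k2")
  counts["g3", ] <- 1e7 - colSums(counts[c("g1", "g2"), ])
  meta <- tibble::tibble(sample_id = colnames(counts),
                         group = c("case", "case", "control", "control"))
  # CPM: g1 = 0.4 in cases, 0 in controls; g2 = 0.2 everywhere
  res <- filter_expressed(counts, meta, min_cpm = 0.3, min_frac = 0.5)
  expect_true("g1" %in% res$kept_genes)
  expect_false("g2" %in% res$kept_genes)

  all_kept <- filter_expressed(counts, meta, min_cpm = 0)
  expect_equal(all_kept$n_after, 3)

  bad_meta <- meta
  bad_meta$group <- "case"
  expect_error(filter_expressed(counts, bad_meta), "control")
})

test_that("filter_expressed is monotone in the CPM threshold", {
  sim <- small_cohort(seed = 13, n_genes = 200)
  meta <- sim$metadata
  kept_loose <- filter_expressed(sim$counts, meta, min_cpm = 0.1)$kept_genes
  kept_tight <- filter_expressed(sim$counts, meta, min_cpm = 5)$kept_genes
  expect_true(all(kept_tight %in% kept_loose))
})

test_that("normalize_log equals log2(CPM + 0.5) for identical columns and is
          invariant to rescaling one sample", {
  counts <- make_counts(rep(c(100, 300, 600), 3), 3, 3)
  norm <- normalize_log(counts)
  expect_equal(unname(norm$size_factors), rep(1, 3))
  expect_equal(norm$values, log2(compute_cpm(counts) + 0.5))

  sim <- small_cohort(seed = 14, n_genes = 150)
  counts2 <- sim$counts
  doubled <- counts2
  doubled[, 3] <- doubled[, 3] * 2
  a <- normalize_log(counts2)$values
  b <- normalize_log(doubled)$values
  expect_equal(b, a, tolerance = 1e-10)

  counts3 <- counts
  counts3[1, ] <- 0
  v <- normalize_log(counts3)$values
  expect_equal(unname(diff(range(v[1, ]))), 0)  # all-zero gene is a flat row
})

test_that("parallel analysis keeps no surrogate variables on pure noise", {
  set.seed(2)
  expr <- matrix(rnorm(2000 * 30), 2000, 30,
                 dimnames = list(sprintf("g%04d", 1:2000),
                                 sprintf("s%02d", 1:30)))
  meta <- tibble::tibble(sample_id = colnames(expr),
                         group = rep(c("case", "control"), 15))
  sv <- estimate_surrogate_variables(expr, meta, seed = 2)
  expect_equal(ncol(sv), 0)

  # and a forced k = 0 gives the same empty matrix
  sv0 <- estimate_surrogate_variables(expr, meta, n_sv = 0, seed = 2)
  expect_equal(dim(sv0), c(30, 0))
})

test_that("a planted batch shift is captured by the top surrogate variable", {
  design <- synthetic_design(n_genes = 2000, n_case = 15, n_control = 15,
                             batch_levels = 2,
                             batch_effect_sd = log(2),   # 1 log2 unit
                             dispersion = 0.05, seed = 9)
  sim <- simulate_dataset(design)
  expr <- normalize_log(filter_expressed(sim$counts, sim$metadata)$counts)$values
  sv <- estimate_surrogate_variables(expr, sim$metadata, primary = "group",
                                     seed = 3)
  expect_gte(ncol(sv), 1)
  batch <- as.numeric(sim$truth$batch[colnames(expr)] == 1)
  expect_gt(abs(cor(sv[, 1], batch)), 0.8)
  # near-orthogonal to the primary contrast
  grp <- as.numeric(sim$metadata$group == "case")
  expect_lt(abs(cor(sv[, 1], grp)), 0.3)
})

test_that("surrogate-variable estimation rejects rank-deficient designs", {
  set.seed(3)
  expr <- matrix(rnorm(100 * 10), 100, 10,
                 dimnames = list(sprintf("g%03d", 1:100),
                                 sprintf("s%02d", 1:10)))
  meta <- tibble::tibble(sample_id = colnames(expr),
                         group = rep(c("case", "control"), 5),
                         copy = rep(c("case", "control"), 5))
  expect_error(
    estimate_surrogate_variables(expr, meta, adjust = "copy", seed = 1),
    "rank deficient"
  )
})

test_that("sample weights flag noisy samples and sit near 1 otherwise", {
  set.seed(4)
  expr <- matrix(rnorm(2000 * 30), 2000, 30,
                 dimnames = list(sprintf("g%04d", 1:2000),
                                 sprintf("s%02d", 1:30)))
  X <- stats::model.matrix(~rep(c(0, 1), 15))
  w <- estimate_sample_weights(expr, X)
  expect_true(all(w >= 0.8 & w <= 1.25))
  expect_equal(exp(mean(log(w))), 1, tolerance = 1e-12)

  noisy <- expr
  noisy[, 7] <- noisy[, 7] * 2             # 4x residual variance
  w2 <- estimate_sample_weights(noisy, X)
  expect_equal(unname(which.min(w2)), 7)
  expect_lt(w2[7], 1)

  # identical samples in a single design cell: zero residuals, weights 1
  same <- matrix(rep(rnorm(50), 4), 50, 4,
                 dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:4)))
  expect_equal(unname(estimate_sample_weights(same, matrix(1, 4, 1))),
               rep(1, 4))

  expect_error(estimate_sample_weights(expr[, 1:3], diag(4)[1:3, ]),
               "fewer samples")
})

test_that("weight-distribution comparison is an exact two-sample KS", {
  w <- c(0.9, 1, 1.1, 1.2)
  res <- compare_weight_distributions(w, w)
  expect_equal(res$ks_statistic, 0)
  expect_equal(res$p, 1)
  expect_equal(compare_weight_distributions(1:4, 11:14)$ks_statistic, 1)

  # brute-force ECDF oracle on random vectors
  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(7)
    b <- rnorm(9, 0.5)
    grid <- sort(c(a, b))
    d_oracle <- max(abs(vapply(grid, function(t) mean(a <= t) - mean(b <= t),
                               numeric(1))))
    expect_equal(compare_weight_distributions(a, b)$ks_statistic, d_oracle,
                 tolerance = 1e-12)
  }
})
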