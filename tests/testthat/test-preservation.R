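test_that("reference modules are mapped onto the shared gene universe", {
  sim <- small_cohort(seed = 33, n_genes = 150, n = 8, module_sizes = c(40),
                      loading = 0.8, disrupted = NULL, n_deg = 0)
  sp <- split_expression(sim)
  labels <- setNames(rep(c(1L, 0L), c(40, nrow(sp$control) - 40)),
                     rownames(sp$control))
  m1 <- map_reference_modules(labels, sp$case)
  expect_identical(m1$labels, labels)
  expect_length(m1$dropped_genes, 0)

  m2 <- map_reference_modules(labels, sp$case[-(1:10), ])
  expect_equal(m2$dropped_genes, rownames(sp$control)[1:10])
  expect_equal(sum(m2$labels == 1), 30)

  other <- sp$case
  rownames(other) <- paste0("x", rownames(other))
  expect_error(map_reference_modules(labels, other), "overlap")
})

test_that("observed statistics are exact on self-comparison and see disruption", {
  sim <- small_cohort(seed = 34, n_genes = 300, n = 20, module_sizes = 100,
                      loading = 0.8, disrupted = 1, n_deg = 0)
  sp <- split_expression(sim)
  labels <- sim$truth$module_membership[rownames(sp$control)]

  self <- observed_stats(sp$control, sp$control, labels, beta = 6)
  for (s in c("cor_kim", "cor_kme", "cor_cor")) {
    expect_equal(self$observed[self$stat == s], 1, tolerance = 1e-10)
  }

  ref_density <- observed_stats(sp$control, sp$control, labels, beta = 6)
  test_density <- observed_stats(sp$control, sp$case, labels, beta = 6)
  expect_gte(ref_density$observed[ref_density$stat == "mean_cor"], 0.4)
  expect_lte(test_density$observed[test_density$stat == "mean_cor"], 0.1)

  tiny <- labels
  tiny[] <- 0L
  tiny[1:2] <- 1L
  flagged <- observed_stats(sp$control, sp$case, tiny, beta = 6)
  expect_true(all(!flagged$defined))
})

test_that("permutation Z-scores are seeded and calibrated on random modules", {
  sim <- small_cohort(seed = 35, n_genes = 250, n = 12, module_sizes = 50,
                      loading = 0.85, disrupted = NULL, n_deg = 0)
  sp <- split_expression(sim)
  labels <- sim$truth$module_membership[rownames(sp$control)]

  z1 <- permutation_null(sp$control, sp$case, labels, beta = 6,
                         n_perm = 30, seed = 5)
  z2 <- permutation_null(sp$control, sp$case, labels, beta = 6,
                         n_perm = 30, seed = 5)
  expect_identical(z1, z2)
  expect_error(permutation_null(sp$control, sp$case, labels, beta = 6,
                                n_perm = 10), "at least 20")

  # a random 'module' in both datasets has |Z| mostly within 2
  zs <- unlist(lapply(1:10, function(s) {
    simn <- small_cohort(seed = 100 + s, n_genes = 150, n = 12,
                         module_sizes = integer(0), loading = numeric(0),
                         disrupted = NULL, n_deg = 0)
    spn <- split_expression(simn)
    lab <- setNames(rep(0L, nrow(spn$control)), rownames(spn$control))
    lab[seq_len(40)] <- 1L
    z <- permutation_null(spn$control, spn$case, lab, beta = 6,
                          n_perm = 50, seed = s)
    z$z[z$defined]
  }))
  expect_gte(mean(abs(zs) <= 2, na.rm = TRUE), 0.9)
})

test_that("Zsummary and medianRank summarize the Z table as specified", {
  mk_row <- function(module, stat, observed, z) {
    tibble::tibble(module = module, size = 50, stat = stat,
                   observed = observed, defined = TRUE,
                   perm_mean = 0, perm_sd = 1, z = z)
  }
  stats <- c("mean_cor", "mean_adj", "prop_var_explained", "mean_signed_kme",
             "cor_kim", "cor_kme", "cor_cor")
  # module 1 dominates every statistic; module 3 is worst everywhere
  ztab <- dplyr::bind_rows(
    mk_row(1L, stats, observed = c(0.9, 0.8, 0.9, 0.9, 0.9, 0.9, 0.9), z = 5),
    mk_row(2L, stats, observed = c(0.5, 0.4, 0.5, 0.5, 0.5, 0.5, 0.5), z = 3),
    mk_row(3L, stats, observed = c(0.1, 0.05, 0.1, 0.1, 0.1, 0.1, 0.1), z = 1)
  )
  s <- summarize_preservation(ztab)
  expect_equal(s$median_rank, c(1, 2, 3))
  expect_equal(s$zsummary, c(5, 3, 1))          # constant Z per module

  # ties across modules get equal average ranks
  ztie <- dplyr::bind_rows(mk_row(1L, stats, 0.5, 2), mk_row(2L, stats, 0.5, 2))
  stie <- summarize_preservation(ztie)
  expect_equal(stie$median_rank, c(1.5, 1.5))

  # medianRank is invariant to monotone rescaling of one statistic
  zresc <- ztab
  idx <- zresc$stat == "mean_adj"
  zresc$observed[idx] <- exp(10 * zresc$observed[idx])
  expect_equal(summarize_preservation(zresc)$median_rank, s$median_rank)

  expect_warning(summarize_preservation(mk_row(1L, stats, 0.5, 2)),
                 "degenerate")
})

test_that("module kME correlation has the expected limits", {
  set.seed(36)
  k <- setNames(runif(500, -1, 1), paste0("g", 1:500))
  expect_equal(module_kme_correlation(k, k)$r, 1)
  expect_equal(module_kme_correlation(k, -k)$r, -1)
  noise <- setNames(runif(500, -1, 1), names(k))
  expect_lt(abs(module_kme_correlation(k, noise)$r), 0.15)
  expect_error(module_kme_correlation(k[1:2], k[1:2]), "3")
})

test_that("least-preserved selection follows the agreement and tie-break rules", {
  # synthetic preservation object; helper builds kME pairs with target cor
  set.seed(37)
  base <- rnorm(60)
  pair_with_cor <- function(r) {
    y <- r * base + sqrt(1 - r^2) * rnorm(60)
    genes <- paste0("g", 1:60)
    list(ref = setNames(base, genes), test = setNames(y, genes))
  }
  mk_pres <- function(zsummary, median_rank, kme_rs) {
    stats <- tibble::tibble(
      module = seq_along(zsummary), size = 60,
      z_density = zsummary, z_connectivity = zsummary,
      zsummary = zsummary, median_rank = median_rank
    )
    kme <- lapply(kme_rs, pair_with_cor)
    names(kme) <- as.character(seq_along(kme_rs))
    structure(list(stats = stats, kme = kme, n_perm = 50, beta = 6),
              class = "module_preservation")
  }

  # agreement: module 3 lowest Zsummary and highest medianRank
  agree <- mk_pres(zsummary = c(12, 9, 1), median_rank = c(1, 2, 3),
                   kme_rs = c(0.9, 0.8, 0.1))
  sel <- select_least_preserved(agree)
  expect_equal(sel$module, 3L)
  expect_false(sel$tie_break)

  # disagreement: pick the candidate with the most neutral kME correlation
  dis <- mk_pres(zsummary = c(1, 9, 12), median_rank = c(1, 2, 3),
                 kme_rs = c(0.90, 0.50, -0.05))
  sel2 <- select_least_preserved(dis)
  expect_true(sel2$tie_break)
  r_oracle <- vapply(dis$kme, function(km) {
    unname(cor(km$ref, km$test))
  }, numeric(1))
  expect_equal(sel2$module,
               as.integer(names(r_oracle)[which.min(abs(r_oracle))]))
  expect_equal(sort(sel2$candidates$module), 1:3)
})

test_that("self-comparison preserves modules at least as well as disruption", {
  for (s in 1:5) {
    sim <- small_cohort(seed = 200 + s, n_genes = 200, n = 12,
                        module_sizes = 60, loading = 0.8, disrupted = 1,
                        n_deg = 0)
    sp <- split_expression(sim)
    labels <- sim$truth$module_membership[rownames(sp$control)]
    # single planted module: the medianRank degeneracy warning is expected
    pres_self <- suppressWarnings(
      module_preservation(sp$control, sp$control, labels, beta = 6,
                          n_perm = 40, seed = s)
    )
    pres_dis <- suppressWarnings(
      module_preservation(sp$control, sp$case, labels, beta = 6,
                          n_perm = 40, seed = s)
    )
    expect_gte(pres_self$stats$zsummary[1], pres_dis$stats$zsummary[1])
  }
})
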