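test_that("correlation matrix handles self, anti-correlation and missingness", {
  set.seed(11)
  x <- rnorm(20)
  expr <- rbind(g1 = x, g2 = -x, g3 = rnorm(20), g4 = rep(1, 20))
  colnames(expr) <- sprintf("s%02d", 1:20)
  expr["g3", 1:13] <- NA                     # 65% missing -> removed
  res <- correlation_matrix(expr)
  expect_equal(res$removed_genes, "g3")
  expect_equal(res$cor["g1", "g1"], 1)
  expect_equal(res$cor["g1", "g2"], -1)
  expect_equal(res$zero_variance_genes, "g4")
  expect_true(all(res$cor["g4", c("g1", "g2")] == 0))
})

test_that("adjacency is the |cor|^beta power transform", {
  cm <- matrix(c(1, 0.5, 0.5, 1), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(adjacency(cm, 9)["a", "b"], 0.001953125)
  expect_equal(adjacency(cm, 1), abs(cm), ignore_attr = TRUE)
  expect_error(adjacency(cm, 0.5), "power")

  cm2 <- matrix(c(1, -1, -1, 1), 2, dimnames = dimnames(cm))
  expect_equal(adjacency(cm2, 7)["a", "b"], 1)

  # monotone decreasing in beta below |cor| = 1, order preserving at fixed beta
  set.seed(12)
  r <- sort(runif(10, 0.05, 0.95))
  for (b in c(2, 6, 12)) {
    expect_true(all(diff(r^b) > 0))
    expect_true(all(r^(b + 1) < r^b))
  }
})

test_that("TOM matches the brute-force triple loop and stays in [0, 1]", {
  # hand examples
  a0 <- diag(3); dimnames(a0) <- list(paste0("g", 1:3), paste0("g", 1:3))
  expect_equal(tom_similarity(a0), a0)

  a1 <- matrix(0.5, 3, 3); diag(a1) <- 1
  dimnames(a1) <- dimnames(a0)
  expect_equal(tom_similarity(a1)["g1", "g2"], 0.75 / 1.5)

  a2 <- diag(3); a2[1, 2] <- a2[2, 1] <- 1
  dimnames(a2) <- dimnames(a0)
  expect_equal(tom_similarity(a2)["g1", "g2"], 1)

  set.seed(13)
  for (i in 1:20) {
    a <- random_adjacency(10)
    t1 <- tom_similarity(a)
    t2 <- tom_brute_force(a)
    expect_lt(max(abs(unname(t1) - t2)), 1e-12)
    expect_true(all(t1 >= 0 & t1 <= 1 + 1e-12))
  }

  asym <- random_adjacency(4)
  asym[1, 2] <- asym[1, 2] + 0.1
  expect_error(tom_similarity(asym), "symmetric")
})

test_that("soft-threshold selection finds a scale-free power on hub-and-spoke data", {
  # hub-and-spoke latent modules of geometrically decreasing size give a
  # heavy-tailed connectivity distribution
  set.seed(15)
  n <- 60
  sizes <- c(150, 80, 40, 20, 10)
  loads <- c(0.95, 0.9, 0.85, 0.8, 0.75)
  expr <- do.call(rbind, lapply(seq_along(sizes), function(m) {
    f <- rnorm(n)
    t(sapply(seq_len(sizes[m]), function(i) {
      a <- loads[m] * runif(1, 0.6, 1)
      a * f + rnorm(n, 0, sqrt(1 - a^2))
    }))
  }))
  expr <- rbind(expr, matrix(rnorm(100 * n), 100, n))
  rownames(expr) <- sprintf("g%04d", seq_len(nrow(expr)))
  colnames(expr) <- sprintf("s%02d", seq_len(n))

  soft <- pick_soft_threshold(expr, betas = 1:12)
  expect_true(soft$reached_r2)
  row <- soft$fit_table[soft$fit_table$beta == soft$beta, ]
  expect_gte(row$r_squared, 0.8)
  expect_lt(row$slope, 0)                 # frequency falls with connectivity
  # smallest qualifying power is chosen
  expect_equal(soft$beta,
               min(soft$fit_table$beta[soft$fit_table$r_squared >= 0.8]))

  # independent recomputation of the fit index for the chosen power
  cm <- correlation_matrix(expr)$cor
  k <- rowSums(abs(cm)^soft$beta) - 1
  k <- k[k > 0]
  bin <- cut(k, breaks = 10, include.lowest = TRUE)
  freq <- tapply(k, bin, length); mk <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0
  r2_oracle <- summary(lm(log10(freq[ok]) ~ log10(mk[ok])))$r.squared
  expect_equal(row$r_squared, r2_oracle, tolerance = 1e-12)

  expect_equal(suppressWarnings(pick_soft_threshold(expr, r2_min = 0)$beta), 1)
})

test_that("module detection recovers planted blocks and handles edge cases", {
  # two blocks with perfect within-TOM and none between
  n <- 200
  tom <- matrix(0, n, n)
  tom[1:100, 1:100] <- 0.9
  tom[101:200, 101:200] <- 0.9
  diag(tom) <- 1
  dimnames(tom) <- list(paste0("g", 1:n), paste0("g", 1:n))
  part <- detect_modules(1 - tom, min_size = 50)
  expect_equal(sort(unname(part$module_sizes)), c(100, 100))
  expect_equal(length(unique(part$labels[1:100])), 1)
  expect_equal(length(unique(part$labels[101:200])), 1)
  expect_true(all(part$labels > 0))

  expect_warning(p2 <- detect_modules(1 - tom, min_size = 500), "unassigned")
  expect_true(all(p2$labels == 0))

  same <- matrix(0, 10, 10)
  dimnames(same) <- list(paste0("g", 1:10), paste0("g", 1:10))
  p3 <- detect_modules(same, min_size = 3)
  expect_true(all(p3$labels == 1))
})

test_that("module detection is equivariant under gene permutation", {
  sim <- small_cohort(seed = 16, n_genes = 250, n = 12,
                      module_sizes = c(50, 70), loading = 0.85,
                      disrupted = NULL, n_deg = 0)
  expr <- normalize_log(sim$counts)$values
  tom <- tom_similarity(adjacency(correlation_matrix(expr)$cor, 6))
  p1 <- detect_modules(1 - tom, min_size = 30)
  set.seed(17)
  perm <- sample(nrow(tom))
  p2 <- detect_modules(1 - tom[perm, perm], min_size = 30)
  expect_equal(p2$labels[names(p1$labels)], p1$labels)
})

test_that("module eigengenes summarize their module and orient positively", {
  set.seed(18)
  prof <- rnorm(30)
  expr <- rbind(
    g1 = prof, g2 = 2 * prof + 5, g3 = prof * 0.5 - 1,  # rank-1 module
    g4 = prof, g5 = -prof                               # antipodal pair
  )
  colnames(expr) <- sprintf("s%02d", 1:30)
  labels <- c(g1 = 1L, g2 = 1L, g3 = 1L, g4 = 2L, g5 = 2L)
  me <- module_eigengenes(expr, labels)
  expect_equal(me$variance_explained[["ME1"]], 1, tolerance = 1e-12)
  expect_equal(abs(cor(me$values[, "ME1"], prof)), 1, tolerance = 1e-12)
  # orientation: mean member kME is non-negative in every module
  k <- kme(expr, me$values)
  for (m in 1:2) {
    members <- names(labels)[labels == m]
    expect_gte(mean(k$values[members, paste0("ME", m)]), 0)
  }

  # a planted factor is recovered by the eigengene
  f <- rnorm(40)
  mod <- t(sapply(1:30, function(i) 0.9 * f + rnorm(40, 0, sqrt(1 - 0.81))))
  rownames(mod) <- paste0("m", 1:30)
  colnames(mod) <- paste0("s", 1:40)
  me2 <- module_eigengenes(mod, setNames(rep(1L, 30), rownames(mod)))
  expect_gt(abs(cor(me2$values[, 1], f)), 0.9)

  const <- matrix(1, 3, 5, dimnames = list(paste0("c", 1:3), paste0("s", 1:5)))
  expect_error(module_eigengenes(const, setNames(rep(1L, 3), rownames(const))),
               "constant")
})

test_that("kME is a correlation with the expected bounds", {
  set.seed(19)
  f <- rnorm(200)
  expr <- rbind(hub = f, noise = rnorm(200),
                flat = rep(2, 200))
  colnames(expr) <- paste0("s", 1:200)
  me <- matrix(f, 200, 1, dimnames = list(colnames(expr), "ME1"))
  k <- kme(expr, me)
  expect_equal(unname(k$values["hub", 1]), 1, tolerance = 1e-12)
  expect_lt(abs(k$values["noise", 1]), 0.2)
  expect_equal(k$constant_genes, "flat")
  expect_equal(unname(k$values["flat", 1]), 0)
  expect_true(all(k$values >= -1 & k$values <= 1))
})
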