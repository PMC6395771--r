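# Shared fixtures and cached heavy computations.

# tiny deterministic cohort used across module tests
small_cohort <- function(seed = 5, n_genes = 300, n = 10,
                         module_sizes = c(40, 60), loading = 0.85,
                         disrupted = 1, n_deg = 20, batch_sd = 0) {
  simulate_dataset(synthetic_design(
    n_genes = n_genes, n_case = n, n_control = n,
    module_sizes = module_sizes, module_loadings = loading,
    disrupted_module = disrupted, n_deg = n_deg, deg_log2fc = 2,
    dispersion = 0.05, batch_effect_sd = batch_sd, seed = seed
  ))
}

split_expression <- function(sim) {
  filt <- filter_expressed(sim$counts, sim$metadata)
  expr <- normalize_log(filt$counts)$values
  list(
    expr = expr,
    control = expr[, sim$metadata$sample_id[sim$metadata$group == "control"],
                   drop = FALSE],
    case = expr[, sim$metadata$sample_id[sim$metadata$group == "case"],
                drop = FALSE]
  )
}

random_adjacency <- function(n) {
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  a
}

# brute-force oracles -------------------------------------------------------

tom_brute_force <- function(a) {
  n <- nrow(a)
  out <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      ki <- sum(a[i, -i])
      kj <- sum(a[j, -j])
      out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  out
}

bh_step_up <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

hypergeom_tail <- function(k, N, K, n) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# cached disruption benchmark shared by the recovery and calibration checks
benchmark_cache <- new.env(parent = emptyenv())
get_disruption_benchmark <- function(seeds = 1:20) {
  key <- paste(seeds, collapse = ",")
  if (is.null(benchmark_cache[[key]])) {
    benchmark_cache[[key]] <- disruption_benchmark(seeds, beta = 6,
                                                   min_size = 30, n_perm = 100)
  }
  benchmark_cache[[key]]
}
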