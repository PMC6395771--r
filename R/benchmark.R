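# Simulation benchmarks: disrupted-module recovery / Zsummary calibration and
# differential-expression calibration. These encode the package's standard
# study conditions so tests, scripts and vignettes all run the same ones.

#' Standard design for the disrupted-module recovery benchmark
#'
#' 2000 genes with three planted modules (100/150/200 genes) at loading 0.8,
#' the size-150 module disrupted in cases (`break_correlation`), 20 samples
#' per group, NB dispersion 0.05, and no batch effect (the benchmark plants
#' correlation structure only).
#'
#' @param seed Integer seed.
#' @return A [synthetic_design()].
#' @export
disruption_benchmark_design <- function(seed = 1L) {
  synthetic_design(
    n_genes = 2000, n_case = 20, n_control = 20,
    module_sizes = c(100, 150, 200), module_loadings = 0.8,
    disrupted_module = 2, disruption_mode = "break_correlation",
    n_deg = 0, dispersion = 0.05, batch_effect_sd = 0,
    seed = seed
  )
}

#' Disrupted-module recovery and Zsummary calibration benchmark
#'
#' For each seed: simulate the standard design ([disruption_benchmark_design()]),
#' filter and normalize, build the control (reference) network at the given
#' power, run [module_preservation()] against the case data and
#' [select_least_preserved()]. A seed counts as *recovered* when the selected
#' module is the detected module that contains the majority of the planted
#' disrupted genes; it counts as *calibrated* when every detected module
#' carrying an intact planted module reaches Zsummary > 10 while the disrupted
#' one falls below 2.
#'
#' @param seeds Integer vector of simulation seeds.
#' @param beta Soft-threshold power (default 6).
#' @param min_size Minimum module size for detection (default 30).
#' @param n_perm Preservation permutations (default 100).
#'
#' @return A tibble with one row per seed: `seed`, `n_modules`, `selected`,
#'   `disrupted_detected`, `recovered`, `zsummary_disrupted`,
#'   `min_zsummary_intact`, `calibrated`, `tie_break`.
#' @export
disruption_benchmark <- function(seeds, beta = 6, min_size = 30, n_perm = 100) {
  purrr::map_dfr(seeds, function(s) {
    sim <- simulate_dataset(disruption_benchmark_design(seed = s))
    filt <- filter_expressed(sim$counts, sim$metadata)
    expr <- normalize_log(filt$counts)$values
    ctrl <- sim$metadata$sample_id[sim$metadata$group == "control"]
    case <- sim$metadata$sample_id[sim$metadata$group == "case"]
    net <- build_network(expr[, ctrl], beta = beta, min_size = min_size)
    pres <- module_preservation(expr[, ctrl], expr[, case], net$labels,
                                beta = beta, n_perm = n_perm, seed = s)
    sel <- select_least_preserved(pres)

    planted <- sim$truth$module_membership[names(net$labels)]
    detected_for <- vapply(seq_along(sim$design$module_sizes), function(pm) {
      tb <- table(net$labels[planted == pm & net$labels > 0])
      if (!length(tb)) return(NA_integer_)
      as.integer(names(tb)[which.max(tb)])
    }, integer(1))
    disrupted_det <- detected_for[sim$truth$disrupted_module]
    intact_det <- setdiff(detected_for[-sim$truth$disrupted_module], NA_integer_)

    z <- setNames(pres$stats$zsummary, pres$stats$module)
    tibble(
      seed = s,
      n_modules = nrow(pres$stats),
      selected = sel$module,
      disrupted_detected = disrupted_det,
      recovered = !is.na(disrupted_det) && sel$module == disrupted_det,
      zsummary_disrupted = unname(z[as.character(disrupted_det)]),
      min_zsummary_intact = if (length(intact_det)) {
        min(z[as.character(intact_det)])
      } else NA_real_,
      calibrated = !is.na(disrupted_det) && length(intact_det) > 0 &&
        z[as.character(disrupted_det)] < 2 &&
        min(z[as.character(intact_det)]) > 10,
      tie_break = sel$tie_break
    )
  })
}

#' Differential-expression calibration benchmark
#'
#' Simulates a dataset with no coexpression modules, runs the full DE stage
#' (size factors, dispersion estimation, NB Wald fit with a batch covariate),
#' and reports: the fraction of null genes with raw `p <= 0.05` (type-I
#' check), and — when DEGs are planted — the sensitivity of the relaxed
#' (`p <= 0.01`) set and the sign agreement of the recovered genes'
#' fold-change estimates with the planted signs.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes (default 2000).
#' @param n_per_group Samples per group (default 20).
#' @param n_deg Planted DEGs (default 0 = pure null).
#' @param deg_log2fc Planted log2 fold change(s), e.g. `c(2, -2)`.
#' @param dispersion NB dispersion (default 0.05).
#'
#' @return A list: `type1_fraction` (null genes only), `sensitivity`,
#'   `sign_agreement`, `n_null`, `de` (the result tibble), `truth`.
#' @export
de_calibration <- function(seed = 1L, n_genes = 2000, n_per_group = 20,
                           n_deg = 0, deg_log2fc = 2, dispersion = 0.05) {
  design <- synthetic_design(
    n_genes = n_genes, n_case = n_per_group, n_control = n_per_group,
    module_sizes = integer(), module_loadings = numeric(),
    n_deg = n_deg, deg_log2fc = deg_log2fc, dispersion = dispersion,
    base_mean_log_range = log(c(50, 1000)),
    batch_levels = 2, batch_effect_sd = 0.1, seed = seed
  )
  sim <- simulate_dataset(design)
  filt <- filter_expressed(sim$counts, sim$metadata)
  de <- fit_nb_glm_wald(filt$counts, sim$metadata, covariates = "batch")
  truth <- sim$truth$deg_table
  is_deg <- de$gene_id %in% truth$gene
  null_p <- de$p[!is_deg & de$converged]
  type1 <- mean(null_p <= 0.05)
  sens <- NA_real_
  sign_agree <- NA_real_
  if (n_deg > 0) {
    degs <- call_degs(de)
    hits <- intersect(degs$relaxed, truth$gene)
    sens <- length(hits) / nrow(truth)
    est <- setNames(de$log2fc, de$gene_id)[hits]
    tru <- setNames(truth$true_log2fc, truth$gene)[hits]
    sign_agree <- if (length(hits)) mean(sign(est) == sign(tru)) else NA_real_
  }
  list(type1_fraction = type1, sensitivity = sens, sign_agreement = sign_agree,
       n_null = length(null_p), de = de, truth = truth)
}
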