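# Full-pipeline orchestration: simulate/load -> preprocess -> differential
# expression -> control-reference network -> module preservation -> hub
# conservation -> enrichment, per region, then cross-region overlap.

default_config <- function() {
  list(
    seed = 1L,
    regions = list(),
    preprocess = list(min_cpm = 0.3, min_frac = 0.5, pseudocount = 0.5,
                      n_sv = "auto"),
    diffexp = list(covariates = c("sex", "age", "batch"),
                   adj_alpha = 0.05, raw_alpha = 0.01),
    network = list(beta = "auto", r2_min = 0.8, min_module_size = 500),
    preserve = list(n_perm = 100),
    hubs = list(threshold = 0.9),
    enrich = list(n_iter = 10000)
  )
}

#' Read and validate a pipeline configuration
#'
#' Accepts a YAML file path or a list. Each entry of `regions` provides either
#' `counts`/`metadata` file paths or a `simulate` block of [synthetic_design()]
#' arguments. Unknown keys, at the top level or within a stage block, are
#' rejected before any computation.
#'
#' @param config A list or path to a YAML file.
#' @return The validated, default-completed configuration list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("`config` must be a list or a YAML file path.")
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s.", toString(unknown)))
  }
  for (stage in setdiff(names(defaults), c("seed", "regions"))) {
    if (!is.null(config[[stage]])) {
      bad <- setdiff(names(config[[stage]]), names(defaults[[stage]]))
      if (length(bad)) {
        abort(sprintf("unknown key(s) in `%s` block: %s.", stage, toString(bad)))
      }
    }
  }
  cfg <- modifyList(defaults, config)
  if (!length(cfg$regions)) abort("config must define at least one region.")
  if (is.null(names(cfg$regions)) || any(names(cfg$regions) == "")) {
    abort("every region must be named.")
  }
  for (r in names(cfg$regions)) {
    reg <- cfg$regions[[r]]
    has_files <- all(c("counts", "metadata") %in% names(reg))
    has_sim <- "simulate" %in% names(reg)
    if (!has_files && !has_sim) {
      abort(sprintf("region `%s` needs either counts+metadata paths or a simulate block.", r))
    }
  }
  cfg
}

region_inputs <- function(region_cfg, region_name, seed) {
  if ("simulate" %in% names(region_cfg)) {
    args <- region_cfg$simulate
    args$region_label <- region_name
    args$seed <- args$seed %||% seed
    design <- do.call(synthetic_design, args)
    sim <- simulate_dataset(design)
    list(counts = sim$counts, metadata = sim$metadata, truth = sim$truth)
  } else {
    counts <- read_counts(region_cfg$counts)
    metadata <- read_metadata(region_cfg$metadata, colnames(counts))
    list(counts = counts, metadata = metadata, truth = NULL)
  }
}

run_region <- function(counts, metadata, cfg, seed, gene_sets = NULL) {
  pp <- cfg$preprocess
  filt <- filter_expressed(counts, metadata, min_cpm = pp$min_cpm,
                           min_frac = pp$min_frac)
  norm <- normalize_log(filt$counts, pseudocount = pp$pseudocount)
  expr <- norm$values

  sv <- estimate_surrogate_variables(
    expr, metadata, primary = "group",
    adjust = intersect(cfg$diffexp$covariates, names(metadata)),
    n_sv = pp$n_sv, seed = seed
  )

  meta <- metadata[match(colnames(expr), metadata$sample_id), ]
  meta$group <- factor(meta$group, levels = c("control", "case"))
  X0 <- build_model_matrix(meta, c("group", intersect(cfg$diffexp$covariates,
                                                      names(meta))))
  w_plain <- estimate_sample_weights(expr, X0)
  w_sv <- if (ncol(sv) > 0) {
    estimate_sample_weights(expr, cbind(X0, sv))
  } else {
    w_plain
  }
  weight_check <- compare_weight_distributions(w_plain, w_sv)

  de <- fit_nb_glm_wald(filt$counts, metadata,
                        covariates = intersect(cfg$diffexp$covariates,
                                               names(metadata)),
                        sv = if (ncol(sv) > 0) sv else NULL)
  degs <- call_degs(de, adj_alpha = cfg$diffexp$adj_alpha,
                    raw_alpha = cfg$diffexp$raw_alpha)

  ctrl_ids <- metadata$sample_id[metadata$group == "control"]
  case_ids <- metadata$sample_id[metadata$group == "case"]
  expr_ctrl <- expr[, ctrl_ids, drop = FALSE]
  expr_case <- expr[, case_ids, drop = FALSE]

  net <- build_network(expr_ctrl, beta = cfg$network$beta,
                       r2_min = cfg$network$r2_min,
                       min_size = cfg$network$min_module_size)
  if (!any(net$labels > 0)) {
    abort("network stage: no module of the requested minimum size was found.")
  }
  pres <- module_preservation(expr_ctrl, expr_case, net$labels,
                              beta = net$beta,
                              n_perm = cfg$preserve$n_perm, seed = seed + 1L)
  sel <- select_least_preserved(pres)
  mod_genes <- names(net$labels)[net$labels == sel$module]
  hubs <- hub_report(expr_ctrl, expr_case, mod_genes, module = sel$module,
                     threshold = cfg$hubs$threshold)
  hub_degs <- hub_deg_overlap(hubs, degs$relaxed)

  enr <- NULL
  if (!is.null(gene_sets)) {
    background <- rownames(expr)
    enr <- list(
      module_ora = ora(mod_genes, gene_sets, background),
      deg_ora = if (length(degs$relaxed) > 0) {
        ora(degs$relaxed, gene_sets, background)
      } else NULL,
      deg_mset = if (length(degs$relaxed) > 0) {
        mset(degs$relaxed, gene_sets[[1]], background,
             n_iter = cfg$enrich$n_iter, seed = seed + 2L)
      } else NULL
    )
  }

  list(
    n_genes_before = filt$n_before, n_genes_after = filt$n_after,
    expr = expr, sv = sv, weights = list(plain = w_plain, with_sv = w_sv),
    weight_check = weight_check,
    de = de, degs = degs,
    network = net, preservation = pres, selection = sel,
    hubs = hubs, hub_degs = hub_degs, enrichment = enr
  )
}

#' Run the full analysis pipeline
#'
#' Executes, for every configured region independently: expression filtering,
#' normalization, surrogate-variable estimation, sample-weight diagnostics,
#' negative-binomial Wald differential expression with DEG calling at the
#' strict (adjusted) and relaxed (raw) thresholds, control-reference network
#' construction, permutation module preservation with least-preserved-module
#' selection, hub conservation on that module, and (when gene sets are
#' supplied or simulated) enrichment. Cross-region DEG overlap and direction
#' concordance run afterwards. Every stochastic stage is seeded from the
#' global seed, so a rerun with the same config is identical.
#'
#' @param config A configuration list or YAML path (see
#'   [read_pipeline_config()]).
#' @param gene_sets Optional named list of gene sets used for enrichment.
#'
#' @return A list of class `pipeline_report` with `regions` (per-region result
#'   lists), `cross_region` (overlap/concordance, `NULL` for a single region),
#'   `summary` (one-row-per-region tibble), and `config`.
#' @export
run_pipeline <- function(config, gene_sets = NULL) {
  cfg <- read_pipeline_config(config)
  seed <- as.integer(cfg$seed)
  regions <- names(cfg$regions)
  results <- list()
  for (i in seq_along(regions)) {
    r <- regions[i]
    inp <- region_inputs(cfg$regions[[r]], r, seed + 100L * i)
    results[[r]] <- run_region(inp$counts, inp$metadata, cfg,
                               seed = seed + 100L * i + 1L,
                               gene_sets = gene_sets)
    results[[r]]$truth <- inp$truth
  }

  cross <- if (length(regions) >= 2) {
    overlap_and_concordance(
      results = lapply(results, `[[`, "de"),
      sets = lapply(results, function(x) x$degs$relaxed)
    )
  } else NULL

  summary <- purrr::map_dfr(regions, function(r) {
    x <- results[[r]]
    tibble(
      region = r,
      genes_filtered = x$n_genes_after,
      n_sv = ncol(x$sv),
      deg_strict = x$degs$n_strict,
      deg_relaxed = x$degs$n_relaxed,
      n_modules = length(x$network$module_sizes),
      beta = x$network$beta,
      least_preserved = x$selection$module,
      tie_break = x$selection$tie_break,
      hubs_exclusive_control = x$hubs$n_exclusive_control,
      hubs_shared = x$hubs$n_shared,
      hubs_exclusive_case = x$hubs$n_exclusive_case
    )
  })

  structure(
    list(regions = results, cross_region = cross, summary = summary,
         config = cfg),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  print(x$summary)
  if (!is.null(x$cross_region)) {
    cat(sprintf("cross-region: %d shared DEGs, concordance %.2f\n",
                x$cross_region$n_shared,
                x$cross_region$concordance %||% NA_real_))
  }
  invisible(x)
}
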