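#' Describe a synthetic case-control RNA-seq design
#'
#' Captures every parameter of the generative model used by
#' [simulate_dataset()]: negative-binomial counts whose log-mean combines a
#' per-gene baseline, latent-factor coexpression modules, planted
#' differential-expression shifts in cases, a laboratory batch effect and a
#' library-size offset. One module can be "disrupted" in cases, i.e. lose its
#' correlation structure while keeping its marginal means.
#'
#' @param n_genes Number of genes.
#' @param n_case,n_control Samples per group. Defaults mirror a small
#'   postmortem brain cohort (6 cases, 8 controls).
#' @param module_sizes Integer vector of planted module sizes; modules occupy
#'   the leading genes in order. `sum(module_sizes) <= n_genes`.
#' @param module_loadings Per-module factor loading in `[0, 1)` on the
#'   natural-log mean scale (recycled to `length(module_sizes)`). Larger
#'   loadings give tighter within-module correlation.
#' @param disrupted_module Index of the module whose co-variation is destroyed
#'   in case samples, or `NULL` for none.
#' @param disruption_mode `"break_correlation"` replaces the shared latent
#'   factor with i.i.d. per-gene factors in cases (variance preserved,
#'   co-variation destroyed); `"attenuate"` halves the loading in cases.
#' @param n_deg Number of planted differentially expressed genes, drawn from
#'   genes outside the planted modules when enough are available.
#' @param deg_log2fc True case/control log2 fold change(s); recycled over the
#'   planted genes, so mixed signs can be planted with e.g. `c(2, -2)`.
#' @param dispersion Negative-binomial dispersion `alpha >= 0` (`0` gives
#'   Poisson counts).
#' @param base_mean_log_range Range (natural-log scale) of per-gene baseline
#'   mean expression.
#' @param batch_levels Number of laboratory batches; samples are assigned
#'   round-robin within each group.
#' @param batch_effect_sd SD of the per-gene, per-batch shift on the
#'   natural-log mean scale.
#' @param library_size_range Library sizes are drawn log-uniformly over this
#'   range; only their ratios matter (they enter as log offsets).
#' @param region_label Region tag written into the sample metadata.
#' @param seed Integer seed; the whole dataset is deterministic given it.
#'
#' @return An object of class `synthetic_design` (a validated list).
#' @seealso [simulate_dataset()], [simulate_gene_sets()]
#' @export
synthetic_design <- function(n_genes = 2000,
                             n_case = 6,
                             n_control = 8,
                             module_sizes = integer(),
                             module_loadings = numeric(),
                             disrupted_module = NULL,
                             disruption_mode = c("break_correlation", "attenuate"),
                             n_deg = 0,
                             deg_log2fc = 0,
                             dispersion = 0.05,
                             base_mean_log_range = log(c(10, 1000)),
                             batch_levels = 2,
                             batch_effect_sd = 0.2,
                             library_size_range = c(5e6, 15e6),
                             region_label = "R1",
                             seed = 1L) {
  disruption_mode <- match.arg(disruption_mode)
  module_sizes <- as.integer(module_sizes)
  if (length(module_sizes)) {
    module_loadings <- rep_len(module_loadings, length(module_sizes))
  }
  design <- structure(
    list(
      n_genes = n_genes, n_case = n_case, n_control = n_control,
      module_sizes = module_sizes, module_loadings = module_loadings,
      disrupted_module = disrupted_module, disruption_mode = disruption_mode,
      n_deg = n_deg, deg_log2fc = deg_log2fc, dispersion = dispersion,
      base_mean_log_range = base_mean_log_range,
      batch_levels = batch_levels, batch_effect_sd = batch_effect_sd,
      library_size_range = library_size_range,
      region_label = region_label, seed = as.integer(seed)
    ),
    class = "synthetic_design"
  )
  validate_synthetic_design(design)
}

validate_synthetic_design <- function(design) {
  d <- design
  if (!is_count(d$n_genes)) abort("invalid design: `n_genes` must be a positive integer.")
  if (!is_count(d$n_case)) abort("invalid design: `n_case` must be a positive integer.")
  if (!is_count(d$n_control)) abort("invalid design: `n_control` must be a positive integer.")
  if (length(d$module_sizes) && any(d$module_sizes < 2)) {
    abort("invalid design: every entry of `module_sizes` must be >= 2.")
  }
  if (sum(d$module_sizes) > d$n_genes) {
    abort("invalid design: `module_sizes` sum exceeds `n_genes`.")
  }
  if (length(d$module_loadings) != length(d$module_sizes)) {
    abort("invalid design: `module_loadings` must match `module_sizes` in length.")
  }
  if (length(d$module_loadings) &&
      (any(d$module_loadings < 0) || any(d$module_loadings >= 1))) {
    abort("invalid design: `module_loadings` must lie in [0, 1).")
  }
  if (!is.null(d$disrupted_module)) {
    if (!is_count(d$disrupted_module) || d$disrupted_module > length(d$module_sizes)) {
      abort("invalid design: `disrupted_module` must index an entry of `module_sizes`.")
    }
  }
  if (!is_count(d$n_deg, zero_ok = TRUE) || d$n_deg > d$n_genes) {
    abort("invalid design: `n_deg` must be a count <= `n_genes`.")
  }
  if (!is.numeric(d$dispersion) || length(d$dispersion) != 1 || d$dispersion < 0) {
    abort("invalid design: `dispersion` must be a single value >= 0.")
  }
  if (length(d$base_mean_log_range) != 2 || diff(d$base_mean_log_range) < 0) {
    abort("invalid design: `base_mean_log_range` must be an increasing interval.")
  }
  if (!is_count(d$batch_levels)) abort("invalid design: `batch_levels` must be a positive integer.")
  if (d$batch_effect_sd < 0) abort("invalid design: `batch_effect_sd` must be >= 0.")
  if (length(d$library_size_range) != 2 || any(d$library_size_range <= 0) ||
      diff(d$library_size_range) < 0) {
    abort("invalid design: `library_size_range` must be a positive increasing interval.")
  }
  design
}

#' Simulate a case-control count dataset with planted structure
#'
#' Draws gene-level read counts for the two groups under the generative model
#' described in [synthetic_design()]. Counts are negative binomial with
#' log-mean
#' `baseline + loading * module factor + DEG shift (cases) + batch shift +
#' log library-size offset`. Latent factors are standard normal per sample;
#' under `break_correlation` the disrupted module's case samples receive
#' independent per-gene factors, so its within-module correlation is destroyed
#' while marginal means are unchanged.
#'
#' @param design A [synthetic_design()].
#' @param seed Optional seed overriding `design$seed`.
#'
#' @return A `synthetic_cohort` list with elements
#'   - `counts`: combined genes x samples integer matrix,
#'   - `counts_case`, `counts_control`: the per-group submatrices,
#'   - `metadata`: tibble with `sample_id`, `group`, `sex`, `age`, `batch`,
#'     `region`,
#'   - `truth`: planted ground truth (`module_membership` named integer vector
#'     with 0 = background, `disrupted_module`, `deg_table` tibble of
#'     `gene`/`true_log2fc`, `batch`, `library_sizes`).
#' @export
simulate_dataset <- function(design, seed = design$seed) {
  validate_synthetic_design(design)
  d <- design
  n <- d$n_case + d$n_control
  gene_ids <- sprintf("g%05d", seq_len(d$n_genes))
  sample_ids <- c(sprintf("case_%02d", seq_len(d$n_case)),
                  sprintf("ctrl_%02d", seq_len(d$n_control)))
  group <- rep(c("case", "control"), c(d$n_case, d$n_control))

  membership <- integer(d$n_genes)
  if (length(d$module_sizes)) {
    membership[seq_len(sum(d$module_sizes))] <-
      rep(seq_along(d$module_sizes), d$module_sizes)
  }
  names(membership) <- gene_ids

  # batch assignment: round-robin within each group, never confounded with it
  batch <- unlist(lapply(c(d$n_case, d$n_control), function(k) {
    rep_len(seq_len(d$batch_levels), k)
  }))
  names(batch) <- sample_ids

  with_seed(as.integer(seed), {
    baseline <- runif(d$n_genes, d$base_mean_log_range[1], d$base_mean_log_range[2])
    lib <- exp(runif(n, log(d$library_size_range[1]), log(d$library_size_range[2])))
    names(lib) <- sample_ids
    offset <- log(lib) - mean(log(lib))

    batch_shift <- matrix(rnorm(d$n_genes * d$batch_levels, 0, d$batch_effect_sd),
                          nrow = d$n_genes)

    background <- gene_ids[membership == 0]
    deg_pool <- if (d$n_deg <= length(background)) background else gene_ids
    deg_genes <- if (d$n_deg > 0) sample(deg_pool, d$n_deg) else character()
    true_lfc <- rep_len(d$deg_log2fc, d$n_deg)

    log_mu <- matrix(baseline, nrow = d$n_genes, ncol = n)
    rownames(log_mu) <- gene_ids
    colnames(log_mu) <- sample_ids

    for (m in seq_along(d$module_sizes)) {
      rows <- which(membership == m)
      a <- d$module_loadings[m]
      shared <- rnorm(n)
      contrib <- a * matrix(shared, nrow = length(rows), ncol = n, byrow = TRUE)
      if (!is.null(d$disrupted_module) && m == d$disrupted_module) {
        is_case <- group == "case"
        if (d$disruption_mode == "break_correlation") {
          contrib[, is_case] <- a * matrix(rnorm(length(rows) * sum(is_case)),
                                           nrow = length(rows))
        } else {
          contrib[, is_case] <- contrib[, is_case] * 0.5
        }
      }
      log_mu[rows, ] <- log_mu[rows, ] + contrib
    }

    if (d$n_deg > 0) {
      shift <- true_lfc * log(2)
      log_mu[deg_genes, group == "case"] <-
        log_mu[deg_genes, group == "case"] + shift
    }

    log_mu <- log_mu + batch_shift[, batch] +
      matrix(offset, nrow = d$n_genes, ncol = n, byrow = TRUE)

    mu <- exp(log_mu)
    counts <- if (d$dispersion == 0) {
      matrix(rpois(length(mu), lambda = mu), nrow = d$n_genes)
    } else {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / d$dispersion),
             nrow = d$n_genes)
    }
    dimnames(counts) <- dimnames(log_mu)

    sex <- sample(c("F", "M"), n, replace = TRUE)
    age <- round(rnorm(n, 75, 5))

    metadata <- tibble(
      sample_id = sample_ids,
      group = group,
      sex = sex,
      age = age,
      batch = paste0("b", batch),
      region = d$region_label
    )

    truth <- list(
      module_membership = membership,
      disrupted_module = d$disrupted_module,
      deg_table = tibble(gene = deg_genes, true_log2fc = true_lfc),
      batch = batch,
      library_sizes = lib
    )

    structure(
      list(
        counts = counts,
        counts_case = counts[, group == "case", drop = FALSE],
        counts_control = counts[, group == "control", drop = FALSE],
        metadata = metadata,
        truth = truth,
        design = d
      ),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d genes x %d samples (%d case / %d control)\n",
    nrow(x$counts), ncol(x$counts),
    ncol(x$counts_case), ncol(x$counts_control)
  ))
  cat(sprintf("  modules: %s; disrupted: %s; planted DEGs: %d\n",
              if (length(x$design$module_sizes)) toString(x$design$module_sizes) else "none",
              x$truth$disrupted_module %||% "none",
              nrow(x$truth$deg_table)))
  invisible(x)
}

#' Simulate GMT-style gene sets, one enriched for the planted DEGs
#'
#' Builds `n_sets` gene sets over the simulated gene universe. The first set
#' (`set_01`, the "designated" set) draws `round(set_size * enriched_fraction)`
#' of its members from the planted DEG list and the remainder from non-DEG
#' genes; all other sets are uniform draws from the universe.
#'
#' @param truth The `truth` element of a [simulate_dataset()] result.
#' @param n_sets Number of gene sets.
#' @param set_size Genes per set; must not exceed the universe.
#' @param enriched_fraction Fraction of the designated set drawn from the DEG
#'   list.
#' @param seed Integer seed.
#'
#' @return A list with `sets` (named list of gene-id vectors), `universe`, and
#'   `enriched_set` (name of the designated set).
#' @export
simulate_gene_sets <- function(truth, n_sets, set_size, enriched_fraction, seed = 1L) {
  universe <- names(truth$module_membership)
  if (set_size > length(universe)) {
    abort("`set_size` exceeds the gene universe.")
  }
  deg <- truth$deg_table$gene
  non_deg <- setdiff(universe, deg)
  with_seed(as.integer(seed), {
    n_from_deg <- min(round(set_size * enriched_fraction), length(deg))
    designated <- c(
      sample(deg, n_from_deg),
      sample(non_deg, set_size - n_from_deg)
    )
    sets <- c(
      list(sample(designated)),  # shuffle so DEG members are not listed first
      lapply(seq_len(max(n_sets - 1, 0)), function(i) sample(universe, set_size))
    )[seq_len(n_sets)]
    names(sets) <- sprintf("set_%02d", seq_len(n_sets))
    list(sets = sets, universe = universe, enriched_set = names(sets)[1])
  })
}
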