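# Reference-based module preservation: observed density/connectivity
# statistics, permutation Z-scores, Zsummary, medianRank, and the
# least-preserved-module selection rule with a kME-correlation tie-break.

DENSITY_STATS <- c("mean_cor", "mean_adj", "prop_var_explained", "mean_signed_kme")
CONNECTIVITY_STATS <- c("cor_kim", "cor_kme", "cor_cor")
PRESERVATION_STATS <- c(DENSITY_STATS, CONNECTIVITY_STATS)

#' Map reference modules onto a test dataset
#'
#' Applies the reference (control) partition to the test (case) expression:
#' the same gene sets form the "same modules" in the test data. Genes absent
#' from the test data are dropped from both views and reported.
#'
#' @param ref_labels Named gene -> module integer vector from the reference
#'   network (0 = unassigned).
#' @param test_expr Test genes x samples expression matrix.
#'
#' @return A list with `labels` (restricted to the shared universe) and
#'   `dropped_genes`.
#' @export
map_reference_modules <- function(ref_labels, test_expr) {
  shared <- intersect(names(ref_labels), rownames(test_expr))
  if (!length(shared)) abort("reference and test gene universes do not overlap.")
  dropped <- setdiff(names(ref_labels), shared)
  list(labels = ref_labels[shared], dropped_genes = dropped)
}

# first principal component of a genes x samples submatrix; constant genes
# are ignored, orientation fixed so mean member correlation is >= 0
eigengene_of <- function(sub) {
  sds <- apply(sub, 1, sd)
  use <- sds > 0
  if (!any(use)) return(NULL)
  z <- t(scale(t(sub[use, , drop = FALSE])))
  sv <- svd(t(z), nu = 1, nv = 0)
  e <- sv$u[, 1]
  if (mean(cor(t(sub[use, , drop = FALSE]), e)) < 0) e <- -e
  list(e = e, ve = sv$d[1]^2 / sum(sv$d^2))
}

safe_cor <- function(x, y) {
  r <- suppressWarnings(cor(x, y))
  if (is.na(r)) 0 else r
}

# the 7 preservation statistics for one gene set, ref vs test
stats_for_genes <- function(ref_expr, test_expr, genes, beta) {
  ref_sub <- ref_expr[genes, , drop = FALSE]
  test_sub <- test_expr[genes, , drop = FALSE]
  cor_ref <- suppressWarnings(cor(t(ref_sub)))
  cor_test <- suppressWarnings(cor(t(test_sub)))
  cor_ref[is.na(cor_ref)] <- 0
  cor_test[is.na(cor_test)] <- 0
  adj_ref <- abs(cor_ref)^beta
  adj_test <- abs(cor_test)^beta

  eg_test <- eigengene_of(test_sub)
  eg_ref <- eigengene_of(ref_sub)
  kme_test <- if (!is.null(eg_test)) {
    r <- suppressWarnings(cor(t(test_sub), eg_test$e))[, 1]
    r[is.na(r)] <- 0
    r
  } else rep(0, length(genes))
  kme_ref <- if (!is.null(eg_ref)) {
    r <- suppressWarnings(cor(t(ref_sub), eg_ref$e))[, 1]
    r[is.na(r)] <- 0
    r
  } else rep(0, length(genes))

  kim_ref <- rowSums(adj_ref) - 1
  kim_test <- rowSums(adj_test) - 1

  c(
    mean_cor = mean(upper_tri_values(cor_test)),
    mean_adj = mean(upper_tri_values(adj_test)),
    prop_var_explained = if (!is.null(eg_test)) eg_test$ve else 0,
    mean_signed_kme = mean(kme_test),
    cor_kim = safe_cor(kim_ref, kim_test),
    cor_kme = safe_cor(kme_ref, kme_test),
    cor_cor = safe_cor(upper_tri_values(cor_ref), upper_tri_values(cor_test))
  )
}

#' Observed preservation statistics per module
#'
#' Density statistics evaluated on the test data (`mean_cor`: mean
#' off-diagonal within-module correlation; `mean_adj`: mean within-module
#' adjacency at the given power; `prop_var_explained`: eigengene variance
#' explained; `mean_signed_kme`), and connectivity statistics comparing
#' reference and test (`cor_kim`: correlation of intramodular connectivities;
#' `cor_kme`: correlation of module memberships; `cor_cor`: correlation of the
#' vectorized within-module correlation matrices). Modules with fewer than 3
#' genes are flagged undefined.
#'
#' @param ref_expr,test_expr Genes x samples expression matrices over a shared
#'   gene universe.
#' @param labels Named gene -> module vector (0 = unassigned, excluded).
#' @param beta Soft-threshold power for the adjacency-based statistics.
#'
#' @return A tibble: one row per module x statistic with `observed` values and
#'   a `defined` flag.
#' @export
observed_stats <- function(ref_expr, test_expr, labels, beta) {
  mods <- sort(unique(labels[labels > 0]))
  purrr::map_dfr(mods, function(m) {
    genes <- names(labels)[labels == m]
    if (length(genes) < 3) {
      return(tibble(module = m, size = length(genes),
                    stat = PRESERVATION_STATS, observed = NA_real_,
                    defined = FALSE))
    }
    s <- stats_for_genes(ref_expr, test_expr, genes, beta)
    tibble(module = m, size = length(genes), stat = names(s),
           observed = unname(s), defined = TRUE)
  })
}

#' Permutation null and Z-scores for preservation statistics
#'
#' For each module, draws `n_perm` random gene sets of the same size from the
#' analyzed universe (all genes shared by reference and test, including
#' unassigned ones), recomputes every preservation statistic on each draw, and
#' standardizes the observed value:
#' `Z = (observed - permutation mean) / permutation sd`. A zero permutation sd
#' yields a signed-infinite Z that is flagged and excluded from the medians
#' downstream.
#'
#' @inheritParams observed_stats
#' @param n_perm Number of permutations (>= 20; default 100).
#' @param seed Integer seed; results are deterministic given it.
#'
#' @return A tibble per module x statistic: `observed`, `perm_mean`,
#'   `perm_sd`, `z`, `defined`.
#' @export
permutation_null <- function(ref_expr, test_expr, labels, beta,
                             n_perm = 100, seed = 1L) {
  if (n_perm < 20) abort("`n_perm` must be at least 20.")
  universe <- intersect(names(labels), rownames(ref_expr))
  universe <- intersect(universe, rownames(test_expr))
  obs <- observed_stats(ref_expr, test_expr, labels, beta)
  mods <- unique(obs$module[obs$defined])
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))

  perms <- with_seed(as.integer(seed), {
    lapply(seq_along(mods), function(i) {
      vapply(seq_len(n_perm), function(p) {
        genes <- sample(universe, sizes[i])
        stats_for_genes(ref_expr, test_expr, genes, beta)
      }, numeric(length(PRESERVATION_STATS)))
    })
  })

  null_tbl <- purrr::map_dfr(seq_along(mods), function(i) {
    tibble(
      module = mods[i],
      stat = PRESERVATION_STATS,
      perm_mean = rowMeans(perms[[i]]),
      perm_sd = apply(perms[[i]], 1, sd)
    )
  })
  out <- dplyr::left_join(obs, null_tbl, by = c("module", "stat"))
  out$z <- ifelse(
    !out$defined, NA_real_,
    ifelse(out$perm_sd > 0,
           (out$observed - out$perm_mean) / out$perm_sd,
           sign(out$observed - out$perm_mean) * Inf)
  )
  if (any(is.infinite(out$z), na.rm = TRUE)) {
    warn("some permutation sds were zero; infinite Z-scores excluded from summaries.")
  }
  out
}

#' Zsummary and medianRank per module
#'
#' `Zsummary = mean(median of the density Zs, median of the connectivity Zs)`
#' — low values (around 2) mean little preservation, high values (10 and up)
#' mean strong preservation. `medianRank` ignores permutations: for each
#' statistic the modules are ranked on the observed value (rank 1 = most
#' preserved, average ranks on ties) and the module's median rank across
#' statistics is reported, so the least preserved module has the highest
#' medianRank.
#'
#' @param z_table Output of [permutation_null()].
#'
#' @return A tibble per module: `size`, `z_density`, `z_connectivity`,
#'   `zsummary`, `median_rank`.
#' @export
summarize_preservation <- function(z_table) {
  mods <- unique(z_table$module[z_table$defined])
  if (length(mods) < 2) {
    warn("fewer than 2 modules: medianRank is degenerate (all ranks 1).")
  }
  obs_wide <- tidyr::pivot_wider(
    z_table[z_table$defined, c("module", "stat", "observed")],
    names_from = "stat", values_from = "observed"
  )
  ranks <- purrr::map_dfc(PRESERVATION_STATS, function(s) {
    r <- rank(-obs_wide[[s]], ties.method = "average")
    setNames(tibble(r), s)
  })
  median_rank <- apply(as.matrix(ranks), 1, median)

  per_module <- purrr::map_dfr(seq_along(obs_wide$module), function(i) {
    m <- obs_wide$module[i]
    zt <- z_table[z_table$module == m & z_table$defined, ]
    zd <- zt$z[zt$stat %in% DENSITY_STATS]
    zc <- zt$z[zt$stat %in% CONNECTIVITY_STATS]
    zd <- zd[is.finite(zd)]
    zc <- zc[is.finite(zc)]
    z_density <- if (length(zd)) median(zd) else NA_real_
    z_connectivity <- if (length(zc)) median(zc) else NA_real_
    tibble(
      module = m,
      size = zt$size[1],
      z_density = z_density,
      z_connectivity = z_connectivity,
      zsummary = mean(c(z_density, z_connectivity), na.rm = TRUE),
      median_rank = median_rank[i]
    )
  })
  per_module
}

#' Correlation of module membership (kME) between conditions
#'
#' Pearson correlation, across the genes of one module, of the gene's own
#' module kME in the reference data versus the test data, with the standard
#' correlation t-test p-value. A preserved module keeps its membership
#' ordering (`r` near 1); a module that lost its structure is near 0.
#'
#' @param kme_ref,kme_test Named numeric vectors of own-module kME over the
#'   module's genes in each condition.
#'
#' @return A one-row tibble with `r`, `p`, `n`.
#' @export
module_kme_correlation <- function(kme_ref, kme_test) {
  genes <- intersect(names(kme_ref), names(kme_test))
  if (length(genes) < 3) abort("at least 3 shared module genes are required.")
  ct <- cor.test(kme_ref[genes], kme_test[genes])
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(genes))
}

#' Reference-based module preservation analysis
#'
#' Runs the full preservation workflow: map the reference partition onto the
#' test data, compute observed statistics, permutation Z-scores, Zsummary and
#' medianRank, and record per-module own-module kME vectors in both conditions
#' for the selection tie-break.
#'
#' @param ref_expr Reference (control) genes x samples expression matrix.
#' @param test_expr Test (case) expression matrix.
#' @param ref_labels Named gene -> module vector from the reference network.
#' @param beta Soft-threshold power.
#' @param n_perm Permutations (default 100).
#' @param seed Integer seed.
#'
#' @return An object of class `module_preservation`: `stats` (per-module
#'   summary tibble), `z_table`, `kme` (per-module ref/test own-kME vectors),
#'   `n_perm`, `beta`, `dropped_genes`.
#' @export
module_preservation <- function(ref_expr, test_expr, ref_labels, beta,
                                n_perm = 100, seed = 1L) {
  mapped <- map_reference_modules(ref_labels, test_expr)
  labels <- mapped$labels
  shared <- names(labels)
  ref_expr <- ref_expr[shared, , drop = FALSE]
  test_expr <- test_expr[shared, , drop = FALSE]

  z_table <- permutation_null(ref_expr, test_expr, labels, beta,
                              n_perm = n_perm, seed = seed)
  stats <- summarize_preservation(z_table)

  kme_pairs <- lapply(stats$module, function(m) {
    genes <- names(labels)[labels == m]
    eg_ref <- eigengene_of(ref_expr[genes, , drop = FALSE])
    eg_test <- eigengene_of(test_expr[genes, , drop = FALSE])
    kr <- if (is.null(eg_ref)) rep(0, length(genes)) else {
      suppressWarnings(cor(t(ref_expr[genes, , drop = FALSE]), eg_ref$e))[, 1]
    }
    kt <- if (is.null(eg_test)) rep(0, length(genes)) else {
      suppressWarnings(cor(t(test_expr[genes, , drop = FALSE]), eg_test$e))[, 1]
    }
    kr[is.na(kr)] <- 0
    kt[is.na(kt)] <- 0
    list(ref = setNames(kr, genes), test = setNames(kt, genes))
  })
  names(kme_pairs) <- as.character(stats$module)

  structure(
    list(stats = stats, z_table = z_table, kme = kme_pairs,
         n_perm = n_perm, beta = beta, dropped_genes = mapped$dropped_genes),
    class = "module_preservation"
  )
}

#' @export
print.module_preservation <- function(x, ...) {
  cat(sprintf("<module_preservation> %d modules, %d permutations, beta = %s\n",
              nrow(x$stats), x$n_perm, format(x$beta)))
  print(x$stats)
  invisible(x)
}

#' Select the least preserved module
#'
#' If the module ranked least preserved by medianRank (highest) is also the
#' one ranked least preserved by Zsummary (lowest), it is selected outright.
#' Otherwise the union of the 3 least preserved modules under each criterion
#' forms the candidate pool, the reference-vs-test kME correlation is computed
#' for each candidate, and the module with the most neutral correlation
#' (smallest `|r|`) is selected. The returned rationale records both
#' criteria, the candidates and their kME correlations.
#'
#' @param preservation A [module_preservation()] object.
#'
#' @return A list with `module` (selected id), `tie_break` (logical),
#'   `candidates` (tibble with `module`, `zsummary`, `median_rank`, `kme_r`,
#'   `kme_p`), `by_median_rank`, `by_zsummary`.
#' @export
select_least_preserved <- function(preservation) {
  stats <- preservation$stats
  if (!nrow(stats)) abort("no modules with defined preservation statistics.")
  by_rank <- stats$module[which.max(stats$median_rank)]
  by_z <- stats$module[which.min(stats$zsummary)]
  if (by_rank == by_z) {
    kc <- module_kme_correlation(preservation$kme[[as.character(by_rank)]]$ref,
                                 preservation$kme[[as.character(by_rank)]]$test)
    return(list(
      module = by_rank, tie_break = FALSE,
      by_median_rank = by_rank, by_zsummary = by_z,
      candidates = tibble(
        module = by_rank,
        zsummary = stats$zsummary[stats$module == by_rank],
        median_rank = stats$median_rank[stats$module == by_rank],
        kme_r = kc$r, kme_p = kc$p
      )
    ))
  }
  top_rank <- stats$module[order(-stats$median_rank)][seq_len(min(3, nrow(stats)))]
  top_z <- stats$module[order(stats$zsummary)][seq_len(min(3, nrow(stats)))]
  pool <- union(top_rank, top_z)
  cand <- purrr::map_dfr(pool, function(m) {
    kc <- module_kme_correlation(preservation$kme[[as.character(m)]]$ref,
                                 preservation$kme[[as.character(m)]]$test)
    tibble(module = m,
           zsummary = stats$zsummary[stats$module == m],
           median_rank = stats$median_rank[stats$module == m],
           kme_r = kc$r, kme_p = kc$p)
  })
  sel <- cand$module[which.min(abs(cand$kme_r))]
  list(module = sel, tie_break = TRUE,
       by_median_rank = by_rank, by_zsummary = by_z,
       candidates = cand)
}
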