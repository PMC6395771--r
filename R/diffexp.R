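#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes of
#' `counts[g, s] / geometric mean of gene g across samples`, computed on genes
#' with nonzero counts in all samples, then rescaled so the factors have
#' geometric mean 1. If no gene is nonzero everywhere, the median is taken per
#' sample over that sample's positive-count genes, with a warning.
#'
#' @param counts Genes x samples count matrix.
#' @return A named positive per-sample factor vector.
#' @export
estimate_size_factors <- function(counts) {
  assert_count_matrix(counts)
  if (ncol(counts) == 1) return(setNames(1, colnames(counts)))
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (any(all_pos)) {
    log_geo <- rowMeans(log(counts[all_pos, , drop = FALSE]))
    ratios <- log(counts[all_pos, , drop = FALSE]) - log_geo
    f <- exp(apply(ratios, 2, median))
  } else {
    warn("no gene has nonzero counts in every sample; using positive-count medians.")
    f <- vapply(seq_len(ncol(counts)), function(s) {
      pos <- counts[, s] > 0
      if (!any(pos)) return(1)
      log_geo <- rowMeans(log(pmax(counts[pos, , drop = FALSE], 0.5)))
      exp(median(log(counts[pos, s]) - log_geo))
    }, numeric(1))
  }
  f <- f / geometric_mean(f)
  setNames(f, colnames(counts))
}

#' Per-gene negative-binomial dispersions
#'
#' Method-of-moments estimate on size-factor normalized counts,
#' `alpha = max(0, (s^2 - mu) / mu^2)`, shrunk 50/50 toward a fitted
#' mean-dispersion trend `alpha_tr(mu) = a0 + a1/mu` (ordinary least squares
#' over genes with positive mean). All-zero genes get dispersion 0 and are
#' flagged.
#'
#' @param counts Genes x samples count matrix.
#' @param size_factors Optional; defaults to [estimate_size_factors()].
#' @return A tibble with `gene_id`, `base_mean`, `dispersion_raw`,
#'   `dispersion_trend`, `dispersion`, `flagged`.
#' @export
estimate_dispersions <- function(counts, size_factors = estimate_size_factors(counts)) {
  assert_count_matrix(counts)
  if (ncol(counts) < 2) abort("dispersion estimation needs >= 2 samples.")
  norm <- sweep(counts, 2, size_factors, "/")
  mu <- rowMeans(norm)
  s2 <- apply(norm, 1, var)
  raw <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)
  use <- mu > 0
  trend <- rep(0, length(mu))
  if (sum(use) >= 3 && sd(1 / mu[use]) > 0) {
    fit <- lm(raw[use] ~ I(1 / mu[use]))
    trend[use] <- pmax(0, coef(fit)[1] + coef(fit)[2] / mu[use])
  } else {
    trend[use] <- mean(raw[use])
  }
  disp <- ifelse(use, 0.5 * raw + 0.5 * trend, 0)
  disp[s2 == 0] <- 0                      # no variance, no overdispersion evidence
  tibble(
    gene_id = rownames(counts),
    base_mean = unname(mu),
    dispersion_raw = unname(raw),
    dispersion_trend = unname(trend),
    dispersion = unname(disp),
    flagged = unname(!use)
  )
}

nb_family <- function(alpha) {
  if (alpha < 1e-8) poisson(link = "log") else MASS::negative.binomial(theta = 1 / alpha)
}

#' Negative-binomial Wald differential expression
#'
#' Fits, per gene, a negative-binomial log-link GLM by iteratively reweighted
#' least squares with the gene's dispersion held fixed, using
#' `~ group + covariates (+ surrogate variables)` and a `log(size factor)`
#' offset. The group coefficient is reported as `log2fc` (case over control),
#' with Wald `z = coef/se` and a two-sided normal p-value, BH-adjusted across
#' genes. All-zero genes and fits that do not converge within `maxit`
#' iterations are flagged with `p = 1`.
#'
#' @param counts Genes x samples count matrix (pre-filtered).
#' @param metadata Sample metadata with `sample_id`, `group` and any
#'   covariates.
#' @param covariates Metadata columns to adjust for (e.g. `c("sex", "age",
#'   "batch")`).
#' @param sv Optional samples x k surrogate-variable matrix (rows matched to
#'   `colnames(counts)`).
#' @param size_factors,dispersions Optional precomputed values (see
#'   [estimate_size_factors()], [estimate_dispersions()]).
#' @param maxit IRLS iteration cap (default 50).
#'
#' @return A tibble with `gene_id`, `base_mean`, `log2fc`, `se`, `wald_z`,
#'   `p`, `p_adj`, `converged`.
#' @export
fit_nb_glm_wald <- function(counts, metadata, covariates = character(),
                            sv = NULL, size_factors = NULL,
                            dispersions = NULL, maxit = 50) {
  assert_count_matrix(counts)
  assert_metadata(metadata, colnames(counts))
  meta <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  meta$group <- factor(meta$group, levels = c("control", "case"))
  X <- build_model_matrix(meta, c("group", covariates))
  if (!is.null(sv) && ncol(sv) > 0) {
    sv <- as.matrix(sv)
    if (!is.null(rownames(sv))) sv <- sv[colnames(counts), , drop = FALSE]
    X <- cbind(X, sv)
    if (qr(X)$rank < ncol(X)) abort("design with surrogate variables is rank deficient.")
  }
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (is.null(dispersions)) dispersions <- estimate_dispersions(counts, size_factors)
  alpha <- if (is.data.frame(dispersions)) {
    setNames(dispersions$dispersion, dispersions$gene_id)[rownames(counts)]
  } else {
    dispersions[rownames(counts)]
  }
  off <- log(size_factors)
  coef_idx <- match("groupcase", colnames(X))
  norm_mean <- rowMeans(sweep(counts, 2, size_factors, "/"))

  res <- lapply(seq_len(nrow(counts)), function(g) {
    y <- counts[g, ]
    if (all(y == 0)) {
      return(c(log2fc = 0, se = NA_real_, z = 0, p = 1, conv = 0))
    }
    fit <- suppressWarnings(
      glm.fit(X, y, family = nb_family(alpha[g]), offset = off,
              control = list(maxit = maxit))
    )
    if (!fit$converged || fit$rank < ncol(X)) {
      return(c(log2fc = 0, se = NA_real_, z = 0, p = 1, conv = 0))
    }
    p_rank <- fit$rank
    Rr <- fit$qr$qr[seq_len(p_rank), seq_len(p_rank), drop = FALSE]
    Rr[lower.tri(Rr)] <- 0
    covmat <- chol2inv(Rr)
    se_all <- rep(NA_real_, ncol(X))
    se_all[fit$qr$pivot[seq_len(p_rank)]] <- sqrt(diag(covmat))
    b <- unname(fit$coefficients[coef_idx])
    se <- se_all[coef_idx]
    z <- b / se
    c(log2fc = b / log(2), se = se / log(2), z = z,
      p = min(1, 2 * pnorm(-abs(z))), conv = 1)
  })
  res <- do.call(rbind, res)
  out <- tibble(
    gene_id = rownames(counts),
    base_mean = norm_mean,
    log2fc = res[, "log2fc"],
    se = res[, "se"],
    wald_z = res[, "z"],
    p = res[, "p"],
    converged = res[, "conv"] == 1
  )
  out$p_adj <- adjust_bh(out$p)
  out[, c("gene_id", "base_mean", "log2fc", "se", "wald_z", "p", "p_adj", "converged")]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin, validating wrapper around
#' `stats::p.adjust(method = "BH")` so every module shares one implementation.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
adjust_bh <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Call differentially expressed genes at two thresholds
#'
#' `strict` uses the BH-adjusted threshold (`p_adj <= adj_alpha`); `relaxed`
#' uses the unadjusted threshold (`p <= raw_alpha`) — an exploratory set for
#' underpowered cohorts. Non-converged fits are excluded from both.
#'
#' @param results A [fit_nb_glm_wald()] result tibble.
#' @param adj_alpha Adjusted-p threshold (default 0.05).
#' @param raw_alpha Raw-p threshold (default 0.01).
#' @return A list with gene-id vectors `strict` and `relaxed` plus their sizes.
#' @export
call_degs <- function(results, adj_alpha = 0.05, raw_alpha = 0.01) {
  ok <- results$converged
  strict <- results$gene_id[ok & results$p_adj <= adj_alpha]
  relaxed <- results$gene_id[ok & results$p <= raw_alpha]
  if (!all(strict %in% relaxed) && adj_alpha <= raw_alpha) {
    warn("strict DEG set is not contained in the relaxed set; inspect the fits.")
  }
  list(strict = strict, relaxed = relaxed,
       n_strict = length(strict), n_relaxed = length(relaxed))
}

#' Cross-region DEG overlap and direction concordance
#'
#' Venn-style exclusive/shared counts of DEG sets across regions, and, for
#' every gene shared by two or more regions, whether its log2 fold changes
#' agree in sign everywhere it appears. Genes with a zero log2 fold change in
#' any sharing region are counted as neither concordant nor discordant and
#' reported separately.
#'
#' @param results Named list (by region) of [fit_nb_glm_wald()] tibbles.
#' @param sets Named list (same names) of DEG gene-id vectors.
#'
#' @return A list: `overlaps` (tibble of region combination and gene count),
#'   `shared` (per shared gene: regions, signs, concordance), `n_shared`,
#'   `n_same_direction`, `concordance`, `inverted_genes`, `zero_lfc_genes`.
#' @export
overlap_and_concordance <- function(results, sets) {
  if (length(sets) < 2) abort("at least two regions are required.")
  if (is.null(names(sets)) || is.null(names(results)) ||
      !setequal(names(sets), names(results))) {
    abort("`results` and `sets` must be named lists over the same regions.")
  }
  regions <- names(sets)
  for (r in regions) {
    if (anyDuplicated(sets[[r]])) abort(sprintf("duplicated gene in region `%s`.", r))
    if (anyDuplicated(results[[r]]$gene_id)) {
      abort(sprintf("duplicated gene in region `%s` results.", r))
    }
  }
  membership <- tibble(gene = unique(unlist(sets)))
  for (r in regions) membership[[r]] <- membership$gene %in% sets[[r]]
  combo <- apply(membership[regions], 1, function(m) paste(regions[m], collapse = "&"))
  overlaps <- dplyr::count(tibble(combination = combo), .data$combination, name = "n_genes")

  shared_genes <- membership$gene[rowSums(as.matrix(membership[regions])) >= 2]
  shared <- purrr::map_dfr(shared_genes, function(g) {
    in_regions <- regions[vapply(regions, function(r) g %in% sets[[r]], logical(1))]
    lfc <- vapply(in_regions, function(r) {
      results[[r]]$log2fc[match(g, results[[r]]$gene_id)]
    }, numeric(1))
    signs <- sign(lfc)
    tibble(
      gene = g,
      regions = paste(in_regions, collapse = "&"),
      n_regions = length(in_regions),
      has_zero = any(signs == 0),
      concordant = !any(signs == 0) && length(unique(signs)) == 1
    )
  })
  n_zero <- if (nrow(shared)) sum(shared$has_zero) else 0L
  n_eval <- nrow(shared) - n_zero
  n_same <- if (nrow(shared)) sum(shared$concordant) else 0L
  list(
    overlaps = overlaps,
    shared = shared,
    n_shared = nrow(shared),
    n_same_direction = n_same,
    concordance = if (n_eval > 0) n_same / n_eval else NA_real_,
    inverted_genes = if (nrow(shared)) shared$gene[!shared$concordant & !shared$has_zero] else character(),
    zero_lfc_genes = if (nrow(shared)) shared$gene[shared$has_zero] else character()
  )
}
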