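#' Counts per million
#'
#' `cpm[g, s] = counts[g, s] * 1e6 / library size of s`, with library size the
#' column sum.
#'
#' @param counts Genes x samples count matrix with dimnames.
#' @return A numeric matrix of the same shape.
#' @export
compute_cpm <- function(counts) {
  assert_count_matrix(counts)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    abort(sprintf("zero library size for sample(s): %s.",
                  toString(colnames(counts)[lib == 0])))
  }
  sweep(counts, 2, lib, "/") * 1e6
}

#' Filter to expressed genes by a group-wise CPM rule
#'
#' A gene is kept if, in at least one group (case or control), the fraction of
#' samples with CPM at or above `min_cpm` is at least `min_frac`. With the
#' defaults this is the "at least 0.3 CPM in 50% of the samples of a group"
#' rule common in low-input bulk RNA-seq.
#'
#' @param counts Genes x samples count matrix.
#' @param metadata Sample metadata with `sample_id` and `group`.
#' @param min_cpm CPM threshold (default 0.3).
#' @param min_frac Required within-group fraction of samples (default 0.5);
#'   the boundary is inclusive (`>=`).
#'
#' @return A list with `counts` (the filtered matrix), `kept_genes`,
#'   `n_before` and `n_after`.
#' @export
filter_expressed <- function(counts, metadata, min_cpm = 0.3, min_frac = 0.5) {
  assert_count_matrix(counts)
  assert_metadata(metadata, colnames(counts))
  meta <- metadata[match(colnames(counts), metadata$sample_id), ]
  for (g in c("case", "control")) {
    if (!any(meta$group == g)) abort(sprintf("group `%s` has no samples.", g))
  }
  cpm <- compute_cpm(counts)
  ok <- rep(FALSE, nrow(counts))
  for (g in c("case", "control")) {
    cols <- meta$group == g
    frac <- rowMeans(cpm[, cols, drop = FALSE] >= min_cpm)
    ok <- ok | (frac >= min_frac)
  }
  list(
    counts = counts[ok, , drop = FALSE],
    kept_genes = rownames(counts)[ok],
    n_before = nrow(counts),
    n_after = sum(ok)
  )
}

#' Size-factor normalized log2 expression
#'
#' Scales each sample by its median-of-ratios size factor (see
#' [estimate_size_factors()]), converts to a common counts-per-million scale
#' using the geometric-mean library size of the scaled matrix, and returns
#' `log2(scaled CPM + pseudocount)`. This yields a variance-stabilized
#' log-scale matrix suitable for correlation networks; scaling one sample's
#' counts by a constant leaves its normalized values unchanged.
#'
#' @param counts Genes x samples count matrix (normally already filtered).
#' @param pseudocount Added before the log (default 0.5).
#'
#' @return A list with `values` (log2 matrix) and `size_factors`.
#' @export
normalize_log <- function(counts, pseudocount = 0.5) {
  assert_count_matrix(counts)
  sf <- estimate_size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  scale_lib <- geometric_mean(colSums(norm))
  values <- log2(norm * 1e6 / scale_lib + pseudocount)
  list(values = values, size_factors = sf)
}

build_model_matrix <- function(metadata, terms) {
  terms <- terms[terms %in% names(metadata)]
  f <- if (length(terms)) {
    stats::reformulate(terms)
  } else {
    ~1
  }
  X <- model.matrix(f, data = metadata)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    abort(sprintf("design matrix is rank deficient; collinear column(s): %s.",
                  toString(bad)))
  }
  X
}

#' Estimate surrogate variables by residual SVD with parallel analysis
#'
#' Hidden-covariate estimation in two steps: (1) regress every gene on the
#' full model (primary variable plus adjustment variables) and keep the
#' residual matrix; (2) take its right singular vectors as surrogate-variable
#' candidates. When `n_sv = "auto"`, the number retained is chosen by
#' permutation parallel analysis: each gene's expression values are permuted
#' independently across samples (`n_perm` times), the permuted matrix is
#' residualized on the same design (so observed and null spectra live in the
#' same residual subspace), and the k-th observed singular value must exceed
#' the 95th percentile of the permuted k-th singular values; the count of
#' leading components passing is k (stopping at the first failure).
#'
#' Because the primary variable is part of the regression, the returned
#' surrogate variables are near-orthogonal to the primary contrast.
#'
#' @param expr Genes x samples log-expression matrix.
#' @param metadata Sample metadata; rows are matched to `colnames(expr)`.
#' @param primary Name of the variable of interest (kept in the model so SVs
#'   do not absorb it).
#' @param adjust Character vector of known adjustment variables.
#' @param n_sv `"auto"` or a fixed number of surrogate variables.
#' @param n_perm Permutations for parallel analysis (default 20).
#' @param seed Integer seed (permutation step only).
#'
#' @return A samples x k matrix (k may be 0) with columns `SV1`, `SV2`, ...
#' @export
estimate_surrogate_variables <- function(expr, metadata, primary = "group",
                                         adjust = character(), n_sv = "auto",
                                         n_perm = 20, seed = 1L) {
  assert_metadata(metadata, colnames(expr))
  meta <- metadata[match(colnames(expr), metadata$sample_id), ]
  X <- build_model_matrix(meta, c(primary, adjust))
  n <- ncol(expr)
  fit <- lm.fit(X, t(expr))
  R <- fit$residuals                      # samples x genes
  max_k <- n - qr(X)$rank
  if (identical(n_sv, "auto")) {
    sv_obs <- svd(R, nu = 0, nv = 0)$d
    hat <- X %*% solve(crossprod(X), t(X))
    E <- t(expr)                          # samples x genes
    perm_d <- with_seed(as.integer(seed), {
      vapply(seq_len(n_perm), function(i) {
        Ep <- apply(E, 2, sample)         # permute each gene across samples
        Rp <- Ep - hat %*% Ep             # residualize exactly as observed
        svd(Rp, nu = 0, nv = 0)$d
      }, numeric(length(sv_obs)))
    })
    thresh <- apply(perm_d, 1, quantile, probs = 0.95)
    pass <- sv_obs > thresh
    k <- if (pass[1]) which.min(c(pass, FALSE)) - 1L else 0L
    k <- min(k, max_k)
  } else {
    if (!is_count(n_sv, zero_ok = TRUE)) abort("`n_sv` must be 'auto' or a count.")
    k <- min(n_sv, max_k)
  }
  if (k == 0) {
    sv <- matrix(numeric(0), nrow = n, ncol = 0)
    rownames(sv) <- colnames(expr)
    return(sv)
  }
  sv <- svd(t(R), nu = 0, nv = k)$v       # right singular vectors over samples
  dimnames(sv) <- list(colnames(expr), paste0("SV", seq_len(k)))
  sv
}

#' Per-sample quality weights
#'
#' Summarises each sample's agreement with the fitted gene-wise means: the
#' weight is the inverse of the sample's mean squared residual about the
#' model fit, normalized so the weights have geometric mean 1. Well-behaved
#' samples sit near 1; a noisy sample gets a weight below 1. This is a
#' per-sample diagnostic in the spirit of expression quality weights, not an
#' observation-level precision weight.
#'
#' @param expr Genes x samples log-expression matrix.
#' @param design Samples x p design matrix.
#'
#' @return A named per-sample weight vector.
#' @export
estimate_sample_weights <- function(expr, design) {
  if (!is.matrix(design)) design <- as.matrix(design)
  n <- ncol(expr)
  if (nrow(design) != n) abort("`design` rows must match samples.")
  if (n < ncol(design) + 1) abort("fewer samples than design columns.")
  fit <- lm.fit(design, t(expr))
  mse <- rowMeans(fit$residuals^2)
  if (all(mse < 1e-12)) {
    return(setNames(rep(1, n), colnames(expr)))
  }
  mse <- pmax(mse, 1e-12)
  w <- 1 / mse
  w <- w / geometric_mean(w)
  setNames(w, colnames(expr))
}

#' Compare two weight distributions (two-sample KS)
#'
#' Kolmogorov-Smirnov two-sample statistic with the asymptotic p-value, plus
#' the mean, variance and median of each weight vector — the diagnostic used
#' to check whether adding surrogate variables changes the sample-weight
#' distribution.
#'
#' @param w1,w2 Numeric weight vectors.
#' @return A one-row tibble with `ks_statistic`, `p`, and per-vector
#'   `mean`/`var`/`median`.
#' @export
compare_weight_distributions <- function(w1, w2) {
  if (!length(w1) || !length(w2)) abort("both weight vectors must be non-empty.")
  ks <- suppressWarnings(ks.test(w1, w2, exact = FALSE))
  tibble(
    ks_statistic = unname(ks$statistic), p = ks$p.value,
    mean_1 = mean(w1), var_1 = var(w1), median_1 = median(w1),
    mean_2 = mean(w2), var_2 = var(w2), median_2 = median(w2)
  )
}
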