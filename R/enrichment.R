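# Gene-set enrichment: hypergeometric over-representation, randomization
# (sampling) enrichment, GWAS-style p-value filtering, and cross-study
# fold-change direction concordance.

# exact string harmonization: case-fold and strip a trailing version suffix
harmonize_ids <- function(x) {
  sub("\\.[0-9]+$", "", toupper(x))
}

#' Over-representation analysis (hypergeometric)
#'
#' For each gene set, the upper-tail hypergeometric probability of observing
#' at least the seen overlap between the query list and the set, given the
#' background universe: `P(X >= k)` with universe size `N`, set size `K`,
#' query size `n`. P-values are BH-adjusted across sets ([adjust_bh()]).
#' Gene ids are harmonized by case-folding and stripping trailing ".N"
#' version suffixes; query genes outside the background are dropped with a
#' warning, and empty sets are dropped with a warning.
#'
#' @param query Gene-id vector.
#' @param sets Named list of gene-id vectors.
#' @param background Gene-id vector (the universe).
#'
#' @return A tibble sorted by `p`: `set`, `set_size`, `overlap`,
#'   `expected`, `fold_enrichment`, `p`, `fdr`, `overlap_genes`.
#' @export
ora <- function(query, sets, background) {
  if (!length(query)) abort("`query` must be non-empty.")
  background <- unique(harmonize_ids(background))
  query <- unique(harmonize_ids(query))
  outside <- setdiff(query, background)
  if (length(outside)) {
    warn(sprintf("%d query gene(s) outside the background were dropped.",
                 length(outside)))
    query <- intersect(query, background)
  }
  if (!length(query)) abort("no query genes remain within the background.")
  sets <- lapply(sets, function(s) intersect(unique(harmonize_ids(s)), background))
  empty <- vapply(sets, function(s) length(s) == 0, logical(1))
  if (any(empty)) {
    warn(sprintf("dropped %d empty gene set(s).", sum(empty)))
    sets <- sets[!empty]
  }
  if (!length(sets)) abort("no non-empty gene sets to test.")
  N <- length(background)
  n <- length(query)
  res <- purrr::imap_dfr(sets, function(s, name) {
    K <- length(s)
    hits <- intersect(query, s)
    k <- length(hits)
    expected <- n * K / N
    tibble(
      set = name, set_size = K, overlap = k, expected = expected,
      fold_enrichment = if (expected > 0) k / expected else NA_real_,
      p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
      overlap_genes = list(hits)
    )
  })
  res$fdr <- adjust_bh(res$p)
  res <- res[order(res$p), c("set", "set_size", "overlap", "expected",
                             "fold_enrichment", "p", "fdr", "overlap_genes")]
  res
}

#' Randomization (sampling) enrichment test
#'
#' Draws `n_iter` gene lists of the query's size uniformly without replacement
#' from the background and compares their overlap with the target set to the
#' observed overlap. The empirical p-value uses the add-one correction,
#' `p = (1 + #{draws with overlap >= observed}) / (n_iter + 1)`, so it is
#' always positive.
#'
#' @param query Gene-id vector.
#' @param set Target gene-id vector.
#' @param background Gene-id vector (universe).
#' @param n_iter Number of random draws (default 10000; fewer than 100 draws
#'   warns).
#' @param seed Integer seed.
#'
#' @return A one-row tibble: `overlap`, `expected`, `p`, `n_iter`, plus the
#'   null overlap counts in `null_overlaps` (list column).
#' @export
mset <- function(query, set, background, n_iter = 10000, seed = 1L) {
  background <- unique(harmonize_ids(background))
  query <- intersect(unique(harmonize_ids(query)), background)
  set <- intersect(unique(harmonize_ids(set)), background)
  if (!length(query)) abort("`query` has no genes in the background.")
  if (length(query) > length(background)) abort("query larger than background.")
  if (n_iter < 100) warn("`n_iter` < 100 gives a very coarse empirical p-value.")
  observed <- length(intersect(query, set))
  in_set <- background %in% set
  null_overlaps <- with_seed(as.integer(seed), {
    vapply(seq_len(n_iter), function(i) {
      sum(in_set[sample.int(length(background), length(query))])
    }, numeric(1))
  })
  tibble(
    overlap = observed,
    expected = length(query) * length(set) / length(background),
    p = (1 + sum(null_overlaps >= observed)) / (n_iter + 1),
    n_iter = n_iter,
    null_overlaps = list(null_overlaps)
  )
}

#' Filter an association table to significant genes
#'
#' Keeps genes with `p < threshold` (strictly below, so `p == 1e-5` is
#' excluded at the default), collapses duplicates, and skips malformed rows
#' (missing gene or non-finite p) with a logged count.
#'
#' @param assoc Data frame with columns `gene` and `p`.
#' @param threshold Significance cutoff (default `1e-5`).
#'
#' @return A unique gene-id vector.
#' @export
gwas_gene_filter <- function(assoc, threshold = 1e-5) {
  if (!all(c("gene", "p") %in% names(assoc))) {
    abort("`assoc` must have columns `gene` and `p`.")
  }
  bad <- is.na(assoc$gene) | assoc$gene == "" | !is.finite(assoc$p)
  if (any(bad)) {
    inform(sprintf("skipped %d malformed row(s).", sum(bad)))
    assoc <- assoc[!bad, ]
  }
  unique(assoc$gene[assoc$p < threshold])
}

#' Cross-study log2 fold-change direction concordance
#'
#' For genes shared by two DE result lists, counts how many have fold changes
#' of the same sign. Genes with a zero fold change in either study are counted
#' as neither concordant nor discordant and reported separately.
#'
#' @param lfc_a,lfc_b Named numeric vectors (gene -> log2 fold change).
#'
#' @return A list: `n_shared`, `n_same_direction`, `fraction`,
#'   `inverted_genes`, `zero_lfc_genes`.
#' @export
cross_study_concordance <- function(lfc_a, lfc_b) {
  shared <- intersect(names(lfc_a), names(lfc_b))
  if (!length(shared)) abort("no shared genes between the two lists.")
  sa <- sign(lfc_a[shared])
  sb <- sign(lfc_b[shared])
  zero <- sa == 0 | sb == 0
  same <- !zero & (sa * sb > 0)
  list(
    n_shared = length(shared),
    n_same_direction = sum(same),
    fraction = if (any(!zero)) sum(same) / sum(!zero) else NA_real_,
    inverted_genes = shared[!zero & !same],
    zero_lfc_genes = shared[zero]
  )
}
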