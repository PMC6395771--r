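#' Gene-gene Pearson correlation matrix
#'
#' Pairwise-complete Pearson correlation between all gene pairs, after
#' removing genes with more than `max_na_frac` missing values. Zero-variance
#' genes get correlation 0 against everything (flagged), so they cannot
#' attach to modules.
#'
#' @param expr Genes x samples log-expression matrix (may contain `NA`).
#' @param max_na_frac Maximum tolerated per-gene missing fraction (default
#'   0.5).
#'
#' @return A list with `cor` (genes x genes), `removed_genes`, and
#'   `zero_variance_genes`.
#' @export
correlation_matrix <- function(expr, max_na_frac = 0.5) {
  if (ncol(expr) < 3) abort("at least 3 samples are required.")
  na_frac <- rowMeans(is.na(expr))
  removed <- rownames(expr)[na_frac > max_na_frac]
  keep <- expr[na_frac <= max_na_frac, , drop = FALSE]
  v <- apply(keep, 1, var, na.rm = TRUE)
  zero_var <- rownames(keep)[!is.na(v) & v == 0]
  cmat <- suppressWarnings(cor(t(keep), use = "pairwise.complete.obs"))
  if (length(zero_var)) {
    cmat[zero_var, ] <- 0
    cmat[, zero_var] <- 0
  }
  cmat[is.na(cmat)] <- 0
  diag(cmat) <- 1
  list(cor = cmat, removed_genes = removed, zero_variance_genes = zero_var)
}

#' Soft-threshold (power) adjacency
#'
#' Unsigned weighted adjacency `a_ij = |cor_ij|^beta`, unit diagonal. Raising
#' the power suppresses weak correlations so the connectivity distribution
#' approaches a scale-free law.
#'
#' @param cor_matrix Symmetric correlation matrix.
#' @param beta Soft-threshold power, `>= 1`.
#' @return The adjacency matrix with attribute `beta`.
#' @export
adjacency <- function(cor_matrix, beta) {
  if (!is.numeric(beta) || length(beta) != 1 || beta < 1) {
    abort("`beta` must be a single power >= 1.")
  }
  a <- abs(cor_matrix)^beta
  diag(a) <- 1
  attr(a, "beta") <- beta
  a
}

#' Scale-free topology fit across candidate powers
#'
#' For each candidate power, computes the connectivity
#' `k_i = sum_{j != i} a_ij`, bins it into `n_bins` equal-width bins, and
#' regresses `log10(bin frequency)` on `log10(mean k in bin)` over non-empty
#' bins; the R^2 of that regression is the scale-free fit index. (Equal-width
#' binning is essential: equal-count bins have constant frequency by
#' construction, which makes the fit index degenerate.) The chosen power is
#' the smallest with `R^2 >= r2_min`; if none qualifies the power with the
#' best fit is returned with a warning.
#'
#' @param expr Genes x samples log-expression matrix (>= 50 genes).
#' @param betas Candidate powers (default 1:20).
#' @param r2_min Required fit (default 0.8).
#' @param n_bins Connectivity histogram bins (default 10).
#'
#' @return A list with `beta` (chosen power), `fit_table` (tibble of `beta`,
#'   `r_squared`, `slope`, `mean_connectivity`), and `reached_r2`.
#' @export
pick_soft_threshold <- function(expr, betas = 1:20, r2_min = 0.8, n_bins = 10) {
  if (nrow(expr) < 50) abort("at least 50 genes are needed for a degree distribution.")
  cm <- correlation_matrix(expr)$cor
  fit_one <- function(beta) {
    a <- adjacency(cm, beta)
    k <- rowSums(a) - 1
    if (sd(k) == 0 || all(k <= 0)) {
      return(tibble(beta = beta, r_squared = 0, slope = NA_real_,
                    mean_connectivity = mean(k), degenerate = TRUE))
    }
    k_pos <- k[k > 0]
    bin <- cut(k_pos, breaks = n_bins, include.lowest = TRUE)
    freq <- tapply(k_pos, bin, length)
    mean_k <- tapply(k_pos, bin, mean)
    ok <- !is.na(freq) & freq > 0
    if (sum(ok) < 3) {
      return(tibble(beta = beta, r_squared = 0, slope = NA_real_,
                    mean_connectivity = mean(k), degenerate = TRUE))
    }
    fit <- lm(log10(freq[ok]) ~ log10(mean_k[ok]))
    tibble(beta = beta,
           r_squared = summary(fit)$r.squared,
           slope = coef(fit)[2],
           mean_connectivity = mean(k),
           degenerate = FALSE)
  }
  fit_table <- purrr::map_dfr(betas, fit_one)
  qualify <- fit_table$beta[fit_table$r_squared >= r2_min]
  if (length(qualify)) {
    chosen <- min(qualify)
    reached <- TRUE
  } else {
    chosen <- fit_table$beta[which.max(fit_table$r_squared)]
    reached <- FALSE
    warn(sprintf("no power reached R^2 >= %.2f; returning the best fit (beta = %d).",
                 r2_min, chosen))
  }
  list(beta = chosen, fit_table = fit_table, reached_r2 = reached)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for `i != j`, with
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`;
#' `TOM_ii = 1`. High topological overlap means two genes share neighbours as
#' well as a direct edge; `1 - TOM` is the module-detection dissimilarity.
#'
#' @param adj Symmetric adjacency matrix in `[0, 1]` with unit diagonal.
#' @return The TOM similarity matrix.
#' @export
tom_similarity <- function(adj) {
  if (!isSymmetric(unname(adj), tol = 1e-10)) abort("adjacency must be symmetric.")
  a <- adj
  diag(a) <- 0
  l <- a %*% a                       # l_ij = sum_u a_iu a_uj, u != i,j given zero diag
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect modules by average-linkage clustering of TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut by a
#' deterministic static height sweep: candidate heights run from 0.99 of the
#' tallest merge downward over the tree's merge heights; at each height the
#' clusters of size `>= min_size` are the candidate modules. The chosen
#' height maximizes the number of such modules, with ties broken by the
#' number of genes they cover and then by the larger height — counting
#' modules first keeps distinct modules from being absorbed into one
#' background-inflated cluster near the top of the tree. Genes outside any
#' module get label 0. Modules are relabelled 1, 2, ... by decreasing size.
#'
#' @param dissimilarity Square symmetric dissimilarity matrix (typically
#'   `1 - tom_similarity(...)`).
#' @param min_size Minimum module size (default 500, matching genome-scale
#'   runs; use ~30 for small simulations).
#'
#' @return A list with `labels` (named integer vector, 0 = unassigned),
#'   `module_sizes`, `cut_height`, and the `hclust` tree.
#' @export
detect_modules <- function(dissimilarity, min_size = 500) {
  n <- nrow(dissimilarity)
  if (n != ncol(dissimilarity)) abort("dissimilarity must be square.")
  tree <- hclust(as.dist(dissimilarity), method = "average")
  # ties can leave sub-epsilon height inversions that cutree rejects
  tree$height <- cummax(tree$height)
  if (min_size > n) {
    warn("`min_size` exceeds the number of genes; all genes unassigned.")
    labels <- setNames(integer(n), rownames(dissimilarity))
    return(list(labels = labels, module_sizes = integer(), cut_height = NA_real_,
                tree = tree))
  }
  hmax <- max(tree$height)
  if (hmax <= 0) {
    # all genes identical: one module
    labels <- setNames(rep(1L, n), rownames(dissimilarity))
    return(list(labels = labels, module_sizes = setNames(n, "1"),
                cut_height = 0, tree = tree))
  }
  cap <- 0.99 * hmax
  heights <- sort(unique(c(tree$height[tree$height <= cap], cap)), decreasing = TRUE)
  cuts <- cutree(tree, h = heights)                # n x length(heights)
  score <- vapply(seq_along(heights), function(j) {
    sizes <- tabulate(cuts[, j])
    big <- sizes[sizes >= min_size]
    c(n_modules = length(big), coverage = sum(big))
  }, numeric(2))
  best_n <- score["n_modules", ] == max(score["n_modules", ])
  best_cov <- score["coverage", ] == max(score["coverage", best_n])
  best <- which(best_n & best_cov)[1]              # first = largest height on ties
  h_best <- heights[best]
  assign <- cuts[, best]
  sizes <- tabulate(assign)
  keep <- which(sizes >= min_size)
  labels <- integer(n)
  if (length(keep)) {
    keep <- keep[order(sizes[keep], decreasing = TRUE)]
    for (i in seq_along(keep)) labels[assign == keep[i]] <- i
  }
  names(labels) <- rownames(dissimilarity)
  sizes_out <- table(labels[labels > 0])
  list(
    labels = labels,
    module_sizes = setNames(as.integer(sizes_out), names(sizes_out)),
    cut_height = h_best,
    tree = tree
  )
}

#' Module eigengenes
#'
#' The eigengene of a module is the first right-singular vector of the
#' gene-standardized module submatrix across samples (its first principal
#' component), sign-oriented so that the mean correlation of member genes
#' with it is non-negative. The variance explained by that component is
#' reported per module.
#'
#' @param expr Genes x samples log-expression matrix.
#' @param labels Named gene -> module integer vector (0 = unassigned).
#'
#' @return A list with `values` (samples x modules matrix, columns `ME1`,
#'   ...) and `variance_explained`.
#' @export
module_eigengenes <- function(expr, labels) {
  labels <- labels[rownames(expr)]
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) abort("no modules to summarize.")
  me <- matrix(NA_real_, nrow = ncol(expr), ncol = length(mods),
               dimnames = list(colnames(expr), paste0("ME", mods)))
  ve <- setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    genes <- names(labels)[labels == mods[i]]
    if (length(genes) < 2) abort(sprintf("module %d has fewer than 2 genes.", mods[i]))
    sub <- expr[genes, , drop = FALSE]
    sds <- apply(sub, 1, sd)
    if (all(sds == 0)) abort(sprintf("module %d contains only constant genes.", mods[i]))
    if (any(sds == 0)) sub <- sub[sds > 0, , drop = FALSE]
    z <- t(scale(t(sub)))
    sv <- svd(t(z), nu = 1, nv = 0)
    e <- sv$u[, 1]
    if (mean(cor(t(sub), e)) < 0) e <- -e
    me[, i] <- e
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(values = me, variance_explained = ve)
}

#' Module membership (kME)
#'
#' `kME[g, m]` is the Pearson correlation of gene g's expression with module
#' m's eigengene. Constant genes get kME 0 and are flagged.
#'
#' @param expr Genes x samples log-expression matrix.
#' @param me Samples x modules eigengene matrix (from [module_eigengenes()]).
#'
#' @return A list with `values` (genes x modules kME matrix) and
#'   `constant_genes`.
#' @export
kme <- function(expr, me) {
  if (nrow(me) != ncol(expr)) abort("eigengene samples must match expression samples.")
  sds <- apply(expr, 1, sd)
  constant <- rownames(expr)[sds == 0]
  k <- suppressWarnings(cor(t(expr), me))
  k[is.na(k)] <- 0
  list(values = k, constant_genes = constant)
}

#' Build a coexpression network end to end
#'
#' Convenience wrapper: correlation -> (optional) soft-threshold selection ->
#' adjacency -> TOM -> module detection -> eigengenes -> kME.
#'
#' @param expr Genes x samples log-expression matrix.
#' @param beta `"auto"` (choose by scale-free fit) or a fixed power.
#' @param r2_min Scale-free fit threshold when `beta = "auto"`.
#' @param min_size Minimum module size.
#' @param max_na_frac Per-gene missingness tolerance.
#'
#' @return A list of class `coexpression_network` with `cor`, `beta`,
#'   `adjacency`, `tom`, `labels`, `module_sizes`, `me`, `kme`, and
#'   `soft_threshold` (fit table when `beta = "auto"`).
#' @export
build_network <- function(expr, beta = "auto", r2_min = 0.8, min_size = 500,
                          max_na_frac = 0.5) {
  cm <- correlation_matrix(expr, max_na_frac = max_na_frac)
  soft <- NULL
  if (identical(beta, "auto")) {
    soft <- pick_soft_threshold(expr[rownames(cm$cor), , drop = FALSE], r2_min = r2_min)
    beta <- soft$beta
  }
  adj <- adjacency(cm$cor, beta)
  tom <- tom_similarity(adj)
  part <- detect_modules(1 - tom, min_size = min_size)
  me <- if (any(part$labels > 0)) {
    module_eigengenes(expr[names(part$labels), , drop = FALSE], part$labels)
  } else NULL
  km <- if (!is.null(me)) kme(expr[names(part$labels), , drop = FALSE], me$values) else NULL
  structure(
    list(
      cor = cm$cor, beta = beta, adjacency = adj, tom = tom,
      labels = part$labels, module_sizes = part$module_sizes,
      cut_height = part$cut_height,
      me = me, kme = km, soft_threshold = soft,
      removed_genes = cm$removed_genes
    ),
    class = "coexpression_network"
  )
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("<coexpression_network> %d genes, beta = %s\n",
              length(x$labels), format(x$beta)))
  cat(sprintf("  modules (size): %s; unassigned: %d\n",
              if (length(x$module_sizes)) {
                paste(sprintf("%s (%d)", names(x$module_sizes), x$module_sizes),
                      collapse = ", ")
              } else "none",
              sum(x$labels == 0)))
  invisible(x)
}
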