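#' Identify hub genes of a module in one condition
#'
#' A module gene is a hub when the absolute Pearson correlation between its
#' expression and the module eigengene (its `|kME|`) is at or above
#' `threshold`, computed on that condition's own data — so the case-side
#' eigengene is recomputed on case expression, and hub loss reflects case
#' connectivity. Constant genes are excluded with a flag.
#'
#' @param expr Genes x samples expression matrix for one condition.
#' @param module_genes Gene ids of the module.
#' @param threshold Absolute-kME hub cutoff (default 0.9).
#'
#' @return A list with `hubs` (gene ids), `kme` (named vector over module
#'   genes), and `constant_genes`.
#' @export
identify_hubs <- function(expr, module_genes, threshold = 0.9) {
  module_genes <- intersect(module_genes, rownames(expr))
  if (!length(module_genes)) abort("no module genes present in the expression matrix.")
  sub <- expr[module_genes, , drop = FALSE]
  eg <- eigengene_of(sub)
  if (is.null(eg)) abort("module contains only constant genes.")
  k <- suppressWarnings(cor(t(sub), eg$e))[, 1]
  constant <- module_genes[is.na(k)]
  k[is.na(k)] <- 0
  list(
    hubs = module_genes[!module_genes %in% constant & abs(k) >= threshold],
    kme = setNames(k, module_genes),
    constant_genes = constant
  )
}

#' Hub conservation between conditions
#'
#' Splits the union of control and case hub sets into hubs exclusive to
#' controls, shared hubs, and hubs exclusive to cases.
#'
#' @param hubs_control,hubs_case Gene-id vectors.
#' @return A list with the three gene sets and their counts
#'   (`n_exclusive_control`, `n_shared`, `n_exclusive_case`).
#' @export
hub_conservation <- function(hubs_control, hubs_case) {
  shared <- intersect(hubs_control, hubs_case)
  list(
    exclusive_control = setdiff(hubs_control, shared),
    shared = shared,
    exclusive_case = setdiff(hubs_case, shared),
    n_exclusive_control = length(setdiff(hubs_control, shared)),
    n_shared = length(shared),
    n_exclusive_case = length(setdiff(hubs_case, shared))
  )
}

#' Hub report for a module
#'
#' Convenience wrapper computing per-condition hubs ([identify_hubs()]) and
#' their conservation ([hub_conservation()]) for one module.
#'
#' @param expr_control,expr_case Per-condition genes x samples matrices.
#' @param module_genes Gene ids of the module.
#' @param module Module id recorded in the report.
#' @param threshold Absolute-kME hub cutoff (default 0.9).
#'
#' @return A `hub_report` list: `module`, `hubs_control`, `hubs_case`,
#'   the conservation split, and per-condition kME vectors.
#' @export
hub_report <- function(expr_control, expr_case, module_genes, module = NA,
                       threshold = 0.9) {
  hc <- identify_hubs(expr_control, module_genes, threshold)
  ha <- identify_hubs(expr_case, module_genes, threshold)
  cons <- hub_conservation(hc$hubs, ha$hubs)
  structure(
    c(list(module = module, module_genes = module_genes,
           hubs_control = hc$hubs, hubs_case = ha$hubs,
           kme_control = hc$kme, kme_case = ha$kme,
           threshold = threshold),
      cons),
    class = "hub_report"
  )
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf(
    "<hub_report> module %s: %d genes; hubs: %d control-exclusive, %d shared, %d case-exclusive (|kME| >= %.2f)\n",
    format(x$module), length(x$module_genes),
    x$n_exclusive_control, x$n_shared, x$n_exclusive_case, x$threshold
  ))
  invisible(x)
}

#' Overlap of module DEGs with hub status
#'
#' Intersects the module's genes with a DEG set and annotates every
#' overlapping gene with its hub status in each condition.
#'
#' @param report A [hub_report()].
#' @param degs Gene-id vector (typically the relaxed DEG set).
#'
#' @return A tibble with `gene`, `hub_in_control`, `hub_in_case`.
#' @export
hub_deg_overlap <- function(report, degs) {
  genes <- intersect(report$module_genes, degs)
  tibble(
    gene = genes,
    hub_in_control = genes %in% report$hubs_control,
    hub_in_case = genes %in% report$hubs_case
  )
}
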