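# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' Tidy a module preservation result
#'
#' @param x A [module_preservation()] object.
#' @param ... Unused.
#' @return The per-module summary tibble (`module`, `size`, `z_density`,
#'   `z_connectivity`, `zsummary`, `median_rank`).
#' @exportS3Method generics::tidy
tidy.module_preservation <- function(x, ...) {
  x$stats
}

#' One-row summary of a module preservation result
#'
#' @param x A [module_preservation()] object.
#' @param ... Unused.
#' @return A one-row tibble: module count, permutations, power, the module ids
#'   least preserved by each criterion.
#' @exportS3Method generics::glance
glance.module_preservation <- function(x, ...) {
  tibble(
    n_modules = nrow(x$stats),
    n_perm = x$n_perm,
    beta = x$beta,
    least_by_zsummary = x$stats$module[which.min(x$stats$zsummary)],
    least_by_median_rank = x$stats$module[which.max(x$stats$median_rank)],
    min_zsummary = min(x$stats$zsummary),
    max_median_rank = max(x$stats$median_rank)
  )
}

#' Tidy a coexpression network
#'
#' @param x A [build_network()] object.
#' @param ... Unused.
#' @return A tibble with `gene`, `module` and the gene's own-module `kme`
#'   (`NA` for unassigned genes).
#' @exportS3Method generics::tidy
tidy.coexpression_network <- function(x, ...) {
  own_kme <- rep(NA_real_, length(x$labels))
  if (!is.null(x$kme)) {
    for (m in unique(x$labels[x$labels > 0])) {
      idx <- which(x$labels == m)
      own_kme[idx] <- x$kme$values[names(x$labels)[idx], paste0("ME", m)]
    }
  }
  tibble(gene = names(x$labels), module = unname(x$labels), kme = own_kme)
}

#' Tidy a hub report
#'
#' @param x A [hub_report()] object.
#' @param ... Unused.
#' @return Per module gene: kME in each condition and hub flags.
#' @exportS3Method generics::tidy
tidy.hub_report <- function(x, ...) {
  g <- x$module_genes
  tibble(
    gene = g,
    kme_control = unname(x$kme_control[g]),
    kme_case = unname(x$kme_case[g]),
    hub_in_control = g %in% x$hubs_control,
    hub_in_case = g %in% x$hubs_case
  )
}

#' Preservation statistics plot (medianRank and Zsummary vs module size)
#'
#' Two panels in the conventional layout: each module is a labelled point;
#' in the medianRank panel the least preserved module sits highest, in the
#' Zsummary panel it sits lowest. Dashed guides mark the weak (2) and strong
#' (10) preservation levels on the Zsummary scale.
#'
#' @param object A [module_preservation()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.module_preservation <- function(object, ...) {
  s <- object$stats
  long <- tidyr::pivot_longer(
    s[, c("module", "size", "zsummary", "median_rank")],
    cols = c("zsummary", "median_rank"),
    names_to = "statistic", values_to = "value"
  )
  long$statistic <- factor(long$statistic, levels = c("median_rank", "zsummary"),
                           labels = c("medianRank", "Zsummary"))
  guides <- tibble(statistic = factor("Zsummary",
                                      levels = c("medianRank", "Zsummary")),
                   y = c(2, 10))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$size, y = .data$value)) +
    ggplot2::geom_hline(data = guides,
                        ggplot2::aes(yintercept = .data$y),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$module),
                       vjust = -0.8, size = 3) +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "module size (genes)", y = NULL,
                  title = "Module preservation")
}

#' kME scatter for one module (reference vs test)
#'
#' Each point is one module gene; the axes are its own-module kME in the
#' reference (control) and test (case) data. A preserved module hugs the
#' diagonal; a disrupted one collapses to a horizontal cloud near zero.
#'
#' @param preservation A [module_preservation()] object.
#' @param module Module id to display.
#' @return A ggplot object.
#' @export
plot_kme_scatter <- function(preservation, module) {
  km <- preservation$kme[[as.character(module)]]
  if (is.null(km)) abort(sprintf("module `%s` not found.", format(module)))
  d <- tibble(kme_ref = unname(km$ref), kme_test = unname(km$test))
  r <- module_kme_correlation(km$ref, km$test)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$kme_ref, y = .data$kme_test)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.5) +
    ggplot2::labs(
      x = "kME (control)", y = "kME (case)",
      title = sprintf("Module %s kME correlation", format(module)),
      subtitle = sprintf("n = %d, cor = %.3f, p = %.3g", r$n, r$r, r$p)
    )
}

#' Scale-free topology fit plot
#'
#' R-squared of the log-log connectivity fit across candidate soft-threshold
#' powers, with the usual 0.8 guide.
#'
#' @param soft A [pick_soft_threshold()] result.
#' @param r2_min Guide level (default 0.8).
#' @return A ggplot object.
#' @export
plot_soft_threshold <- function(soft, r2_min = 0.8) {
  ggplot2::ggplot(soft$fit_table,
                  ggplot2::aes(x = .data$beta, y = .data$r_squared)) +
    ggplot2::geom_hline(yintercept = r2_min, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "soft-threshold power", y = expression(R^2),
                  title = "Scale-free topology fit")
}
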