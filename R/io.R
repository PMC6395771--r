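# Tab-separated and GMT readers/writers. Counts round-trip exactly (integers);
# real-valued tables round-trip to full double precision.

#' Read a genes x samples count matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#'
#' @param path File path.
#' @return An integer-mode numeric matrix with dimnames.
#' @export
read_counts <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tbl) < 2) abort("count table needs a gene-id column plus >= 1 sample.")
  genes <- as.character(tbl[[1]])
  if (anyDuplicated(genes)) {
    dup <- which(duplicated(genes))
    abort(sprintf("duplicate gene id(s) at data line(s): %s.",
                  toString(head(dup, 5))))
  }
  m <- as.matrix(tbl[, -1])
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)
    abort(sprintf("missing/ragged values at data line(s): %s.",
                  toString(head(bad, 5))))
  }
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Write a count matrix as TSV
#' @param counts Genes x samples matrix.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  tbl <- tibble::as_tibble(counts, rownames = "gene_id")
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Requires at least `sample_id` and `group` columns; `group` must be
#' `case`/`control`.
#'
#' @param path File path.
#' @param sample_ids Optional sample ids that must all be present.
#' @return A tibble.
#' @export
read_metadata <- function(path, sample_ids = NULL) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta <- tibble::as_tibble(as.data.frame(meta))
  assert_metadata(meta, sample_ids)
  meta
}

#' Write sample metadata as TSV
#' @param metadata Data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  readr::write_tsv(metadata, path, progress = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>...`.
#'
#' @param path File path.
#' @return A named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    sets <- fgsea::gmtPathways(path)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(vapply(fields, length, integer(1)) < 3)
    if (length(short)) {
      abort(sprintf("GMT line(s) with fewer than 3 fields: %s.",
                    toString(head(short, 5))))
    }
    sets <- lapply(fields, function(f) f[-(1:2)])
    names(sets) <- vapply(fields, `[[`, character(1), 1)
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of gene-id vectors.
#' @param path File path.
#' @param descriptions Optional per-set description strings (defaults to the
#'   set names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  if (is.null(names(sets))) abort("`sets` must be named.")
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write the main pipeline result tables under a directory
#'
#' Emits, per region, the DE table, module assignment, preservation summary
#' and hub report as TSV, plus the cross-region summary.
#'
#' @param report A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (r in names(report$regions)) {
    reg <- report$regions[[r]]
    readr::write_tsv(reg$de, file.path(out_dir, paste0(r, "_diffexp.tsv")),
                     progress = FALSE)
    readr::write_tsv(
      tibble(gene = names(reg$network$labels), module = reg$network$labels),
      file.path(out_dir, paste0(r, "_modules.tsv")), progress = FALSE
    )
    readr::write_tsv(reg$preservation$stats,
                     file.path(out_dir, paste0(r, "_preservation.tsv")),
                     progress = FALSE)
    readr::write_tsv(reg$selection$candidates,
                     file.path(out_dir, paste0(r, "_selection.tsv")),
                     progress = FALSE)
  }
  readr::write_tsv(report$summary, file.path(out_dir, "summary.tsv"),
                   progress = FALSE)
  invisible(out_dir)
}
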