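# Internal validation and small numeric helpers.

assert_count_matrix <- function(counts, arg = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort(sprintf("`%s` must be a numeric genes x samples matrix.", arg))
  }
  if (any(counts < 0)) abort(sprintf("`%s` contains negative values.", arg))
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort(sprintf("`%s` must carry gene ids (rownames) and sample ids (colnames).", arg))
  }
  if (anyDuplicated(rownames(counts))) {
    abort(sprintf("`%s` has duplicated gene ids.", arg))
  }
  if (anyDuplicated(colnames(counts))) {
    abort(sprintf("`%s` has duplicated sample ids.", arg))
  }
  invisible(counts)
}

assert_metadata <- function(meta, sample_ids = NULL) {
  if (!is.data.frame(meta)) abort("`meta` must be a data frame.")
  needed <- c("sample_id", "group")
  missing <- setdiff(needed, names(meta))
  if (length(missing)) {
    abort(sprintf("metadata is missing column(s): %s.", toString(missing)))
  }
  if (!all(meta$group %in% c("case", "control"))) {
    abort("metadata `group` must be 'case' or 'control'.")
  }
  if (!is.null(sample_ids)) {
    absent <- setdiff(sample_ids, meta$sample_id)
    if (length(absent)) {
      abort(sprintf("metadata missing sample(s): %s.", toString(head(absent, 5))))
    }
  }
  invisible(meta)
}

# scalar positive-integer check used by design validators
is_count <- function(x, zero_ok = FALSE) {
  is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == round(x) && (x > 0 || (zero_ok && x == 0))
}

geometric_mean <- function(x) exp(mean(log(x)))

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

upper_tri_values <- function(m) m[upper.tri(m)]
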