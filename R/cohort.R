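#' Wald test on the log odds ratio of a 2x2 table
#'
#' For a 2x2 contingency table with rows = group (case, control) and columns =
#' category levels, computes the odds ratio `OR = (a*d)/(b*c)`, its standard
#' error on the log scale `sqrt(1/a + 1/b + 1/c + 1/d)`, the Wald statistic
#' `z = log(OR)/se` and the two-sided normal p-value. Any zero cell triggers
#' the Haldane-Anscombe correction (+0.5 to every cell), flagged in the result.
#'
#' @param tab A 2x2 numeric matrix of non-negative counts, or a length-4
#'   vector `c(a, b, c, d)` read row-wise.
#'
#' @return A one-row tibble with `odds_ratio`, `log_or`, `se`, `z`,
#'   `p_two_sided` and `haldane_corrected`.
#' @examples
#' log_odds_ratio_wald(matrix(c(2, 3, 4, 5), 2)) # sex split in a 6 vs 8 cohort
#' @export
log_odds_ratio_wald <- function(tab) {
  if (is.vector(tab) && length(tab) == 4) tab <- matrix(tab, 2, byrow = TRUE)
  if (!is.matrix(tab) || !all(dim(tab) == c(2, 2))) {
    abort("`tab` must be a 2x2 table.")
  }
  if (any(tab < 0)) abort("counts must be non-negative.")
  if (any(rowSums(tab) == 0)) abort("each row must contain at least one count.")
  corrected <- any(tab == 0)
  if (corrected) tab <- tab + 0.5
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  se <- sqrt(sum(1 / tab))
  z <- log(or) / se
  p <- min(1, 2 * pnorm(-abs(z)))
  tibble(
    odds_ratio = or, log_or = log(or), se = se, z = z,
    p_two_sided = p, haldane_corrected = corrected
  )
}

#' Mood's median test
#'
#' Classifies every observation against the pooled grand median (values equal
#' to it count as "at or below") and applies Fisher's exact test to the
#' resulting 2x2 table — appropriate at the very small group sizes of a
#' postmortem cohort. If all values tie at the grand median the test is
#' degenerate and `p = 1` is returned with a warning.
#'
#' @param x,y Numeric vectors for the two groups.
#'
#' @return A one-row tibble with the 2x2 cell counts, the grand median and the
#'   exact two-sided `p`.
#' @export
median_test <- function(x, y) {
  if (!length(x) || !length(y)) abort("both samples must be non-empty.")
  pooled <- c(x, y)
  gm <- median(pooled)
  above <- c(sum(x > gm), sum(y > gm))
  below <- c(sum(x <= gm), sum(y <= gm))
  if (all(above == 0)) {
    warn("all values tied at the grand median; median test is degenerate.")
    p <- 1
  } else {
    p <- fisher.test(rbind(above, below))$p.value
  }
  tibble(
    grand_median = gm,
    above_x = above[1], above_y = above[2],
    at_or_below_x = below[1], at_or_below_y = below[2],
    p = p
  )
}

#' Group-comparison table for cohort metadata
#'
#' Summarises each requested variable by group and attaches the matching test:
#' Mood's [median_test()] for continuous variables (reporting medians and
#' means with standard errors) and the Wald [log_odds_ratio_wald()] test for
#' two-level categorical variables (reporting `n (%)`).
#'
#' @param metadata Data frame with at least `group` (`"case"`/`"control"`) and
#'   the requested variables.
#' @param variables Named character vector mapping variable name to type,
#'   `"continuous"` or `"categorical"`.
#'
#' @return A tibble with one row per variable: `variable`, `type`, per-group
#'   summary strings, and `p`.
#' @export
cohort_table <- function(metadata, variables) {
  assert_metadata(metadata)
  groups <- unique(metadata$group)
  if (length(groups) < 2) abort("both groups must be present in `metadata`.")
  purrr::imap_dfr(variables, function(type, var) {
    if (!var %in% names(metadata)) {
      abort(sprintf("variable `%s` not found in metadata.", var))
    }
    v_case <- metadata[[var]][metadata$group == "case"]
    v_ctrl <- metadata[[var]][metadata$group == "control"]
    if (type == "continuous") {
      res <- median_test(v_case, v_ctrl)
      summ <- function(v) sprintf(
        "median %.1f, mean %.1f (%.1f)",
        median(v), mean(v), sd(v) / sqrt(length(v))
      )
      tibble(
        variable = var, type = type,
        case_summary = summ(v_case), control_summary = summ(v_ctrl),
        p = res$p
      )
    } else if (type == "categorical") {
      lev <- sort(unique(c(v_case, v_ctrl)))
      if (length(lev) != 2) {
        abort(sprintf("categorical variable `%s` must have exactly 2 levels.", var))
      }
      tab <- rbind(
        c(sum(v_case == lev[1]), sum(v_case == lev[2])),
        c(sum(v_ctrl == lev[1]), sum(v_ctrl == lev[2]))
      )
      res <- log_odds_ratio_wald(tab)
      summ <- function(r) sprintf(
        "%s %d (%.0f%%) / %s %d (%.0f%%)",
        lev[1], r[1], 100 * r[1] / sum(r), lev[2], r[2], 100 * r[2] / sum(r)
      )
      tibble(
        variable = var, type = type,
        case_summary = summ(tab[1, ]), control_summary = summ(tab[2, ]),
        p = res$p_two_sided
      )
    } else {
      abort(sprintf("unknown variable type `%s` for `%s`.", type, var))
    }
  })
}
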