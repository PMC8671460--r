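#' Two-class differential killing-activity comparison
#'
#' Per compound, compares logFC between an in-group of cell lines (e.g. one
#' tumour type) and an out-group (everything else) with Welch's
#' unequal-variance two-sample t-test. The effect size is `mean(in) -
#' mean(out)`; a compound is significant when `p < alpha` *and* the effect
#' size is negative (more killing in-group). Compounds with fewer than two
#' non-missing values in either group are skipped with a warning.
#'
#' @param data A [drug_response] or wide logFC tibble.
#' @param in_ids,out_ids Disjoint cell-line id vectors.
#' @param alpha Significance level on the raw p-value (default 0.01; no
#'   multiple-testing correction - validation is by screen intersection).
#' @return Tibble with one row per tested compound: `compound_id`,
#'   `effect_size`, `p_value`, `neg_log10_p`, `significant`.
#' @export
two_class_compare <- function(data, in_ids, out_ids, alpha = 0.01) {
  logfc <- resolve_logfc(data)
  if (length(intersect(in_ids, out_ids)) > 0) {
    abort("`in_ids` and `out_ids` must not overlap.")
  }
  m <- tbl_to_matrix(logfc, "compound_id")
  missing_cols <- setdiff(c(in_ids, out_ids), colnames(m))
  if (length(missing_cols) > 0) {
    abort(sprintf("unknown line id(s): %s", paste(missing_cols, collapse = ", ")))
  }
  a <- m[, in_ids, drop = FALSE]
  b <- m[, out_ids, drop = FALSE]
  ok <- rowSums(!is.na(a)) >= 2 & rowSums(!is.na(b)) >= 2
  if (!all(ok)) {
    warn(sprintf(
      "skipping %d compound(s) with < 2 values in a group.", sum(!ok)
    ))
  }
  rows <- purrr::map(which(ok), function(i) {
    x <- a[i, ][!is.na(a[i, ])]
    y <- b[i, ][!is.na(b[i, ])]
    eff <- mean(x) - mean(y)
    p <- if (var(x) == 0 && var(y) == 0) {
      if (eff == 0) 1 else 0
    } else {
      stats::t.test(x, y, var.equal = FALSE)$p.value
    }
    tibble::tibble(
      compound_id = rownames(m)[i],
      effect_size = eff,
      p_value = p,
      neg_log10_p = -log10(p),
      significant = p < alpha & eff < 0
    )
  })
  dplyr::bind_rows(rows)
}

#' Intersect hit sets from two screens
#'
#' Reduces each input to unique compound names (duplicated screen entries
#' collapse first) and returns the names found in both - the
#' primary-and-secondary-screen consistency filter.
#'
#' @param primary_hits,secondary_hits Character vectors of compound names, or
#'   tibbles with a `compound_id` column (rows where `significant` is `FALSE`
#'   are dropped first if that column is present).
#' @return Sorted character vector of shared compound names.
#' @export
intersect_screens <- function(primary_hits, secondary_hits) {
  as_names <- function(x) {
    if (is.data.frame(x)) {
      if ("significant" %in% names(x)) x <- x[x$significant, , drop = FALSE]
      x <- x$compound_id
    }
    unique(as.character(x))
  }
  sort(intersect(as_names(primary_hits), as_names(secondary_hits)))
}

#' Two-sided unpaired Mann-Whitney test
#'
#' Rank-based two-group comparison: exact enumeration p-value for small
#' untied samples (`n * m <= 400`), normal approximation with tie correction
#' otherwise. With all values tied across both groups the p-value is 1.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return List with `u` (the Mann-Whitney U statistic for `group_a`) and
#'   `p_value` (two-sided).
#' @export
mannwhitney_compare <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("both groups must be non-empty.")
  }
  n <- length(group_a)
  m <- length(group_b)
  ranks <- rank(c(group_a, group_b))
  u <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  if (length(unique(c(group_a, group_b))) == 1) {
    return(list(u = u, p_value = 1))
  }
  has_ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- (n * m <= 400) && !has_ties
  wt <- suppressWarnings(
    wilcox.test(group_a, group_b,
      alternative = "two.sided",
      exact = exact, correct = TRUE
    )
  )
  list(u = u, p_value = min(1, wt$p.value))
}
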