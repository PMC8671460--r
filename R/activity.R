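#' Flag sensitive cell lines at a logFC cutoff
#'
#' A line is sensitive to a compound when its logFC is strictly below the
#' cutoff ("less than -1 logFC" at the default). Missing logFC entries are
#' neither sensitive nor evaluable.
#'
#' @param data A [drug_response] or wide logFC tibble.
#' @param cutoff Sensitivity cutoff on the logFC scale (default -1).
#' @return Tibble of logicals (`compound_id` + one column per line); `NA`
#'   where the input was missing.
#' @export
call_sensitive <- function(data, cutoff = -1) {
  logfc <- resolve_logfc(data)
  if (!is.finite(cutoff)) {
    if (is.na(cutoff)) abort("`cutoff` must not be NA.")
  }
  m <- tbl_to_matrix(logfc, "compound_id")
  sens <- m < cutoff
  out <- tibble::as_tibble(as.data.frame(sens, check.names = FALSE))
  tibble::add_column(out, compound_id = logfc$compound_id, .before = 1)
}

#' Call active compounds from per-line sensitivity flags
#'
#' A compound is active when at least `min_lines` cell lines are sensitive
#' (the screen's definition: three or more sensitive lines, above 10% of a
#' 28-line panel). Compounds killing more than 90% of evaluable lines are
#' additionally flagged broadly toxic (`is_broad`), the selectivity shading
#' of the mechanism-of-action landscape.
#'
#' @param sens Sensitivity tibble from [call_sensitive()] (`NA` = not
#'   evaluable).
#' @param min_lines Minimum number of sensitive lines for an active call.
#' @param broad_frac Fraction of evaluable lines above which an active
#'   compound counts as broadly toxic.
#' @return Tibble with one row per compound: `compound_id`, `n_sensitive`,
#'   `n_evaluable`, `frac_sensitive`, `is_active`, `is_broad`,
#'   `sensitive_lines` (list column of line ids).
#' @export
call_active <- function(sens, min_lines = 3, broad_frac = 0.9) {
  min_lines <- assert_count(min_lines, "min_lines", min = 1L)
  m <- tbl_to_matrix(sens, "compound_id") > 0 # logical via numeric round-trip
  line_ids <- colnames(m)
  n_sens <- unname(rowSums(m, na.rm = TRUE))
  n_eval <- unname(rowSums(!is.na(m)))
  frac <- ifelse(n_eval > 0, n_sens / n_eval, 0)
  tibble::tibble(
    compound_id = sens$compound_id,
    n_sensitive = as.integer(n_sens),
    n_evaluable = as.integer(n_eval),
    frac_sensitive = frac,
    is_active = n_sens >= min_lines,
    is_broad = .data$is_active & frac > broad_frac,
    sensitive_lines = lapply(
      seq_len(nrow(m)),
      function(i) line_ids[which(m[i, ])]
    )
  )
}

#' Summarize the mechanism-of-action landscape of active compounds
#'
#' Tallies, per mechanism of action (MOA), how many compounds were tested,
#' how many are active, the active percentage, and how many active compounds
#' are broadly toxic. Compounds annotated with several comma-separated MOA
#' labels count once under each label; compounds without an annotation are
#' grouped as `"unknown"`.
#'
#' @param calls Activity tibble from [call_active()].
#' @param compounds Compound annotation tibble (`compound_id`, `moa`,
#'   optionally `category`).
#' @param min_tested Display floor: keep MOAs with at least this many tested
#'   compounds (default 5, the landscape-figure convention).
#' @param category Optional filter on compound category before tallying.
#' @return `moa_landscape` tibble sorted by `n_active` descending:
#'   `moa`, `n_tested`, `n_active`, `pct_active`, `n_broad`.
#' @export
moa_landscape <- function(calls, compounds, min_tested = 5, category = NULL) {
  ann <- tibble::as_tibble(compounds)
  if (!"moa" %in% names(ann)) ann$moa <- NA_character_
  df <- dplyr::left_join(calls, ann, by = "compound_id")
  if (!is.null(category)) df <- df[df$category %in% category, , drop = FALSE]
  df$moa[is.na(df$moa) | df$moa == ""] <- "unknown"
  out <- df |>
    tidyr::separate_longer_delim("moa", delim = stringr::regex(",\\s*")) |>
    dplyr::group_by(moa = stringr::str_trim(.data$moa)) |>
    dplyr::summarise(
      n_tested = dplyr::n(),
      n_active = sum(.data$is_active),
      pct_active = .data$n_active / .data$n_tested,
      n_broad = sum(.data$is_broad),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_tested >= min_tested) |>
    dplyr::arrange(dplyr::desc(.data$n_active), .data$moa)
  class(out) <- c("moa_landscape", class(out))
  out
}
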