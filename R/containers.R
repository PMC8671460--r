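#' Bundle a screen matrix with compound and cell-line annotations
#'
#' A `drug_response` object carries the three tables a pooled-screen analysis
#' needs: the log fold-change (logFC) matrix in wide tibble form (one row per
#' compound, one numeric column per cell line; logFC is relative to the DMSO
#' vehicle control, more negative = more killing), a compound annotation table
#' and a cell-line annotation table.
#'
#' @param logfc Tibble with a `compound_id` character column followed by one
#'   numeric column per cell line. Compound ids must be unique; so must line
#'   ids. Missing values are allowed and are carried through as `NA`.
#' @param compounds Optional tibble of compound annotations with at least a
#'   `compound_id` column; typical columns are `name`, `category` (one of
#'   `"targeted cancer"`, `"chemotherapy"`, `"non-oncology"`), `moa`
#'   (comma-separated mechanism-of-action labels), `targets`, `phase`.
#' @param lines Optional tibble of cell-line annotations with at least a
#'   `line_id` column; typical columns are `lineage` and `subtype`.
#'
#' @return An object of class `drug_response`.
#' @export
drug_response <- function(logfc, compounds = NULL, lines = NULL) {
  logfc <- tibble::as_tibble(logfc)
  if (!"compound_id" %in% names(logfc)) {
    abort("`logfc` must have a `compound_id` column.")
  }
  if (anyDuplicated(logfc$compound_id)) {
    abort("`compound_id` values must be unique; collapse replicates first.")
  }
  line_ids <- setdiff(names(logfc), "compound_id")
  if (anyDuplicated(line_ids)) abort("cell-line column names must be unique.")
  vals <- as.matrix(logfc[line_ids])
  if (any(is.infinite(vals))) abort("logFC values must be finite or NA.")
  if (is.null(compounds)) {
    compounds <- tibble::tibble(compound_id = logfc$compound_id)
  }
  if (is.null(lines)) lines <- tibble::tibble(line_id = line_ids)
  structure(
    list(
      logfc = logfc,
      compounds = tibble::as_tibble(compounds),
      lines = tibble::as_tibble(lines)
    ),
    class = "drug_response"
  )
}

#' @export
print.drug_response <- function(x, ...) {
  n_lines <- ncol(x$logfc) - 1L
  cat(
    "<drug_response> ", nrow(x$logfc), " compounds x ", n_lines,
    " cell lines\n",
    sep = ""
  )
  n_miss <- sum(is.na(x$logfc[-1]))
  if (n_miss > 0) cat("  missing values: ", n_miss, "\n", sep = "")
  invisible(x)
}

# wide tibble (id column + numeric columns) -> numeric matrix with rownames
tbl_to_matrix <- function(tbl, id_col) {
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  storage.mode(m) <- "double"
  rownames(m) <- tbl[[id_col]]
  m
}

matrix_to_tbl <- function(m, id_col) {
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  ids <- rownames(m) %||% rep(NA_character_, nrow(m))
  tibble::add_column(out, !!id_col := ids, .before = 1)
}

# Accept either a drug_response or a wide logFC tibble; return the tibble.
resolve_logfc <- function(data) {
  if (inherits(data, "drug_response")) {
    return(data$logfc)
  }
  data <- tibble::as_tibble(data)
  if (!"compound_id" %in% names(data)) {
    abort("expected a `drug_response` object or a tibble with `compound_id`.")
  }
  data
}

# Accept a wide expression tibble (gene + per-line columns).
resolve_expression <- function(data) {
  if (inherits(data, "expression_matrix")) data <- tibble::as_tibble(data)
  data <- tibble::as_tibble(data)
  if (!"gene" %in% names(data)) {
    abort("expected an expression tibble with a `gene` column.")
  }
  data
}

assert_count <- function(x, name, min = 0L) {
  if (length(x) != 1 || is.na(x) || x < min || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

assert_proportion <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  as.numeric(x)
}
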