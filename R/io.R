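#' Read a PRISM-style logFC matrix with annotations
#'
#' Reads a compounds x cell-lines log fold-change CSV together with the two
#' annotation files the screen distributes: a line-info table mapping
#' screen-internal column identifiers to cell-line names and lineages, and an
#' optional compound-info table carrying name / category / mechanism-of-action
#' annotations. Replicate rows that share a compound identity (the compound
#' name when annotations are supplied, otherwise the row identifier) are
#' collapsed by the per-line arithmetic mean, ignoring missing values.
#'
#' @param matrix_file CSV path; first column is the compound identifier,
#'   remaining columns are screen-internal cell-line identifiers.
#' @param line_info CSV path with columns `screen_id`, `line_id` and
#'   optionally `lineage`. Matrix columns with no entry here are dropped with
#'   a warning; two screen columns mapping to the same `line_id` is an error.
#' @param compound_info Optional CSV path with at least `compound_id` and
#'   `name` columns (plus `category`, `moa`, `targets`, `phase`).
#' @param lineage Optional lineage filter (e.g. `"upper aerodigestive"`);
#'   keeps only cell lines annotated with that lineage.
#' @return A [drug_response] object with unique compound ids.
#' @export
read_logfc_matrix <- function(matrix_file, line_info, compound_info = NULL,
                              lineage = NULL) {
  mat <- readr::read_csv(matrix_file, show_col_types = FALSE)
  names(mat)[1] <- "compound_id"
  info <- readr::read_csv(line_info, show_col_types = FALSE)
  if (!all(c("screen_id", "line_id") %in% names(info))) {
    abort("`line_info` must have `screen_id` and `line_id` columns.")
  }

  screen_cols <- setdiff(names(mat), "compound_id")
  mapped <- match(screen_cols, info$screen_id)
  if (anyNA(mapped)) {
    warn(sprintf(
      "dropping %d screen column(s) with no cell-line mapping: %s",
      sum(is.na(mapped)),
      paste(head(screen_cols[is.na(mapped)], 5), collapse = ", ")
    ))
    screen_cols <- screen_cols[!is.na(mapped)]
    mapped <- mapped[!is.na(mapped)]
  }
  line_ids <- info$line_id[mapped]
  if (anyDuplicated(line_ids)) {
    abort("two screen columns map to the same cell-line id.")
  }
  mat <- mat[c("compound_id", screen_cols)]
  names(mat) <- c("compound_id", line_ids)

  lineages <- if ("lineage" %in% names(info)) info$lineage[mapped] else NULL
  if (!is.null(lineage)) {
    if (is.null(lineages)) abort("`line_info` has no `lineage` column to filter on.")
    keep <- lineages == lineage
    mat <- mat[c("compound_id", line_ids[keep])]
    line_ids <- line_ids[keep]
    lineages <- lineages[keep]
  }

  compounds <- NULL
  if (!is.null(compound_info)) {
    ann <- readr::read_csv(compound_info, show_col_types = FALSE)
    if (!all(c("compound_id", "name") %in% names(ann))) {
      abort("`compound_info` must have `compound_id` and `name` columns.")
    }
    key <- ann$name[match(mat$compound_id, ann$compound_id)]
    key[is.na(key)] <- mat$compound_id[is.na(key)]
    mat$compound_id <- key
    mat <- collapse_replicates(mat)
    ann <- ann[!duplicated(ann$name), , drop = FALSE]
    compounds <- dplyr::left_join(
      tibble::tibble(compound_id = mat$compound_id),
      dplyr::rename(dplyr::select(ann, -"compound_id"),
        compound_id = "name"
      ) |>
        dplyr::mutate(name = .data$compound_id),
      by = "compound_id"
    )
  } else {
    mat <- collapse_replicates(mat)
  }

  lines <- tibble::tibble(line_id = line_ids)
  if (!is.null(lineages)) lines$lineage <- lineages
  drug_response(mat, compounds = compounds, lines = lines)
}

#' Collapse replicate compound rows by per-line mean
#'
#' Rows sharing a `compound_id` are averaged per cell line; missing values
#' are ignored in the mean (all-missing cells stay missing). Collapsing an
#' already-unique matrix is a no-op, and the result does not depend on input
#' row order (rows come out sorted by compound id for that reason).
#'
#' @param logfc Wide logFC tibble (`compound_id` + per-line columns).
#' @return Collapsed tibble with unique, sorted compound ids.
#' @export
collapse_replicates <- function(logfc) {
  logfc <- resolve_logfc(logfc)
  out <- logfc |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(dplyr::across(
      dplyr::everything(),
      ~ {
        v <- mean(.x, na.rm = TRUE)
        if (is.nan(v)) NA_real_ else v
      }
    ), .groups = "drop") |>
    dplyr::arrange(.data$compound_id)
  out
}

#' Read a log2(TPM + 1) expression matrix
#'
#' Accepts the DepMap CSV dialect where gene headers look like
#' `"EGFR (1956)"` (symbol followed by an Entrez id) as well as plain
#' symbols, and normalizes orientation to genes x lines: if the gene-style
#' headers are on the columns the matrix is transposed. Values must be
#' non-negative (the log2(TPM + 1) scale); duplicate symbols after parsing
#' keep the first occurrence with a warning.
#'
#' @param file CSV path. The first column holds row identifiers.
#' @return Expression tibble: `gene` column + one numeric column per line.
#' @export
read_expression <- function(file) {
  raw <- readr::read_csv(file, show_col_types = FALSE)
  names(raw)[1] <- ".id"
  dialect <- "\\s\\(\\d+\\)$"
  col_genes <- mean(grepl(dialect, names(raw)[-1])) > 0.5
  if (col_genes) {
    # lines x genes on disk -> transpose
    m <- tbl_to_matrix(raw, ".id")
    m <- t(m)
    genes <- rownames(m)
  } else {
    m <- tbl_to_matrix(raw, ".id")
    genes <- raw$.id
  }
  genes <- sub(dialect, "", genes)
  if (any(m < 0, na.rm = TRUE)) {
    abort("negative expression value found; expected log2(TPM + 1) >= 0.")
  }
  dup <- duplicated(genes)
  if (any(dup)) {
    warn(sprintf(
      "%d duplicate gene symbol(s) after parsing; keeping first occurrence.",
      sum(dup)
    ))
    m <- m[!dup, , drop = FALSE]
    genes <- genes[!dup]
  }
  rownames(m) <- genes
  matrix_to_tbl(m, "gene")
}

#' Write / read expression data in GCT 1.2 format
#'
#' GCT 1.2 is the tab-separated exchange format GSEA tools consume: a
#' `#1.2` version line, a row/column count line, then a header with `NAME`,
#' `Description` and one column per sample. `write_gct()` and `read_gct()`
#' round-trip values exactly.
#'
#' @param expr Expression tibble (`gene` + per-line columns).
#' @param path File path.
#' @return `write_gct()` returns `path` invisibly; `read_gct()` returns an
#'   expression tibble.
#' @export
write_gct <- function(expr, path) {
  expr <- resolve_expression(expr)
  lines_ids <- setdiff(names(expr), "gene")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#1.2", con)
  writeLines(paste(nrow(expr), length(lines_ids), sep = "\t"), con)
  writeLines(paste(c("NAME", "Description", lines_ids), collapse = "\t"), con)
  if (nrow(expr) > 0) {
    body <- cbind(
      expr$gene, "na",
      format(as.matrix(expr[lines_ids]), digits = 15, trim = TRUE)
    )
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_gct
#' @export
read_gct <- function(path) {
  txt <- readLines(path)
  if (length(txt) < 3 || txt[1] != "#1.2") {
    abort("not a GCT 1.2 file (missing #1.2 header).")
  }
  counts <- suppressWarnings(as.integer(strsplit(txt[2], "\t")[[1]]))
  if (length(counts) < 2 || anyNA(counts)) {
    abort("malformed GCT count line.")
  }
  header <- strsplit(txt[3], "\t")[[1]]
  n_row <- counts[1]
  n_col <- counts[2]
  if (length(txt) - 3L != n_row || length(header) != n_col + 2L) {
    abort("GCT count line inconsistent with body.")
  }
  if (n_row == 0) {
    out <- tibble::tibble(gene = character(0))
    for (l in header[-(1:2)]) out[[l]] <- numeric(0)
    return(out)
  }
  body <- do.call(rbind, strsplit(txt[-(1:3)], "\t"))
  vals <- matrix(as.numeric(body[, -(1:2), drop = FALSE]), nrow = n_row)
  dimnames(vals) <- list(body[, 1], header[-(1:2)])
  matrix_to_tbl(vals, "gene")
}

#' Read a GMT gene-set collection
#'
#' Each tab-separated line is `set-name`, `description`, then member genes.
#' Set order follows the file; genes are de-duplicated within a set; lines
#' with fewer than three fields are skipped with a warning.
#'
#' @param path GMT file path.
#' @return Named list mapping set name to a character vector of genes.
#' @export
read_gmt <- function(path) {
  txt <- readLines(path)
  txt <- txt[nzchar(txt)]
  fields <- strsplit(txt, "\t")
  short <- lengths(fields) < 3
  if (any(short)) {
    warn(sprintf("skipping %d GMT line(s) with fewer than 3 fields.", sum(short)))
    fields <- fields[!short]
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  sets
}
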