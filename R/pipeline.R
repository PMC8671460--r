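#' Assemble a pipeline configuration
#'
#' Collects every tunable threshold of the screen-analysis pipeline with its
#' conventional default: the logFC sensitivity cutoff (-1), the minimum
#' sensitive-line count for an active call (3), the differential-sensitivity
#' alpha (0.01), t-SNE settings (perplexity 30, learning rate 100, 10 runs),
#' the kNN consistency rule (k = 10, minimum neighbor fraction 0.5), the DEG
#' q cutoff (0.05) and the GSEA settings (1000 permutations, auto mode, FDR
#' 0.25). Configurations round-trip losslessly through JSON via
#' [write_config()] / [read_config()].
#'
#' @param inputs Named list of input paths (`matrix`, `line_info`,
#'   `compound_info`, `expression`, `gene_sets`); may be empty for synthetic
#'   runs.
#' @param cutoff,min_lines,alpha,deg_q Stage thresholds (see above).
#' @param tsne,knn,gsea Named lists overriding the embedding, proximity and
#'   enrichment defaults.
#' @param synth Named list overriding [generate_screen()] /
#'   [generate_expression()] defaults for synthetic runs.
#' @param seed Integer master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(inputs = list(), cutoff = -1, min_lines = 3,
                            alpha = 0.01, deg_q = 0.05,
                            tsne = list(), knn = list(), gsea = list(),
                            synth = list(), seed = 1L) {
  cfg <- list(
    inputs = inputs,
    cutoff = cutoff,
    min_lines = assert_count(min_lines, "min_lines", min = 1L),
    alpha = alpha,
    deg_q = deg_q,
    tsne = modifyList(
      list(perplexity = 30, learning_rate = 100, n_runs = 10),
      tsne
    ),
    knn = modifyList(list(k = 10, min_frac = 0.5), knn),
    gsea = modifyList(
      list(n_perm = 1000, mode = "auto", fdr = 0.25),
      gsea
    ),
    synth = synth,
    seed = as.integer(seed)
  )
  if (cfg$alpha <= 0 || cfg$alpha >= 1) abort("`alpha` must lie in (0, 1).")
  if (cfg$deg_q <= 0 || cfg$deg_q >= 1) abort("`deg_q` must lie in (0, 1).")
  if (cfg$knn$min_frac <= 0 || cfg$knn$min_frac > 1) {
    abort("`knn$min_frac` must lie in (0, 1].")
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

files_reproduce <- c(
  "primary_replicate_collapsed_logfold_change.csv",
  "primary-screen-cell-line-info.csv",
  "compound_annotations.csv",
  "CCLE_expression.csv"
)

#' Run the screen-analysis pipeline end to end
#'
#' Executes the stages in order - ingest, threshold calibration, sensitivity
#' and activity calling, MOA landscape, clustering and repeated embedding
#' with consistency MOA assignment, two-class differential sensitivity,
#' biomarker discovery (extreme groups, moderated-t DEGs, over-representation,
#' Pearson shortlist, signature scores) and permutation GSEA - writing
#' plain-TSV/JSON outputs plus a log to `output_dir`. Every output records
#' the configuration hash; rerunning with the same configuration reproduces
#' the outputs.
#'
#' In `"synthetic"` mode the inputs are generated by [generate_screen()] /
#' [generate_expression()] (written to disk as CSV and re-read through the
#' real parsers) and the planted truth is carried into the result for
#' recovery checks. In `"reproduce"` mode the pinned screen downloads must
#' be present in `inputs$dir`; a missing file raises an error naming it.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Directory for outputs (created if needed).
#' @param mode `"synthetic"` or `"reproduce"`.
#' @return Invisibly, a named list with the per-stage results (`screen`,
#'   `truth`, `calibration`, `activity`, `landscape`, `embedding`,
#'   `moa_assignments`, `differential`, `deg`, `enrichment`, ...).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         output_dir = tempfile("run"),
                         mode = c("synthetic", "reproduce")) {
  mode <- match.arg(mode)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  cfg_hash <- rlang::hash(unclass(config))
  log_path <- file.path(output_dir, "pipeline.log")
  logf <- function(...) {
    cat(sprintf("[%s] ", format(Sys.time(), "%H:%M:%S")), sprintf(...), "\n",
      sep = "", file = log_path, append = TRUE
    )
  }
  logf("config hash: %s", cfg_hash)
  logf(
    "defaults in force: cutoff=%g min_lines=%d alpha=%g deg_q=%g perplexity=%g eta=%g runs=%d k=%d min_frac=%g n_perm=%d fdr=%g seed=%d",
    config$cutoff, config$min_lines, config$alpha, config$deg_q,
    config$tsne$perplexity, config$tsne$learning_rate, config$tsne$n_runs,
    config$knn$k, config$knn$min_frac, config$gsea$n_perm, config$gsea$fdr,
    config$seed
  )
  write_config(config, file.path(output_dir, "config.json"))

  if (mode == "reproduce") {
    dir <- config$inputs$dir %||% "."
    missing <- files_reproduce[!file.exists(file.path(dir, files_reproduce))]
    if (length(missing) > 0) {
      abort(c(
        "reproduce mode requires the pinned screen downloads:",
        setNames(file.path(dir, missing), rep("x", length(missing)))
      ))
    }
    screen <- read_logfc_matrix(
      file.path(dir, files_reproduce[1]),
      file.path(dir, files_reproduce[2]),
      file.path(dir, files_reproduce[3]),
      lineage = config$inputs$lineage %||% "upper aerodigestive"
    )
    truth <- NULL
    expr <- read_expression(file.path(dir, files_reproduce[4]))
    expr_truth <- NULL
    gene_sets <- if (!is.null(config$inputs$gene_sets)) {
      read_gmt(config$inputs$gene_sets)
    } else {
      NULL
    }
  } else {
    synth_args <- modifyList(
      list(seed = config$seed),
      config$synth[intersect(
        names(config$synth),
        names(formals(generate_screen))
      )]
    )
    sim <- do.call(generate_screen, synth_args)
    paths <- write_screen_csv(sim, file.path(output_dir, "synthetic"))
    screen <- read_logfc_matrix(
      paths[["matrix"]], paths[["line_info"]], paths[["compound_info"]]
    )
    # synthetic compound ids are their own names, so re-join truth directly;
    # the biomarker labels live in the truth sidecar, not the screen CSVs
    truth <- sim$truth
    screen$lines$biomarker <-
      unname(truth$biomarker_label[screen$lines$line_id])
    line_ids <- screen$lines$line_id
    sens_lines <- screen$lines$line_id[screen$lines$biomarker == 1]
    ex <- generate_expression(
      n_genes = config$synth$n_genes %||% 1000,
      lines = line_ids,
      group_a = sens_lines,
      enriched_sets = list(planted_set = sprintf("g%04d", 1:20)),
      seed = config$seed + 1L
    )
    expr <- ex$expr
    expr_truth <- ex$truth
    gene_sets <- c(
      list(planted_set = sprintf("g%04d", 1:20)),
      lapply(1:5, function(i) sprintf("g%04d", 20 + (i - 1) * 20 + 1:20))
    )
    names(gene_sets)[-1] <- paste0("random_set_", 1:5)
  }
  logf("ingest: %d compounds x %d lines", nrow(screen$logfc), ncol(screen$logfc) - 1)

  # calibration on a biomarker-stratified construction
  calib_set <- generate_calibration_set(
    n_pos = 10, n_neg = 40, seed = config$seed
  )
  calibration <- youden_scan(calib_set)
  chosen <- attr(calibration, "chosen_threshold")
  logf("calibration: chosen threshold %g", chosen)
  readr::write_tsv(tidy(calibration), file.path(output_dir, "calibration.tsv"))

  sens <- call_sensitive(screen, cutoff = config$cutoff)
  activity <- call_active(sens, min_lines = config$min_lines)
  readr::write_tsv(
    dplyr::select(activity, -"sensitive_lines"),
    file.path(output_dir, "activity.tsv")
  )
  logf("activity: %d of %d compounds active", sum(activity$is_active), nrow(activity))

  landscape <- moa_landscape(activity, screen$compounds, min_tested = 5)
  readr::write_tsv(landscape, file.path(output_dir, "moa_landscape.tsv"))

  active_ids <- activity$compound_id[activity$is_active]
  embedding <- NULL
  assignments <- NULL
  if (length(active_ids) >= 12) {
    active_tbl <- screen$logfc[screen$logfc$compound_id %in% active_ids, ]
    d <- spearman_distance(active_tbl, axis = "compounds")
    embedding <- suppressWarnings(tsne_runs(
      d,
      perplexity = config$tsne$perplexity,
      learning_rate = config$tsne$learning_rate,
      n_runs = config$tsne$n_runs
    ))
    ann <- screen$compounds
    known <- ann[
      ann$compound_id %in% active_ids &
        !is.na(ann$moa) & ann$moa != "unknown",
    ]
    queries <- setdiff(active_ids, known$compound_id)
    if (nrow(known) >= config$knn$k && length(queries) > 0) {
      assignments <- consistent_proximity(
        embedding, queries,
        setNames(known$moa, known$compound_id),
        k = config$knn$k, min_frac = config$knn$min_frac
      )
      readr::write_tsv(assignments, file.path(output_dir, "moa_assignments.tsv"))
      logf(
        "proximity: %d of %d queries assigned",
        sum(!is.na(assignments$assigned_moa)), nrow(assignments)
      )
    }
  }

  # two-class comparison: biomarker-positive vs negative lines stands in for
  # the tumour-type in/out split when running synthetically
  differential <- NULL
  if (!is.null(screen$lines$biomarker)) {
    in_ids <- screen$lines$line_id[screen$lines$biomarker == 1]
    out_ids <- screen$lines$line_id[screen$lines$biomarker == 0]
    if (length(in_ids) >= 2 && length(out_ids) >= 2) {
      differential <- two_class_compare(screen, in_ids, out_ids,
        alpha = config$alpha
      )
      readr::write_tsv(differential, file.path(output_dir, "differential.tsv"))
    }
  }

  deg <- NULL
  enrichment <- NULL
  correlations <- NULL
  signature <- NULL
  if (!is.null(expr)) {
    line_ids <- setdiff(names(expr), "gene")
    grp_a <- if (mode == "synthetic") {
      screen$lines$line_id[screen$lines$biomarker == 1]
    } else {
      config$inputs$group_a
    }
    grp_b <- setdiff(line_ids, grp_a)
    if (length(grp_a) >= 2 && length(grp_b) >= 2) {
      deg <- moderated_t_test(expr, grp_a, grp_b, q_cutoff = config$deg_q)
      readr::write_tsv(deg, file.path(output_dir, "deg.tsv"))
      logf("deg: %d significant at q < %g", sum(deg$significant), config$deg_q)
      if (!is.null(gene_sets)) {
        hit <- deg$gene[deg$significant & deg$direction == "up"]
        if (length(hit) > 0) {
          over <- overrepresentation(hit, deg$gene, gene_sets)
          readr::write_tsv(over, file.path(output_dir, "overrepresentation.tsv"))
        }
        enrichment <- permutation_significance(
          expr, grp_a, grp_b, gene_sets,
          n_perm = config$gsea$n_perm, mode = config$gsea$mode,
          min_size = min(15, min(lengths(gene_sets))),
          seed = config$seed + 2L
        )
        readr::write_tsv(
          dplyr::select(enrichment, -"leading_edge"),
          file.path(output_dir, "gsea.tsv")
        )
      }
      if (!is.null(expr_truth) && length(expr_truth$response) > 0) {
        correlations <- correlate_expression(expr, expr_truth$response)
        readr::write_tsv(correlations, file.path(output_dir, "correlations.tsv"))
      }
      sig_genes <- head(expr$gene, 5)
      signature <- signature_score(expr, sig_genes)
      readr::write_tsv(signature, file.path(output_dir, "signature.tsv"))
    }
  }

  summary <- list(
    config_hash = cfg_hash,
    chosen_threshold = chosen,
    n_compounds = nrow(screen$logfc),
    n_lines = ncol(screen$logfc) - 1L,
    n_active = sum(activity$is_active),
    n_differential = if (!is.null(differential)) sum(differential$significant) else NA,
    n_deg = if (!is.null(deg)) sum(deg$significant) else NA
  )
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  logf("done")

  invisible(list(
    config = config, config_hash = cfg_hash, output_dir = output_dir,
    screen = screen, truth = truth, expr = expr, expr_truth = expr_truth,
    calibration = calibration, activity = activity, landscape = landscape,
    embedding = embedding, moa_assignments = assignments,
    differential = differential, deg = deg, enrichment = enrichment,
    correlations = correlations, signature = signature
  ))
}
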