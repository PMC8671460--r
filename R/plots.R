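#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_vline geom_hline labs facet_wrap theme_minimal scale_colour_manual
NULL

#' @export
ggplot2::autoplot

#' Plot a calibration curve
#'
#' Sensitivity, specificity and Youden's J across the threshold grid, with
#' the chosen threshold marked.
#'
#' @param object A `calibration_curve` from [youden_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibration_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tidy(object)[c("threshold", "sensitivity", "specificity", "youden")],
    -"threshold",
    names_to = "measure", values_to = "value"
  )
  ggplot(long, aes(.data$threshold, .data$value, colour = .data$measure)) +
    geom_line() +
    geom_vline(
      xintercept = attr(object, "chosen_threshold"),
      linetype = "dashed"
    ) +
    labs(
      x = "logFC threshold", y = NULL,
      title = "Youden scan",
      subtitle = sprintf(
        "chosen threshold = %.3g", attr(object, "chosen_threshold")
      )
    ) +
    theme_minimal()
}

#' Plot a mechanism-of-action landscape
#'
#' Active-compound counts per MOA, shaded by the broadly toxic fraction.
#'
#' @param object A `moa_landscape` tibble from [moa_landscape()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.moa_landscape <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    moa = stats::reorder(.data$moa, .data$n_active)
  )
  ggplot(df, aes(.data$n_active, .data$moa, fill = .data$n_broad / pmax(1, .data$n_active))) +
    geom_col() +
    ggplot2::geom_text(
      aes(label = sprintf("%.0f%%", 100 * .data$pct_active)),
      hjust = -0.1, size = 3
    ) +
    ggplot2::scale_fill_gradient(
      low = "steelblue", high = "navy",
      name = "broad fraction", limits = c(0, 1)
    ) +
    labs(
      x = "active compounds", y = NULL,
      title = "MOA landscape",
      subtitle = "bar labels: % of tested compounds active"
    ) +
    theme_minimal()
}

#' Plot repeated t-SNE embeddings
#'
#' @param object An `embedding_set` from [tsne_runs()].
#' @param moa Optional named character vector (item id -> MOA) used to
#'   colour points.
#' @param runs Runs to display (default: the first).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.embedding_set <- function(object, moa = NULL, runs = 1, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$run %in% runs, ]
  if (!is.null(moa)) {
    df$moa <- dplyr::coalesce(unname(moa[df$item]), "unknown")
  }
  p <- ggplot(df, aes(.data$T1, .data$T2)) +
    theme_minimal() +
    labs(title = "t-SNE embedding of killing profiles")
  p <- if (!is.null(moa)) {
    p + geom_point(aes(colour = .data$moa), size = 1.5)
  } else {
    p + geom_point(size = 1.5)
  }
  if (length(runs) > 1) p <- p + facet_wrap(~run)
  p
}

#' Volcano plot of differential hits
#'
#' Works for both differential killing activity ([two_class_compare()]) and
#' differential expression ([moderated_t_test()]) tables.
#'
#' @param hits Tibble with an effect column (`effect_size` or `mean_diff`),
#'   `p_value` and `significant`.
#' @return A ggplot object.
#' @export
plot_volcano <- function(hits) {
  eff <- if ("effect_size" %in% names(hits)) "effect_size" else "mean_diff"
  ggplot(hits, aes(.data[[eff]], -log10(.data$p_value))) +
    geom_point(aes(colour = .data$significant), size = 1, alpha = 0.7) +
    scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    labs(x = eff, y = "-log10(p)", title = "Differential hits") +
    theme_minimal()
}

#' Plot a GSEA running enrichment score
#'
#' @param ranked A `ranked_list`.
#' @param gene_set Gene-set members.
#' @param weight_p Hit-weight exponent.
#' @return A ggplot object.
#' @export
plot_running_sum <- function(ranked, gene_set, weight_p = 1) {
  es <- enrichment_score(ranked, gene_set, weight_p)
  df <- dplyr::mutate(es$running, position = dplyr::row_number())
  ggplot(df, aes(.data$position, .data$running)) +
    geom_line(colour = "forestgreen") +
    geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_rug(
      data = df[df$hit, ], sides = "b",
      alpha = 0.5, length = ggplot2::unit(0.03, "npc")
    ) +
    labs(
      x = "rank position", y = "running enrichment",
      title = sprintf("ES = %.3f", es$es)
    ) +
    theme_minimal()
}

#' Tidy an enrichment result
#'
#' @param x An `enrichment_result` from [permutation_significance()].
#' @param ... Unused.
#' @return A plain tibble without the leading-edge list column.
#' @export
tidy.enrichment_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$n_leading_edge <- lengths(out$leading_edge)
  out$leading_edge <- NULL
  out
}

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(
    n_sets = nrow(x),
    n_fdr25 = sum(x$fdr_q < 0.25, na.rm = TRUE),
    mode = attr(x, "mode"),
    n_perm = attr(x, "n_perm")
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
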