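#' Pick extreme responder groups by mean drug response
#'
#' Ranks cell lines by their mean logFC over a compound set (e.g. the active
#' MEK inhibitors); the `n_extreme` lowest-mean lines form the sensitive
#' group and the `n_extreme` highest the resistant group. Missing values are
#' excluded from the means; ties are broken lexicographically by line id.
#'
#' @param data A [drug_response] or wide logFC tibble.
#' @param compound_set Non-empty character vector of compound ids.
#' @param n_extreme Group size; `2 * n_extreme` must not exceed the line
#'   count.
#' @return List with `sensitive` and `resistant` id vectors and `ranking`, a
#'   tibble of per-line means sorted ascending.
#' @export
rank_lines_by_mean_response <- function(data, compound_set, n_extreme) {
  if (length(compound_set) == 0) abort("`compound_set` must be non-empty.")
  n_extreme <- assert_count(n_extreme, "n_extreme", min = 1L)
  logfc <- resolve_logfc(data)
  m <- tbl_to_matrix(logfc, "compound_id")
  missing_cpd <- setdiff(compound_set, rownames(m))
  if (length(missing_cpd) > 0) {
    abort(sprintf(
      "unknown compound id(s): %s", paste(missing_cpd, collapse = ", ")
    ))
  }
  sub <- m[compound_set, , drop = FALSE]
  means <- colMeans(sub, na.rm = TRUE)
  if (2 * n_extreme > length(means)) {
    abort("fewer cell lines than `2 * n_extreme`.")
  }
  ord <- order(means, names(means))
  ranking <- tibble::tibble(
    line_id = names(means)[ord],
    mean_logfc = unname(means[ord])
  )
  list(
    sensitive = ranking$line_id[seq_len(n_extreme)],
    resistant = rev(ranking$line_id)[seq_len(n_extreme)],
    ranking = ranking
  )
}

# Newton solve of trigamma(x) = y (vectorized), as used for the prior df.
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (yi > 1e7) {
      return(1 / sqrt(yi))
    }
    if (yi < 1e-6) {
      return(1 / yi)
    }
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2)
      x <- x + dif
      if (abs(dif / x) < 1e-8) break
    }
    x
  }, numeric(1))
}

#' Fit empirical-Bayes variance-prior parameters
#'
#' Moment-matches the ensemble of per-gene log sample variances against the
#' scaled-F model underlying the moderated t-statistic: solves
#' `trigamma(d0 / 2) = var(log s^2) - trigamma(dg / 2)` for the prior
#' degrees of freedom `d0`, then recovers the prior variance `s0^2` from the
#' mean of the bias-corrected log variances. When the log variances have no
#' excess spread beyond their sampling noise, `d0 = Inf` and every variance
#' is shrunk fully to `s0^2`.
#'
#' @param sample_variances Per-gene sample variances (>= 10 genes, all
#'   non-negative).
#' @param df Residual degrees of freedom `dg` of each variance (scalar or
#'   per-gene).
#' @return An `eb_params` list with `d0` (prior df, possibly `Inf`) and
#'   `s0_sq` (prior variance).
#' @export
fit_eb_params <- function(sample_variances, df) {
  s2 <- as.numeric(sample_variances)
  if (length(s2) < 10) abort("need at least 10 genes to fit the prior.")
  if (any(s2 < 0)) abort("variances must be non-negative.")
  df <- rep_len(as.numeric(df), length(s2))
  pos <- s2 > 0
  if (sum(pos) < 10) abort("need at least 10 positive variances.")
  z <- log(s2[pos])
  dg <- df[pos]
  e <- z - digamma(dg / 2) + log(dg / 2)
  excess <- var(z) - mean(trigamma(dg / 2))
  if (!is.finite(excess) || excess <= 1e-10) {
    d0 <- Inf
    s0_sq <- mean(s2)
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "eb_params")
}

#' @export
print.eb_params <- function(x, ...) {
  cat("<eb_params> d0 =", x$d0, " s0_sq =", x$s0_sq, "\n")
  invisible(x)
}

#' @export
glance.eb_params <- function(x, ...) {
  tibble::tibble(d0 = x$d0, s0_sq = x$s0_sq)
}

#' Moderated two-sample t-test for differential expression
#'
#' Per-gene two-group comparison with empirical-Bayes variance shrinkage:
#' the pooled sample variance `s_g^2` (residual df `dg = nA + nB - 2`) is
#' shrunk to the posterior `(d0 s0^2 + dg s_g^2) / (d0 + dg)`, the moderated
#' t-statistic is the mean difference over the posterior standard error, and
#' p-values use `d0 + dg` degrees of freedom. Multiplicity is controlled by
#' Benjamini-Hochberg q-values. `d0 = 0` recovers the ordinary pooled
#' t-test; `d0 = Inf` fixes every variance at `s0^2`.
#'
#' @param expr Expression tibble (`gene` + per-line columns).
#' @param group_a,group_b Disjoint line-id vectors, each of size >= 2.
#'   `mean_diff` is group A minus group B.
#' @param eb Optional `eb_params` (otherwise fitted from the data with
#'   [fit_eb_params()]).
#' @param q_cutoff Significance threshold on the q-value (default 0.05).
#' @return Tibble: `gene`, `mean_diff`, `t`, `p_value`, `q_value`,
#'   `direction` (`"up"` iff `mean_diff > 0`), `significant`; the fitted
#'   prior is attached as attribute `eb`.
#' @export
moderated_t_test <- function(expr, group_a, group_b, eb = NULL,
                             q_cutoff = 0.05) {
  expr <- resolve_expression(expr)
  if (length(intersect(group_a, group_b)) > 0) {
    abort("groups must be disjoint.")
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 lines.")
  }
  m <- tbl_to_matrix(expr, "gene")
  missing_l <- setdiff(c(group_a, group_b), colnames(m))
  if (length(missing_l) > 0) {
    abort(sprintf("unknown line id(s): %s", paste(missing_l, collapse = ", ")))
  }
  a <- m[, group_a, drop = FALSE]
  b <- m[, group_b, drop = FALSE]
  na <- length(group_a)
  nb <- length(group_b)
  dg <- na + nb - 2
  mean_diff <- rowMeans(a) - rowMeans(b)
  va <- apply(a, 1, var)
  vb <- apply(b, 1, var)
  s2 <- ((na - 1) * va + (nb - 1) * vb) / dg
  if (is.null(eb)) eb <- fit_eb_params(s2, dg)
  d0 <- eb$d0
  s0 <- eb$s0_sq
  post <- if (is.infinite(d0)) rep(s0, length(s2)) else {
    (d0 * s0 + dg * s2) / (d0 + dg)
  }
  se <- sqrt(post * (1 / na + 1 / nb))
  tstat <- ifelse(se == 0 & mean_diff == 0, 0, mean_diff / se)
  df_total <- d0 + dg
  p <- if (is.infinite(df_total)) {
    2 * pnorm(-abs(tstat))
  } else {
    2 * pt(-abs(tstat), df = df_total)
  }
  p[is.infinite(tstat)] <- 0
  q <- p.adjust(p, method = "BH")
  out <- tibble::tibble(
    gene = rownames(m),
    mean_diff = unname(mean_diff),
    t = unname(tstat),
    p_value = unname(p),
    q_value = unname(q),
    direction = ifelse(mean_diff > 0, "up", "down"),
    significant = q < q_cutoff
  )
  attr(out, "eb") <- eb
  out
}

#' Hypergeometric over-representation of hit genes in gene sets
#'
#' One-sided hypergeometric tail test of the overlap between a hit-gene list
#' and each gene set (membership restricted to the universe), the stand-in
#' for portal-based pathway enrichment of a DEG list.
#'
#' @param hit_genes Character vector, a subset of `universe_genes`.
#' @param universe_genes Non-empty background gene universe.
#' @param gene_sets Named list of gene vectors (e.g. from [read_gmt()]).
#' @return Tibble ordered by p-value: `set_name`, `n_set` (set size within
#'   the universe), `overlap`, `p_value`, `q_value` (BH).
#' @export
overrepresentation <- function(hit_genes, universe_genes, gene_sets) {
  universe_genes <- unique(universe_genes)
  if (length(universe_genes) == 0) abort("universe must be non-empty.")
  hit_genes <- unique(hit_genes)
  if (!all(hit_genes %in% universe_genes)) {
    abort("`hit_genes` must be a subset of `universe_genes`.")
  }
  n_univ <- length(universe_genes)
  n_hit <- length(hit_genes)
  rows <- purrr::imap(gene_sets, function(gs, nm) {
    gs <- intersect(unique(gs), universe_genes)
    k <- length(intersect(gs, hit_genes))
    p <- phyper(k - 1, length(gs), n_univ - length(gs), n_hit,
      lower.tail = FALSE
    )
    tibble::tibble(
      set_name = nm, n_set = length(gs), overlap = k,
      p_value = min(1, p)
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$p_value)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out
}

#' Correlate gene expression with drug response
#'
#' Per-gene Pearson correlation between expression and a per-line drug
#' response (logFC), with the two-sided p-value from the t-transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df. Genes with p < 0.05
#' are shortlisted as candidate biomarkers. Genes with zero expression
#' variance (or fewer than 3 paired observations) are excluded with a
#' warning.
#'
#' @param expr Expression tibble (`gene` + per-line columns).
#' @param response Named numeric vector of per-line response values (names =
#'   line ids), or unnamed and aligned with the expression columns.
#' @param genes Optional subset of genes to test (default: all).
#' @return Tibble: `gene`, `r`, `n`, `p_value`, `shortlisted`.
#' @export
correlate_expression <- function(expr, response, genes = NULL) {
  expr <- resolve_expression(expr)
  m <- tbl_to_matrix(expr, "gene")
  if (is.null(names(response))) {
    if (length(response) != ncol(m)) {
      abort("unnamed `response` must align with the expression columns.")
    }
    names(response) <- colnames(m)
  }
  shared <- intersect(colnames(m), names(response))
  if (length(shared) < 3) abort("need >= 3 lines shared with `response`.")
  m <- m[, shared, drop = FALSE]
  resp <- response[shared]
  if (sd(resp, na.rm = TRUE) == 0) abort("`response` has zero variance.")
  if (!is.null(genes)) {
    known <- intersect(genes, rownames(m))
    if (length(known) < length(genes)) {
      warn(sprintf(
        "%d requested gene(s) absent from the matrix.",
        length(genes) - length(known)
      ))
    }
    m <- m[known, , drop = FALSE]
  }
  rows <- purrr::map(seq_len(nrow(m)), function(i) {
    x <- m[i, ]
    ok <- !is.na(x) & !is.na(resp)
    n <- sum(ok)
    if (n < 3 || sd(x[ok]) == 0) {
      return(tibble::tibble(
        gene = rownames(m)[i], r = NA_real_, n = n,
        p_value = NA_real_, shortlisted = NA
      ))
    }
    r <- cor(x[ok], resp[ok])
    p <- if (abs(r) >= 1) 0 else {
      2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2)
    }
    tibble::tibble(
      gene = rownames(m)[i], r = r, n = n,
      p_value = p, shortlisted = p < 0.05
    )
  })
  out <- dplyr::bind_rows(rows)
  if (anyNA(out$r)) {
    warn(sprintf(
      "excluding %d gene(s) with zero variance or < 3 paired observations.",
      sum(is.na(out$r))
    ))
    out <- out[!is.na(out$r), , drop = FALSE]
  }
  out
}

#' Gene-signature scores as mean per-gene Z-scores
#'
#' Standardizes each signature gene across cell lines (Z-score: mean 0, sd
#' 1) and averages the Z-scores per line - the "average expression
#' (Z-score)" summary used for ligand signatures. Standardizing first puts
#' genes of very different absolute abundance on an equal footing. Genes
#' absent from the matrix are skipped with a warning; constant genes carry
#' no ranking information and are skipped likewise.
#'
#' @param expr Expression tibble (`gene` + per-line columns).
#' @param gene_list Signature gene ids; at least one must be present.
#' @return Tibble with `line_id` and `score`.
#' @export
signature_score <- function(expr, gene_list) {
  expr <- resolve_expression(expr)
  m <- tbl_to_matrix(expr, "gene")
  present <- intersect(gene_list, rownames(m))
  if (length(present) == 0) abort("no signature gene found in the matrix.")
  if (length(present) < length(gene_list)) {
    warn(sprintf(
      "%d signature gene(s) absent from the matrix; skipped.",
      length(gene_list) - length(present)
    ))
  }
  sub <- m[present, , drop = FALSE]
  sds <- apply(sub, 1, sd)
  if (any(sds == 0)) {
    warn(sprintf("%d constant signature gene(s) skipped.", sum(sds == 0)))
    sub <- sub[sds > 0, , drop = FALSE]
    if (nrow(sub) == 0) abort("all signature genes are constant.")
  }
  z <- t(scale(t(sub)))
  tibble::tibble(line_id = colnames(sub), score = unname(colMeans(z)))
}
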