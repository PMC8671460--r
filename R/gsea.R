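#' Rank genes by the signal-to-noise ratio between two classes
#'
#' Per-gene ranking metric `(muA - muB) / (sdA + sdB)` where each class
#' standard deviation is floored at `max(0.2 * |class mean|, 0.2)`, the
#' reference GSEA tool's documented signal-to-noise definition (the floor
#' keeps near-constant genes from dominating). Genes are ordered by metric
#' descending, ties broken by gene name for determinism.
#'
#' @param expr Expression tibble (`gene` + per-line columns).
#' @param class_a,class_b Line-id vectors, each of size >= 2. Positive
#'   metric = higher in class A.
#' @return A `ranked_list` tibble with columns `gene` and `metric`, sorted.
#' @export
signal_to_noise_rank <- function(expr, class_a, class_b) {
  expr <- resolve_expression(expr)
  if (length(class_a) < 2 || length(class_b) < 2) {
    abort("each class needs at least 2 lines.")
  }
  m <- tbl_to_matrix(expr, "gene")
  missing_l <- setdiff(c(class_a, class_b), colnames(m))
  if (length(missing_l) > 0) {
    abort(sprintf("unknown line id(s): %s", paste(missing_l, collapse = ", ")))
  }
  metric <- s2n_metric(m[, class_a, drop = FALSE], m[, class_b, drop = FALSE])
  out <- tibble::tibble(gene = rownames(m), metric = metric)
  out <- out[order(-out$metric, out$gene), ]
  class(out) <- c("ranked_list", class(out))
  out
}

# signal-to-noise on matrices (genes x samples), with the 0.2 sd floor
s2n_metric <- function(a, b) {
  mu_a <- rowMeans(a)
  mu_b <- rowMeans(b)
  sd_a <- pmax(apply(a, 1, sd), 0.2 * abs(mu_a), 0.2)
  sd_b <- pmax(apply(b, 1, sd), 0.2 * abs(mu_b), 0.2)
  unname((mu_a - mu_b) / (sd_a + sd_b))
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list: positions holding set genes ("hits") increment the
#' running sum by `|metric|^p` normalized by the sum over hits, the others
#' decrement by `1 / (N - Nh)`. The enrichment score is the signed maximum
#' deviation of the running sum from zero. `weight_p = 0` recovers the
#' classic unweighted KS statistic.
#'
#' @param ranked A `ranked_list` from [signal_to_noise_rank()], or any tibble
#'   with `gene` and `metric` columns already in ranked order.
#' @param gene_set Character vector; members absent from the list are
#'   dropped, and at least one must remain.
#' @param weight_p Hit-weight exponent (default 1).
#' @return List with `es` and `running`, a tibble of the per-position
#'   running sum (`gene`, `hit`, `running`).
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  hit <- ranked$gene %in% gene_set
  if (!any(hit)) abort("no gene of the set occurs in the ranked list.")
  run <- es_running(ranked$metric, hit, weight_p)
  es <- run[es_peak(run)]
  list(
    es = es,
    running = tibble::tibble(gene = ranked$gene, hit = hit, running = run)
  )
}

# core running-sum; metric already in ranked order, hit logical
es_running <- function(metric, hit, weight_p) {
  n <- length(metric)
  n_hit <- sum(hit)
  w <- abs(metric)^weight_p * hit
  total <- sum(w)
  inc <- if (total > 0) w / total else hit / n_hit # all-zero weights: uniform
  miss <- n - n_hit
  dec <- if (miss > 0) (1 - hit) / miss else rep(0, n)
  cumsum(inc - dec)
}

# position of the signed maximum deviation; ties (within floating-point
# dust of the maximum) break toward the earliest position
es_peak <- function(run) {
  which(abs(run) >= max(abs(run)) - 1e-12)[1]
}

es_only <- function(metric, hit, weight_p) {
  run <- es_running(metric, hit, weight_p)
  run[es_peak(run)]
}

#' Permutation-based enrichment significance for gene-set collections
#'
#' Computes the observed weighted-KS enrichment score per gene set, then a
#' permutation null: phenotype permutations reshuffle the class labels and
#' re-rank (preserving gene-gene correlation), gene-set permutations draw
#' random same-size sets on the observed ranking (the small-sample
#' fallback). The normalized enrichment score (NES) divides each ES by the
#' mean magnitude of same-sign permuted scores for that set; the nominal p
#' is the same-sign permutation tail fraction; the FDR q follows the
#' GSEA-standard ratio of normalized tail fractions, clipped to [0, 1].
#'
#' @param expr Expression tibble (`gene` + per-line columns).
#' @param class_a,class_b Line-id vectors defining the contrast (positive ES
#'   = enriched in class A).
#' @param gene_sets Named list of gene vectors (e.g. [read_gmt()]).
#' @param n_perm Number of permutations (>= 100).
#' @param mode `"phenotype"`, `"gene_set"`, or `"auto"` (phenotype when both
#'   classes have >= 7 samples, the reference tool's small-sample guidance).
#' @param weight_p Hit-weight exponent (default 1).
#' @param min_size,max_size Gene-set size filter after restricting to genes
#'   present in the ranking (defaults 15 and 500).
#' @param seed Integer seed; results are deterministic given the seed.
#' @return An `enrichment_result` tibble ordered by NES descending:
#'   `set_name`, `size`, `es`, `nes`, `nominal_p`, `fdr_q`, `leading_edge`
#'   (list column of genes up to the running-sum extremum). Attributes
#'   `mode` and `n_perm` record the null used.
#' @export
permutation_significance <- function(expr, class_a, class_b, gene_sets,
                                     n_perm = 1000,
                                     mode = c("auto", "phenotype", "gene_set"),
                                     weight_p = 1, min_size = 15,
                                     max_size = 500, seed = 1L) {
  mode <- match.arg(mode)
  if (n_perm < 100) abort("`n_perm` must be >= 100.")
  expr <- resolve_expression(expr)
  if (mode == "auto") {
    mode <- if (min(length(class_a), length(class_b)) >= 7) {
      "phenotype"
    } else {
      "gene_set"
    }
  }
  if (mode == "phenotype" && min(length(class_a), length(class_b)) < 3) {
    abort("phenotype permutation needs >= 3 samples per class.")
  }

  ranked <- signal_to_noise_rank(expr, class_a, class_b)
  genes <- ranked$gene
  n_genes <- length(genes)

  sizes0 <- vapply(gene_sets, function(g) length(intersect(g, genes)), 0L)
  if (any(sizes0 == 0)) {
    warn(sprintf(
      "dropping %d set(s) with no gene in the expression matrix.",
      sum(sizes0 == 0)
    ))
  }
  keep <- sizes0 >= max(1, min_size) & sizes0 <= max_size
  gene_sets <- gene_sets[keep]
  if (length(gene_sets) == 0) abort("no gene set passes the size filter.")

  hits <- lapply(gene_sets, function(g) genes %in% g)
  sizes <- vapply(hits, sum, 0L)
  obs_es <- vapply(hits, function(h) es_only(ranked$metric, h, weight_p), 0)

  n_sets <- length(gene_sets)
  m <- tbl_to_matrix(expr, "gene")[genes, , drop = FALSE]
  perm_es <- withr::with_seed(seed, {
    if (mode == "phenotype") {
      cols <- c(class_a, class_b)
      na <- length(class_a)
      vapply(seq_len(n_perm), function(p) {
        perm <- sample(cols)
        met <- s2n_metric(
          m[, perm[seq_len(na)], drop = FALSE],
          m[, perm[-seq_len(na)], drop = FALSE]
        )
        ord <- order(-met, genes)
        met_sorted <- met[ord]
        vapply(seq_len(n_sets), function(j) {
          es_only(met_sorted, hits[[j]][ord], weight_p)
        }, 0)
      }, numeric(n_sets))
    } else {
      vapply(seq_len(n_perm), function(p) {
        vapply(seq_len(n_sets), function(j) {
          h <- logical(n_genes)
          h[sample.int(n_genes, sizes[j])] <- TRUE
          es_only(ranked$metric, h, weight_p)
        }, 0)
      }, numeric(n_sets))
    }
  })
  perm_es <- matrix(perm_es, nrow = n_sets) # sets x perms

  pos_mean <- apply(perm_es, 1, function(e) mean(e[e >= 0]))
  neg_mean <- apply(perm_es, 1, function(e) mean(abs(e[e < 0])))
  norm_of <- function(e, i) {
    ifelse(e >= 0, e / pos_mean[i], e / neg_mean[i])
  }
  nes <- vapply(seq_len(n_sets), function(i) norm_of(obs_es[i], i), 0)
  perm_nes <- t(vapply(
    seq_len(n_sets),
    function(i) norm_of(perm_es[i, ], i),
    numeric(n_perm)
  ))

  nominal_p <- vapply(seq_len(n_sets), function(i) {
    e <- perm_es[i, ]
    if (obs_es[i] >= 0) {
      same <- e[e >= 0]
      if (length(same) == 0) return(0)
      mean(same >= obs_es[i])
    } else {
      same <- e[e < 0]
      if (length(same) == 0) return(0)
      mean(same <= obs_es[i])
    }
  }, 0)

  all_perm_nes <- as.vector(perm_nes)
  all_perm_nes <- all_perm_nes[is.finite(all_perm_nes)]
  obs_f <- nes[is.finite(nes)]
  fdr_q <- vapply(seq_len(n_sets), function(i) {
    s <- nes[i]
    if (!is.finite(s)) {
      return(NA_real_)
    }
    if (s >= 0) {
      denom_perm <- sum(all_perm_nes >= 0)
      num <- if (denom_perm > 0) sum(all_perm_nes >= s) / denom_perm else 0
      denom_obs <- sum(obs_f >= 0)
      den <- if (denom_obs > 0) sum(obs_f >= s) / denom_obs else 1
    } else {
      denom_perm <- sum(all_perm_nes < 0)
      num <- if (denom_perm > 0) sum(all_perm_nes <= s) / denom_perm else 0
      denom_obs <- sum(obs_f < 0)
      den <- if (denom_obs > 0) sum(obs_f <= s) / denom_obs else 1
    }
    if (den == 0) {
      return(0)
    }
    min(1, max(0, num / den))
  }, 0)

  leading <- purrr::map(seq_len(n_sets), function(i) {
    run <- es_running(ranked$metric, hits[[i]], weight_p)
    peak <- es_peak(run)
    if (obs_es[i] >= 0) {
      genes[seq_len(peak)][hits[[i]][seq_len(peak)]]
    } else {
      idx <- seq(peak + 1, n_genes)
      genes[idx][hits[[i]][idx]]
    }
  })

  out <- tibble::tibble(
    set_name = names(gene_sets),
    size = as.integer(sizes),
    es = obs_es,
    nes = nes,
    nominal_p = nominal_p,
    fdr_q = fdr_q,
    leading_edge = leading
  )
  out <- out[order(-out$nes), ]
  structure(out,
    mode = mode, n_perm = n_perm,
    class = c("enrichment_result", class(out))
  )
}

#' Intersect enriched gene sets across datasets
#'
#' Filters each dataset's enrichment results to sets with the requested
#' enrichment direction and `fdr_q` below the cutoff, then reports the sets
#' shared by all datasets together with pairwise overlap counts - the
#' cross-dataset consistency check for hallmark enrichments.
#'
#' @param results_by_dataset Named list (>= 2 entries) of
#'   `enrichment_result` tibbles from [permutation_significance()].
#' @param fdr_cut FDR cutoff (default 0.25, the conventional GSEA screen).
#' @param direction `"positive"` (enriched in class A) or `"negative"`.
#' @return List of class `enrichment_comparison` with `per_dataset` (named
#'   list of passing set names), `intersection` (sets shared by all), and
#'   `pairwise` (tibble of pairwise overlap counts).
#' @export
compare_enriched_sets <- function(results_by_dataset, fdr_cut = 0.25,
                                  direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (length(results_by_dataset) < 2) abort("need at least 2 datasets.")
  if (is.null(names(results_by_dataset))) {
    names(results_by_dataset) <- paste0("dataset", seq_along(results_by_dataset))
  }
  per <- purrr::map(results_by_dataset, function(res) {
    sgn <- if (direction == "positive") res$nes >= 0 else res$nes < 0
    sort(res$set_name[sgn & !is.na(res$fdr_q) & res$fdr_q < fdr_cut])
  })
  inter <- Reduce(intersect, per)
  nm <- names(per)
  pairs <- utils::combn(nm, 2)
  pairwise <- tibble::tibble(
    dataset_a = pairs[1, ],
    dataset_b = pairs[2, ],
    n_shared = apply(pairs, 2, function(p) {
      length(intersect(per[[p[1]]], per[[p[2]]]))
    })
  )
  structure(
    list(per_dataset = per, intersection = inter, pairwise = pairwise),
    class = "enrichment_comparison"
  )
}

#' @export
print.enrichment_comparison <- function(x, ...) {
  cat("<enrichment_comparison>\n")
  for (nm in names(x$per_dataset)) {
    cat("  ", nm, ": ", length(x$per_dataset[[nm]]), " enriched set(s)\n",
      sep = ""
    )
  }
  cat(
    "  shared by all: ", length(x$intersection),
    if (length(x$intersection) > 0) {
      paste0(" (", paste(x$intersection, collapse = ", "), ")")
    } else {
      ""
    }, "\n",
    sep = ""
  )
  invisible(x)
}
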