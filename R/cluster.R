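#' One-minus-Spearman distance between killing profiles
#'
#' Pairwise-complete Spearman rank correlation (average ranks for ties)
#' between compound profiles (rows) or cell-line profiles (columns), mapped
#' to the distance `1 - rho` in `[0, 2]`. Pairs sharing fewer than 3
#' non-missing observations get a missing distance, with a warning.
#'
#' @param data A [drug_response] or wide logFC tibble.
#' @param axis Whether items are `"compounds"` (rows) or `"lines"` (columns).
#' @return A symmetric `distance_matrix` (base matrix with item dimnames and
#'   zero diagonal).
#' @export
spearman_distance <- function(data, axis = c("compounds", "lines")) {
  axis <- match.arg(axis)
  m <- tbl_to_matrix(resolve_logfc(data), "compound_id")
  if (axis == "compounds") m <- t(m)
  # items are now columns
  rho <- suppressWarnings(
    cor(m, method = "spearman", use = "pairwise.complete.obs")
  )
  shared <- crossprod(!is.na(m))
  d <- 1 - rho
  low <- shared < 3
  diag(low) <- FALSE
  if (any(low)) {
    warn(sprintf(
      "%d item pair(s) share fewer than 3 observations; distance set missing.",
      sum(low) / 2
    ))
    d[low] <- NA_real_
  }
  diag(d) <- 0
  structure(d, class = c("distance_matrix", class(d)), axis = axis)
}

#' Agglomerative clustering of a distance matrix
#'
#' Complete-linkage (by default) hierarchical clustering on a precomputed
#' distance matrix, as used for both compound and cell-line dendrograms of a
#' screen heatmap.
#'
#' @param dist A `distance_matrix` from [spearman_distance()] (or any
#'   symmetric matrix with dimnames).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return An [stats::hclust] merge tree.
#' @export
hcluster <- function(dist, linkage = "complete") {
  if (anyNA(dist)) {
    abort(paste(
      "distance matrix contains missing entries;",
      "filter items or impute before clustering."
    ))
  }
  hclust(as.dist(dist), method = linkage)
}

#' Cut a dendrogram into k clusters
#'
#' Removes the `k - 1` tallest merges and returns the induced partition.
#'
#' @param tree An [stats::hclust] object.
#' @param k Number of clusters, between 1 and the number of items.
#' @return Tibble with columns `item` and `cluster`.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$labels %||% tree$order)
  if (k < 1 || k > n) abort("`k` must lie in [1, number of items].")
  cl <- cutree(tree, k = k)
  tibble::tibble(item = names(cl), cluster = as.integer(cl))
}

#' Repeated 2-D t-SNE embeddings of a distance matrix
#'
#' Runs several independent t-SNE embeddings (distinct seeds) of the same
#' precomputed distance matrix. Repeated runs are the input to the
#' consistency rule of [consistent_proximity()]: a mechanism is only assigned
#' to a query compound when the proximity holds in every run.
#'
#' @param dist A `distance_matrix` (no missing entries).
#' @param perplexity t-SNE perplexity (default 30). When the item count is
#'   too small for the requested perplexity it is reduced to the largest
#'   feasible value, with a warning.
#' @param learning_rate t-SNE learning rate / epsilon (default 100).
#' @param n_runs Number of independent runs (default 10).
#' @param seeds Integer seeds, one per run (default `1:n_runs`).
#' @param max_iter Optimizer iterations per run.
#' @param theta Barnes-Hut accuracy parameter (0 = exact).
#' @return An `embedding_set` tibble with columns `run`, `seed`, `item`,
#'   `T1`, `T2` and attributes `perplexity`, `learning_rate`.
#' @export
tsne_runs <- function(dist, perplexity = 30, learning_rate = 100,
                      n_runs = 10, seeds = NULL, max_iter = 1000,
                      theta = 0.5) {
  if (anyNA(dist) || any(!is.finite(dist))) {
    abort("distance matrix must be finite for embedding.")
  }
  n <- nrow(dist)
  if (is.null(seeds)) seeds <- seq_len(n_runs)
  if (length(seeds) != n_runs) abort("`seeds` must have length `n_runs`.")
  max_perp <- floor((n - 1) / 3)
  if (perplexity > max_perp) {
    warn(sprintf(
      "item count %d too small for perplexity %g; using %d.",
      n, perplexity, max_perp
    ))
    perplexity <- max_perp
  }
  items <- rownames(dist) %||% as.character(seq_len(n))
  runs <- purrr::map2(seq_len(n_runs), seeds, function(r, s) {
    withr::with_seed(s, {
      fit <- Rtsne::Rtsne(
        stats::as.dist(dist),
        dims = 2, perplexity = perplexity, eta = learning_rate,
        is_distance = TRUE, pca = FALSE, max_iter = max_iter,
        theta = theta, check_duplicates = FALSE, verbose = FALSE
      )
    })
    tibble::tibble(
      run = r, seed = s, item = items,
      T1 = fit$Y[, 1], T2 = fit$Y[, 2]
    )
  })
  out <- dplyr::bind_rows(runs)
  structure(out,
    perplexity = perplexity, learning_rate = learning_rate,
    class = c("embedding_set", class(out))
  )
}

#' Assign putative mechanisms by all-runs embedding proximity
#'
#' For each query compound (typically non-oncology, mechanism unknown) and
#' each embedding run, the `k` nearest embedded compounds (2-D Euclidean,
#' the query itself excluded) are tallied by the mechanism of action of the
#' reference compounds among them; neighbors outside the reference set
#' dilute every fraction, so a query must sit inside a mechanism's cluster
#' - not merely closer to it than to the others - to gather support. A run
#' supports mechanism `m` when `m`'s fraction of the `k` neighbors is at
#' least `min_frac` and is the unique plurality. A mechanism is assigned
#' only when the same mechanism is supported in every run - the
#' conservative consistency rule behind highlighting repurposing
#' candidates.
#'
#' @param emb An `embedding_set` from [tsne_runs()].
#' @param query_ids Item ids to assign.
#' @param reference_moa Named character vector (names = reference item ids,
#'   values = MOA labels) or a tibble with `compound_id` and `moa` columns.
#' @param k Number of nearest reference neighbors per run.
#' @param min_frac Minimum neighbor fraction for a run to support a
#'   mechanism.
#' @return Tibble with one row per query: `query_id`, `assigned_moa` (`NA`
#'   when no mechanism is supported in all runs), `supporting_runs` (runs
#'   supporting the modal mechanism), `mean_neighbor_frac` (mean supporting
#'   fraction over those runs).
#' @export
consistent_proximity <- function(emb, query_ids, reference_moa, k = 10,
                                 min_frac = 0.5) {
  if (is.data.frame(reference_moa)) {
    reference_moa <- setNames(
      as.character(reference_moa$moa),
      reference_moa$compound_id
    )
  }
  ref_ids <- names(reference_moa)
  if (length(ref_ids) == 0) abort("reference set must be non-empty.")
  if (k > length(ref_ids)) abort("`k` cannot exceed the reference set size.")
  if (min_frac <= 0 || min_frac > 1) abort("`min_frac` must lie in (0, 1].")

  runs <- split(emb, emb$run)
  n_runs <- length(runs)

  support <- purrr::map(runs, function(rt) {
    coords <- as.matrix(rt[c("T1", "T2")])
    rownames(coords) <- rt$item
    vapply(query_ids, function(q) {
      others <- setdiff(rt$item, q)
      xy <- coords[others, , drop = FALSE]
      d2 <- (xy[, 1] - coords[q, 1])^2 + (xy[, 2] - coords[q, 2])^2
      nn <- others[order(d2)[seq_len(min(k, length(others)))]]
      moas <- reference_moa[nn[nn %in% ref_ids]]
      if (length(moas) == 0) {
        return(NA_character_)
      }
      tab <- sort(table(moas), decreasing = TRUE)
      frac <- tab[1] / k
      unique_plurality <- length(tab) == 1 || tab[1] > tab[2]
      if (frac >= min_frac && unique_plurality) {
        paste(names(tab)[1], frac, sep = "\r")
      } else {
        NA_character_
      }
    }, character(1))
  })

  rows <- purrr::map(seq_along(query_ids), function(i) {
    per_run <- vapply(support, `[[`, character(1), i)
    moas <- sub("\r.*$", "", per_run)
    fracs <- suppressWarnings(as.numeric(sub("^.*\r", "", per_run)))
    ok <- !is.na(moas)
    if (!any(ok)) {
      return(tibble::tibble(
        query_id = query_ids[i], assigned_moa = NA_character_,
        supporting_runs = 0L, mean_neighbor_frac = NA_real_
      ))
    }
    tab <- sort(table(moas[ok]), decreasing = TRUE)
    modal <- names(tab)[1]
    n_support <- as.integer(tab[1])
    tibble::tibble(
      query_id = query_ids[i],
      assigned_moa = if (n_support == n_runs) modal else NA_character_,
      supporting_runs = n_support,
      mean_neighbor_frac = mean(fracs[ok & moas == modal])
    )
  })
  dplyr::bind_rows(rows)
}
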