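test_that("spearman distance matches hand-computed rank correlations", {
  tbl <- tibble::tibble(
    compound_id = c("a", "b", "c"),
    l1 = c(1, 1, 4), l2 = c(2, 3, 3), l3 = c(3, 2, 2), l4 = c(4, 4, 1)
  )
  d <- spearman_distance(tbl)
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "b"], 0.2) # rho = 0.8 by hand
  expect_equal(d["a", "c"], 2) # exactly reversed ranks
  expect_true(isSymmetric(unclass(d)))
})

test_that("spearman distance is invariant under monotone transforms and flags sparse pairs", {
  set.seed(3)
  tbl <- tibble::tibble(
    compound_id = c("a", "b"),
    !!!setNames(as.list(as.data.frame(matrix(rnorm(16), 2))), paste0("l", 1:8))
  )
  d1 <- spearman_distance(tbl)
  warped <- tbl
  warped[warped$compound_id == "a", -1] <-
    exp(warped[warped$compound_id == "a", -1]) # strictly monotone
  d2 <- spearman_distance(warped)
  expect_equal(d1["a", "b"], d2["a", "b"])

  sparse <- tibble::tibble(
    compound_id = c("a", "b"),
    l1 = c(1, 2), l2 = c(2, NA), l3 = c(3, NA), l4 = c(NA, 1)
  )
  expect_warning(ds <- spearman_distance(sparse), "fewer than 3")
  expect_true(is.na(ds["a", "b"]))
})

test_that("complete-linkage agglomeration follows the hand-worked merge order", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 0.1
  d["A", "C"] <- d["C", "A"] <- 0.9
  d["B", "C"] <- d["C", "B"] <- 0.95
  hc <- hcluster(d)
  expect_equal(hc$height, c(0.1, 0.95)) # first {A,B}, then complete-linkage max
  expect_true(all(diff(hc$height) >= 0)) # monotone heights

  cl <- cut_tree(hc, 2)
  expect_equal(cl$cluster[cl$item == "A"], cl$cluster[cl$item == "B"])
  expect_false(cl$cluster[cl$item == "A"] == cl$cluster[cl$item == "C"])
  expect_equal(unique(cut_tree(hc, 1)$cluster), 1L)
  expect_equal(sort(cut_tree(hc, 3)$cluster), 1:3)
  expect_error(cut_tree(hc, 0), "k")

  d["A", "B"] <- d["B", "A"] <- NA
  expect_error(hcluster(d), "missing")
})

test_that("two-item and identical-item dendrograms are degenerate but valid", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(hcluster(d2)$height, 0.4)
  d0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(all(hcluster(d0)$height == 0))
})

test_that("t-SNE runs are seed-deterministic and separate planted blobs", {
  sim <- generate_screen(
    n_compounds = 40, n_lines = 15, frac_active = 1,
    moa_spec = c(blob1 = 20, blob2 = 20), noise_sd = 0.2, seed = 4
  )
  d <- spearman_distance(sim$screen$logfc)
  expect_warning(
    emb <- tsne_runs(d, perplexity = 30, n_runs = 3, seeds = c(5, 5, 6)),
    "perplexity"
  )
  r1 <- emb[emb$run == 1, c("T1", "T2")]
  r2 <- emb[emb$run == 2, c("T1", "T2")]
  expect_identical(r1, r2) # same seed, identical coordinates
  expect_false(identical(r1, emb[emb$run == 3, c("T1", "T2")]))

  moa <- sim$truth$moa_assignment
  for (r in unique(emb$run)) {
    co <- emb[emb$run == r, ]
    xy <- as.matrix(co[c("T1", "T2")])
    rownames(xy) <- co$item
    within <- function(ids) mean(dist(xy[ids, ]))
    b1 <- names(moa)[moa == "blob1"]
    b2 <- names(moa)[moa == "blob2"]
    between <- mean(sqrt(rowSums((
      xy[rep(b1, length(b2)), ] - xy[rep(b2, each = length(b1)), ]
    )^2)))
    expect_lt(within(b1), between)
    expect_lt(within(b2), between)
  }
})

test_that("proximity assignment requires unanimous, dominant, unique support", {
  ref <- fixture_reference_moa()
  emb <- fixture_embedding(n_runs = 3, query_at = c(0, 0))
  res <- consistent_proximity(emb, "query", ref, k = 5, min_frac = 0.6)
  expect_equal(res$assigned_moa, "EGFR inhibitor")
  expect_equal(res$supporting_runs, 3L)
  expect_equal(res$mean_neighbor_frac, 1)

  # far from every cluster: no support anywhere
  far <- fixture_embedding(n_runs = 3, query_at = c(50, -50))
  none <- consistent_proximity(far, "query", ref, k = 5, min_frac = 0.6)
  expect_true(is.na(none$assigned_moa))

  # supported in 2 of 3 runs only -> no assignment (all-runs rule)
  mixed <- dplyr::bind_rows(
    fixture_embedding(n_runs = 2, query_at = c(0, 0)),
    dplyr::mutate(fixture_embedding(n_runs = 1, query_at = c(50, -50)), run = 3)
  )
  part <- consistent_proximity(mixed, "query", ref, k = 5, min_frac = 0.6)
  expect_true(is.na(part$assigned_moa))
  expect_equal(part$supporting_runs, 2L)

  # two mechanisms tied at min_frac: the run does not support either
  tie_emb <- tibble::tibble(
    run = 1, seed = 1,
    item = c("e1", "e2", "m1", "m2", "query"),
    T1 = c(1, -1, 0, 0, 0), T2 = c(0, 0, 1, -1, 0)
  )
  tie_ref <- setNames(c("EGFR", "EGFR", "MEK", "MEK"), c("e1", "e2", "m1", "m2"))
  tie <- consistent_proximity(tie_emb, "query", tie_ref, k = 4, min_frac = 0.5)
  expect_true(is.na(tie$assigned_moa))

  expect_error(
    consistent_proximity(emb, "query", character(0), k = 2),
    "non-empty"
  )
  expect_error(consistent_proximity(emb, "query", ref, k = 50), "exceed")
})
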