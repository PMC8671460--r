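test_that("signal-to-noise ranking applies the sd floor and antisymmetry", {
  ex <- tibble::tibble(
    gene = c("flat", "shift"),
    a1 = c(3, 2), a2 = c(3, 2), b1 = c(3, 0), b2 = c(3, 0)
  )
  rk <- signal_to_noise_rank(ex, c("a1", "a2"), c("b1", "b2"))
  expect_equal(rk$metric[rk$gene == "flat"], 0)
  # sd 0 floored at max(0.2 * |mean|, 0.2): 0.4 and 0.2 -> 2 / 0.6
  expect_equal(rk$metric[rk$gene == "shift"], 2 / 0.6)

  swapped <- signal_to_noise_rank(ex, c("b1", "b2"), c("a1", "a2"))
  expect_equal(
    swapped$metric[match(rk$gene, swapped$gene)], -rk$metric
  )
  expect_error(signal_to_noise_rank(ex, "a1", c("b1", "b2")), "at least 2")
})

test_that("enrichment score matches the running-sum oracle on random lists", {
  set.seed(41)
  for (i in 1:60) {
    n <- sample(10:50, 1)
    rl <- tibble::tibble(
      gene = sprintf("G%02d", 1:n),
      metric = sort(rnorm(n), decreasing = TRUE)
    )
    gs <- sample(rl$gene, sample(2:min(8, n - 1), 1))
    p <- sample(c(0, 1), 1)
    es <- enrichment_score(rl, gs, weight_p = p)
    expect_equal(es$es, oracle_es(rl$metric, rl$gene %in% gs, p))
    # conservation: the running sum returns to zero
    expect_lt(abs(dplyr::last(es$running$running)), 1e-9)
    expect_lte(abs(es$es), 1)
  }
})

test_that("enrichment score agrees with the fgsea statistic", {
  set.seed(43)
  for (i in 1:10) {
    n <- 40
    rl <- tibble::tibble(
      gene = sprintf("G%02d", 1:n),
      metric = sort(rnorm(n), decreasing = TRUE)
    )
    gs <- sample(rl$gene, 6)
    mine <- enrichment_score(rl, gs, weight_p = 1)$es
    stats <- setNames(rl$metric, rl$gene)
    ref <- fgsea::calcGseaStat(stats, selectedStats = which(rl$gene %in% gs))
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("boundary gene sets produce the expected extreme scores", {
  rl <- tibble::tibble(gene = sprintf("G%02d", 1:10), metric = 10:1)
  expect_equal(enrichment_score(rl, "G01")$es, 1)
  expect_equal(enrichment_score(rl, "G10")$es, -1) # deepest just before the hit
  expect_error(enrichment_score(rl, "absent"), "no gene")
})

test_that("permutation significance finds a planted set and is deterministic", {
  lines <- sprintf("l%02d", 1:16)
  planted <- sprintf("g%04d", 1:20)
  ex <- generate_expression(
    n_genes = 400, lines = lines, group_a = lines[1:8],
    deg_frac = 0, enriched_sets = list(planted = planted),
    enrich_delta = 1.2, noise_sd = 1, seed = 47
  )
  sets <- c(
    list(planted = planted),
    setNames(
      lapply(1:5, function(i) sprintf("g%04d", 20 + (i - 1) * 20 + 1:20)),
      paste0("bystander", 1:5)
    )
  )
  res <- permutation_significance(
    ex$expr, lines[1:8], lines[9:16], sets,
    n_perm = 200, mode = "phenotype", seed = 3
  )
  expect_equal(attr(res, "mode"), "phenotype")
  expect_equal(res$set_name[which.max(abs(res$nes))], "planted")
  expect_lte(res$nominal_p[res$set_name == "planted"], 0.05)
  expect_true(all(res$fdr_q >= 0 & res$fdr_q <= 1, na.rm = TRUE))
  expect_true(all(sign(res$nes) == sign(res$es) | res$es == 0))
  # leading edge of the planted set is drawn from the planted genes
  lead <- res$leading_edge[[which(res$set_name == "planted")]]
  expect_true(all(lead %in% planted))

  res2 <- permutation_significance(
    ex$expr, lines[1:8], lines[9:16], sets,
    n_perm = 200, mode = "phenotype", seed = 3
  )
  expect_identical(as.data.frame(res), as.data.frame(res2))

  # small-sample auto mode falls back to gene-set permutation
  small_lines <- sprintf("s%02d", 1:8)
  ex_small <- generate_expression(
    n_genes = 400, lines = small_lines, group_a = small_lines[1:4],
    deg_frac = 0, enriched_sets = list(planted = planted),
    enrich_delta = 1.5, noise_sd = 1, seed = 49
  )
  res3 <- permutation_significance(
    ex_small$expr, small_lines[1:4], small_lines[5:8], sets,
    n_perm = 100, mode = "auto", seed = 5
  )
  expect_equal(attr(res3, "mode"), "gene_set")
  expect_equal(res3$set_name[which.max(abs(res3$nes))], "planted")

  # sets with no gene in the matrix are dropped with a warning
  expect_warning(
    permutation_significance(
      ex$expr, lines[1:8], lines[9:16],
      c(sets, list(ghost = c("zz1", "zz2"))),
      n_perm = 100, seed = 1
    ),
    "no gene"
  )
})

test_that("label swap mirrors enrichment scores", {
  lines <- sprintf("l%02d", 1:12)
  ex <- generate_expression(
    n_genes = 200, lines = lines, group_a = lines[1:6],
    deg_frac = 0, enriched_sets = list(s = sprintf("g%04d", 1:15)),
    seed = 51
  )
  rk_ab <- signal_to_noise_rank(ex$expr, lines[1:6], lines[7:12])
  rk_ba <- signal_to_noise_rank(ex$expr, lines[7:12], lines[1:6])
  es_ab <- enrichment_score(rk_ab, sprintf("g%04d", 1:15))$es
  es_ba <- enrichment_score(rk_ba, sprintf("g%04d", 1:15))$es
  expect_equal(es_ab, -es_ba, tolerance = 1e-9)
})

test_that("cross-dataset intersection of enriched sets counts shared hallmarks", {
  mk <- function(names, qs, nes = 1) {
    structure(
      tibble::tibble(
        set_name = names, size = 20L, es = nes * 0.5, nes = nes,
        nominal_p = 0.01, fdr_q = qs,
        leading_edge = replicate(length(names), character(0), simplify = FALSE)
      ),
      class = c("enrichment_result", class(tibble::tibble()))
    )
  }
  shared <- c("E2F_TARGETS", "MYC_TARGETS_V2", "G2M_CHECKPOINT", "SPERMATOGENESIS")
  r1 <- mk(c(shared, "ONLY1"), rep(0.1, 5))
  r2 <- mk(c(shared, "ONLY2"), rep(0.2, 5))
  r3 <- mk(c(shared, "ONLY3", "ONLY4"), c(rep(0.05, 4), 0.1, 0.3))
  cmp <- compare_enriched_sets(list(a = r1, b = r2, c = r3), fdr_cut = 0.25)
  expect_setequal(cmp$intersection, shared)
  expect_equal(nrow(cmp$pairwise), 3)
  expect_equal(cmp$pairwise$n_shared[1], 4)

  # identical lists intersect to the filtered list; disjoint lists to nothing
  same <- compare_enriched_sets(list(x = r1, y = r1))
  expect_setequal(same$intersection, c(shared, "ONLY1"))
  disjoint <- compare_enriched_sets(list(x = mk("A", 0.1), y = mk("B", 0.1)))
  expect_length(disjoint$intersection, 0)

  # direction filter removes positively enriched sets
  neg <- compare_enriched_sets(list(x = r1, y = r2), direction = "negative")
  expect_length(neg$intersection, 0)
  expect_error(compare_enriched_sets(list(r1)), "at least 2")
})
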