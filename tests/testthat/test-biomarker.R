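test_that("extreme-responder selection orders lines by mean response", {
  tbl <- tibble::tibble(
    compound_id = c("m1", "m2"),
    w = c(-2, -2), x = c(-1, -1), y = c(0, 0), z = c(1, 1)
  )
  grp <- rank_lines_by_mean_response(tbl, c("m1", "m2"), 1)
  expect_equal(grp$sensitive, "w")
  expect_equal(grp$resistant, "z")

  full <- rank_lines_by_mean_response(tbl, c("m1", "m2"), 2)
  expect_setequal(c(full$sensitive, full$resistant), c("w", "x", "y", "z"))
  expect_error(rank_lines_by_mean_response(tbl, c("m1", "m2"), 3), "fewer")
  expect_error(rank_lines_by_mean_response(tbl, character(0), 1), "non-empty")

  # planted-susceptible lines surface as the sensitive extreme
  sim <- generate_screen(
    n_compounds = 40, n_lines = 10, frac_active = 0.5,
    moa_spec = c(MEKi = 10), susceptible_frac = 0.5, seed = 6
  )
  moa <- sim$truth$moa_assignment
  meki <- names(moa)[moa == "MEKi"]
  latent <- sim$truth$moa_latent["MEKi", ]
  grp2 <- rank_lines_by_mean_response(sim$screen, meki, 3)
  expect_true(all(latent[grp2$sensitive] > 0))
})

test_that("EB prior fitting handles the degenerate and model-simulated cases", {
  expect_equal(
    fit_eb_params(rep(2.5, 50), df = 10),
    structure(list(d0 = Inf, s0_sq = 2.5), class = "eb_params")
  )
  expect_error(fit_eb_params(1:5, df = 4), "at least 10")
  expect_error(fit_eb_params(c(-1, rep(1, 20)), df = 4), "non-negative")

  set.seed(5)
  d0 <- 4
  dg <- 10
  true_var <- d0 * 1 / rchisq(5000, d0)
  s2 <- true_var * rchisq(5000, dg) / dg
  eb <- fit_eb_params(s2, dg)
  expect_gte(eb$d0, 3)
  expect_lte(eb$d0, 5)
  expect_gte(eb$s0_sq, 0.9)
  expect_lte(eb$s0_sq, 1.1)
})

test_that("EB prior fit agrees with the limma cross-check", {
  set.seed(17)
  s2 <- (4 / rchisq(2000, 4)) * rchisq(2000, 8) / 8
  eb <- fit_eb_params(s2, 8)
  ref <- limma::fitFDist(s2, df1 = 8)
  expect_equal(eb$d0, ref$df2, tolerance = 1e-6)
  expect_equal(eb$s0_sq, ref$scale, tolerance = 1e-6)
})

test_that("moderated t reproduces the stated formula and its limits", {
  ex <- tibble::tibble(
    gene = "g1",
    A1 = 5, A2 = 5, A3 = 6, A4 = 6, B1 = 1, B2 = 1, B3 = 2, B4 = 2
  )
  fixed <- structure(list(d0 = Inf, s0_sq = 0.25), class = "eb_params")
  mt <- moderated_t_test(ex, paste0("A", 1:4), paste0("B", 1:4), eb = fixed)
  expect_equal(mt$mean_diff, 4)
  expect_equal(mt$t, 4 / (0.5 * sqrt(0.5)), tolerance = 1e-12)
  expect_equal(mt$direction, "up")

  # d0 = 0: moderation vanishes, ordinary pooled t recovered exactly
  set.seed(23)
  expr <- tibble::tibble(
    gene = sprintf("g%03d", 1:50),
    !!!setNames(as.list(as.data.frame(matrix(rnorm(500), 50))), paste0("s", 1:10))
  )
  ga <- paste0("s", 1:5)
  gb <- paste0("s", 6:10)
  none <- structure(list(d0 = 0, s0_sq = 1), class = "eb_params")
  mt0 <- moderated_t_test(expr, ga, gb, eb = none)
  m <- as.matrix(expr[-1])
  pooled_t <- apply(m, 1, function(v) {
    unname(stats::t.test(v[1:5], v[6:10], var.equal = TRUE)$statistic)
  })
  expect_equal(mt0$t, unname(pooled_t), tolerance = 1e-10)

  # identical groups: no signal anywhere
  dup <- expr
  dup[paste0("s", 6:10)] <- dup[ga]
  mtd <- moderated_t_test(dup, ga, gb)
  expect_true(all(mtd$mean_diff == 0))
  expect_true(all(!mtd$significant))

  expect_error(moderated_t_test(expr, ga, c("s5", "s6")), "disjoint")
})

test_that("BH q-values are monotone in p-rank and order-invariant", {
  set.seed(29)
  lines <- sprintf("l%02d", 1:12)
  ex <- generate_expression(
    n_genes = 300, lines = lines, group_a = lines[1:6],
    deg_frac = 0.1, seed = 31
  )
  deg <- moderated_t_test(ex$expr, lines[1:6], lines[7:12])
  ord <- order(deg$p_value)
  expect_true(all(diff(deg$q_value[ord]) >= -1e-12))
  shuffled <- ex$expr[sample(nrow(ex$expr)), ]
  deg2 <- moderated_t_test(shuffled, lines[1:6], lines[7:12])
  expect_equal(
    deg2$q_value[match(deg$gene, deg2$gene)], deg$q_value
  )
})

test_that("hypergeometric over-representation matches the closed form", {
  universe <- sprintf("u%02d", 1:20)
  hits <- universe[1:5]
  sets <- list(
    good = c(universe[2:5], universe[10]), # overlap 4 of 5
    cold = universe[16:18] # overlap 0
  )
  res <- overrepresentation(hits, universe, sets)
  expect_equal(
    res$p_value[res$set_name == "good"], 76 / 15504,
    tolerance = 1e-12
  )
  expect_equal(res$overlap[res$set_name == "good"], 4L)
  expect_gte(res$p_value[res$set_name == "cold"], 0.5)
  expect_equal(res$set_name[1], "good") # ordered by p

  # degenerate: hit set identical to the set and the universe
  degenerate <- overrepresentation(universe, universe, list(all = universe))
  expect_equal(degenerate$p_value, 1)

  expect_error(overrepresentation("x", character(0), list()), "non-empty")
  expect_error(overrepresentation("zz", universe, list()), "subset")
})

test_that("expression-response correlation matches hand computation", {
  ex <- tibble::tibble(
    gene = c("lin", "hand", "flat"),
    l1 = c(1, 2, 5), l2 = c(2, 1, 5), l3 = c(3, 4, 5),
    l4 = c(4, 3, 5), l5 = c(5, 5, 5)
  )
  resp <- setNames(c(1, 2, 3, 4, 5), paste0("l", 1:5))
  expect_warning(res <- correlate_expression(ex, resp), "zero variance")
  expect_equal(res$r[res$gene == "lin"], 1)
  expect_equal(res$p_value[res$gene == "lin"], 0)
  expect_equal(res$r[res$gene == "hand"], 0.8) # classic hand example
  expect_false("flat" %in% res$gene)

  # three points with r = 0 -> p = 1
  ex3 <- tibble::tibble(gene = "g", a = 0, b = 1, c = 0)
  r3 <- correlate_expression(ex3, setNames(c(-1, 0, 1), c("a", "b", "c")))
  expect_equal(r3$r, 0)
  expect_equal(r3$p_value, 1)

  # planted negative-slope gene is shortlisted with the right sign
  lines <- sprintf("l%02d", 1:15)
  exn <- generate_expression(
    n_genes = 50, lines = lines, corr_spec = c(g0001 = -1),
    deg_frac = 0, noise_sd = 0.3, seed = 7
  )
  hit <- correlate_expression(exn$expr, exn$truth$response, genes = "g0001")
  expect_true(hit$shortlisted)
  expect_lt(hit$r, 0)
})

test_that("signature scores are mean Z-scores with the stated invariances", {
  ex <- tiny_expression()
  single <- signature_score(ex, "EGFR")
  z <- scale(as.numeric(ex[ex$gene == "EGFR", -1]))
  expect_equal(single$score, as.numeric(z))

  # two perfectly anti-correlated genes cancel to zero
  anti <- tibble::tibble(
    gene = c("up", "down"), l1 = c(1, 4), l2 = c(2, 3), l3 = c(3, 2), l4 = c(4, 1)
  )
  expect_true(all(abs(signature_score(anti, c("up", "down"))$score) < 1e-12))

  # affine rescaling of one gene leaves scores unchanged
  sig <- c("EGFR", "AREG", "TGFA")
  base <- signature_score(ex, sig)
  rescaled <- ex
  rescaled[rescaled$gene == "AREG", -1] <-
    rescaled[rescaled$gene == "AREG", -1] * 7 + 100
  expect_equal(signature_score(rescaled, sig)$score, base$score)

  expect_warning(
    partial <- signature_score(ex, c("EGFR", "NOPE")),
    "absent"
  )
  expect_equal(partial$score, single$score)
  expect_error(signature_score(ex, "NOPE"), "no signature gene")
})
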