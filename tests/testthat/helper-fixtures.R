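# tiny hand-sized fixtures shared across test files

tiny_logfc <- function() {
  tibble::tibble(
    compound_id = c("cpdA", "cpdB", "cpdC"),
    line1 = c(-1.5, -1.0, 0.1),
    line2 = c(-2.0, -0.2, NA),
    line3 = c(-0.2, -1.3, 0.4)
  )
}

tiny_expression <- function() {
  tibble::tibble(
    gene = c("EGFR", "AREG", "TGFA"),
    l1 = c(5, 2, 1),
    l2 = c(6, 3, 2),
    l3 = c(7, 4, 3),
    l4 = c(8, 5, 4)
  )
}

# an embedding set constructed by hand: a 10-member reference cluster at the
# origin, a second cluster far away, plus unlabeled background compounds
# scattered around (50, -50); identical across runs
fixture_embedding <- function(n_runs = 3, query_at = c(0, 0)) {
  ref1 <- sprintf("egfr%02d", 1:10)
  ref2 <- sprintf("mek%02d", 1:10)
  bg <- sprintf("bg%02d", 1:10)
  one_run <- function(r) {
    tibble::tibble(
      run = r,
      seed = r,
      item = c(ref1, ref2, bg, "query"),
      T1 = c(cos(1:10), 100 + cos(1:10), 50 + cos(1:10), query_at[1]),
      T2 = c(sin(1:10), 100 + sin(1:10), -50 + sin(1:10), query_at[2])
    )
  }
  out <- dplyr::bind_rows(lapply(seq_len(n_runs), one_run))
  structure(out, class = c("embedding_set", class(out)))
}

fixture_reference_moa <- function() {
  stats::setNames(
    rep(c("EGFR inhibitor", "MEK inhibitor"), each = 10),
    c(sprintf("egfr%02d", 1:10), sprintf("mek%02d", 1:10))
  )
}

# brute-force confusion counting, independent of the package implementation
oracle_confusion <- function(values, labels, t) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(values)) {
    pred <- values[i] < t
    pos <- labels[i] == 1
    if (pred && pos) tp <- tp + 1L
    if (pred && !pos) fp <- fp + 1L
    if (!pred && !pos) tn <- tn + 1L
    if (!pred && pos) fn <- fn + 1L
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# step-by-step running-sum oracle for the weighted KS enrichment score;
# the signed maximum deviation, earliest position on (float-dust) ties
oracle_es <- function(metric, hit, weight_p = 1) {
  n <- length(metric)
  nh <- sum(hit)
  nr <- sum(abs(metric[hit])^weight_p)
  run <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- acc + if (hit[i]) abs(metric[i])^weight_p / nr else -1 / (n - nh)
    run[i] <- acc
  }
  run[which(abs(run) >= max(abs(run)) - 1e-12)[1]]
}
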