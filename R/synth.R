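#' Generate a synthetic pooled drug-repurposing screen with planted truth
#'
#' Emulates a PRISM-style primary screen: a compounds x cell-lines log
#' fold-change matrix in which a planted fraction of compounds is genuinely
#' active. Active compounds kill through a mechanism-of-action (MOA) latent
#' susceptibility shared by all compounds of the same MOA, so compounds with a
#' common mechanism show correlated killing profiles (the structure the
#' clustering and embedding stages exploit). Everything else is Gaussian
#' baseline noise on the logFC scale.
#'
#' The generative model is
#' \deqn{logFC(c, l) = \mu_{effect} \cdot \lambda(moa(c), l) + \epsilon,\quad
#'       \epsilon \sim N(0, \sigma^2)}
#' for active compounds, and pure noise otherwise. The latent susceptibility
#' \eqn{\lambda(m, l)} is Bernoulli(`susceptible_frac`) times
#' Uniform(`latent_range`), so each mechanism kills a subset of lines with
#' variable strength and leaves the rest untouched (selective rather than
#' uniformly broad activity). Planted killing shifts are always non-positive.
#'
#' @param n_compounds,n_lines Numbers of compounds and cell lines.
#' @param moa_spec Named integer vector mapping MOA label to the number of
#'   active compounds planted with that mechanism. `NULL` plants four blocks
#'   of up to 25 compounds each. Active compounds beyond the blocks get
#'   idiosyncratic (compound-private) susceptibility profiles and the label
#'   `"unknown"`.
#' @param frac_active Fraction of compounds planted as active.
#' @param effect_mu Mean planted logFC shift for active compounds (must be
#'   <= 0; default -2.5).
#' @param noise_sd Standard deviation of the Gaussian logFC noise (>= 0).
#' @param susceptible_frac Probability that a line is susceptible to a given
#'   mechanism.
#' @param latent_range Range of the Uniform draw for susceptible lines'
#'   latent strength; `c(1, 1)` makes susceptible lines respond with exactly
#'   `effect_mu`.
#' @param biomarker_frac Fraction of lines labelled biomarker-positive (the
#'   label is carried in the line annotations and the truth object).
#' @param seed Integer seed; the same seed reproduces the output exactly.
#'
#' @return A list with elements `screen` (a [drug_response]) and `truth`, a
#'   `screen_truth` list with fields `active_compounds`, `effect_size`
#'   (matrix of planted mean shifts, 0 for inactive compounds),
#'   `moa_assignment`, `moa_latent`, `biomarker_label`, `noise_sd`, `seed`.
#' @export
generate_screen <- function(n_compounds = 500, n_lines = 28,
                            moa_spec = NULL, frac_active = 0.2,
                            effect_mu = -2.5, noise_sd = 0.4,
                            susceptible_frac = 0.6,
                            latent_range = c(0.5, 1),
                            biomarker_frac = 0.3,
                            seed = 1L) {
  n_compounds <- assert_count(n_compounds, "n_compounds")
  n_lines <- assert_count(n_lines, "n_lines")
  frac_active <- assert_proportion(frac_active, "frac_active")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (effect_mu > 0) abort("`effect_mu` must be <= 0 (a killing shift).")
  if (is.null(moa_spec)) {
    n_active_planned <- round(frac_active * n_compounds)
    per <- min(25L, n_active_planned %/% 4L)
    moa_spec <- setNames(
      rep(per, 4L),
      c(
        "EGFR inhibitor", "MEK inhibitor",
        "PI3K/AKT/MTOR inhibitor", "aurora kinase inhibitor"
      )
    )
    moa_spec <- moa_spec[moa_spec > 0]
  }

  withr::with_seed(seed, {
    compound_ids <- sprintf("cpd%04d", seq_len(n_compounds))
    line_ids <- sprintf("line%02d", seq_len(n_lines))

    n_active <- round(frac_active * n_compounds)
    active <- sort(sample(n_compounds, n_active))
    if (sum(moa_spec) > n_active) {
      warn("`moa_spec` plants more compounds than `frac_active` allows; truncating.")
      keep <- cumsum(moa_spec) <= n_active
      moa_spec <- moa_spec[keep]
    }

    moa <- rep("unknown", n_compounds)
    moa_labels <- rep(names(moa_spec), times = moa_spec)
    if (length(moa_labels) > 0) {
      moa[active[seq_along(moa_labels)]] <- moa_labels
    }

    # latent susceptibility per mechanism; idiosyncratic actives get a
    # private profile keyed by their compound id
    latent_keys <- unique(c(
      names(moa_spec),
      compound_ids[active[moa[active] == "unknown"]]
    ))
    draw_latent <- function() {
      rbinom(n_lines, 1L, susceptible_frac) *
        runif(n_lines, latent_range[1], latent_range[2])
    }
    moa_latent <- do.call(rbind, lapply(latent_keys, function(k) draw_latent()))
    if (length(latent_keys) == 0) {
      moa_latent <- matrix(0, 0, n_lines)
    }
    rownames(moa_latent) <- latent_keys
    colnames(moa_latent) <- line_ids

    effect <- matrix(0, n_compounds, n_lines,
      dimnames = list(compound_ids, line_ids)
    )
    for (i in active) {
      key <- if (moa[i] == "unknown") compound_ids[i] else moa[i]
      effect[i, ] <- effect_mu * moa_latent[key, ]
    }

    noise <- matrix(rnorm(n_compounds * n_lines, 0, noise_sd),
      n_compounds, n_lines
    )
    values <- effect + noise

    category <- rep("non-oncology", n_compounds)
    category[moa != "unknown"] <- "targeted cancer"
    others <- which(moa == "unknown")
    if (length(others) > 0) {
      # mirror the screen's rough composition among unlabelled compounds
      cat_draw <- sample(
        c("targeted cancer", "chemotherapy", "non-oncology"),
        length(others),
        replace = TRUE, prob = c(0.21, 0.02, 0.77)
      )
      category[others] <- cat_draw
    }

    biomarker <- rbinom(n_lines, 1L, biomarker_frac)

    screen <- drug_response(
      logfc = matrix_to_tbl(values, "compound_id"),
      compounds = tibble::tibble(
        compound_id = compound_ids,
        name = compound_ids,
        category = category,
        moa = moa,
        targets = NA_character_,
        phase = NA_character_
      ),
      lines = tibble::tibble(
        line_id = line_ids,
        lineage = "upper aerodigestive",
        subtype = sample(c("OSCC", "non-OSCC"), n_lines, replace = TRUE),
        biomarker = biomarker
      )
    )

    truth <- structure(
      list(
        active_compounds = compound_ids[active],
        effect_size = effect,
        moa_assignment = setNames(moa, compound_ids),
        moa_latent = moa_latent,
        biomarker_label = setNames(biomarker, line_ids),
        noise_sd = noise_sd,
        seed = seed
      ),
      class = "screen_truth"
    )
    list(screen = screen, truth = truth)
  })
}

#' Generate a synthetic expression matrix with planted signal
#'
#' Emulates a log2(TPM + 1) expression matrix (genes x cell lines) with three
#' kinds of planted structure: differential genes shifted by `+/- deg_delta`
#' in `group_a`, genes linearly dependent on a per-line response vector
#' (planted Pearson biomarkers), and gene sets with a coordinated shift in
#' `group_a` (planted enrichment for GSEA). Baseline abundances are Uniform(2,
#' 8) and Gaussian noise is added on the log2 scale; emitted values are
#' clipped at 0 to stay on the non-negative log2(TPM + 1) scale.
#'
#' @param n_genes Number of genes (`g0001`, `g0002`, ...).
#' @param lines Character vector of cell-line ids.
#' @param group_a Subset of `lines` forming the contrast group A.
#' @param deg_frac Fraction of genes planted as differential (half up, half
#'   down in group A).
#' @param deg_delta Planted log2 shift for differential genes.
#' @param corr_spec Named numeric vector mapping gene id to slope; those genes
#'   are generated as `6 + slope * response + noise`.
#' @param response Per-line numeric response vector driving `corr_spec` genes
#'   (recycled into the truth object); default standard normal draws.
#' @param enriched_sets Named list of gene-id vectors planted with a
#'   coordinated `enrich_delta` shift upward in group A.
#' @param enrich_delta Coordinated shift for `enriched_sets` genes.
#' @param noise_sd Gaussian noise standard deviation (log2 scale).
#' @param seed Integer seed.
#'
#' @return List with `expr` (tibble: `gene` column + one column per line) and
#'   `truth` (`expression_truth` list: `deg_up`, `deg_down`, `corr_genes`
#'   (named slopes), `enriched_sets`, `response`, `seed`).
#' @export
generate_expression <- function(n_genes = 2000, lines, group_a = character(),
                                deg_frac = 0.05, deg_delta = 2,
                                corr_spec = NULL, response = NULL,
                                enriched_sets = NULL, enrich_delta = 1,
                                noise_sd = 1, seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes")
  deg_frac <- assert_proportion(deg_frac, "deg_frac")
  if (!all(group_a %in% lines)) {
    abort("`group_a` must be a subset of `lines`.")
  }
  n_lines <- length(lines)
  genes <- sprintf("g%04d", seq_len(n_genes))
  if (!is.null(corr_spec) && !all(names(corr_spec) %in% genes)) {
    abort("`corr_spec` names must be gene ids of the emitted matrix.")
  }
  if (!is.null(enriched_sets) && !all(unlist(enriched_sets) %in% genes)) {
    abort("`enriched_sets` genes must be gene ids of the emitted matrix.")
  }

  withr::with_seed(seed, {
    if (is.null(response)) response <- rnorm(n_lines)
    response <- setNames(as.numeric(response), lines)

    base <- runif(n_genes, 2, 8)
    vals <- matrix(base, n_genes, n_lines) +
      matrix(rnorm(n_genes * n_lines, 0, noise_sd), n_genes, n_lines)
    dimnames(vals) <- list(genes, lines)

    in_a <- lines %in% group_a

    reserved <- names(corr_spec)
    n_deg <- round(deg_frac * n_genes)
    deg_pool <- setdiff(genes, c(reserved, unlist(enriched_sets)))
    deg <- sample(deg_pool, min(n_deg, length(deg_pool)))
    half <- length(deg) %/% 2
    deg_up <- deg[seq_len(half)]
    deg_down <- setdiff(deg, deg_up)
    if (any(in_a)) {
      vals[deg_up, in_a] <- vals[deg_up, in_a] + deg_delta
      vals[deg_down, in_a] <- vals[deg_down, in_a] - deg_delta
    }

    for (g in names(corr_spec)) {
      vals[g, ] <- 6 + corr_spec[[g]] * response +
        rnorm(n_lines, 0, noise_sd)
    }

    for (s in names(enriched_sets)) {
      gs <- enriched_sets[[s]]
      if (any(in_a)) vals[gs, in_a] <- vals[gs, in_a] + enrich_delta
    }

    vals <- pmax(vals, 0)

    truth <- structure(
      list(
        deg_up = deg_up,
        deg_down = deg_down,
        corr_genes = corr_spec %||% setNames(numeric(0), character(0)),
        enriched_sets = names(enriched_sets) %||% character(0),
        response = response,
        seed = seed
      ),
      class = "expression_truth"
    )
    list(expr = matrix_to_tbl(vals, "gene"), truth = truth)
  })
}

#' Generate a biomarker-stratified calibration set
#'
#' Draws per-line drug responses from two Gaussians: biomarker-positive lines
#' (expected responders, e.g. BRAF-V600E melanoma under a BRAF inhibitor)
#' around `mu_pos` and biomarker-negative lines around `mu_neg`. This is the
#' construction used to pick a logFC sensitivity cutoff by Youden scanning.
#'
#' @param n_pos,n_neg Numbers of biomarker-positive / negative lines (>= 1).
#' @param mu_pos,mu_neg Group mean logFC values.
#' @param sd Common standard deviation (>= 0).
#' @param seed Integer seed.
#' @return Tibble with columns `line_id`, `logfc`, `biomarker` (1 = positive).
#' @export
generate_calibration_set <- function(n_pos, n_neg, mu_pos = -1.8,
                                     mu_neg = -0.2, sd = 0.5, seed = 1L) {
  n_pos <- assert_count(n_pos, "n_pos", min = 1L)
  n_neg <- assert_count(n_neg, "n_neg", min = 1L)
  if (sd < 0) abort("`sd` must be >= 0.")
  withr::with_seed(seed, {
    tibble::tibble(
      line_id = sprintf("line%02d", seq_len(n_pos + n_neg)),
      logfc = c(rnorm(n_pos, mu_pos, sd), rnorm(n_neg, mu_neg, sd)),
      biomarker = rep(c(1L, 0L), c(n_pos, n_neg))
    )
  })
}

#' Write a synthetic screen in the CSV dialect the readers consume
#'
#' Emits `matrix.csv` (compounds x lines logFC, with a screen-internal column
#' id per line), `line_info.csv` (screen id to line name/lineage map),
#' `compound_info.csv` (annotations) and `truth.json` (planted ground truth
#' sidecar) so that synthetic data exercises the real parsers.
#'
#' @param sim Result of [generate_screen()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_screen_csv <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  screen <- sim$screen
  line_ids <- setdiff(names(screen$logfc), "compound_id")
  screen_col <- sprintf("SCR%03d", seq_along(line_ids))
  mat <- screen$logfc
  names(mat) <- c("compound_id", screen_col)
  paths <- c(
    matrix = file.path(dir, "matrix.csv"),
    line_info = file.path(dir, "line_info.csv"),
    compound_info = file.path(dir, "compound_info.csv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_csv(mat, paths[["matrix"]])
  readr::write_csv(
    tibble::tibble(
      screen_id = screen_col,
      line_id = line_ids,
      lineage = screen$lines$lineage[match(line_ids, screen$lines$line_id)]
    ),
    paths[["line_info"]]
  )
  readr::write_csv(screen$compounds, paths[["compound_info"]])
  truth <- sim$truth
  jsonlite::write_json(
    list(
      active_compounds = truth$active_compounds,
      moa_assignment = as.list(truth$moa_assignment),
      biomarker_label = as.list(truth$biomarker_label),
      noise_sd = truth$noise_sd,
      seed = truth$seed
    ),
    paths[["truth"]],
    auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
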