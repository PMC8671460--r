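---
title: "Methods: calibrated analysis of pooled drug-repurposing screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated analysis of pooled drug-repurposing screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repurposr)
```

## The problem and the data

Pooled viability screens expose a panel of barcoded cancer cell lines to
thousands of compounds at a single dose and read out, per compound and cell
line, the log fold change (logFC) of barcode abundance relative to the DMSO
vehicle. More negative logFC means more killing. A cancer-type-specific
analysis of such a screen asks four questions in sequence: which compounds
genuinely kill (activity calling at a calibrated cutoff); which pharmacology
classes they represent (mechanism-of-action landscape and co-clustering);
which compounds kill this tumour type *preferentially* (two-class
differential sensitivity against the rest of the screen); and what
transcriptomic features predict response (differential expression,
correlation shortlists, signature scores and gene set enrichment).

`repurposr` implements that pipeline for compounds-by-lines logFC matrices
with compound and cell-line annotations, plus a synthetic-data generator
that plants known structure so every stage can be validated against ground
truth without downloading a screen.

## Threshold calibration

The sensitivity cutoff on logFC is not arbitrary: it is chosen against
biomarker ground truth. Cell lines carrying a proven response biomarker
(e.g. BRAF-V600E melanoma under a BRAF inhibitor) are the expected
responders; a line is *predicted* sensitive when its logFC falls strictly
below a candidate threshold `t`. Scanning `t` over the observed values and
maximizing Youden's index

$$J(t) = \mathrm{sensitivity}(t) + \mathrm{specificity}(t) - 1$$

selects the cutoff; ties in `J` break toward the smallest `|t|`, the most
conservative call rate. `youden_scan()` returns the whole curve and the
chosen threshold; at the conventions of this screen family the scan lands
near the classical `logFC = -1` rule, which downstream stages use as their
default. A value exactly at the threshold is predicted resistant (the rule
is "less than", not "at most").

`generate_calibration_set()` emulates the construction with two Gaussians
(responders at `mu_pos = -1.8`, non-responders at `mu_neg = -0.2`, common
`sd = 0.5`, 10 vs 40 lines). The group separation (about 3 standard
deviations) is what a strong mutational biomarker looks like in this kind
of data; under those conditions the chosen threshold concentrates in
`[-1.4, -0.6]`.

## Activity calling and the MOA landscape

At the calibrated cutoff, a compound is *active* when at least `min_lines =
3` cell lines are sensitive — an absolute count, kept fixed even when panel
sizes differ, because the count (not the ratio) is what the screen's
definition states. Missing logFC entries are neither sensitive nor
evaluable; they are excluded from both the numerator and denominator rather
than treated as resistant. Active compounds killing more than 90% of
evaluable lines are flagged broadly toxic; in the landscape summary
(`moa_landscape()`) that separates selective mechanisms from compounds
hitting essential processes. Compounds with several comma-separated
mechanism labels count once under each label, and mechanisms with fewer
than five tested compounds are hidden from the landscape by default — a
display floor on *tested* compounds, because the landscape's percentages
use tested compounds as the denominator.

## Co-clustering and mechanism assignment by embedding consistency

Killing profiles are compared with the rank-based distance `1 - Spearman's
rho` (pairwise-complete, average ranks on ties), which ignores the scale of
killing and rewards shared *patterns* of susceptible lines. Hierarchical
clustering uses complete linkage on that distance via `stats::hclust`,
whose input-order tie-break is deterministic; we use it as-is rather than
re-implementing agglomeration for an id-lexicographic tie rule, since equal
merge heights are measure-zero events in real data.

For two-dimensional maps, `tsne_runs()` drives the Rtsne implementation of
t-SNE (perplexity 30, learning rate 100) on the precomputed distance —
re-implementing the optimizer is a non-goal. Because t-SNE is stochastic,
the pipeline runs it ten times from seeds `1..n_runs` and only trusts
conclusions stable across all runs. When an item set is too small for the
requested perplexity the largest feasible value is used, with a warning.

The consistency rule (`consistent_proximity()`) assigns a putative
mechanism to a query compound (typically a non-oncology compound with
unknown pharmacology) only when, **in every run**, among its `k = 10`
nearest embedded neighbours the fraction belonging to one reference
mechanism reaches `min_frac` and is the unique plurality. Neighbours are
taken over *all* embedded compounds, not just the references: unlabeled
neighbours dilute every mechanism's fraction, so a query must sit inside a
mechanism's cluster, not merely closer to it than to the other clusters.
This distinction matters — if neighbours were restricted to references,
every embedded compound would always have `k` reference neighbours and
whichever cluster is marginally closest would dominate them, assigning
mechanisms to essentially everything.

A limitation worth stating plainly: with a 28-line panel, roughly 2–5% of
pure-noise profiles have chance rank-correlation of ~0.5 with some
mechanism's susceptibility pattern. Such a compound is embedded inside that
cluster in every run, and no rule consuming the embedding (or the distance
matrix itself) can reject it. The all-runs rule with a strict neighbourhood
fraction (we use `min_frac = 0.9` in the validation study) removes almost
all noise adoptions but cannot remove these; a rare false assignment at
this panel size is intrinsic to profile-similarity inference.

## Differential killing activity

`two_class_compare()` tests, per compound, the in-group (e.g. one tumour
type) against the out-group with Welch's unequal-variance t-test; the
effect size is the difference of group means. The underlying portal
analysis the field uses does not document its statistic, so Welch is our
explicit, robust choice for very unequal group sizes (28 vs ~550); this is
a reproduction caveat, not a claim of exactness. Significance requires `p <
0.01` *and* a negative effect (more killing in-group); no multiplicity
correction is applied at this stage because the screen design validates
primary-screen hits by intersection with an independent secondary screen
(`intersect_screens()`). Group-level confirmations use the exact two-sided
Mann-Whitney test (`mannwhitney_compare()`), with exact enumeration for
small untied samples and the tie-corrected normal approximation otherwise.

## Transcriptomic biomarkers

Extreme responder groups are chosen by ranking lines on their mean logFC
over a compound class (`rank_lines_by_mean_response()`); ties break
lexicographically so the grouping is reproducible. Differential expression
between groups uses a moderated t-statistic: per-gene pooled variances
$s_g^2$ (residual df $d_g$) are shrunk toward an empirical-Bayes prior,

$$\tilde{s}_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
  t_g = \frac{\bar{x}_A - \bar{x}_B}{\tilde{s}_g\sqrt{1/n_A + 1/n_B}},$$

with p-values on $d_0 + d_g$ degrees of freedom and Benjamini–Hochberg
q-values (default significance `q < 0.05`, no fold-change floor — the
conventional default of moderated-t workflows, exposed as a parameter).
The prior `(d0, s0^2)` is fitted by moment-matching the log sample
variances against the scaled-F model: solve `trigamma(d0/2) = var(log s^2)
- trigamma(dg/2)`, then recover `s0^2` from the bias-corrected mean. When
the log variances show no excess spread the prior df is infinite and all
variances shrink to their common value. `d0 = 0` recovers the ordinary
pooled t-test exactly, which is how the implementation is validated.

Pathway membership of a DEG list is tested by one-sided hypergeometric
over-representation against a user-supplied gene-set collection — a
deliberate stand-in for web-portal network enrichment, which is out of
scope. Candidate single-gene biomarkers are shortlisted by Pearson
correlation with drug response (two-sided p from the t-transform on `n - 2`
df, shortlist at `p < 0.05`), and gene signatures are scored as the
per-line mean of gene-wise Z-scores — mean-of-Z rather than Z-of-mean, so
genes of very different absolute abundance contribute equally and the score
is invariant to affine rescaling of any one gene.

## Gene set enrichment

`signal_to_noise_rank()` ranks genes by `(muA - muB)/(sdA + sdB)` with each
class standard deviation floored at `max(0.2 * |mean|, 0.2)` (the reference
tool's documented metric; the floor keeps near-constant genes from
producing unbounded metrics). `enrichment_score()` walks the ranked list:
set genes increment the running sum by `|metric|^p` (normalized over hits,
`p = 1` by default), others decrement by `1/(N - N_hits)`; the enrichment
score is the signed maximum deviation. On exact ties of the maximum
deviation — which arise only through floating-point dust — the earliest
position wins, a documented deterministic tie-break.

`permutation_significance()` builds the null either by phenotype
permutation (reshuffling class labels and re-ranking; preserves gene-gene
correlation) or by gene-set permutation (random same-size sets on the
observed ranking). The mode defaults to phenotype when both classes have at
least 7 samples, the reference tool's small-sample guidance, and is
exposed as a parameter since typical extreme-group designs (4v4, 6v6) sit
at that boundary. NES divides each ES by the mean magnitude of same-sign
permuted scores for that set; the nominal p is the same-sign permutation
tail fraction; the FDR q is the GSEA-standard ratio of normalized tail
fractions, clipped to `[0, 1]`. Sets are filtered to sizes 15–500 by
default. Cross-dataset agreement of enriched sets uses
`compare_enriched_sets()` at the conventional `FDR < 0.25` screen.

## What the synthetic generator emulates — and what it does not

`generate_screen()` emits `logFC(c, l) = effect_mu * latent(moa(c), l) +
Normal(0, noise_sd^2)` for active compounds and pure noise otherwise. The
latent susceptibility per mechanism and line is Bernoulli(0.6) times
Uniform(0.5, 1), so each mechanism kills a subset of lines with variable
strength — the selective-versus-broad structure visible in real landscape
figures. Defaults (500 compounds, 28 lines, 20% active, mean shift -2.5,
noise sd 0.4) mirror the screen scale the pipeline targets; category labels
follow the real screen's rough 21/2/77 composition of targeted, chemo-
and non-oncology compounds. The noise model is an assumption: logFC
residuals are taken Gaussian because the screen literature characterizes no
distribution; nothing downstream depends on tails beyond the threshold
rule. Not emulated: pooled-barcode deconvolution, paracrine confounding
between co-cultured lines, and dose–response structure (the primary screen
is single-dose). Passing recovery tests on this generator therefore
validates the statistical machinery, not those assay-level artefacts.

`generate_expression()` plants three kinds of signal on a log2(TPM+1)
baseline (Uniform(2, 8) plus Gaussian noise): differential genes shifted by
±delta in one group, genes linear in a per-line response vector, and gene
sets with a coordinated shift. Values are clipped at zero to stay on the
non-negative scale; with the default baselines clipping is effectively
never triggered.

## Validation study sizes and numerical choices

The packaged validation studies (the test suite and `scripts/acceptance.R`)
use these problem sizes, chosen as the smallest at which the planted
effects are comfortably identifiable rather than borderline:

* calibration: 200 random oracle instances; 20 seeds of the 10v40 Gaussian
  construction;
* activity: 20 seeds of the default 500x28 screen;
* differential killing: 2,000 null compounds and 25 planted selective
  compounds among 500, in-group 28 vs out-group 100;
* moderated t: 5,000 model-simulated variances for prior recovery
  (`d0 = 4`, `s0^2 = 1`); planted DEGs at 2,000 genes, 5% differential,
  shift 2, noise 1, in a 10v10 design — at the paper-style 6v6 extreme
  groups the same effect size yields only ~64% power, so the recovery
  claim is stated at 10v10 and the pipeline keeps 6v6 for its own
  extreme-group contrast;
* GSEA: 500 random running-sum oracle lists; a planted 20-gene set among
  400 genes at 8v8 with 1,000 phenotype permutations; 20-seed null
  calibration at 200 permutations;
* embedding: 20 seeds of a 200-compound screen with four 20-compound
  mechanism blocks, a diffuse background of idiosyncratic actives, 15
  pure-noise queries, 10 t-SNE runs at perplexity 30, `k = 10`,
  `min_frac = 0.9`.

Other numerical choices: missing logFC values are preserved and excluded
pairwise (rank correlations are pairwise-complete; pairs sharing fewer than
3 observations get a missing distance); compounds with fewer than two
non-missing values in either group are skipped, not failed, in the
two-class comparison; zero-variance genes are excluded from correlation
shortlists and signatures with a warning; and every stochastic stage takes
an explicit integer seed, with repeated-embedding seeds defaulting to
`1..n_runs` so the all-runs criterion is reproducible.

## Known limitations

Counts from the original screen releases (total compounds, per-category
actives, portal differential hits) depend on the pinned downloads and on
the portal's undocumented test statistic; `run_pipeline(mode =
"reproduce")` executes the full recipe when those files are supplied
locally but the package makes no claim of bit-exact portal agreement. The
permutation GSEA matches the reference tool's definitions, not its RNG
stream, so NES/p values on real data are comparable in distribution rather
than identical. And, as discussed above, rare chance-correlated noise
profiles at small panel sizes are indistinguishable from genuine mechanism
sharing in any profile-similarity analysis.
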