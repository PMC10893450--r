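---
title: "Inferring and dating whole-genome duplications with wgdinfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and dating whole-genome duplications with wgdinfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdinfer)
```

## The problem

A whole-genome duplication (WGD) doubles every gene of a genome at one
instant. Most duplicates are subsequently lost, but the survivors form a
cohort of paralog pairs that are all the same age. Two independent kinds of
evidence reveal such an event long after the fact:

* the *Ks age distribution* of within-species paralog pairs shows a
  Gaussian-like peak superimposed on the exponential-like background of
  continuous small-scale duplication (Ks, synonymous substitutions per
  synonymous site, acts as an approximately neutral molecular clock);
* mapping rooted gene trees onto the species tree concentrates duplication
  nodes on one species-tree branch, and — diagnostically for WGD — both
  duplicate copies tend to be retained in *both* descendant lineages of
  that branch (the "(AB)(AB)" pattern).

`wgdinfer` implements both routes, the conversion of Ks peaks to absolute
ages, a correction for lineages with heterogeneous synonymous rates, and
the downstream gene-set statistics (positive selection, functional
enrichment, gene fractions). Because real transcriptome collections are
large and uncontrolled, the package also ships a forward simulator that
plants WGD episodes with known parameters; every claim the pipeline makes
is validated against that ground truth in the test suite.

## The substitution model and the simulator

`simulate_codon_pair()` and `simulate_wgd_dataset()` evolve codon
sequences under a deliberately minimal process:

* point mutations hit each nucleotide position uniformly, with equal
  exchange rates among the three alternative bases (Jukes–Cantor-like);
* a mutation creating a stop codon is rejected and redrawn, so sequences
  stay translatable end to end;
* synonymous changes are always accepted; nonsynonymous changes are
  accepted with probability `omega` (the target Ka/Ks, default 0.2 —
  ordinary purifying selection). Values of `omega` above 1 cannot be
  produced by thinning and are capped with a warning;
* a branch of length `t` (one-path Ks units) receives
  `Poisson(3 L t)` mutation attempts for `L` codons, which yields `t`
  accepted synonymous substitutions per synonymous site in expectation.

This process has no indels, no codon-usage bias, no among-site rate
variation, no hybridization or subgenome exchange. That is intentional:
with equal exchange rates, the Nei–Gojobori counting estimator paired with
the Jukes–Cantor correction is approximately unbiased, so simulator truth
and estimator output are directly comparable, and any disagreement in the
tests indicates a real defect rather than model mismatch. The flip side is
documented honestly: passing tests show the pipeline recovers what this
generator plants; they do not show robustness to alignment error, GC bias
or rate variation in real data.

A dataset is generated per gene family: one ancestral gene enters the root
and descends the species tree. At a planted `wgd_episode()` every extant
copy duplicates and each new duplicate survives with the episode's
`retention_prob`; small-scale duplications and losses arrive as Poisson
processes (`ssd_rate`, `loss_rate` per branch-Ks unit, defaults 0.05 and
0.02 — low retained-SSD rates typical of curated family sets); sequence
lengths are Poisson around `mean_length_codons` (default 200, a typical
conserved-CDS length). Families that go fully extinct are regenerated (and
counted).

Two unit conventions matter:

* **Species-tree branch lengths** are one-path Ks at a reference rate —
  standard tree units.
* **Episode ages (`age_ks`)** are the *pairwise* Ks at which the episode's
  duplicate pairs will appear on a Ks plot; internally the one-path depth
  is `age_ks / 2`. This keeps the planted value directly comparable to the
  fitted peak position and to the dating formula below.

Lineage rate heterogeneity is modelled by per-tip multipliers; an internal
branch is scaled by the mean multiplier of its descendant tips. The mean
is exactly the averaging assumption the rate-correction algebra makes (see
below), so the simulator provides a fair test of that algebra rather than
an unfalsifiable mirror of it.

The truth table labels *every* within-family gene pair with the node where
it diverged — an episode id, `ssd`, or `speciation` — and its true
pairwise Ks (sum of scaled branch lengths along both paths).

## Ka/Ks estimation

Protein translations of a pair are aligned globally (BLOSUM62, gap open
10, extension 0.5 — Biostrings' conventions, deterministic tie-breaking)
and the alignment is back-translated onto codons. NG86 counting then runs
per ungapped codon column:

* *sites*: at each codon position, the three single-base alternatives are
  classified synonymous / nonsynonymous; alternatives creating stops are
  removed and the fractions renormalised over the remainder; synonymous
  sites `S` are averaged over the two sequences;
* *differences*: codons differing at 2–3 positions are averaged over all
  substitution orders, discarding orders that pass through a stop codon
  (all orders are kept in the rare case every one does);
* `ps = Sd / S`, `pn = Nd / N`, and `Ks`, `Ka` follow by the Jukes–Cantor
  correction `-(3/4) log(1 - (4/3) p)`. Saturated (`p >= 3/4`) or
  degenerate (`S = 0`) cases are returned as `NA` with a reason, never
  silently dropped; `Ka/Ks > 1` flags candidate positive selection.

All 61×61 codon-pair difference counts and the per-codon site counts are
precomputed once per session, so the estimator is lookup-table fast. The
test suite checks it against an independently written enumeration oracle,
and against simulator truth: the mean estimate over replicate pairs tracks
the planted Ks within ±10% for Ks up to about 1.5. Above that the usual
saturation bias of counting estimators sets in — visible in our own
simulations as a few-percent underestimate by Ks ≈ 2 — which is why
analyses here keep the quantitative claims to peaks below ~1.5 and treat
older peaks as qualitative.

## Ks distributions and redundancy weights

A family of m co-orthologous genes contains m(m−1)/2 pairs but only m−1
duplication events; feeding all pairs into a distribution would overweight
large families. `add_node_weights()` single-linkage-clusters each family's
within-species genes on their pairwise Ks; every internal node of the
dendrogram distributes total weight 1 equally among the gene pairs it
joins. Each duplication event therefore contributes unit weight, and a
family's total weight is m − 1. Ortholog pairs (for divergence peaks) are
chosen by reciprocal best hit, scored internally by shared protein 5-mers
(a user-supplied score table, e.g. from BLASTP, takes precedence).

Distributions are filtered to the closed interval `[0.1, 5]` — dropping
very recent duplicates (allelic variants, assembly redundancy) and
saturated values — with per-reason drop counts retained. Boundary values
are kept; the interval bounds are configurable.

## Mixture modelling and peak calling

`fit_gmm()` fits Gaussian mixtures with k = 1..k_max components by EM on
the raw Ks values. Weighted observations enter the responsibilities and
the effective sample size `n_eff = sum(w)`; BIC is
`-2 logL + (3k - 1) log(n_eff)` and is minimised by `select_model()`, ties
going to fewer components. Fitting on raw (not log) Ks matches how such
distributions are usually modelled and plotted; a `log_transform` switch
is provided. Numerical choices: k-means++ seeding on a caller-supplied
seed (fits are exactly reproducible), best of `n_restarts` runs by
log-likelihood, variance floor 1e-4 (so an all-equal input yields a
floored component rather than a singularity), convergence at log-likelihood
increments below `tol` with non-convergence flagged rather than fatal.
Components with mixing weight ≥ `min_weight` (default 0.1) are reported
as peaks.

`place_peak()` compares a WGD peak to the dominant component of an
interspecific (ortholog) distribution: a WGD peak at higher Ks than the
divergence peak predates the speciation (`before_divergence`), lower means
it followed (`after_divergence`), and within a tolerance (default 0.1 Ks,
since "coincident" is inherently qualitative) the two are tied.

## Tree-based detection

For each family, `build_nj_gene_tree()` computes a neighbor-joining tree
on protein p-distances (global alignment first when lengths differ), and
`root_gene_tree()` roots it on the branch minimising implied duplications,
breaking ties by implied losses and then lexicographically — fully
deterministic. `reconcile()` performs standard LCA mapping: an internal
node is a duplication iff it maps to the same species-tree node as one of
its children. Note a consequence exercised in the tests: a duplication
retained in only one species maps to that species' *tip*, not to an
ancestral branch. Duplications with node support below `support_threshold`
(default 50, the usual bootstrap convention) are discarded; unannotated
nodes pass.

A duplication at internal node v (child lineages A, B) is typed `AB_AB`
when each of the two gene-tree child subtrees contains at least one
species from A and one from B — both copies retained in both lineages.
Tip-mapped duplications are typed `other`.

`summarize_gd()` tallies per-node event counts, families hit, the GD
ratio (events / total families) and the (AB)(AB) percentage;
`call_wgd()` flags a node when, with strict inequalities, either
GD > 450 ∧ ratio > 4.5% ∧ (AB)(AB) > 50%, or GD > 1000 ∧ ratio > 5% ∧
(AB)(AB) > 20%. The absolute count thresholds presume transcriptome-scale
family numbers (~10⁴); `criteria = "scaled"` multiplies them by
`n_families / 10000` for desk-scale datasets while leaving the scale-free
ratio and percentage thresholds untouched. Duplications at the species
tree root are tallied but never auto-flagged — with a single outgroup a
root signal cannot be distinguished from sampling artefacts — and a
warning is raised if the root would otherwise qualify.

`extract_wgd_duplicates()` returns, per flagged node, the within-species
cross-subtree gene pairs of each event — the inputs for the selection
screen and enrichment tests.

## Dating and cross-lineage rate correction

Assuming approximately linear synonymous accumulation, a pair at
divergence Ks split `Ks / (2 r)` years ago; with the default
r = 11.04e-9 synonymous substitutions per site per year (an absolute
estimate for a homosporous fern reference lineage) the package reports
ages in Mya and classifies them against closed time windows (larger Mya =
earlier; default boundary tolerance 0).

When a target lineage's synonymous rate differs from the reference's, its
Ks values live on a different scale. If both the reference and a *bridge*
lineage show the same ancient WGD, the ratio of their peak positions
`C_bridge = Ks_ref / Ks_bridge` measures the rate difference directly. The
reference's own coefficient is fixed at 1 — it defines the scale, and no
other value keeps the algebra self-consistent. Coefficients of
interspecific distributions are arithmetic means of the two lineage
coefficients, `C_b(x,y) = (C_x + C_y)/2`; aligning the corrected
bridge–target ortholog peak to the corrected bridge–reference one (the two
mark the same divergence when reference and target are sister lineages
relative to the bridge) gives

```
C_target = 2 * C_b(bridge, target) - C_bridge,   Ks' = C_target * Ks.
```

The arithmetic-mean step is an approximation (exact only for equal rates);
on simulated three-lineage datasets with rate multipliers 1 / 0.7 / 0.5
the corrected target peak lands within a few percent of the
reference-scale planted age, inside the ±10% the tests assert. Peak
inputs come from BIC-selected dominant components; printed values can be
supplied manually. The chain refuses geometries implying a non-positive
target coefficient.

## Gene-set statistics

* `screen_positive_selection()`: strict Ka/Ks > 1; undefined ratios are
  excluded from the denominator and reported separately.
* `hypergeometric_enrichment()`: upper-tail `P(X >= k)` per term against a
  configurable universe (default: all annotated genes — ordinary
  over-representation practice), Benjamini–Hochberg q-values, terms with
  fewer than `min_term_size = 3` universe genes skipped. Annotation maps
  are taken as given; no ontology-hierarchy propagation is performed.
* `gene_fraction_test()`: per-species target-gene fractions, genus means,
  and an independent two-sample t-test between two genera — Welch's by
  default (the safer choice under unequal variances; Student's pooled
  test is an option), with the conventional significance stars. Zero
  within-genus variance on both sides is handled explicitly (p = 1 for
  equal means; an exact difference is reported with a warning otherwise).

## Problem sizes and reproducibility

The validation suite uses datasets of 150–500 families on 3–4-species
trees with 200–300-codon genes — sizes at which every stage's statistical
behaviour (binomial retention counts, mixture recovery, reconciliation
precision) is already well separated from noise while the whole suite runs
in minutes. The end-to-end recovery property (a planted episode at pair-Ks
1.1, retention 0.8, 500 families) asserts that across 20 independent
seeds, at least 90% of runs both fit a mixture component with mean in
[1.0, 1.2] and flag exactly the planted species-tree node under scaled
thresholds. All stochastic code takes explicit seeds and restores the
caller's RNG state; identical seeds give byte-identical datasets and fits.

## Known limitations

* NG86 with Jukes–Cantor correction saturates above Ks ≈ 1.5–2; old peaks
  are qualitative.
* The simulator omits indels, codon-usage bias, site-rate variation and
  allopolyploid subgenome exchange; conclusions about such data require
  external validation.
* NJ gene trees carry no support values, so the support filter is inert in
  simulated pipelines (it matters for user-supplied bootstrapped trees).
* The rate-correction chain inherits the arithmetic-mean approximation of
  its coefficients and assumes the bridge diverged before the
  reference/target split.
* Enrichment treats annotation terms independently; GO DAG semantics are
  out of scope.
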