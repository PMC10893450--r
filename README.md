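# wgdinfer

Detect, type, and date whole-genome duplication (WGD) events from
coding-sequence collections.

Polyploidization duplicates every gene at once, so it leaves two
complementary fingerprints in a set of transcriptomes or genomes:

1. **A burst of equally aged paralog pairs.** The age of a duplicate pair is
   measured by Ks, the number of synonymous substitutions per synonymous
   site, which accumulates approximately neutrally. Small-scale duplications
   produce an exponential-like background of mostly young pairs; a WGD adds
   a Gaussian-like peak at its age.
2. **Duplications that map to the same species-tree branch in many gene
   families**, with both duplicate copies retained in both descendant
   lineages of that branch — the "(AB)(AB)" retention pattern.

`wgdinfer` implements both routes and the downstream arithmetic, for people
studying paleopolyploidy in plant (or other eukaryote) lineages:

- **NG86 Ka/Ks** — codon alignments are built by globally aligning the
  protein translations (BLOSUM62, affine gaps) and back-translating; sites
  and pathway-averaged differences are counted by the Nei–Gojobori method
  with Jukes–Cantor correction `d = -(3/4) log(1 - (4/3) p)`. Stop-codon
  paths are excluded and site fractions renormalised.
- **Ks age distributions** — all within-family, within-species paralog
  pairs, node-weighted by single-linkage clustering so each duplication
  event contributes total weight 1; ortholog pairs by reciprocal best hit;
  closed retention filter `Ks in [0.1, 5]`.
- **Mixture peaks** — weighted EM Gaussian mixtures fitted to the raw Ks
  values for k = 1..k_max, component count chosen by minimum
  `BIC = -2 logL + (3k - 1) log(n_eff)`; peaks placed relative to
  ortholog-divergence peaks.
- **Tree reconciliation** — neighbor-joining gene trees (protein
  p-distance), minimal-duplication rooting, LCA mapping onto a species
  tree, (AB)(AB) typing, and dual-criterion WGD calling
  (GD > 450, ratio > 4.5%, (AB)(AB) > 50% — or GD > 1000, ratio > 5%,
  (AB)(AB) > 20%; strict inequalities, rescalable to small datasets).
- **Dating and rate correction** — `date = Ks / (2 r)` in Mya (default
  r = 11.04e-9 synonymous substitutions/site/year), window comparisons,
  and the bridge-species correction chain
  `C_bridge = Ks_ref / Ks_bridge`, `C_b(x,y) = (C_x + C_y)/2`,
  `C_target = 2 C_b(bridge,target) - C_bridge`, `Ks' = C_target Ks` that
  rescales a rate-heterogeneous lineage onto a reference Ks scale.
- **Selection and gene sets** — strict Ka/Ks > 1 positive-selection screen,
  upper-tail hypergeometric enrichment with Benjamini–Hochberg correction,
  and between-genus gene-fraction t-tests.
- **A forward simulator** (`simulate_wgd_dataset`) that evolves codon
  sequences down a species tree with planted WGD episodes, small-scale
  duplications, losses and lineage-specific rate multipliers, emitting
  FASTA/TSV/newick plus a full ground-truth table — so the entire pipeline
  is testable without any external data.

## Worked example

Plant a WGD at pair-Ks 1.1 (80% retention) on the stem of clade (A,B) of a
four-species tree, then recover it by both routes:

```r
library(wgdinfer)

spec <- species_tree_spec("(((A:0.4,B:0.4)AB:0.35,C:0.75)ABC:0.25,O:1.0)root;")
ep   <- wgd_episode("AB", age_ks = 1.1, retention_prob = 0.8)
ds   <- simulate_wgd_dataset(spec, list(ep), n_families = 500, seed = 42)
res  <- wgd_pipeline(ds, focal_species = "A", seed = 1)

res$model
#> mixture_model: k = 2, logL = 32.764, BIC = -35.256
#>   weight  mean     sd
#> 1 0.7706 1.073 0.1530
#> 2 0.2294 1.106 0.4268

res$summary[, c("node", "gd_count", "gd_ratio", "abab_percent", "wgd_flag")]
#>   node gd_count gd_ratio abab_percent wgd_flag
#> 1    A       17    0.034      0.00000    FALSE
#> 2    B       16    0.032      0.00000    FALSE
#> 3    C       23    0.046      0.00000    FALSE
#> 4    O        3    0.006      0.00000    FALSE
#> 5 root       19    0.038      0.00000    FALSE
#> 6  ABC       17    0.034      0.00000    FALSE
#> 7   AB      412    0.824     91.50485     TRUE
```

The dominant mixture component sits at Ks 1.07 — the planted age within
estimation error — and the tree route flags exactly the planted node `AB`
(412 of 500 families duplicated there, 91.5% of them (AB)(AB)-type).
Converting the peak to time:

```r
date_from_ks(res$peaks$mean_ks[1])
#> Ks = 1.07256 at r = 1.104e-08 /site/year -> 48.58 Mya
```

Cross-lineage rate correction, using the printed shared-peak values of a
reference (3.0713) and a slower bridge lineage (2.0878):

```r
correction_coefficient(3.0713, 2.0878)
#> [1] 1.47107
```

A thin CLI wrapping these functions is installed at
`system.file("exec/wgdinfer", package = "wgdinfer")` with subcommands
`simulate`, `ks`, `fitpeaks`, `reconcile`, `date`, `correct`, `select`
and `enrich`.

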