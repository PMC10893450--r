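# Forward simulator: codon pairs, planted-WGD datasets, round trips.

test_that("zero-divergence and omega = 0 edge cases behave", {
  p0 <- simulate_codon_pair(100, 0.0, 1.0, 7)
  expect_identical(p0$cds_a, p0$cds_b)
  expect_equal(p0$true_ks, 0)

  p <- simulate_codon_pair(100, 0.5, 0.0, 3)
  expect_equal(p$true_ka, 0)
  # identical proteins even though synonymous changes accumulated
  aa_a <- as.character(Biostrings::translate(Biostrings::DNAString(p$cds_a)))
  aa_b <- as.character(Biostrings::translate(Biostrings::DNAString(p$cds_b)))
  expect_identical(aa_a, aa_b)
  expect_gt(p$true_ks, 0)

  expect_error(simulate_codon_pair(5, 1, 0.2, 1), "length_codons")
  expect_error(simulate_codon_pair(100, -1, 0.2, 1), "target_ks")
  expect_error(simulate_codon_pair(100, 1, -0.2, 1), "omega")
})

test_that("realized Ks converges to the target and NG86 recovers it", {
  n_rep <- 60
  true_ks <- ng_ks <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    p <- simulate_codon_pair(300, 1.2, 0.2, 1000 + i)
    true_ks[i] <- p$true_ks
    est <- ng86(align_codon_pair(p$cds_a, p$cds_b))
    ng_ks[i] <- est$Ks
  }
  se <- sd(true_ks) / sqrt(n_rep)
  expect_lt(abs(mean(true_ks) - 1.2), 3 * se)
  expect_lt(abs(mean(ng_ks) - 1.2), 0.15)
  # estimator tracks the realized divergence within 10% at Ks <= 1.5
  expect_lt(abs(mean(ng_ks) / mean(true_ks) - 1), 0.1)
})

test_that("no-episode, no-SSD datasets are single copy and congruent", {
  ds <- simulate_wgd_dataset(toy_spec(), list(), n_families = 20,
                             ssd_rate = 0, loss_rate = 0, seed = 5)
  counts <- table(ds$families$family, ds$families$species)
  expect_true(all(counts == 1))
  expect_true(all(ds$truth$origin == "speciation"))
  st <- toy_st()
  for (fam in names(ds$gene_trees)) {
    gt <- ape::read.tree(text = ds$gene_trees[[fam]])
    events <- reconcile(root_gene_tree(gt, st), st, family = fam)
    expect_length(events, 0)
  }
})

test_that("full retention doubles copy number below the episode", {
  ep <- wgd_episode("AB", age_ks = 1.1, retention_prob = 1)
  ds <- simulate_wgd_dataset(toy_spec(), list(ep), n_families = 15,
                             ssd_rate = 0, loss_rate = 0, seed = 9)
  counts <- table(ds$families$family, ds$families$species)
  expect_true(all(counts[, c("A", "B")] == 2))
  expect_true(all(counts[, c("C", "O")] == 1))
  # every within-species duplicate pair is labelled with the episode
  wi <- ds$truth[sub("\\|.*$", "", ds$truth$gene_a) ==
                   sub("\\|.*$", "", ds$truth$gene_b), ]
  expect_true(all(wi$origin == "wgd1"))
  expect_true(all(abs(wi$true_ks - 1.1) < 1e-9))
})

test_that("retention probability is respected across families", {
  ep <- wgd_episode("AB", age_ks = 1.1, retention_prob = 0.6)
  ds <- simulate_wgd_dataset(toy_spec(), list(ep), n_families = 400,
                             ssd_rate = 0, loss_rate = 0, seed = 11)
  counts <- table(ds$families$family, ds$families$species)
  frac_dup <- mean(counts[, "A"] == 2)
  se <- sqrt(0.6 * 0.4 / 400)
  expect_lt(abs(frac_dup - 0.6), 4 * se)
})

test_that("truth labels partition within-species paralog pairs", {
  ep <- wgd_episode("AB", age_ks = 1.1, retention_prob = 0.8)
  ds <- simulate_wgd_dataset(toy_spec(), list(ep), n_families = 40, seed = 3)
  pairs <- paralog_pairs(ds$families$gene, ds$families)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  truth_keys <- key(ds$truth$gene_a, ds$truth$gene_b)
  pair_keys <- key(pairs$gene_a, pairs$gene_b)
  expect_true(all(pair_keys %in% truth_keys))
  expect_false(any(duplicated(truth_keys)))
})

test_that("rate multipliers scale true Ks along both paths", {
  mult <- c(A = 1, B = 1, C = 0.5, O = 1)
  ds <- simulate_wgd_dataset(toy_spec(mult), list(), n_families = 5,
                             ssd_rate = 0, loss_rate = 0, seed = 21)
  # A-C ortholog pairs: A path 0.4 + 0.35 = 0.75 at rate 1; C path 0.75
  # at rate 0.5; expected pair Ks = 0.75 + 0.375
  ac <- ds$truth[sub("\\|.*$", "", ds$truth$gene_a) == "A" &
                   sub("\\|.*$", "", ds$truth$gene_b) == "C", ]
  expect_true(all(abs(ac$true_ks - (0.75 + 0.375)) < 1e-9))
})

test_that("same seed gives identical datasets", {
  ep <- wgd_episode("AB", age_ks = 1.1, retention_prob = 0.8)
  d1 <- simulate_wgd_dataset(toy_spec(), list(ep), n_families = 10, seed = 33)
  d2 <- simulate_wgd_dataset(toy_spec(), list(ep), n_families = 10, seed = 33)
  expect_identical(d1$collections, d2$collections)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$gene_trees, d2$gene_trees)
})

test_that("episode placement outside the stem branch errors", {
  expect_error(
    simulate_wgd_dataset(toy_spec(), list(wgd_episode("AB", 2.0, 0.5)),
                         n_families = 2, seed = 1),
    "valid depth interval")
})

test_that("datasets round-trip through disk", {
  ep <- wgd_episode("AB", age_ks = 1.1, retention_prob = 0.8)
  ds <- simulate_wgd_dataset(toy_spec(), list(ep), n_families = 6, seed = 8)
  dir <- withr::local_tempdir()
  manifest <- write_dataset(ds, dir)
  expect_setequal(manifest$file,
                  c(paste0(names(ds$collections), ".fasta"),
                    "families.tsv", "truth.tsv", "trees/"))
  expect_equal(manifest$records[manifest$file == "families.tsv"],
               nrow(ds$families))
  back <- read_dataset(dir)
  for (sp in names(ds$collections))
    expect_identical(back$collections[[sp]][names(ds$collections[[sp]])],
                     ds$collections[[sp]])
  expect_equal(sort(back$families$gene), sort(ds$families$gene))
  for (fam in names(ds$gene_trees)) {
    t1 <- ape::read.tree(text = ds$gene_trees[[fam]])
    t2 <- ape::read.tree(text = back$gene_trees[[fam]])
    expect_true(ape::all.equal.phylo(t1, t2, use.edge.length = FALSE))
  }
  expect_error(write_dataset(ds, dir), "exist")
  expect_silent(write_dataset(ds, dir, overwrite = TRUE))
})
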