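# LCA reconciliation, rooting, (AB)(AB) typing and WGD calling.

test_that("single-copy congruent families yield no duplication events", {
  st <- toy_st()
  gt <- ape::read.tree(text = "(((A|f|1,B|f|1),C|f|1),O|f|1);")
  expect_length(reconcile(gt, st), 0)
})

test_that("the textbook (AB)(AB) and (AA)B cases reconcile correctly", {
  st <- toy_st()
  g1 <- ape::read.tree(text = "(((A|f|1,B|f|1),(A|f|2,B|f|2)),O|f|1);")
  ev1 <- reconcile(g1, st, family = "f")
  expect_length(ev1, 1)
  expect_equal(ev1[[1]]$node, "AB")
  expect_equal(ev1[[1]]$type, "AB_AB")

  # a duplication retained only in A maps to the tip A under LCA mapping
  # and can never be (AB)(AB)-typed
  g2 <- ape::read.tree(text = "((A|f|1,A|f|2),B|f|1);")
  ev2 <- reconcile(g2, st)
  expect_length(ev2, 1)
  expect_equal(ev2[[1]]$node, "A")
  expect_equal(ev2[[1]]$type, "other")
})

test_that("species missing from the species tree are reported by name", {
  st <- toy_st()
  gt <- ape::read.tree(text = "((A|f|1,Z|f|1),O|f|1);")
  expect_error(reconcile(gt, st), "Z")
})

test_that("reconciliation matches the brute-force oracle on random trees", {
  st <- toy_st()
  stree <- st$tree
  set.seed(20)
  for (rep in 1:80) {
    n <- sample(3:8, 1)
    gt <- random_gene_tree(n, c("A", "B", "C", "O"))
    ours <- reconcile(gt, st, support_threshold = 0)
    orc <- oracle_reconcile(gt, stree)
    expect_equal(length(ours), length(orc), info = ape::write.tree(gt))
    if (length(ours)) {
      expect_setequal(
        paste(vapply(ours, `[[`, "", "node"), vapply(ours, `[[`, "", "type")),
        paste(vapply(orc, `[[`, "", "node"), vapply(orc, `[[`, "", "type")))
    }
  }
})

test_that("low-support duplications are discarded", {
  st <- toy_st()
  gt <- ape::read.tree(text = "(((A|f|1,B|f|1)90,(A|f|2,B|f|2)95)30,O|f|1)0;")
  expect_length(reconcile(gt, st, support_threshold = 50), 0)
  expect_length(reconcile(gt, st, support_threshold = 20), 1)
})

test_that("minimal-duplication rooting recovers congruent and duplicated trees", {
  st <- toy_st()
  # congruent tree arbitrarily rooted: rooting must imply 0 duplications
  gt <- ape::read.tree(text = "((C|f|1,O|f|1),(A|f|1,B|f|1));")
  rooted <- root_gene_tree(gt, st)
  expect_length(reconcile(rooted, st), 0)

  # tree with one true AB duplication, scrambled rooting
  gt2 <- ape::unroot(ape::read.tree(
    text = "(((A|f|1,B|f|1),(A|f|2,B|f|2)),O|f|1);"))
  rooted2 <- root_gene_tree(gt2, st)
  ev <- reconcile(rooted2, st)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$node, "AB")
  expect_equal(ev[[1]]$type, "AB_AB")
})

test_that("rooted NJ trees recover planted duplications on simulated families", {
  ep <- wgd_episode("AB", age_ks = 1.1, retention_prob = 1)
  ds <- simulate_wgd_dataset(toy_spec(), list(ep), n_families = 12,
                             ssd_rate = 0, loss_rate = 0, seed = 31)
  st <- toy_st()
  seqs <- unlist(unname(lapply(ds$collections, as.list)))
  seqs <- setNames(as.character(seqs), names(seqs))
  hits <- 0
  for (fam in unique(ds$families$family)) {
    g <- ds$families$gene[ds$families$family == fam]
    gt <- root_gene_tree(build_nj_gene_tree(seqs[g]), st)
    ev <- reconcile(gt, st, family = fam)
    if (length(ev) == 1 && ev[[1]]$node == "AB" && ev[[1]]$type == "AB_AB")
      hits <- hits + 1
  }
  expect_gte(hits, 10) # >= 10 of 12 families reconstructed exactly
})

test_that("per-node summaries tally counts, ratios and (AB)(AB) percent", {
  st <- toy_st()
  ev <- c(replicate(6, list(family = "fX", node = "AB", type = "AB_AB"),
                    simplify = FALSE),
          replicate(4, list(family = "fY", node = "AB", type = "other"),
                    simplify = FALSE))
  s <- summarize_gd(ev, n_families = 100, st)
  row <- s[s$node == "AB", ]
  expect_equal(row$gd_count, 10)
  expect_equal(row$family_count, 2)
  expect_equal(row$gd_ratio, 0.1)
  expect_equal(row$abab_percent, 60)
  expect_true(all(s$gd_count[s$node != "AB"] == 0))
  expect_true(is.na(s$abab_percent[s$node == "A"]))

  empty <- summarize_gd(list(), n_families = 100, st)
  expect_true(all(empty$gd_count == 0))
  expect_false(any(empty$wgd_flag))
})

test_that("WGD calling applies the dual criteria with strict inequalities", {
  st <- toy_st()
  mk <- function(gd, ratio, abab) {
    s <- summarize_gd(list(), n_families = 10000, st)
    i <- which(s$node == "AB")
    s$gd_count[i] <- gd; s$gd_ratio[i] <- ratio / 100
    s$abab_percent[i] <- abab
    s
  }
  c1 <- call_wgd(mk(500, 5.0, 60))
  expect_true(c1$wgd_flag[c1$node == "AB"])
  expect_equal(c1$criterion_hit[c1$node == "AB"], 1L)

  c2 <- call_wgd(mk(1200, 5.5, 25))
  expect_true(c2$wgd_flag[c2$node == "AB"])
  expect_equal(c2$criterion_hit[c2$node == "AB"], 2L)

  # 450 is not > 450: no flag
  c3 <- call_wgd(mk(450, 10, 90))
  expect_false(c3$wgd_flag[c3$node == "AB"])

  # scaled mode rescales the count thresholds by n_families / 10000
  s <- summarize_gd(list(), n_families = 500, st)
  i <- which(s$node == "AB")
  s$gd_count[i] <- 30; s$gd_ratio[i] <- 0.06; s$abab_percent[i] <- 80
  expect_false(call_wgd(s, criteria = "paper")$wgd_flag[i])
  expect_true(call_wgd(s, criteria = "scaled")$wgd_flag[i])
})

test_that("a qualifying root node warns instead of being flagged", {
  st <- toy_st()
  s <- summarize_gd(list(), n_families = 10000, st)
  i <- which(s$is_root)
  s$gd_count[i] <- 2000; s$gd_ratio[i] <- 0.2; s$abab_percent[i] <- 90
  expect_warning(out <- call_wgd(s), "root")
  expect_false(out$wgd_flag[i])
})

test_that("duplicate pairs are extracted per species from event subtrees", {
  st <- toy_st()
  gt <- ape::read.tree(text = "(((A|f|1,B|f|1),(A|f|2,B|f|2)),O|f|1);")
  ev <- reconcile(gt, st, family = "f")
  dup <- extract_wgd_duplicates(ev, "AB")
  expect_equal(nrow(dup), 2)
  expect_setequal(paste(dup$gene_a, dup$gene_b),
                  c("A|f|1 A|f|2", "B|f|1 B|f|2"))
  expect_warning(none <- extract_wgd_duplicates(ev, "ABC"), "no gene-duplication")
  expect_equal(nrow(none), 0)
})

test_that("NJ recovers additive four-taxon topologies", {
  # distances from a known additive tree ((a,b),(c,d)) with internal branch
  ds <- simulate_wgd_dataset(toy_spec(), list(), n_families = 8,
                             ssd_rate = 0, loss_rate = 0, seed = 77)
  seqs <- unlist(unname(lapply(ds$collections, as.list)))
  seqs <- setNames(as.character(seqs), names(seqs))
  good <- 0
  for (fam in unique(ds$families$family)) {
    g <- ds$families$gene[ds$families$family == fam]
    nj <- build_nj_gene_tree(seqs[g])
    true_t <- ape::unroot(ape::read.tree(text = ds$gene_trees[[fam]]))
    if (ape::dist.topo(ape::unroot(nj), true_t) == 0) good <- good + 1
  }
  expect_gte(good, 7)
  expect_error(build_nj_gene_tree(seqs[1:2]), ">= 3")
})
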