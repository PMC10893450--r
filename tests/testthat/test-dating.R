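# Ks dating and cross-lineage synonymous-rate correction.

test_that("Ks converts to Mya by date = Ks / (2 r)", {
  expect_equal(date_from_ks(0)$date_mya, 0)
  d12 <- date_from_ks(1.2, 11.04e-9)
  expect_equal(d12$date_mya, 1.2 / (2 * 11.04e-9) / 1e6)
  expect_equal(round(d12$date_mya, 2), 54.35)
  expect_equal(round(date_from_ks(1.3, 11.04e-9)$date_mya, 2), 58.88)
  expect_error(date_from_ks(-1), "non-negative")
  expect_error(date_from_ks(1, 0), "> 0")
})

test_that("dating is linear in Ks and inverse-linear in r", {
  set.seed(1)
  for (i in 1:20) {
    ks <- runif(1, 0.1, 5); r <- runif(1, 1e-9, 2e-8); a <- runif(1, 0.5, 3)
    expect_equal(date_from_ks(a * ks, r)$date_mya,
                 a * date_from_ks(ks, r)$date_mya, tolerance = 1e-12)
    expect_equal(date_from_ks(ks, a * r)$date_mya,
                 date_from_ks(ks, r)$date_mya / a, tolerance = 1e-12)
  }
})

test_that("window comparison uses closed intervals, larger Mya = earlier", {
  expect_equal(compare_to_window(46.2, 3.87, 29.69), "earlier_than")
  expect_equal(compare_to_window(64.8, 57.34, 106.48), "within")
  expect_equal(compare_to_window(50.7, 57.34, 106.48), "later_than")
  expect_equal(compare_to_window(29.69, 3.87, 29.69), "within")
  expect_equal(compare_to_window(3.87, 3.87, 29.69), "within")
  expect_error(compare_to_window(10, 30, 20), "out of order")
})

test_that("correction coefficients are peak ratios", {
  expect_equal(round(correction_coefficient(3.0713, 2.0878), 3), 1.471)
  expect_equal(correction_coefficient(2, 2), 1)
  expect_equal(correction_coefficient(2, 1), 2)
  expect_error(correction_coefficient(0, 1), "> 0")
  expect_error(correction_coefficient(1, -2), "> 0")
})

test_that("the anchor identity holds to machine precision", {
  ch <- correction_chain(3.0713, 2.0878, 1.9, 1.7)
  expect_equal(ch$C_bridge * 2.0878, 3.0713, tolerance = 1e-12)
})

test_that("homogeneous rates give the identity correction", {
  # equal synonymous rates make the shared-event peaks equal and the two
  # bridge ortholog peaks equal; the chain must then collapse to C = 1
  ch <- correction_chain(2.4, 2.4, 1.3, 1.3)
  expect_equal(ch$C_bridge, 1)
  expect_equal(ch$C_target, 1, tolerance = 1e-12)
  ks <- c(0.5, 1.1, 4.9)
  expect_equal(correct_target_ks(ch, ks), ks)
})

test_that("using the reference itself as target returns inputs unchanged", {
  # target = reference: the bridge-target ortholog distribution is the
  # bridge-reference one, whatever the bridge rate is
  for (cb in c(0.7, 1.0, 1.471)) {
    ref_peak <- 3.0713
    bridge_peak <- ref_peak / cb
    ortho <- 1.9
    ch <- correction_chain(ref_peak, bridge_peak, ortho, ortho)
    expect_equal(ch$C_target, 1, tolerance = 1e-12)
    expect_equal(correct_target_ks(ch, c(1, 2)), c(1, 2))
  }
})

test_that("the bridge's own corrected peak reproduces the reference anchor", {
  ch <- correction_chain(3.0713, 2.0878, 1.9, 1.7)
  expect_equal(ch$C_bridge * ch$ks_bridge_peak, ch$ks_ref_peak,
               tolerance = 1e-12)
})

test_that("inconsistent rate geometry is rejected", {
  # a tiny bridge-ref ortholog peak with a huge bridge-target one forces a
  # negative target coefficient
  expect_error(correction_chain(3, 2, 0.2, 10), "not positive")
})

test_that("a simulated slow lineage is corrected back to the reference scale", {
  # ref and target are sisters and bridge is their outgroup, so the
  # bridge-ref and bridge-target ortholog peaks mark the same divergence
  # (the geometry the chain algebra assumes); rates: ref 1, bridge 0.7,
  # target 0.5. A WGD just above the ingroup ancestor is shared by all
  # three. Internal branches are kept short so each lineage's rate is
  # nearly constant along its path, and depths are chosen to keep every
  # peak below the counting estimator's saturation range.
  spec <- species_tree_spec(
    "(((target:0.6,ref:0.6)TR:0.01,bridge:0.61)in:0.3,out:0.91)root;",
    rate_multipliers = c(target = 0.5, bridge = 0.7, ref = 1, out = 1))
  ep <- wgd_episode("in", age_ks = 1.26, retention_prob = 0.9)
  ds <- simulate_wgd_dataset(spec, list(ep), n_families = 150,
                             ssd_rate = 0, loss_rate = 0, seed = 51,
                             mean_length_codons = 300)
  seqs <- unlist(unname(lapply(ds$collections, as.list)))
  seqs <- setNames(as.character(seqs), names(seqs))
  fams <- ds$families

  peak_of <- function(tbl, label) {
    d <- build_ks_distribution(tbl, label = label)
    best <- select_model(fit_gmm(d, k_max = 2, seed = 1))
    best$components$mean[which.max(best$components$weight)]
  }
  intra_peak <- function(sp) {
    pairs <- paralog_pairs(fams$gene[fams$species == sp], fams)
    peak_of(add_node_weights(kaks_pairs(pairs, seqs)), sp)
  }
  inter_peak <- function(sp1, sp2) {
    op <- ortholog_pairs(ds$collections[[sp1]], ds$collections[[sp2]])
    peak_of(kaks_pairs(op, seqs), paste(sp1, sp2))
  }

  ks_ref <- intra_peak("ref")          # shared WGD seen at the reference rate
  ks_bridge <- intra_peak("bridge")    # same event, slower lineage
  expect_gt(ks_ref, ks_bridge)
  ch <- correction_chain(ks_ref, ks_bridge,
                         inter_peak("bridge", "ref"),
                         inter_peak("bridge", "target"))
  ks_target <- intra_peak("target")
  corrected <- correct_target_ks(ch, ks_target)
  # the planted event sits at pair-Ks 1.26 on the reference scale
  expect_lt(abs(corrected - 1.26) / 1.26, 0.1)
  expect_gt(abs(ks_target - 1.26) / 1.26, 0.2) # uncorrected is far off
})
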