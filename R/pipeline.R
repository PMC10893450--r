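# End-to-end convenience wrapper: Ks-based and tree-based WGD evidence from
# a CDS dataset (typically a simulated one with planted ground truth).

#' Run the WGD-inference pipeline on a dataset
#'
#' Ks route: within-species paralog pairs, NG86 Ks, node weighting, the
#' `[0.1, 5]` retention filter, and BIC-selected Gaussian mixture peaks for
#' the focal species. Tree route: a neighbor-joining gene tree per family
#' (protein p-distance), minimal-duplication rooting, LCA reconciliation
#' against the species tree, per-node GD tallies and WGD calling.
#'
#' @param dataset A `wgd_dataset` from [simulate_wgd_dataset()], or a list
#'   with `collections`, `families`, and a species tree reachable via
#'   `spec`.
#' @param focal_species Species whose paralog Ks distribution is modelled;
#'   defaults to the species with the most genes.
#' @param st A [species_tree()]; defaults to the dataset's own tree.
#' @param k_max,n_restarts,seed Mixture-fitting controls ([fit_gmm()]).
#' @param min_weight Component weight floor for peak calling.
#' @param support_threshold Gene-tree support cutoff for counting a
#'   duplication.
#' @param criteria WGD-calling mode, `"scaled"` (default, rescales count
#'   thresholds to the dataset's family number) or `"paper"`.
#' @return A list: `ks_table`, `distribution`, `models`, `model`, `peaks`,
#'   `events`, `summary`.
#' @export
wgd_pipeline <- function(dataset, focal_species = NULL, st = NULL,
                         k_max = 4L, n_restarts = 3L, seed = 1L,
                         min_weight = 0.1, support_threshold = 50,
                         criteria = "scaled") {
  fams <- dataset$families
  sequences <- unlist(unname(lapply(dataset$collections, as.list)))
  sequences <- stats::setNames(as.character(sequences), names(sequences))
  if (is.null(focal_species)) {
    tab <- table(fams$species)
    focal_species <- names(tab)[which.max(tab)]
  }
  if (is.null(st)) st <- species_tree(dataset$spec)

  # --- Ks route -------------------------------------------------------
  genes_focal <- fams$gene[fams$species == focal_species]
  pairs <- paralog_pairs(genes_focal, fams)
  ks_table <- if (nrow(pairs)) add_node_weights(kaks_pairs(pairs, sequences))
  else cbind(pairs, Ks = numeric(0), weight = numeric(0))
  dist <- build_ks_distribution(ks_table, label = focal_species)
  models <- NULL; model <- NULL; peaks <- NULL
  if (nrow(dist$entries) >= 10L) {
    models <- fit_gmm(dist, k_max = k_max, n_restarts = n_restarts,
                      seed = seed)
    model <- select_model(models)
    peaks <- extract_peaks(model, min_weight = min_weight,
                           source = focal_species)
  }

  # --- tree route -----------------------------------------------------
  events <- list()
  fam_ids <- unique(fams$family)
  for (fam in fam_ids) {
    g <- fams$gene[fams$family == fam]
    if (length(g) < 2L) next
    gtree <- if (length(g) == 2L) {
      ape::read.tree(text = paste0("(", g[1], ",", g[2], ");"))
    } else {
      root_gene_tree(build_nj_gene_tree(sequences[g]), st)
    }
    events <- c(events, reconcile(gtree, st,
                                  support_threshold = support_threshold,
                                  family = fam))
  }
  summary <- call_wgd(summarize_gd(events, length(fam_ids), st),
                      criteria = criteria)

  list(focal_species = focal_species, ks_table = ks_table,
       distribution = dist, models = models, model = model, peaks = peaks,
       events = events, summary = summary)
}
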