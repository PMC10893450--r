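#' @useDynLib wgdinfer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Integer amino-acid class per codon (0 = stop) for the C++ kernel.
aa_codes <- function() {
  tb <- ng86_tables()
  code <- match(tb$aa, setdiff(unique(tb$aa), "*"))
  code[tb$aa == "*"] <- 0L
  as.integer(code)
}

# Uniform random stop-free codon sequence.
random_codons <- function(length_codons) {
  tb <- ng86_tables()
  sample(setdiff(seq_len(64L), tb$stop_idx), length_codons, replace = TRUE)
}

# Evolve codon indices over an expected per-site synonymous divergence `ks`
# (one lineage's share). Returns codons plus realized substitution counts.
evolve_branch <- function(codons, ks, omega) {
  n_attempts <- stats::rpois(1L, 3 * length(codons) * ks)
  evolve_codons_cpp(codons, n_attempts, omega, aa_codes())
}

#' Simulate a diverged pair of coding sequences
#'
#' Evolves two descendants independently from a random stop-free ancestor
#' under a per-site point-substitution process: equal exchange rates among
#' the three alternative bases, substitutions creating stop codons rejected
#' and redrawn, synonymous changes always accepted and nonsynonymous changes
#' accepted with probability `omega`. Each descendant accumulates an expected
#' `target_ks / 2` synonymous substitutions per synonymous site, so the pair
#' is separated by `target_ks` in expectation.
#'
#' @param length_codons Number of codons in the ancestor (>= 10).
#' @param target_ks Expected pairwise synonymous divergence (Ks units).
#' @param omega Target Ka/Ks ratio in `[0, 1]`; values above 1 are capped
#'   (every nonsynonymous attempt accepted) with a warning.
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @return A list with `cds_a`, `cds_b` (character CDS), the realized
#'   `true_ks` and `true_ka` computed from the recorded substitution events,
#'   and the raw event counts.
#' @export
simulate_codon_pair <- function(length_codons, target_ks, omega, seed) {
  if (length_codons < 10) stop("length_codons must be >= 10")
  if (target_ks < 0) stop("target_ks must be non-negative")
  if (omega < 0) stop("omega must be non-negative")
  if (omega > 1) warning("omega > 1 is capped at 1 by the acceptance-thinning model")
  tb <- ng86_tables()
  with_seed(seed, {
    anc <- random_codons(length_codons)
    S <- sum(tb$syn_sites[anc])
    N <- sum(tb$nonsyn_sites[anc])
    a <- evolve_branch(anc, target_ks / 2, omega)
    b <- evolve_branch(anc, target_ks / 2, omega)
    list(
      cds_a = codons_to_cds(a$codons),
      cds_b = codons_to_cds(b$codons),
      true_ks = (a$n_syn + b$n_syn) / S,
      true_ka = (a$n_nonsyn + b$n_nonsyn) / N,
      n_syn_events = a$n_syn + b$n_syn,
      n_nonsyn_events = a$n_nonsyn + b$n_nonsyn
    )
  })
}

#' Specify a species tree for simulation
#'
#' @param tree A rooted binary `ape::phylo` tree, or a newick string. Branch
#'   lengths are expected synonymous substitutions per site per lineage
#'   (one-path Ks units) at the reference rate.
#' @param rate_multipliers Named positive scalars, one per tip, modelling
#'   lineage-specific synonymous-rate heterogeneity. Branches are scaled by
#'   the mean multiplier of their descendant tips. Defaults to 1 everywhere.
#' @return A `species_tree_spec` object.
#' @export
species_tree_spec <- function(tree, rate_multipliers = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object or newick string")
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  if (!ape::is.binary(tree)) stop("species tree must be binary")
  if (anyDuplicated(tree$tip.label)) stop("tip names must be unique")
  if (is.null(tree$edge.length)) stop("species tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  if (is.null(tree$node.label) || any(tree$node.label == ""))
    tree$node.label <- paste0("N", seq_len(tree$Nnode))
  if (is.null(rate_multipliers))
    rate_multipliers <- stats::setNames(rep(1, length(tree$tip.label)), tree$tip.label)
  if (!all(tree$tip.label %in% names(rate_multipliers)))
    stop("rate_multipliers must name every tip")
  if (any(rate_multipliers <= 0)) stop("rate multipliers must be > 0")
  structure(list(tree = tree,
                 rate_multipliers = rate_multipliers[tree$tip.label]),
            class = "species_tree_spec")
}

#' Specify a planted WGD episode
#'
#' @param node Species-tree node label (internal node or tip). The episode is
#'   placed on the stem branch of this node so all its descendants inherit
#'   the duplication.
#' @param age_ks Age of the episode expressed as the expected *pairwise* Ks
#'   of its duplicate pairs at the reference rate (the position the episode
#'   occupies on a Ks plot); internally the one-path depth is `age_ks / 2`.
#' @param retention_prob Probability that a duplicate copy survives to the
#'   present, in `[0, 1]`.
#' @export
wgd_episode <- function(node, age_ks, retention_prob) {
  if (age_ks < 0) stop("age_ks must be non-negative")
  if (retention_prob < 0 || retention_prob > 1)
    stop("retention_prob must be in [0, 1]")
  structure(list(node = node, age_ks = age_ks, retention_prob = retention_prob),
            class = "wgd_episode")
}

# Edge table with per-edge rate multipliers (mean of descendant-tip
# multipliers) and node heights (mean reference-Ks distance to tips).
prepare_species_tree <- function(spec) {
  tr <- spec$tree
  ntip <- length(tr$tip.label)
  labels <- c(tr$tip.label, tr$node.label)
  depth <- ape::node.depth.edgelength(tr) # from root, reference scale
  tipsets <- lapply(seq_along(labels), function(n) {
    if (n <= ntip) n else {
      unlist(ape::prop.part(tr)[n - ntip], use.names = FALSE)
    }
  })
  # prop.part lists tips per internal node in node order starting at root
  height <- vapply(seq_along(labels), function(n)
    mean(depth[tipsets[[n]]]) - depth[n], numeric(1))
  mult <- vapply(tipsets, function(tt) mean(spec$rate_multipliers[tr$tip.label[tt]]),
                 numeric(1))
  root <- ntip + 1L
  list(tree = tr, ntip = ntip, labels = labels, root = root,
       depth = depth, height = height, node_mult = mult,
       edge = tr$edge, edge_length = tr$edge.length)
}

# Resolve each episode onto (edge index or 0 for a virtual root stem,
# distance above the child node in reference one-path Ks).
place_episodes <- function(prep, episodes) {
  out <- list()
  for (i in seq_along(episodes)) {
    ep <- episodes[[i]]
    n <- match(ep$node, prep$labels)
    if (is.na(n)) stop("episode node '", ep$node, "' not in species tree")
    a <- ep$age_ks / 2 # one-path depth from tips
    h <- prep$height[n]
    if (n == prep$root) {
      if (a < h - 1e-9) stop("episode age below root height")
      out[[i]] <- list(id = paste0("wgd", i), edge = 0L, above = a - h,
                       retention = ep$retention_prob)
      next
    }
    e <- which(prep$edge[, 2] == n)
    len <- prep$edge_length[e]
    above <- a - h
    if (above < -1e-9 || above > len + 1e-9)
      stop("episode age ", ep$age_ks, " outside the valid depth interval of node '",
           ep$node, "' [", round(2 * h, 4), ", ", round(2 * (h + len), 4), "]")
    # keep the episode strictly inside the edge so the walk always crosses it
    eps_nudge <- min(1e-9, len / 2)
    out[[i]] <- list(id = paste0("wgd", i), edge = e,
                     above = min(max(above, eps_nudge), len - eps_nudge),
                     retention = ep$retention_prob)
  }
  out
}

# Simulate one gene family down the species tree. Returns a nested gene-tree
# structure (absolute realized-Ks depths at every vertex) or NULL if all
# lineages died.
sim_family_tree <- function(prep, placed, ssd_rate, loss_rate, L, omega, aa) {
  ev_rate <- ssd_rate + loss_rate
  p_loss <- if (ev_rate > 0) loss_rate / ev_rate else 0

  evolve_seg <- function(codons, dks) {
    if (dks <= 0) return(list(codons = codons, n_syn = 0L, n_nonsyn = 0L))
    evolve_codons_cpp(codons, stats::rpois(1L, 3 * L * dks), omega, aa)
  }

  # Walk one gene copy along edge e starting `pos` reference-Ks below the
  # parent node; rdepth is the copy's realized-Ks depth so far.
  walk <- function(e, pos, codons, rdepth) {
    len <- prep$edge_length[e]
    child <- prep$edge[e, 2]
    mult <- prep$node_mult[child]
    eps <- Filter(function(p) p$edge == e && p$above < len - pos + 1e-12 &&
                    (len - p$above) > pos + 1e-12, placed)
    ep_pos <- vapply(eps, function(p) len - p$above, numeric(1))
    o <- order(ep_pos)
    eps <- eps[o]; ep_pos <- ep_pos[o]
    repeat {
      t_ev <- if (ev_rate > 0) pos + stats::rexp(1L, ev_rate) else Inf
      t_ep <- if (length(ep_pos)) ep_pos[1] else Inf
      t_next <- min(t_ev, t_ep, len)
      seg <- evolve_seg(codons, (t_next - pos) * mult)
      codons <- seg$codons
      rdepth <- rdepth + (t_next - pos) * mult
      pos <- t_next
      if (pos >= len) break
      if (t_ep <= t_ev) { # WGD episode
        ep <- eps[[1]]
        eps <- eps[-1]; ep_pos <- ep_pos[-1]
        if (stats::runif(1L) < ep$retention) {
          left <- walk(e, pos, codons, rdepth)
          right <- walk(e, pos, codons, rdepth)
          return(join_node(ep$id, rdepth, left, right))
        }
        # duplicate not retained: parent continues unchanged
      } else { # small-scale duplication or loss
        if (stats::runif(1L) < p_loss) return(NULL)
        left <- walk(e, pos, codons, rdepth)
        right <- walk(e, pos, codons, rdepth)
        return(join_node("ssd", rdepth, left, right))
      }
    }
    # reached the bottom of the edge
    if (child <= prep$ntip) {
      return(list(type = "tip", species = prep$labels[child],
                  rdepth = rdepth, codons = codons))
    }
    kids <- which(prep$edge[, 1] == child)
    left <- walk(kids[1], 0, codons, rdepth)
    right <- walk(kids[2], 0, codons, rdepth)
    join_node("speciation", rdepth, left, right)
  }

  join_node <- function(label, rdepth, left, right) {
    if (is.null(left) && is.null(right)) return(NULL)
    if (is.null(left)) return(right)
    if (is.null(right)) return(left)
    list(type = "node", label = label, rdepth = rdepth,
         children = list(left, right))
  }

  root_codons <- random_codons(L)
  root_eps <- Filter(function(p) p$edge == 0L, placed)
  start <- function(codons) {
    kids <- which(prep$edge[, 1] == prep$root)
    left <- walk(kids[1], 0, codons, 0)
    right <- walk(kids[2], 0, codons, 0)
    join_node("speciation", 0, left, right)
  }
  if (length(root_eps) == 0) return(start(root_codons))
  # episodes above the root: nested duplications of the whole family
  build_root <- function(i, codons) {
    if (i > length(root_eps)) return(start(codons))
    ep <- root_eps[[i]]
    if (stats::runif(1L) < ep$retention) {
      left <- build_root(i + 1L, codons)
      right <- build_root(i + 1L, codons)
      join_node(ep$id, 0, left, right)
    } else build_root(i + 1L, codons)
  }
  o <- order(vapply(root_eps, function(p) -p$above, numeric(1)))
  root_eps <- root_eps[o]
  build_root(1L, root_codons)
}

# Depth-first gene naming and flattening of a simulated family tree.
flatten_family <- function(node, family, counter_env) {
  if (is.null(node)) return(list(genes = NULL, truth = NULL))
  if (node$type == "tip") {
    sp <- node$species
    counter_env[[sp]] <- (counter_env[[sp]] %||% 0L) + 1L
    g <- paste(sp, family, counter_env[[sp]], sep = "|")
    return(list(genes = data.frame(gene = g, species = sp, family = family,
                                   rdepth = node$rdepth,
                                   cds = codons_to_cds(node$codons),
                                   stringsAsFactors = FALSE),
                truth = NULL, newick = NULL, tips = g,
                node_ref = list(gene = g, rdepth = node$rdepth)))
  }
  left <- flatten_family(node$children[[1]], family, counter_env)
  right <- flatten_family(node$children[[2]], family, counter_env)
  genes <- rbind(left$genes, right$genes)
  lg <- left$genes; rg <- right$genes
  pairs <- expand.grid(ia = seq_len(nrow(lg)), ib = seq_len(nrow(rg)))
  truth <- data.frame(
    family = family,
    gene_a = pmin(lg$gene[pairs$ia], rg$gene[pairs$ib]),
    gene_b = pmax(lg$gene[pairs$ia], rg$gene[pairs$ib]),
    origin = node$label,
    true_ks = (lg$rdepth[pairs$ia] - node$rdepth) +
      (rg$rdepth[pairs$ib] - node$rdepth),
    stringsAsFactors = FALSE
  )
  list(genes = genes, truth = rbind(left$truth, right$truth, truth))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Newick serialisation of a simulated family tree (lengths in realized Ks).
family_newick <- function(node, parent_rdepth = 0) {
  len <- format(max(node$rdepth - parent_rdepth, 0), digits = 8)
  if (node$type == "tip") return(paste0(node$gene_name, ":", len))
  paste0("(", family_newick(node$children[[1]], node$rdepth), ",",
         family_newick(node$children[[2]], node$rdepth), ")",
         node$label, ":", len)
}

# Attach gene names to tips in the same depth-first order used by
# flatten_family, so the newick and the tables agree.
name_tips <- function(node, family, counter_env) {
  if (is.null(node)) return(NULL)
  if (node$type == "tip") {
    sp <- node$species
    counter_env[[sp]] <- (counter_env[[sp]] %||% 0L) + 1L
    node$gene_name <- paste(sp, family, counter_env[[sp]], sep = "|")
    return(node)
  }
  node$children[[1]] <- name_tips(node$children[[1]], family, counter_env)
  node$children[[2]] <- name_tips(node$children[[2]], family, counter_env)
  node
}

#' Simulate a multi-species dataset with planted WGD episodes
#'
#' Each gene family starts as a single ancestral gene at the species-tree
#' root and evolves down the tree. At a planted WGD episode every extant
#' copy duplicates and each new duplicate survives with the episode's
#' retention probability; small-scale duplications and losses occur as
#' Poisson processes per branch-Ks unit; sequences evolve by the
#' [simulate_codon_pair()] substitution process with branch rates scaled by
#' lineage rate multipliers.
#'
#' @param spec A [species_tree_spec()].
#' @param episodes List of [wgd_episode()] objects (may be empty).
#' @param n_families Number of gene families to simulate.
#' @param ssd_rate Small-scale duplication rate per branch-Ks unit.
#' @param loss_rate Gene-loss rate per branch-Ks unit.
#' @param mean_length_codons Mean CDS length in codons (Poisson around the
#'   mean, floored at 30).
#' @param omega Ka/Ks target ratio of the substitution process.
#' @param seed Integer seed.
#' @param max_retries Regeneration bound for fully extinct families.
#' @return A `wgd_dataset`: per-species CDS collections, a gene/family
#'   table, true gene trees (newick, realized-Ks branch lengths), and a
#'   truth table labelling every within-family gene pair with its origin
#'   (episode id, `ssd`, or `speciation`) and true pairwise Ks.
#' @export
simulate_wgd_dataset <- function(spec, episodes = list(), n_families,
                                 ssd_rate = 0.05, loss_rate = 0.02,
                                 mean_length_codons = 200, omega = 0.2,
                                 seed = 1L, max_retries = 100L) {
  stopifnot(inherits(spec, "species_tree_spec"), n_families >= 1,
            ssd_rate >= 0, loss_rate >= 0, mean_length_codons >= 10)
  prep <- prepare_species_tree(spec)
  placed <- place_episodes(prep, episodes)
  aa <- aa_codes()
  with_seed(seed, {
    fams <- vector("list", n_families)
    trees <- character(n_families)
    n_regen <- 0L
    for (f in seq_len(n_families)) {
      fam_id <- sprintf("fam%04d", f)
      L <- max(30L, stats::rpois(1L, mean_length_codons))
      tree <- NULL
      for (try in seq_len(max_retries)) {
        tree <- sim_family_tree(prep, placed, ssd_rate, loss_rate, L, omega, aa)
        if (!is.null(tree)) break
        n_regen <- n_regen + 1L
      }
      if (is.null(tree))
        stop("family ", fam_id, " went extinct in every retry")
      env <- new.env(parent = emptyenv())
      tree <- name_tips(tree, fam_id, env)
      env2 <- new.env(parent = emptyenv())
      fams[[f]] <- flatten_family(tree, fam_id, env2)
      trees[f] <- paste0(family_newick(tree), ";")
      names(trees)[f] <- fam_id
    }
    genes <- do.call(rbind, lapply(fams, `[[`, "genes"))
    truth <- do.call(rbind, lapply(fams, `[[`, "truth"))
    rownames(genes) <- rownames(truth) <- NULL
    collections <- split(stats::setNames(genes$cds, genes$gene), genes$species)
    if (n_regen > 0)
      message(n_regen, " extinct famil", if (n_regen == 1) "y" else "ies",
              " regenerated")
    structure(list(
      collections = collections,
      families = genes[, c("gene", "family", "species")],
      gene_trees = trees,
      truth = truth,
      spec = spec, episodes = episodes,
      params = list(n_families = n_families, ssd_rate = ssd_rate,
                    loss_rate = loss_rate,
                    mean_length_codons = mean_length_codons,
                    omega = omega, seed = seed, regenerated = n_regen)
    ), class = "wgd_dataset")
  })
}

#' @export
print.wgd_dataset <- function(x, ...) {
  cat("wgd_dataset:", length(x$gene_trees), "families,",
      nrow(x$families), "genes across",
      length(x$collections), "species\n")
  if (length(x$episodes))
    cat("planted episodes:",
        paste(vapply(seq_along(x$episodes), function(i)
          sprintf("wgd%d@%s (Ks %.2f, retention %.2f)", i,
                  x$episodes[[i]]$node, x$episodes[[i]]$age_ks,
                  x$episodes[[i]]$retention_prob), character(1)),
          collapse = "; "), "\n")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits one wrapped FASTA per species, `families.tsv`, `truth.tsv` and a
#' `trees/` directory of newick gene trees.
#'
#' @param dataset A `wgd_dataset`.
#' @param directory Output directory (created if needed).
#' @param overwrite Overwrite existing files.
#' @return A manifest data frame (file, records), invisibly printed.
#' @export
write_dataset <- function(dataset, directory, overwrite = FALSE) {
  stopifnot(inherits(dataset, "wgd_dataset"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  paths <- c(file.path(directory, paste0(names(dataset$collections), ".fasta")),
             file.path(directory, c("families.tsv", "truth.tsv")))
  exists_already <- paths[file.exists(paths)]
  if (length(exists_already) && !overwrite)
    stop("files exist (use overwrite = TRUE): ",
         paste(basename(exists_already), collapse = ", "))
  manifest <- data.frame(file = character(0), records = integer(0))
  for (sp in names(dataset$collections)) {
    seqs <- Biostrings::DNAStringSet(dataset$collections[[sp]])
    f <- file.path(directory, paste0(sp, ".fasta"))
    Biostrings::writeXStringSet(seqs, f, width = 60L)
    manifest <- rbind(manifest, data.frame(file = basename(f),
                                           records = length(seqs)))
  }
  utils::write.table(dataset$families, file.path(directory, "families.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- rbind(manifest, data.frame(file = "families.tsv",
                                         records = nrow(dataset$families)))
  utils::write.table(dataset$truth, file.path(directory, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- rbind(manifest, data.frame(file = "truth.tsv",
                                         records = nrow(dataset$truth)))
  tdir <- file.path(directory, "trees")
  if (!dir.exists(tdir)) dir.create(tdir)
  for (fam in names(dataset$gene_trees))
    writeLines(dataset$gene_trees[[fam]], file.path(tdir, paste0(fam, ".nwk")))
  manifest <- rbind(manifest, data.frame(file = "trees/",
                                         records = length(dataset$gene_trees)))
  manifest
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param directory Directory produced by [write_dataset()].
#' @return A list with `collections`, `families`, `truth` and `gene_trees`.
#' @export
read_dataset <- function(directory) {
  fasta <- list.files(directory, pattern = "\\.fasta$", full.names = TRUE)
  collections <- lapply(fasta, function(f) {
    s <- Biostrings::readDNAStringSet(f)
    stats::setNames(as.character(s), names(s))
  })
  names(collections) <- sub("\\.fasta$", "", basename(fasta))
  families <- utils::read.table(file.path(directory, "families.tsv"),
                                sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  truth <- utils::read.table(file.path(directory, "truth.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  tfiles <- list.files(file.path(directory, "trees"), pattern = "\\.nwk$",
                       full.names = TRUE)
  trees <- vapply(tfiles, readLines, character(1))
  names(trees) <- sub("\\.nwk$", "", basename(tfiles))
  list(collections = collections, families = families, truth = truth,
       gene_trees = trees)
}
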