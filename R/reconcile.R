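# Gene-tree / species-tree LCA reconciliation, (AB)(AB) duplicate-retention
# typing, and dual-criterion WGD calling.

#' Prepare a species tree for reconciliation
#'
#' @param tree Rooted binary `ape::phylo` or newick string. Internal nodes
#'   get labels `N1..` if absent.
#' @return A `species_tree` with precomputed ancestor paths and tip sets.
#' @export
species_tree <- function(tree) {
  if (inherits(tree, "species_tree_spec")) tree <- tree$tree
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  if (!ape::is.binary(tree)) stop("species tree must be binary")
  if (is.null(tree$node.label) || any(tree$node.label == ""))
    tree$node.label <- paste0("N", seq_len(tree$Nnode))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  labels <- c(tree$tip.label, tree$node.label)
  parent <- integer(nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  parent[root] <- 0L
  # root-to-node ancestor paths (including the node itself)
  anc <- vector("list", nnode)
  depth <- integer(nnode)
  order_nodes <- c(root, tree$edge[, 2]) # parents precede children in phylo edge order? ensure below
  # robust: iterate until all filled
  anc[[root]] <- root
  repeat {
    done <- TRUE
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      if (is.null(anc[[ch]]) && !is.null(anc[[p]])) {
        anc[[ch]] <- c(anc[[p]], ch)
        depth[ch] <- depth[p] + 1L
        done <- FALSE
      }
    }
    if (done) break
  }
  tipset <- vector("list", nnode)
  for (i in seq_len(ntip)) tipset[[i]] <- labels[i]
  fill_tips <- function(n) {
    if (!is.null(tipset[[n]])) return(tipset[[n]])
    kids <- tree$edge[tree$edge[, 1] == n, 2]
    res <- sort(unique(unlist(lapply(kids, fill_tips))))
    tipset[[n]] <<- res
    res
  }
  fill_tips(root)
  children <- lapply(seq_len(nnode), function(n)
    tree$edge[tree$edge[, 1] == n, 2])
  structure(list(tree = tree, ntip = ntip, labels = labels, root = root,
                 parent = parent, anc = anc, depth = depth,
                 tipset = tipset, children = children),
            class = "species_tree")
}

# LCA of a set of species-tree node numbers via ancestor-path intersection.
st_lca <- function(st, nodes) {
  nodes <- unique(nodes)
  if (length(nodes) == 1L) return(nodes)
  common <- Reduce(intersect, st$anc[nodes])
  common[length(common)]
}

# Default gene -> species extraction for ids "<species>|<family>|<copy>".
species_of <- function(gene_ids) sub("\\|.*$", "", gene_ids)

#' Neighbor-joining gene tree from a family's coding sequences
#'
#' Distances are protein p-distances (proportion of differing amino-acid
#' sites; sequences of unequal length are globally aligned first). The tree
#' is unrooted; root it with [root_gene_tree()].
#'
#' @param sequences Named CDS vector for one family (>= 3 genes).
#' @return An `ape::phylo` tree.
#' @export
build_nj_gene_tree <- function(sequences) {
  m <- length(sequences)
  if (m < 3L)
    stop("need >= 3 sequences for a gene tree; handle 2-gene families as a single pair")
  tb <- ng86_tables()
  prots <- lapply(names(sequences), function(g)
    tb$aa[check_cds(sequences[[g]], g)])
  names(prots) <- names(sequences)
  d <- matrix(0, m, m, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    a <- prots[[i]]; b <- prots[[j]]
    if (length(a) == length(b)) {
      p <- mean(a != b)
    } else {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(paste(a, collapse = "")),
        Biostrings::AAString(paste(b, collapse = "")),
        substitutionMatrix = scoring_matrix("BLOSUM62"),
        gapOpening = 10, gapExtension = 0.5, type = "global")
      ca <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
      cb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
      keep <- ca != "-" & cb != "-"
      p <- if (any(keep)) mean(ca[keep] != cb[keep]) else 1
    }
    d[i, j] <- d[j, i] <- p
  }
  ape::nj(stats::as.dist(d))
}

# All candidate rootings of an unrooted tree, one per edge.
candidate_rootings <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  out <- list()
  seen <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    tips_below <- if (child <= ntip) tree$tip.label[child]
    else ape::extract.clade(tree, child)$tip.label
    side <- sort(tips_below)
    if (length(side) == 0L || length(side) == ntip) next
    key <- paste(side, collapse = "|")
    other <- paste(sort(setdiff(tree$tip.label, side)), collapse = "|")
    if (key %in% seen || other %in% seen) next
    seen <- c(seen, key)
    rooted <- tryCatch(ape::root(tree, outgroup = tips_below,
                                 resolve.root = TRUE),
                       error = function(err) NULL)
    if (!is.null(rooted) && ape::is.rooted(rooted))
      out[[length(out) + 1L]] <- list(tree = rooted, split = key)
  }
  out
}

#' Root a gene tree by minimal implied duplications
#'
#' Every branch is tried as the root position; the rooting implying the
#' fewest duplications wins, ties broken by fewest implied losses, then
#' lexicographically by the root bipartition, so the result is
#' deterministic.
#'
#' @param tree Unrooted (or arbitrarily rooted) `ape::phylo` gene tree.
#' @param st A [species_tree()].
#' @param get_species Function mapping tip labels to species names.
#' @return A rooted `ape::phylo`.
#' @export
root_gene_tree <- function(tree, st, get_species = species_of) {
  if (length(tree$tip.label) < 3L) stop("gene tree must have >= 3 tips")
  cands <- candidate_rootings(tree)
  best <- NULL
  for (cand in cands) {
    rec <- reconcile_core(cand$tree, st, get_species)
    score <- c(rec$n_dup, rec$n_loss)
    if (is.null(best) ||
        score[1] < best$score[1] ||
        (score[1] == best$score[1] && score[2] < best$score[2]) ||
        (all(score == best$score) && cand$split < best$split)) {
      best <- list(tree = cand$tree, score = score, split = cand$split)
    }
  }
  best$tree
}

# Core LCA reconciliation machinery shared by root_gene_tree and reconcile.
reconcile_core <- function(gtree, st, get_species = species_of) {
  ntip <- length(gtree$tip.label)
  nnode <- ntip + gtree$Nnode
  sp <- get_species(gtree$tip.label)
  missing_sp <- setdiff(sp, st$labels[seq_len(st$ntip)])
  if (length(missing_sp))
    stop("gene-tree species not in species tree: ",
         paste(unique(missing_sp), collapse = ", "))
  sp_node <- match(sp, st$labels)
  mapping <- integer(nnode)
  tipgenes <- vector("list", nnode)
  children <- lapply(seq_len(nnode), function(n)
    gtree$edge[gtree$edge[, 1] == n, 2])
  # internal nodes in DFS postorder (children before parents)
  postorder <- integer(0)
  stack <- ntip + 1L
  visited <- logical(nnode)
  while (length(stack)) {
    n <- stack[length(stack)]
    kids <- children[[n]]
    pending <- kids[!visited[kids] & kids > ntip]
    if (length(pending)) {
      stack <- c(stack, pending)
    } else {
      postorder <- c(postorder, n)
      visited[n] <- TRUE
      stack <- stack[-length(stack)]
    }
  }
  for (i in seq_len(ntip)) {
    mapping[i] <- sp_node[i]
    tipgenes[[i]] <- gtree$tip.label[i]
  }
  n_dup <- 0L; n_loss <- 0L
  dups <- list()
  for (n in postorder) {
    kids <- children[[n]]
    mapping[n] <- st_lca(st, mapping[kids])
    tipgenes[[n]] <- unlist(tipgenes[kids])
    is_dup <- any(mapping[kids] == mapping[n])
    if (is_dup) n_dup <- n_dup + 1L
    for (ch in kids)
      n_loss <- n_loss + (st$depth[mapping[ch]] - st$depth[mapping[n]]) -
        (if (is_dup) 0L else 1L) + (if (mapping[ch] == mapping[n]) 1L else 0L)
    if (is_dup) dups[[length(dups) + 1L]] <-
        list(gene_node = n, kids = kids, mapped = mapping[n])
  }
  list(mapping = mapping, tipgenes = tipgenes, children = children,
       n_dup = n_dup, n_loss = max(n_loss, 0L), dups = dups)
}

#' Reconcile a rooted gene tree with the species tree
#'
#' Standard LCA mapping: each gene-tree internal node maps to the species
#' tree LCA of its tips' species; a node is a duplication iff it maps to
#' the same species-tree node as at least one of its children. Duplications
#' with bootstrap-style support below `support_threshold` are discarded.
#' Each duplication at an internal species-tree node with child lineages A
#' and B is typed `AB_AB` when both gene-tree child subtrees contain at
#' least one species from A and one from B (the retention pattern expected
#' of a WGD); duplications mapped to a species-tree tip are typed `other`.
#'
#' @param gene_tree Rooted `ape::phylo`.
#' @param st A [species_tree()].
#' @param support_threshold Minimum node support (0-100); nodes with no
#'   support annotation always pass.
#' @param family Family id recorded with the events.
#' @param get_species Tip label to species mapper.
#' @return A list of `gd_event`s: gene-tree node, mapped species-tree node
#'   label, type, the two child species sets, and the genes in each child
#'   subtree.
#' @export
reconcile <- function(gene_tree, st, support_threshold = 50,
                      family = NA_character_, get_species = species_of) {
  if (!ape::is.rooted(gene_tree)) stop("gene tree must be rooted")
  gene_tree <- ape::multi2di(gene_tree) # deterministic resolution of polytomies
  rec <- reconcile_core(gene_tree, st, get_species)
  ntip <- length(gene_tree$tip.label)
  support <- function(n) {
    if (is.null(gene_tree$node.label)) return(NA_real_)
    suppressWarnings(as.numeric(gene_tree$node.label[n - ntip]))
  }
  events <- list()
  for (d in rec$dups) {
    s <- support(d$gene_node)
    if (!is.na(s) && s < support_threshold) next
    mapped <- d$mapped
    genes1 <- rec$tipgenes[[d$kids[1]]]
    genes2 <- rec$tipgenes[[d$kids[2]]]
    sp1 <- unique(get_species(genes1))
    sp2 <- unique(get_species(genes2))
    type <- "other"
    if (mapped > st$ntip) {
      ab <- st$children[[mapped]]
      A <- st$tipset[[ab[1]]]; B <- st$tipset[[ab[2]]]
      if (length(intersect(sp1, A)) && length(intersect(sp1, B)) &&
          length(intersect(sp2, A)) && length(intersect(sp2, B)))
        type <- "AB_AB"
    }
    events[[length(events) + 1L]] <- list(
      family = family, gene_node = d$gene_node,
      node = st$labels[mapped], node_is_tip = mapped <= st$ntip,
      type = type, species_left = sp1, species_right = sp2,
      genes_left = genes1, genes_right = genes2)
  }
  events
}

#' Tally gene-duplication events per species-tree node
#'
#' @param events List of `gd_event`s pooled over families (concatenated
#'   [reconcile()] outputs).
#' @param n_families Total number of gene families analysed.
#' @param st A [species_tree()].
#' @return A `reconciliation_summary` data frame with one row per species
#'   tree node: `gd_count` (events), `family_count` (families with >= 1
#'   event), `gd_ratio` (= gd_count / n_families), `abab_percent`, and
#'   placeholder `wgd_flag` / `criterion_hit` columns filled by
#'   [call_wgd()].
#' @export
summarize_gd <- function(events, n_families, st) {
  nodes <- st$labels
  df <- data.frame(node = nodes,
                   is_root = nodes == st$labels[st$root],
                   is_tip = seq_along(nodes) <= st$ntip,
                   gd_count = 0L, family_count = 0L,
                   gd_ratio = 0, abab_percent = NA_real_,
                   wgd_flag = FALSE, criterion_hit = NA_integer_,
                   stringsAsFactors = FALSE)
  if (length(events)) {
    ev_node <- vapply(events, `[[`, character(1), "node")
    ev_fam <- vapply(events, function(e)
      as.character(e$family %||% NA_character_), character(1))
    ev_abab <- vapply(events, function(e) e$type == "AB_AB", logical(1))
    for (i in seq_along(nodes)) {
      sel <- ev_node == nodes[i]
      df$gd_count[i] <- sum(sel)
      df$family_count[i] <- length(unique(ev_fam[sel]))
      if (any(sel)) df$abab_percent[i] <- 100 * mean(ev_abab[sel])
    }
    df$gd_ratio <- df$gd_count / n_families
  }
  attr(df, "n_families") <- n_families
  class(df) <- c("reconciliation_summary", "data.frame")
  df
}

#' Flag putative WGD nodes by the dual count/ratio/(AB)(AB) criteria
#'
#' A node is flagged when, with strict inequalities, either (1) GD count >
#' 450, GD ratio > 4.5% and (AB)(AB) percent > 50%, or (2) GD count > 1000,
#' GD ratio > 5% and (AB)(AB) percent > 20%. The count thresholds assume
#' transcriptome-scale family numbers; `criteria = "scaled"` rescales them
#' by `n_families / 10000` for small simulated datasets (ratio and
#' percentage thresholds are scale-free and unchanged). Duplications at the
#' species-tree root are reported but never flagged automatically.
#'
#' @param summary A [summarize_gd()] result.
#' @param criteria `"paper"` (fixed counts) or `"scaled"`.
#' @return The summary with `wgd_flag` and `criterion_hit` filled in.
#' @export
call_wgd <- function(summary, criteria = c("paper", "scaled")) {
  criteria <- match.arg(criteria)
  n_families <- attr(summary, "n_families")
  scale <- if (criteria == "scaled") n_families / 10000 else 1
  c1_count <- 450 * scale; c2_count <- 1000 * scale
  for (i in seq_len(nrow(summary))) {
    gd <- summary$gd_count[i]
    ratio <- 100 * summary$gd_ratio[i]
    abab <- summary$abab_percent[i]
    if (is.na(abab)) next
    hit1 <- gd > c1_count && ratio > 4.5 && abab > 50
    hit2 <- gd > c2_count && ratio > 5 && abab > 20
    if ((hit1 || hit2) && summary$is_root[i]) {
      warning("root node '", summary$node[i],
              "' meets WGD criteria but is not auto-flagged ",
              "(outgroup sampling is typically insufficient)")
      next
    }
    summary$wgd_flag[i] <- hit1 || hit2
    summary$criterion_hit[i] <- if (hit1) 1L else if (hit2) 2L else NA_integer_
  }
  summary
}

#' Extract within-species duplicate gene pairs of a WGD node
#'
#' For every duplication event mapped to `node`, all cross-subtree pairs of
#' genes from the same species are emitted (the two putative WGD copies),
#' deduplicated and tagged with their family.
#'
#' @param events Pooled `gd_event` list.
#' @param node Species-tree node label.
#' @return Data frame `family`, `node`, `species`, `gene_a`, `gene_b`.
#' @export
extract_wgd_duplicates <- function(events, node) {
  sel <- Filter(function(e) e$node == node, events)
  if (!length(sel)) {
    warning("no gene-duplication events at node '", node, "'")
    return(data.frame(family = character(0), node = character(0),
                      species = character(0), gene_a = character(0),
                      gene_b = character(0)))
  }
  rows <- list()
  for (e in sel) {
    spl <- species_of(e$genes_left)
    spr <- species_of(e$genes_right)
    for (s in intersect(spl, spr)) {
      gl <- e$genes_left[spl == s]
      gr <- e$genes_right[spr == s]
      grid <- expand.grid(a = gl, b = gr, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        family = e$family, node = node, species = s,
        gene_a = pmin(grid$a, grid$b), gene_b = pmax(grid$a, grid$b),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("species", "gene_a", "gene_b")]), , drop = FALSE]
  out[order(out$species, out$gene_a, out$gene_b), , drop = FALSE]
}
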