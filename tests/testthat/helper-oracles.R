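# Independent oracles, written against base R and Biostrings only, used to
# cross-check the package implementations on small inputs.

GC <- Biostrings::GENETIC_CODE
BASES <- c("A", "C", "G", "T")

aa_of <- function(codon) {
  a <- GC[[codon]]
  if (is.null(a) || is.na(a)) "*" else a
}

# --- NG86 enumeration oracle -----------------------------------------

# Synonymous site count of one codon: per position, the fraction of
# non-stop single-base alternatives that keep the amino acid.
oracle_syn_sites <- function(codon) {
  s <- 0
  for (p in 1:3) {
    syn <- 0; valid <- 0
    for (b in setdiff(BASES, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (aa_of(mut) == "*") next
      valid <- valid + 1
      if (aa_of(mut) == aa_of(codon)) syn <- syn + 1
    }
    if (valid > 0) s <- s + syn / valid
  }
  s
}

# All substitution orders between two codons, by depth-first recursion;
# returns average (syn, nonsyn) step counts over stop-free orders, falling
# back to all orders when every one passes through a stop.
oracle_codon_diffs <- function(ca, cb) {
  paths <- function(cur, avoid_stops) {
    pos <- which(strsplit(cur, "")[[1]] != strsplit(cb, "")[[1]])
    if (!length(pos)) return(list(c(0, 0)))
    out <- list()
    for (p in pos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (avoid_stops && aa_of(nxt) == "*") next
      step <- if (aa_of(nxt) == aa_of(cur)) c(1, 0) else c(0, 1)
      for (rest in paths(nxt, avoid_stops))
        out[[length(out) + 1]] <- step + rest
    }
    out
  }
  res <- paths(ca, TRUE)
  if (!length(res)) res <- paths(ca, FALSE)
  colMeans(do.call(rbind, res))
}

# Full NG86 on two equal-length stop-free codon string vectors.
oracle_ng86 <- function(cods_a, cods_b) {
  S <- (sum(vapply(cods_a, oracle_syn_sites, 1)) +
          sum(vapply(cods_b, oracle_syn_sites, 1))) / 2
  N <- 3 * length(cods_a) - S
  diffs <- do.call(rbind, Map(oracle_codon_diffs, cods_a, cods_b))
  Sd <- sum(diffs[, 1]); Nd <- sum(diffs[, 2])
  ps <- Sd / S; pn <- Nd / N
  jc <- function(p) {
    if (!is.finite(p) || p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd, Ks = jc(ps), Ka = jc(pn))
}

random_stopfree_codons <- function(n) {
  ok <- names(GC)[GC != "*"]
  sample(ok, n, replace = TRUE)
}

# --- affine-gap protein alignment oracle (Gotoh) ----------------------

oracle_align_score <- function(pa, pb, mat, gap_open, gap_extend) {
  a <- strsplit(pa, "")[[1]]; b <- strsplit(pb, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  open <- -(gap_open + gap_extend); ext <- -gap_extend
  for (j in 2:(m + 1)) Iy[1, j] <- open + (j - 2) * ext
  for (i in 2:(n + 1)) Ix[i, 1] <- open + (i - 2) * ext
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- mat[a[i - 1], b[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
    Ix[i, j] <- max(M[i - 1, j] + open, Ix[i - 1, j] + ext)
    Iy[i, j] <- max(M[i, j - 1] + open, Iy[i, j - 1] + ext)
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# --- brute-force reconciliation oracle --------------------------------

# Species-tree clades computed by scanning every node's tip set; a gene
# node maps to the smallest clade containing its species; duplication iff
# it maps where one of its children maps.
oracle_reconcile <- function(gtree, stree, get_species = function(x) sub("\\|.*$", "", x)) {
  nt <- length(stree$tip.label)
  clade_tips <- function(n) {
    if (n <= nt) return(stree$tip.label[n])
    kids <- stree$edge[stree$edge[, 1] == n, 2]
    sort(unique(unlist(lapply(kids, clade_tips))))
  }
  clades <- lapply(seq_len(nt + stree$Nnode), clade_tips)
  map_of <- function(species_set) {
    sizes <- vapply(clades, length, 1L)
    cand <- which(vapply(clades, function(cl) all(species_set %in% cl), TRUE))
    cand[which.min(sizes[cand])]
  }
  gnt <- length(gtree$tip.label)
  gtips <- function(n) {
    if (n <= gnt) return(gtree$tip.label[n])
    kids <- gtree$edge[gtree$edge[, 1] == n, 2]
    unlist(lapply(kids, gtips))
  }
  events <- list()
  for (v in (gnt + 1):(gnt + gtree$Nnode)) {
    kids <- gtree$edge[gtree$edge[, 1] == v, 2]
    mv <- map_of(unique(get_species(gtips(v))))
    mk <- vapply(kids, function(k) map_of(unique(get_species(gtips(k)))), 1L)
    if (!any(mk == mv)) next
    type <- "other"
    if (mv > nt) {
      ab <- stree$edge[stree$edge[, 1] == mv, 2]
      A <- clades[[ab[1]]]; B <- clades[[ab[2]]]
      in_both <- vapply(kids, function(k) {
        sp <- unique(get_species(gtips(k)))
        length(intersect(sp, A)) > 0 && length(intersect(sp, B)) > 0
      }, TRUE)
      if (all(in_both)) type <- "AB_AB"
    }
    labels <- c(stree$tip.label, stree$node.label)
    events[[length(events) + 1]] <- list(node = labels[mv], type = type)
  }
  events
}

# random rooted gene tree over a species set, as newick
random_gene_tree <- function(n_leaves, species_pool) {
  sp <- sample(species_pool, n_leaves, replace = TRUE)
  labels <- paste0(sp, "|fam|", seq_len(n_leaves))
  while (length(labels) > 1) {
    i <- sample(length(labels), 2)
    joined <- paste0("(", labels[i[1]], ",", labels[i[2]], ")")
    labels <- c(labels[-i], joined)
  }
  ape::read.tree(text = paste0(labels, ";"))
}

# --- shared fixtures --------------------------------------------------

toy_tree_text <- "(((A:0.4,B:0.4)AB:0.35,C:0.75)ABC:0.25,O:1.0)root;"
toy_spec <- function(mult = NULL)
  species_tree_spec(toy_tree_text, rate_multipliers = mult)
toy_st <- function() species_tree(toy_tree_text)
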