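# Paralog / ortholog pair selection and Ks-age distributions.

#' Enumerate within-species paralog pairs from gene families
#'
#' Within each family, all unordered pairs of genes belonging to the same
#' species are emitted. Redundancy weights (so that one duplication event
#' contributes total weight 1) are assigned later by [add_node_weights()],
#' once Ks values are available.
#'
#' @param genes Character vector of gene ids for one species (or several;
#'   the species of each gene is taken from `families`).
#' @param families Data frame with `gene`, `family` and optionally `species`
#'   columns covering all `genes`.
#' @return Data frame `gene_a`, `gene_b`, `family`, `species` (gene_a <
#'   gene_b lexicographically). Families with fewer than 2 genes of a
#'   species contribute nothing.
#' @export
paralog_pairs <- function(genes, families) {
  miss <- setdiff(genes, families$gene)
  if (length(miss)) stop("genes not covered by the family map: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  fam <- families[families$gene %in% genes, , drop = FALSE]
  if (is.null(fam$species)) fam$species <- sub("\\|.*$", "", fam$gene)
  out <- list()
  for (grp in split(fam, list(fam$family, fam$species), drop = TRUE)) {
    g <- sort(grp$gene)
    m <- length(g)
    if (m < 2L) next
    idx <- utils::combn(m, 2L)
    out[[length(out) + 1L]] <- data.frame(
      gene_a = g[idx[1, ]], gene_b = g[idx[2, ]],
      family = grp$family[1], species = grp$species[1],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      family = character(0), species = character(0)))
  res <- do.call(rbind, out)
  res[order(res$family, res$species, res$gene_a, res$gene_b), , drop = FALSE]
}

#' Node-weight paralog pairs so each duplication event counts once
#'
#' Single-linkage clusters each family's within-species genes on their
#' pairwise Ks values; every internal node of the resulting dendrogram
#' carries total weight 1, split equally among the gene pairs it joins
#' (`1 / (|left| * |right|)` per pair). A family of m genes therefore
#' contributes total weight m - 1, one unit per inferred duplication event.
#'
#' @param pairs Output of [paralog_pairs()] with a `Ks` column appended
#'   (e.g. by [kaks_pairs()]). Pairs with undefined Ks enter the clustering
#'   at a pseudo-distance beyond the saturation bound but keep weight NA
#'   semantics downstream (they are filtered by [build_ks_distribution()]).
#' @return `pairs` with a `weight` column.
#' @export
add_node_weights <- function(pairs) {
  if (is.null(pairs$Ks)) stop("pairs must carry a Ks column")
  if (!nrow(pairs)) return(cbind(pairs, weight = numeric(0)))
  pairs$weight <- NA_real_
  for (key in unique(paste(pairs$family, pairs$species))) {
    sel <- paste(pairs$family, pairs$species) == key
    pp <- pairs[sel, , drop = FALSE]
    genes <- sort(unique(c(pp$gene_a, pp$gene_b)))
    m <- length(genes)
    if (m == 2L) { pairs$weight[sel] <- 1; next }
    d <- matrix(0, m, m, dimnames = list(genes, genes))
    ks <- ifelse(is.na(pp$Ks), 10, pp$Ks) # undefined = very old
    d[cbind(match(pp$gene_a, genes), match(pp$gene_b, genes))] <- ks
    d[cbind(match(pp$gene_b, genes), match(pp$gene_a, genes))] <- ks
    hc <- stats::hclust(stats::as.dist(d), method = "single")
    members <- lapply(seq_len(m), function(i) genes[i])
    clusters <- as.list(genes)
    w <- stats::setNames(rep(NA_real_, nrow(pp)),
                         paste(pp$gene_a, pp$gene_b))
    for (step in seq_len(m - 1L)) {
      pick <- function(j) if (j < 0) genes[-j] else clusters[[j + m]]
      left <- pick(hc$merge[step, 1]); right <- pick(hc$merge[step, 2])
      for (a in left) for (b in right) {
        key2 <- paste(min(a, b), max(a, b))
        w[key2] <- 1 / (length(left) * length(right))
      }
      clusters[[step + m]] <- c(left, right)
    }
    pairs$weight[sel] <- unname(w[paste(pp$gene_a, pp$gene_b)])
  }
  pairs
}

# Shared protein k-mer count between two collections; used as the internal
# similarity score for reciprocal-best-hit orthology.
kmer_scores <- function(collection_a, collection_b, k = 5L) {
  tb <- ng86_tables()
  prot_kmers <- function(cds) {
    aa <- tb$aa[check_cds(cds, "sequence")]
    p <- paste(aa, collapse = "")
    n <- nchar(p)
    if (n < k) return(character(0))
    unique(substring(p, 1:(n - k + 1), k:n))
  }
  ka <- lapply(collection_a, prot_kmers)
  kb <- lapply(collection_b, prot_kmers)
  # inverted index over collection_b
  idx <- new.env(parent = emptyenv())
  for (b in names(kb)) for (km in kb[[b]])
    idx[[km]] <- c(idx[[km]] %||% character(0), b)
  rows <- list()
  for (a in names(ka)) {
    hits <- unlist(lapply(ka[[a]], function(km) idx[[km]] %||% character(0)))
    if (!length(hits)) next
    cnt <- table(hits)
    rows[[a]] <- data.frame(gene_a = a, gene_b = names(cnt),
                            score = as.numeric(cnt),
                            stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0)))
  do.call(rbind, rows)
}

#' Reciprocal-best-hit ortholog pairs between two species
#'
#' Each gene's best-scoring cross-species match is found and a pair is kept
#' when the choice is mutual. Ties break lexicographically by gene id so
#' the result is deterministic. Scores default to an internal shared
#' protein k-mer count; a user-supplied score table bypasses the scorer.
#'
#' @param collection_a,collection_b Named CDS vectors, one per species.
#' @param scores Optional data frame `gene_a`, `gene_b`, `score`.
#' @param k K-mer length of the internal scorer.
#' @param min_score Minimum score for a hit to count.
#' @return Data frame `gene_a`, `gene_b`, `score`.
#' @export
ortholog_pairs <- function(collection_a, collection_b, scores = NULL,
                           k = 5L, min_score = 1) {
  if (is.null(scores)) scores <- kmer_scores(collection_a, collection_b, k)
  scores <- scores[scores$score >= min_score, , drop = FALSE]
  if (!nrow(scores)) {
    warning("empty similarity score table; no ortholog pairs")
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0)))
  }
  best_of <- function(df, by, other) {
    df <- df[order(df[[by]], -df$score, df[[other]]), , drop = FALSE]
    df[!duplicated(df[[by]]), , drop = FALSE]
  }
  ba <- best_of(scores, "gene_a", "gene_b")
  bb <- best_of(scores, "gene_b", "gene_a")
  keep <- merge(ba, bb, by = c("gene_a", "gene_b", "score"))
  keep <- keep[order(keep$gene_a, keep$gene_b), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' Build a filtered Ks-age distribution
#'
#' Retains pairs whose Ks lies in the closed interval `[ks_min, ks_max]`
#' (defaults `[0.1, 5]`, excluding very recent duplicates and saturated
#' values); undefined Ks values are dropped and counted.
#'
#' @param pairs Data frame with a `Ks` column and optionally `weight`
#'   (defaults to 1).
#' @param label Distribution label (species or species pair).
#' @param mode `"intraspecific"` or `"interspecific"`.
#' @param ks_min,ks_max Closed retention bounds.
#' @return A `ks_distribution` with `entries` (pair id, Ks, weight) and a
#'   `dropped` count table.
#' @export
build_ks_distribution <- function(pairs, label = "", mode = "intraspecific",
                                  ks_min = 0.1, ks_max = 5) {
  mode <- match.arg(mode, c("intraspecific", "interspecific"))
  ks <- pairs$Ks
  w <- pairs$weight %||% rep(1, length(ks))
  w[is.na(w)] <- 1
  undef <- is.na(ks)
  below <- !undef & ks < ks_min
  above <- !undef & ks > ks_max
  keep <- !undef & !below & !above
  entries <- data.frame(
    pair = if (!is.null(pairs$gene_a))
      paste(pairs$gene_a[keep], pairs$gene_b[keep], sep = "~")
    else as.character(which(keep)),
    Ks = ks[keep], weight = w[keep], stringsAsFactors = FALSE)
  structure(list(label = label, mode = mode, entries = entries,
                 ks_min = ks_min, ks_max = ks_max,
                 dropped = c(undefined = sum(undef), below_min = sum(below),
                             above_max = sum(above))),
            class = "ks_distribution")
}

#' @export
print.ks_distribution <- function(x, ...) {
  cat(sprintf("ks_distribution '%s' (%s): %d entries, total weight %.2f, Ks in [%g, %g]\n",
              x$label, x$mode, nrow(x$entries), sum(x$entries$weight),
              x$ks_min, x$ks_max))
  d <- x$dropped
  if (sum(d)) cat("  dropped:", paste(names(d), d, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
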