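# Positive-selection screening, hypergeometric over-representation tests,
# and between-genus gene-fraction statistics.

#' Screen duplicate pairs for positive selection
#'
#' A pair is flagged when its Ka/Ks ratio is strictly above 1. Pairs with
#' undefined ratios (zero or saturated Ks) are excluded from the
#' denominator and reported separately, never flagged.
#'
#' @param estimates Data frame with a `ka_ks` column (e.g. [kaks_pairs()]
#'   output), or a list of `kaks_estimate` objects.
#' @return A `selection_screen` list: `pairs_total`, `pairs_positive`,
#'   `fraction_positive`, `pairs_undefined`, and the per-pair table with a
#'   `selected` flag.
#' @export
screen_positive_selection <- function(estimates) {
  if (is.list(estimates) && !is.data.frame(estimates) &&
      all(vapply(estimates, inherits, logical(1), "kaks_estimate")))
    estimates <- do.call(rbind, lapply(estimates, function(e)
      as.data.frame(unclass(e)[c("gene_a", "gene_b", "Ka", "Ks", "ka_ks")])))
  if (!nrow(estimates)) {
    warning("no pairs to screen")
    return(structure(list(pairs_total = 0L, pairs_positive = 0L,
                          fraction_positive = NA_real_, pairs_undefined = 0L,
                          table = estimates), class = "selection_screen"))
  }
  defined <- !is.na(estimates$ka_ks)
  estimates$selected <- defined & estimates$ka_ks > 1
  structure(list(
    pairs_total = sum(defined),
    pairs_positive = sum(estimates$selected),
    fraction_positive = if (any(defined)) sum(estimates$selected) / sum(defined)
    else NA_real_,
    pairs_undefined = sum(!defined),
    table = estimates
  ), class = "selection_screen")
}

#' @export
print.selection_screen <- function(x, ...) {
  cat(sprintf("selection_screen: %d / %d pairs with Ka/Ks > 1 (%.2f%%), %d undefined\n",
              x$pairs_positive, x$pairs_total,
              100 * (x$fraction_positive %||% NA), x$pairs_undefined))
  invisible(x)
}

#' Hypergeometric over-representation test with BH correction
#'
#' For each annotation term with at least `min_term_size` genes in the
#' universe, tests whether the gene set contains more genes with that term
#' than expected by drawing `n = |set|` genes from the universe:
#' upper-tail `P(X >= k)` of the hypergeometric distribution. P-values are
#' Benjamini-Hochberg adjusted across tested terms.
#'
#' @param gene_set Character vector of gene ids (subset of `universe`).
#' @param annotation Data frame `gene`, `term` (long format; one row per
#'   gene-term assignment), or a named list mapping gene -> terms.
#' @param universe Background gene ids; defaults to all annotated genes.
#' @param min_term_size Minimum universe genes per tested term.
#' @return Data frame `term`, `k`, `K`, `n`, `N`, `p_value`, `q_value`,
#'   sorted by p-value.
#' @export
hypergeometric_enrichment <- function(gene_set, annotation, universe = NULL,
                                      min_term_size = 3L) {
  if (is.list(annotation) && !is.data.frame(annotation))
    annotation <- data.frame(
      gene = rep(names(annotation), lengths(annotation)),
      term = unlist(annotation, use.names = FALSE),
      stringsAsFactors = FALSE)
  if (is.null(universe)) universe <- unique(annotation$gene)
  outside <- setdiff(gene_set, universe)
  if (length(outside))
    stop("genes outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  annotation <- annotation[annotation$gene %in% universe, , drop = FALSE]
  N <- length(unique(universe))
  n <- length(unique(gene_set))
  rows <- list()
  for (term in sort(unique(annotation$term))) {
    with_term <- unique(annotation$gene[annotation$term == term])
    K <- length(with_term)
    if (K < min_term_size) next
    k <- length(intersect(gene_set, with_term))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      term = term, k = k, K = K, n = n, N = N, p_value = p,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      q_value = numeric(0)))
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value, out$term), , drop = FALSE]
}

#' Compare target-gene fractions between two genera
#'
#' Per species, the fraction is target gene count / total gene count; the
#' genus fraction is the arithmetic mean over its species. The two genera
#' are compared by an independent two-sample t-test on the per-species
#' fractions (Welch's by default), with the usual significance stars
#' (* < 0.05, ** < 0.01, *** < 0.001).
#'
#' @param counts Data frame `species`, `target_count`, `total_count`.
#' @param genus_map Named character vector, species -> genus (exactly two
#'   genera, each with >= 2 species).
#' @param var_equal Use Student's pooled-variance t-test instead of
#'   Welch's.
#' @return A `gene_fraction_stat`: per-species fractions, genus means, the
#'   t statistic, p-value and stars.
#' @export
gene_fraction_test <- function(counts, genus_map, var_equal = FALSE) {
  stopifnot(all(c("species", "target_count", "total_count") %in% names(counts)))
  counts$fraction <- counts$target_count / counts$total_count
  if (any(counts$fraction < 0 | counts$fraction > 1))
    stop("fractions must lie in [0, 1]")
  counts$genus <- genus_map[counts$species]
  if (anyNA(counts$genus)) stop("genus_map must cover every species")
  genera <- sort(unique(counts$genus))
  if (length(genera) != 2L) stop("exactly two genera required")
  split_f <- split(counts$fraction, counts$genus)
  if (any(lengths(split_f) < 2L))
    stop("each genus needs >= 2 species for a t-test")
  degenerate <- all(vapply(split_f, function(v) stats::var(v) == 0, logical(1)))
  if (degenerate && split_f[[1]][1] == split_f[[2]][1]) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else if (degenerate) {
    # zero within-genus variance but different means: report p = 0 with a
    # warning rather than failing on the 0/0 statistic
    warning("degenerate zero within-genus variance; difference is exact")
    tt <- list(statistic = c(t = Inf), p.value = 0)
  } else {
    tt <- stats::t.test(split_f[[1]], split_f[[2]], var.equal = var_equal)
  }
  p <- tt$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else ""
  structure(list(
    per_species = counts[, c("species", "genus", "target_count",
                             "total_count", "fraction")],
    genus_means = vapply(split_f, mean, numeric(1)),
    t_statistic = unname(tt$statistic),
    p_value = p, stars = stars, welch = !var_equal && !degenerate
  ), class = "gene_fraction_stat")
}

#' @export
print.gene_fraction_stat <- function(x, ...) {
  cat(sprintf("gene_fraction_stat: %s mean = %.4g vs %s mean = %.4g, t = %.3f, p = %.4g %s\n",
              names(x$genus_means)[1], x$genus_means[1],
              names(x$genus_means)[2], x$genus_means[2],
              x$t_statistic, x$p_value, x$stars))
  invisible(x)
}
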