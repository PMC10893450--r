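# Nei-Gojobori (1986) counting estimator with Jukes-Cantor multiple-hit
# correction. Sites are counted per codon from the 3 single-base
# alternatives at each position (stop-creating alternatives removed and the
# fractions renormalised); multi-difference codons are averaged over all
# substitution orders that avoid stop codons.

jc_correct <- function(p) {
  if (is.na(p) || p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' NG86 Ka/Ks estimate for an aligned codon pair
#'
#' @param pair An [align_codon_pair()] result (or any list with parallel
#'   `codons_a` / `codons_b` character tracks using `"---"` for gaps).
#' @return A `kaks_estimate`: synonymous / nonsynonymous site counts `S`,
#'   `N`, difference counts `Sd`, `Nd`, proportions `ps`, `pn`,
#'   Jukes-Cantor-corrected `Ks`, `Ka` and the ratio `ka_ks`. Saturated or
#'   degenerate cases yield `NA` with `undefined_reason` set instead of
#'   being dropped silently.
#' @export
ng86 <- function(pair) {
  keep <- pair$codons_a != "---" & pair$codons_b != "---"
  if (!any(keep)) stop("no ungapped codon columns to estimate from")
  tb <- ng86_tables()
  ia <- codon_index(pair$codons_a[keep])
  ib <- codon_index(pair$codons_b[keep])
  if (any(tb$aa[ia] == "*") || any(tb$aa[ib] == "*"))
    stop("stop codon inside the alignment")
  est <- ng86_core(ia, ib, tb)
  structure(c(list(gene_a = pair$gene_a, gene_b = pair$gene_b), est),
            class = "kaks_estimate")
}

# Estimator core on parallel codon-index vectors (ungapped columns only).
ng86_core <- function(ia, ib, tb = ng86_tables()) {
  S <- (sum(tb$syn_sites[ia]) + sum(tb$syn_sites[ib])) / 2
  N <- (sum(tb$nonsyn_sites[ia]) + sum(tb$nonsyn_sites[ib])) / 2
  Sd <- sum(tb$SD[cbind(ia, ib)])
  Nd <- sum(tb$ND[cbind(ia, ib)])
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  Ks <- if (is.na(ps)) NA_real_ else jc_correct(ps)
  Ka <- if (is.na(pn)) NA_real_ else jc_correct(pn)
  reason <- if (S <= 0) "no synonymous sites"
  else if (!is.na(ps) && ps >= 0.75) "synonymous saturation (ps >= 3/4)"
  else NA_character_
  ka_ks <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
       Ks = Ks, Ka = Ka, ka_ks = ka_ks, undefined_reason = reason)
}

#' @export
print.kaks_estimate <- function(x, ...) {
  cat(sprintf("kaks_estimate %s vs %s: Ks = %s, Ka = %s, Ka/Ks = %s\n",
              x$gene_a, x$gene_b,
              format(x$Ks, digits = 4), format(x$Ka, digits = 4),
              format(x$ka_ks, digits = 4)))
  if (!is.na(x$undefined_reason)) cat("  flagged:", x$undefined_reason, "\n")
  invisible(x)
}

#' Batch Ka/Ks estimation for a table of gene pairs
#'
#' Aligns and estimates every pair; errors in single pairs are converted to
#' all-NA rows with the message recorded.
#'
#' @param pairs Data frame with `gene_a`, `gene_b` columns (extra columns
#'   are carried through).
#' @param sequences Named character vector of CDS covering all genes.
#' @param substitution_matrix,gap_open,gap_extend Protein alignment
#'   parameters (see [align_codon_pair()]).
#' @return `pairs` with `S`, `N`, `Sd`, `Nd`, `Ka`, `Ks`, `ka_ks` columns
#'   appended.
#' @export
kaks_pairs <- function(pairs, sequences, substitution_matrix = "BLOSUM62",
                       gap_open = 10, gap_extend = 0.5) {
  na_row <- list(S = NA_real_, N = NA_real_, Sd = NA_real_, Nd = NA_real_,
                 Ka = NA_real_, Ks = NA_real_, ka_ks = NA_real_)
  if (!nrow(pairs))
    return(cbind(pairs, do.call(rbind, list(as.data.frame(na_row)))[0, ]))
  miss <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(sequences))
  if (length(miss))
    stop("missing sequence for: ", paste(utils::head(miss, 5), collapse = ", "))
  tb <- ng86_tables()
  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  codons <- lapply(genes, function(g)
    tryCatch(check_cds(sequences[[g]], g), error = function(e) NULL))
  names(codons) <- genes
  prot <- vapply(codons, function(idx)
    if (is.null(idx)) NA_character_ else paste(tb$aa[idx], collapse = ""),
    character(1))
  ok <- !is.na(prot[pairs$gene_a]) & !is.na(prot[pairs$gene_b])
  est <- rep(list(na_row), nrow(pairs))
  if (any(ok)) {
    # one vectorised alignment call for the whole batch
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(prot[pairs$gene_a[ok]]),
      Biostrings::AAStringSet(prot[pairs$gene_b[ok]]),
      substitutionMatrix = scoring_matrix(substitution_matrix),
      gapOpening = gap_open, gapExtension = gap_extend, type = "global")
    # project onto pattern coordinates: columns gapped in the pattern are
    # dropped, but NG86 only uses columns ungapped on both sides anyway
    pa <- as.character(Biostrings::pattern(aln))
    pb <- as.character(Biostrings::subject(aln))
    for (w in seq_along(which(ok))) {
      i <- which(ok)[w]
      ca <- strsplit(pa[w], "")[[1]]
      cb <- strsplit(pb[w], "")[[1]]
      keep <- ca != "-" & cb != "-"
      ia <- codons[[pairs$gene_a[i]]][cumsum(ca != "-")[keep]]
      ib <- codons[[pairs$gene_b[i]]][cumsum(cb != "-")[keep]]
      if (length(ia))
        est[[i]] <- ng86_core(ia, ib, tb)[names(na_row)]
    }
  }
  cbind(pairs, do.call(rbind, lapply(est, as.data.frame)))
}
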