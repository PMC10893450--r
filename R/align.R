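# Codon-level pairwise alignment: global protein alignment with affine gaps,
# back-translated onto the underlying codons.

check_cds <- function(cds, gene) {
  n <- nchar(cds)
  if (n %% 3L != 0L)
    stop("CDS of '", gene, "' has length ", n, ", not a multiple of 3")
  idx <- cds_to_codons(cds)
  aa <- ng86_tables()$aa[idx]
  # a single terminal stop is tolerated and trimmed
  if (length(aa) && aa[length(aa)] == "*") {
    idx <- idx[-length(idx)]
    aa <- aa[-length(aa)]
  }
  if (any(aa == "*"))
    stop("internal stop codon in '", gene, "' at codon ",
         which(aa == "*")[1])
  idx
}

scoring_matrix <- function(name) {
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || is.null(e[[name]]))
    stop("unknown substitution matrix '", name, "'")
  e[[name]]
}

# Back-translate one side of a protein alignment onto its codons.
codon_track <- function(aln_chars, codon_idx, codons) {
  out <- rep("---", length(aln_chars))
  out[aln_chars != "-"] <- codons[codon_idx]
  out
}

#' Align two coding sequences at the codon level
#'
#' The protein translations are globally aligned with affine gap costs and
#' the alignment is mapped back onto codons, so every gap is a multiple of
#' 3 nucleotides and the codon track translates to the protein alignment.
#'
#' @param cds_a,cds_b In-frame coding sequences (character). A terminal stop
#'   codon is trimmed; an internal stop is an error naming the gene.
#' @param gene_a,gene_b Gene ids used in messages and results.
#' @param substitution_matrix Name of a protein scoring matrix shipped with
#'   Biostrings (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return An `aligned_codon_pair` with parallel codon tracks (`"---"` for a
#'   gap) and the count of ungapped codon columns.
#' @export
align_codon_pair <- function(cds_a, cds_b, gene_a = "gene_a", gene_b = "gene_b",
                             substitution_matrix = "BLOSUM62",
                             gap_open = 10, gap_extend = 0.5) {
  ia <- check_cds(cds_a, gene_a)
  ib <- check_cds(cds_b, gene_b)
  tb <- ng86_tables()
  prot_a <- paste(tb$aa[ia], collapse = "")
  prot_b <- paste(tb$aa[ib], collapse = "")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(prot_a), Biostrings::AAString(prot_b),
    substitutionMatrix = scoring_matrix(substitution_matrix),
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  codons_a <- codon_track(pa, ia, tb$codons)
  codons_b <- codon_track(pb, ib, tb$codons)
  structure(list(
    gene_a = gene_a, gene_b = gene_b,
    codons_a = codons_a, codons_b = codons_b,
    n_ungapped_codons = sum(codons_a != "---" & codons_b != "---"),
    score = Biostrings::score(aln)
  ), class = "aligned_codon_pair")
}

#' @export
print.aligned_codon_pair <- function(x, ...) {
  cat("aligned_codon_pair:", x$gene_a, "vs", x$gene_b, "-",
      length(x$codons_a), "columns,", x$n_ungapped_codons, "ungapped\n")
  invisible(x)
}
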