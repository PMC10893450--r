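# Codon bookkeeping shared by the NG86 estimator and the forward simulator.
#
# Codons are indexed 1..64 in base-4 order over A,C,G,T. Stop codons carry
# aa "*" and are excluded from site counting; single-base alternatives that
# would create a stop are dropped and the synonymous/nonsynonymous site
# fractions renormalised over the remaining alternatives.

NT <- c("A", "C", "G", "T")

.wgdinfer_env <- new.env(parent = emptyenv())

codon_strings <- function() {
  g <- expand.grid(p3 = NT, p2 = NT, p1 = NT, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

#' @importFrom Biostrings GENETIC_CODE
codon_aa_table <- function() {
  cods <- codon_strings()
  aa <- unname(Biostrings::GENETIC_CODE[cods])
  aa[is.na(aa)] <- "*"
  aa
}

# Index (1..64) of a codon string; vectorised.
codon_index <- function(codons) {
  m <- match(codons, codon_strings())
  if (anyNA(m)) stop("non-ACGT codon encountered: ",
                     paste(unique(codons[is.na(m)]), collapse = ", "))
  m
}

# Split a CDS string into codon indices.
cds_to_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length ", n, " is not a multiple of 3")
  codon_index(substring(cds, seq(1L, n, 3L), seq(3L, n, 3L)))
}

codons_to_cds <- function(idx) paste(codon_strings()[idx], collapse = "")

# Per-codon NG86 synonymous site count, stop-adjusted: at each position the
# 3 single-base alternatives are classified and alternatives creating stop
# codons are removed before taking the synonymous fraction.
build_syn_sites <- function(aa) {
  cods <- codon_strings()
  S <- rep(NA_real_, 64L)
  for (i in seq_len(64L)) {
    if (aa[i] == "*") next
    s <- 0
    for (p in 1:3) {
      alt_syn <- 0L; alt_valid <- 0L
      for (b in NT) {
        if (b == substr(cods[i], p, p)) next
        mut <- cods[i]
        substr(mut, p, p) <- b
        aam <- aa[codon_index(mut)]
        if (aam == "*") next
        alt_valid <- alt_valid + 1L
        if (aam == aa[i]) alt_syn <- alt_syn + 1L
      }
      if (alt_valid > 0L) s <- s + alt_syn / alt_valid
    }
    S[i] <- s
  }
  S
}

# Pathway-averaged synonymous/nonsynonymous difference counts for every
# ordered codon pair. Substitution orders passing through a stop codon are
# discarded; if every order does, all orders are kept as a fallback.
build_diff_tables <- function(aa) {
  cods <- codon_strings()
  SD <- matrix(NA_real_, 64L, 64L)
  ND <- matrix(NA_real_, 64L, 64L)
  perms2 <- list(c(1L, 2L), c(2L, 1L))
  perms3 <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                 c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  for (i in seq_len(64L)) {
    if (aa[i] == "*") next
    ci <- strsplit(cods[i], "")[[1]]
    for (j in seq_len(64L)) {
      if (aa[j] == "*") next
      cj <- strsplit(cods[j], "")[[1]]
      pos <- which(ci != cj)
      d <- length(pos)
      if (d == 0L) { SD[i, j] <- 0; ND[i, j] <- 0; next }
      perms <- switch(d, list(pos), lapply(perms2, function(p) pos[p]),
                      lapply(perms3, function(p) pos[p]))
      count_path <- function(order, require_no_stop) {
        cur <- ci; sd <- 0; nd <- 0
        for (p in order) {
          nxt <- cur
          nxt[p] <- cj[p]
          aan <- aa[codon_index(paste(nxt, collapse = ""))]
          if (aan == "*" && require_no_stop) return(NULL)
          aac <- aa[codon_index(paste(cur, collapse = ""))]
          if (aan == aac) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        c(sd, nd)
      }
      paths <- Filter(Negate(is.null), lapply(perms, count_path, require_no_stop = TRUE))
      if (length(paths) == 0L)
        paths <- lapply(perms, count_path, require_no_stop = FALSE)
      m <- do.call(rbind, paths)
      SD[i, j] <- mean(m[, 1]); ND[i, j] <- mean(m[, 2])
    }
  }
  list(SD = SD, ND = ND)
}

ng86_tables <- function() {
  if (!is.null(.wgdinfer_env$tables)) return(.wgdinfer_env$tables)
  aa <- codon_aa_table()
  syn <- build_syn_sites(aa)
  dt <- build_diff_tables(aa)
  .wgdinfer_env$tables <- list(
    codons = codon_strings(), aa = aa,
    syn_sites = syn, nonsyn_sites = ifelse(is.na(syn), NA_real_, 3 - syn),
    SD = dt$SD, ND = dt$ND,
    stop_idx = which(aa == "*")
  )
  .wgdinfer_env$tables
}

# Translate codon indices to an amino-acid string.
translate_codons <- function(idx) {
  aa <- codon_aa_table()[idx]
  paste(aa, collapse = "")
}
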