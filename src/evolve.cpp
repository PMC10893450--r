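#include <Rcpp.h>
using namespace Rcpp;

// Forward-evolve a codon sequence by n_attempts point-mutation attempts.
//
// Codons are indexed 1..64 in base-4 order over A,C,G,T, so position/base
// arithmetic replaces string handling. Each attempt picks a uniform
// nucleotide position and a uniform alternative base; attempts creating a
// stop codon are redrawn, synonymous changes are always accepted and
// nonsynonymous changes are accepted with probability omega. Uses R's RNG,
// so results are reproducible under set.seed().
//
// aa_code: length-64 integer amino-acid class per codon, 0 for stops.
// [[Rcpp::export]]
List evolve_codons_cpp(IntegerVector codons, int n_attempts, double omega,
                       IntegerVector aa_code) {
  IntegerVector seq = clone(codons);
  const int L = seq.size();
  int n_syn = 0, n_nonsyn = 0;
  if (L == 0 || n_attempts <= 0)
    return List::create(_["codons"] = seq, _["n_syn"] = n_syn,
                        _["n_nonsyn"] = n_nonsyn);

  for (int k = 0; k < n_attempts; ++k) {
    int mut_idx, cod_pos;
    for (;;) { // redraw until the proposed change is stop-free
      int site = (int)(unif_rand() * (3.0 * L));
      if (site >= 3 * L) site = 3 * L - 1;
      cod_pos = site / 3;
      int within = site % 3;            // 0,1,2 from 5' end of the codon
      int cod = seq[cod_pos] - 1;       // 0..63
      int shift = (within == 0) ? 16 : (within == 1 ? 4 : 1);
      int cur_base = (cod / shift) % 4;
      int alt = (int)(unif_rand() * 3.0);
      if (alt >= 3) alt = 2;
      int new_base = (alt >= cur_base) ? alt + 1 : alt; // skip current base
      mut_idx = cod - cur_base * shift + new_base * shift + 1;
      if (aa_code[mut_idx - 1] != 0) break;
    }
    int old_aa = aa_code[seq[cod_pos] - 1];
    int new_aa = aa_code[mut_idx - 1];
    if (new_aa == old_aa) {
      seq[cod_pos] = mut_idx;
      ++n_syn;
    } else if (omega >= 1.0 || unif_rand() < omega) {
      seq[cod_pos] = mut_idx;
      ++n_nonsyn;
    }
  }
  return List::create(_["codons"] = seq, _["n_syn"] = n_syn,
                      _["n_nonsyn"] = n_nonsyn);
}
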