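// Gapless seed extension for the lightweight read mapper: from an exact
// seed match, extend right then left while the running identity of the
// whole matched region stays at or above the floor.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".extend_candidates_cpp")]]
List extend_candidates_cpp(CharacterVector reads, CharacterVector refs,
                           IntegerVector seq_idx, IntegerVector ref_idx,
                           IntegerVector diag, IntegerVector pos,
                           int seed_k, double min_identity) {
  const int n = seq_idx.size();
  IntegerVector score(n), ref_start(n), ref_end(n);
  for (int i = 0; i < n; i++) {
    const char *s = CHAR(STRING_ELT(reads, seq_idx[i] - 1));
    const char *t = CHAR(STRING_ELT(refs, ref_idx[i] - 1));
    const int L = LENGTH(STRING_ELT(reads, seq_idx[i] - 1));
    const int Lt = LENGTH(STRING_ELT(refs, ref_idx[i] - 1));
    const int o = diag[i]; // ref_pos - read_pos (1-based offsets cancel)
    // overlap window on the read (1-based): [a, b]
    const int a = std::max(1, 1 - o);
    const int b = std::min(L, Lt - o);
    const int p0 = pos[i];
    const int p1 = p0 + seed_k - 1;
    int matches = seed_k, len = seed_k;
    int lo = p0, hi = p1;
    // rightwards from the seed end
    for (int p = p1 + 1; p <= b; p++) {
      int m2 = matches + (s[p - 1] == t[p + o - 1] ? 1 : 0);
      int l2 = len + 1;
      if ((double)m2 / l2 < min_identity) break;
      matches = m2;
      len = l2;
      hi = p;
    }
    // leftwards from the seed start
    for (int p = p0 - 1; p >= a; p--) {
      int m2 = matches + (s[p - 1] == t[p + o - 1] ? 1 : 0);
      int l2 = len + 1;
      if ((double)m2 / l2 < min_identity) break;
      matches = m2;
      len = l2;
      lo = p;
    }
    score[i] = matches;
    ref_start[i] = lo + o;
    ref_end[i] = hi + o;
  }
  return List::create(Named("score") = score, Named("ref_start") = ref_start,
                      Named("ref_end") = ref_end);
}
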