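#include <Rcpp.h>
using namespace Rcpp;

// Enumerate maximal TIR arm pairs in a locus.
//
// A pair (i, j, L) has left arm seq[i, i+L) and right arm seq[j, j+L)
// (0-based half-open) with the left arm equal to the reverse complement
// of the right arm up to max_mismatch mismatches.  Pairs are parametrised
// by the ray (i, e) with e = j + L: along a ray the matched position
// pairs (i+k, e-1-k) do not depend on L, so a single greedy walk yields
// the inner-maximal L for that ray.  A pair is reported iff it is
// maximal: not extendable inward (left arm end / right arm start move
// toward each other; impossible after the greedy walk) nor outward
// (adding the position pair (i-1, e)) within the mismatch budget and the
// max_len cap.  Arms must stay strictly disjoint (left arm end < right
// arm start allowed to be adjacent, never overlapping or crossing).
// Search windows restrict which maximal pairs are *reported* (arm starts
// must fall inside them) but do not redefine maximality.
//
// seq: integer codes 0=A,1=C,2=G,3=T, negative = non-ACGT (never matches).
// left_lo..left_hi / right_lo..right_hi: inclusive 0-based ranges for the
// left / right arm start positions.
// [[Rcpp::export(name = ".tir_scan_cpp")]]
IntegerMatrix tir_scan_cpp(IntegerVector seq,
                           int left_lo, int left_hi,
                           int right_lo, int right_hi,
                           int min_len, int max_len, int max_mismatch) {
  int n = seq.size();
  std::vector<int> out_i, out_j, out_L, out_mm;
  auto comp_match = [&](int a, int b) {
    return a >= 0 && b >= 0 && a + b == 3;  // A<->T, C<->G
  };
  if (left_lo < 0) left_lo = 0;
  if (left_hi > n - 1) left_hi = n - 1;
  for (int i = left_lo; i <= left_hi; ++i) {
    int e_lo = right_lo + min_len, e_hi = right_hi + max_len;
    if (e_hi > n) e_hi = n;
    if (e_lo < i + 2) e_lo = i + 2;
    for (int e = e_lo; e <= e_hi; ++e) {
      int mm = 0, L = 0;
      int kmax = (e - 2 - i) / 2;           // largest k with i+k < e-1-k
      bool budget_stop = false;
      while (L <= kmax && L < max_len) {
        if (!comp_match(seq[i + L], seq[e - 1 - L])) {
          if (mm + 1 > max_mismatch) { budget_stop = true; break; }
          ++mm;
        }
        ++L;
      }
      (void)budget_stop;
      if (L < min_len) continue;
      int j = e - L;
      if (j < right_lo || j > right_hi) continue;
      // outer extension: pair (i-1, j, L+1) adds positions (i-1, e)
      if (i - 1 >= 0 && e <= n - 1 && L + 1 <= max_len) {
        if (comp_match(seq[i - 1], seq[e]) || mm + 1 <= max_mismatch)
          continue;  // extendable outward -> not maximal
      }
      out_i.push_back(i);
      out_j.push_back(j);
      out_L.push_back(L);
      out_mm.push_back(mm);
    }
  }
  IntegerMatrix res(out_i.size(), 4);
  for (size_t r = 0; r < out_i.size(); ++r) {
    res(r, 0) = out_i[r];
    res(r, 1) = out_j[r];
    res(r, 2) = out_L[r];
    res(r, 3) = out_mm[r];
  }
  colnames(res) = CharacterVector::create("i", "j", "L", "mm");
  return res;
}
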