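#include <Rcpp.h>
using namespace Rcpp;

// All-vs-all fixed-length Hamming scan between two encoded sequences.
//
// a, b: integer-encoded sequences (A=0, C=1, G=2, T=3; any negative code
// is an ambiguity). A query window containing an ambiguous base is
// unmatchable and skipped; an ambiguous target base counts as a mismatch
// at its position. Early exit once the running mismatch count exceeds
// max_mm keeps the scan fast on random sequence.
//
// Returns parallel integer vectors a_off / b_off (0-based window starts)
// and mm (Hamming distance <= max_mm).
// [[Rcpp::export(name = ".scan_hamming_pairs")]]
List scan_hamming_pairs(IntegerVector a, IntegerVector b, int k, int max_mm) {
  const int la = a.size(), lb = b.size();
  std::vector<int> a_off, b_off, mm_out;
  if (k < 1 || la < k || lb < k)
    return List::create(_["a_off"] = IntegerVector(0),
                        _["b_off"] = IntegerVector(0),
                        _["mm"] = IntegerVector(0));

  // prefix counts of ambiguous bases in the query for O(1) window checks
  std::vector<int> amb(la + 1, 0);
  for (int i = 0; i < la; ++i) amb[i + 1] = amb[i] + (a[i] < 0 ? 1 : 0);

  for (int i = 0; i + k <= la; ++i) {
    if (amb[i + k] - amb[i] > 0) continue;  // unmatchable k-mer
    for (int j = 0; j + k <= lb; ++j) {
      int mm = 0;
      for (int l = 0; l < k; ++l) {
        if (a[i + l] != b[j + l]) {
          if (++mm > max_mm) break;
        }
      }
      if (mm <= max_mm) {
        a_off.push_back(i);
        b_off.push_back(j);
        mm_out.push_back(mm);
      }
    }
  }
  return List::create(_["a_off"] = wrap(a_off),
                      _["b_off"] = wrap(b_off),
                      _["mm"] = wrap(mm_out));
}
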