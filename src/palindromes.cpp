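#include <Rcpp.h>
using namespace Rcpp;

// Watson-Crick complement test; N and ambiguity codes never pair.
static inline bool pairs(char a, char b) {
  switch (a) {
  case 'A': return b == 'T';
  case 'T': return b == 'A';
  case 'C': return b == 'G';
  case 'G': return b == 'C';
  default: return false;
  }
}

// Scan every (center, loop) placement of a linear sequence for the longest
// approximate inverted repeat.  Arms are extended symmetrically; at arm
// length k the mismatch budget is ceil(k * rate); the reported arm is the
// largest k ending on a matching pair that respects the budget.  Semantics
// mirror the plain-R brute-force oracle used in the tests.
// [[Rcpp::export(name = ".scan_palindromes_cpp")]]
DataFrame scan_palindromes_cpp(std::string s, int min_arm, int max_loop,
                               double rate, int max_arm) {
  const int n = (int) s.size();
  std::vector<int> v_start, v_end, v_arm, v_loop, v_mm;
  for (int i = 0; i < n - 1; ++i) {          // i = last left-arm index (0-based)
    for (int l = 0; l <= max_loop; ++l) {
      int j0 = i + l + 1;                    // first right-arm index
      if (j0 >= n) break;
      int kmax = std::min(std::min(i + 1, n - j0), max_arm);
      if (kmax < min_arm) continue;
      int budget_max = (int) std::ceil(kmax * rate);
      int m = 0, best_k = 0, best_m = 0;
      for (int k = 1; k <= kmax; ++k) {
        bool ok = pairs(s[i - k + 1], s[j0 + k - 1]);
        if (!ok) ++m;
        if (m > budget_max) break;           // cannot recover: budget is final
        if (ok && m <= (int) std::ceil(k * rate)) {
          best_k = k; best_m = m;
        }
      }
      if (best_k >= min_arm) {
        v_start.push_back(i - best_k + 2);   // 1-based
        v_end.push_back(j0 + best_k);        // 1-based inclusive
        v_arm.push_back(best_k);
        v_loop.push_back(l);
        v_mm.push_back(best_m);
      }
    }
  }
  return DataFrame::create(_["start"] = v_start, _["end"] = v_end,
                           _["arm"] = v_arm, _["loop"] = v_loop,
                           _["mismatches"] = v_mm);
}
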