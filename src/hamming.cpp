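#include <Rcpp.h>
using namespace Rcpp;

// Hamming scan of a pattern over an integer-encoded sequence.
// Returns 0-based match starts with <= max_mm mismatches and their
// mismatch counts. Early-exits a position once max_mm is exceeded, so a
// random background position costs only a handful of comparisons.
// [[Rcpp::export(name = ".hamming_scan")]]
List hamming_scan(IntegerVector enc, IntegerVector pat, int max_mm) {
  const int L = pat.size();
  const int n = enc.size() - L + 1;
  std::vector<int> starts, mms;
  for (int i = 0; i < n; ++i) {
    int mm = 0;
    for (int k = 0; k < L; ++k) {
      if (enc[i + k] != pat[k]) {
        if (++mm > max_mm) break;
      }
    }
    if (mm <= max_mm) {
      starts.push_back(i);
      mms.push_back(mm);
    }
  }
  return List::create(_["start"] = wrap(starts), _["mm"] = wrap(mms));
}
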