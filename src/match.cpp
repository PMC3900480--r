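#include <Rcpp.h>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Minimum Hamming distance of the shorter sequence slid ungapped along the
// longer one (no overhangs).  Used for mismatch-tolerant assignment of reads
// to reference mature miRNAs.
static int slide_hamming(const std::string& a, const std::string& b) {
  const std::string& s = (a.size() <= b.size()) ? a : b;
  const std::string& l = (a.size() <= b.size()) ? b : a;
  int ns = (int)s.size(), nl = (int)l.size();
  int best = ns + 1;
  for (int off = 0; off + ns <= nl; ++off) {
    int mm = 0;
    for (int k = 0; k < ns && mm < best; ++k)
      if (s[k] != l[off + k]) ++mm;
    best = std::min(best, mm);
  }
  return best;
}

// For each read, the reference with the fewest mismatches (full length of the
// shorter sequence, ungapped).  Ties go to the earlier reference, so callers
// fix tie-breaking by pre-sorting references.  Returns 1-based ref index and
// mismatch count; index 0 when nothing is within max_mismatch.
// [[Rcpp::export]]
List best_hamming_match_cpp(CharacterVector reads, CharacterVector refs,
                            int max_mismatch) {
  int nr = reads.size(), nf = refs.size();
  std::vector<std::string> rf(nf);
  for (int j = 0; j < nf; ++j) rf[j] = as<std::string>(refs[j]);
  IntegerVector idx(nr), mm(nr);
  for (int i = 0; i < nr; ++i) {
    std::string rd = as<std::string>(reads[i]);
    int best = max_mismatch + 1, bj = 0;
    for (int j = 0; j < nf; ++j) {
      int d = slide_hamming(rd, rf[j]);
      if (d < best) { best = d; bj = j + 1; }
    }
    idx[i] = bj;
    mm[i] = (bj > 0) ? best : NA_INTEGER;
  }
  return List::create(_["ref"] = idx, _["mismatches"] = mm);
}
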