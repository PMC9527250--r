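#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Semiglobal alignment: the read is aligned end-to-end (global in the
// read) against a local region of the reference (free gaps at both
// reference ends). Linear gap penalty. Traceback prefers diagonal over
// read-insertion over read-deletion so that tied optima resolve
// deterministically.
//
// Returns score, per-column tallies and `ref_aligned`: for each read
// position the reference base aligned to it, or '-' where the read base
// is an insertion relative to the reference. Reference bases deleted from
// the read do not appear in `ref_aligned` but are counted as gap columns.

// [[Rcpp::export]]
List semiglobal_align_cpp(std::string read, std::string ref,
                          int match, int mismatch, int gap) {
  const int m = read.size(), n = ref.size();
  const int NEG = -1000000000;
  std::vector<int> S((m + 1) * (n + 1), NEG);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  for (int j = 0; j <= n; ++j) S[at(0, j)] = 0;      // free ref prefix
  for (int i = 1; i <= m; ++i) S[at(i, 0)] = i * gap;

  for (int i = 1; i <= m; ++i) {
    const char rc = read[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int sub = (rc == ref[j - 1]) ? match : mismatch;
      int best = S[at(i - 1, j - 1)] + sub;
      const int up = S[at(i - 1, j)] + gap;
      if (up > best) best = up;
      const int left = S[at(i, j - 1)] + gap;
      if (left > best) best = left;
      S[at(i, j)] = best;
    }
  }

  int best_j = 0, best_score = S[at(m, 0)];
  for (int j = 1; j <= n; ++j) {
    if (S[at(m, j)] > best_score) { best_score = S[at(m, j)]; best_j = j; }
  }

  // traceback
  std::string ref_aligned(m, '-');
  int matches = 0, mismatches = 0, gaps = 0, columns = 0;
  int i = m, j = best_j;
  int ref_end = best_j, ref_start = best_j + 1;
  while (i > 0) {
    const int cur = S[at(i, j)];
    if (j > 0 &&
        cur == S[at(i - 1, j - 1)] + ((read[i - 1] == ref[j - 1]) ? match : mismatch)) {
      ref_aligned[i - 1] = ref[j - 1];
      if (read[i - 1] == ref[j - 1]) ++matches; else ++mismatches;
      ++columns; ref_start = j; --i; --j;
    } else if (cur == S[at(i - 1, j)] + gap) {
      ++gaps; ++columns; --i;            // read base against ref gap
    } else {
      ++gaps; ++columns; ref_start = j; --j;  // ref base against read gap
    }
  }

  return List::create(
    _["score"] = best_score, _["matches"] = matches,
    _["mismatches"] = mismatches, _["gaps"] = gaps,
    _["columns"] = columns, _["ref_aligned"] = ref_aligned,
    _["ref_start"] = ref_start, _["ref_end"] = ref_end);
}
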