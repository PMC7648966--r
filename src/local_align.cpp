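#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps.
// A gap of length g costs open + g * extend (both penalties passed as
// positive numbers), i.e. the first gap base costs open + extend.
// Returns score and traceback statistics of one optimal alignment
// (ties broken toward the diagonal, then toward gaps in the subject).
// [[Rcpp::export(name = ".sw_align")]]
IntegerVector sw_align(std::string q, std::string s, int match = 1,
                       int mismatch = -2, int gap_open = 5,
                       int gap_extend = 2) {
  const int m = q.size(), n = s.size();
  const int NEG = -1000000000;
  std::vector<int> H((m + 1) * (n + 1), 0);
  std::vector<int> E((m + 1) * (n + 1), NEG);  // gap in query (subject consumed)
  std::vector<int> F((m + 1) * (n + 1), NEG);  // gap in subject (query consumed)
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int e = std::max(H[at(i, j - 1)] - gap_open - gap_extend,
                       E[at(i, j - 1)] - gap_extend);
      int f = std::max(H[at(i - 1, j)] - gap_open - gap_extend,
                       F[at(i - 1, j)] - gap_extend);
      int sub = (q[i - 1] == s[j - 1]) ? match : mismatch;
      int d = H[at(i - 1, j - 1)] + sub;
      int h = d;
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      E[at(i, j)] = e;
      F[at(i, j)] = f;
      H[at(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // traceback from (bi, bj) in state H until a zero cell
  int i = bi, j = bj, matches = 0, columns = 0, qlo = bi, qhi = bi, slo = bj,
      shi = bj;
  char state = 'H';
  while (i > 0 && j > 0) {
    if (state == 'H') {
      int h = H[at(i, j)];
      if (h == 0) break;
      int sub = (q[i - 1] == s[j - 1]) ? match : mismatch;
      if (h == H[at(i - 1, j - 1)] + sub) {
        if (q[i - 1] == s[j - 1]) ++matches;
        ++columns;
        --i; --j;
      } else if (h == F[at(i, j)]) {
        state = 'F';
      } else {
        state = 'E';
      }
    } else if (state == 'F') {
      ++columns;
      if (F[at(i, j)] == F[at(i - 1, j)] - gap_extend) { --i; }
      else { --i; state = 'H'; }
    } else {  // E
      ++columns;
      if (E[at(i, j)] == E[at(i, j - 1)] - gap_extend) { --j; }
      else { --j; state = 'H'; }
    }
    if (state == 'H' && H[at(i, j)] == 0) break;
  }
  qlo = i + 1; slo = j + 1;

  return IntegerVector::create(_["score"] = best, _["matches"] = matches,
                               _["columns"] = columns,
                               _["q_start"] = (best > 0) ? qlo : 0,
                               _["q_end"] = (best > 0) ? qhi : 0,
                               _["s_start"] = (best > 0) ? slo : 0,
                               _["s_end"] = (best > 0) ? shi : 0);
}
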