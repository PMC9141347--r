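#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with linear gap penalty and a fully
// deterministic tie-break: among all maximal-scoring alignments, prefer the
// one with the earliest query start, then earliest subject start, then the
// fewest gaps. Traceback prefers diagonal moves (fewest gaps) and stops at
// the first zero cell.

struct TraceResult {
  int q_start, s_start, q_end, s_end;
  int matches, columns, gaps;
};

static TraceResult traceback(const std::string &a, const std::string &b,
                             const std::vector<int> &H, int n, int m,
                             int ei, int ej, int match, int mismatch, int gap) {
  int i = ei, j = ej;
  TraceResult r;
  r.q_end = ei; r.s_end = ej;
  r.matches = 0; r.columns = 0; r.gaps = 0;
  while (i > 0 && j > 0 && H[i * (m + 1) + j] > 0) {
    int h = H[i * (m + 1) + j];
    int sub = (a[i - 1] == b[j - 1]) ? match : mismatch;
    if (H[(i - 1) * (m + 1) + (j - 1)] + sub == h) {
      if (a[i - 1] == b[j - 1]) r.matches++;
      r.columns++; i--; j--;
    } else if (i > 0 && H[(i - 1) * (m + 1) + j] + gap == h) {
      r.columns++; r.gaps++; i--;
    } else {
      r.columns++; r.gaps++; j--;
    }
  }
  // trailing zero cells: trim columns consumed past score 0 (loop stops at 0)
  r.q_start = i; r.s_start = j;
  return r;
}

// [[Rcpp::export(name = ".local_align_cpp")]]
List local_align_cpp(std::string a, std::string b,
                     int match = 2, int mismatch = -1, int gap = -2) {
  const int n = a.size(), m = b.size();
  std::vector<int> H((n + 1) * (m + 1), 0);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int sub = (a[i - 1] == b[j - 1]) ? match : mismatch;
      int h = H[(i - 1) * (m + 1) + (j - 1)] + sub;
      int up = H[(i - 1) * (m + 1) + j] + gap;
      int left = H[i * (m + 1) + (j - 1)] + gap;
      if (up > h) h = up;
      if (left > h) h = left;
      if (h < 0) h = 0;
      H[i * (m + 1) + j] = h;
      if (h > best) best = h;
    }
  }
  if (best == 0) {
    return List::create(_["score"] = 0, _["matches"] = 0,
                        _["aligned_columns"] = 0, _["gaps"] = 0,
                        _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0);
  }
  bool have = false;
  TraceResult bestTr;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (H[i * (m + 1) + j] != best) continue;
      TraceResult tr = traceback(a, b, H, n, m, i, j, match, mismatch, gap);
      if (!have ||
          std::tie(tr.q_start, tr.s_start, tr.gaps, tr.q_end, tr.s_end) <
          std::tie(bestTr.q_start, bestTr.s_start, bestTr.gaps,
                   bestTr.q_end, bestTr.s_end)) {
        bestTr = tr; have = true;
      }
    }
  }
  return List::create(_["score"] = best, _["matches"] = bestTr.matches,
                      _["aligned_columns"] = bestTr.columns,
                      _["gaps"] = bestTr.gaps,
                      _["q_start"] = bestTr.q_start, _["q_end"] = bestTr.q_end,
                      _["s_start"] = bestTr.s_start, _["s_end"] = bestTr.s_end);
}
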