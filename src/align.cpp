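#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap alignment kernels over integer-encoded protein sequences
// (0-based state indices into the scoring matrix).  A gap of length k costs
// gap_open + k * gap_extend, the convention used by protein BLAST.

// Optimal Smith-Waterman local alignment score (score only, linear space).
// [[Rcpp::export]]
int sw_score_int(IntegerVector a, IntegerVector b, IntegerMatrix s,
                 int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0;
  const int NEG = -1000000000;
  const int go = -(gap_open + gap_extend);  // open + first extension
  const int ge = -gap_extend;
  std::vector<int> Mrow(m + 1, 0), Drow(m + 1, NEG), Irow(m + 1, NEG);
  std::vector<int> Mprev(m + 1, 0), Dprev(m + 1, NEG), Iprev(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    Mrow[0] = 0; Drow[0] = NEG; Irow[0] = NEG;
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      int d = std::max(Dprev[j] + ge, std::max(Mprev[j] + go, Iprev[j] + go));
      int ins = std::max(Irow[j - 1] + ge,
                         std::max(Mrow[j - 1] + go, Drow[j - 1] + go));
      int prev = std::max(Mprev[j - 1], std::max(Dprev[j - 1], Iprev[j - 1]));
      if (prev < 0) prev = 0;             // a local alignment may start anywhere
      int mm = prev + s(ai, b[j - 1]);
      if (mm < 0) mm = 0;
      Mrow[j] = mm; Drow[j] = d; Irow[j] = ins;
      if (mm > best) best = mm;
    }
    std::swap(Mrow, Mprev); std::swap(Drow, Dprev); std::swap(Irow, Iprev);
  }
  return best;
}

// [[Rcpp::export]]
IntegerVector sw_score_many(IntegerVector query, List subjects, IntegerMatrix s,
                            int gap_open, int gap_extend) {
  const int k = subjects.size();
  IntegerVector out(k);
  for (int t = 0; t < k; ++t) {
    IntegerVector b = subjects[t];
    out[t] = sw_score_int(query, b, s, gap_open, gap_extend);
  }
  return out;
}

// Global (Needleman-Wunsch) alignment with affine gaps, terminal gaps
// penalized, full traceback.  Returns the optimal score and the edit path
// as moves: 0 = diagonal (consume both), 1 = gap in a (consume b),
// 2 = gap in b (consume a).  Traceback ties prefer diagonal, then gap-in-a,
// then gap-in-b, so the reported alignment is deterministic.
// [[Rcpp::export]]
List nw_align_int(IntegerVector a, IntegerVector b, IntegerMatrix s,
                  int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  const int NEG = -1000000000;
  const int go = -(gap_open + gap_extend);
  const int ge = -gap_extend;
  std::vector<std::vector<int> > M(n + 1, std::vector<int>(m + 1, NEG));
  std::vector<std::vector<int> > D(n + 1, std::vector<int>(m + 1, NEG));
  std::vector<std::vector<int> > I(n + 1, std::vector<int>(m + 1, NEG));
  M[0][0] = 0;
  for (int i = 1; i <= n; ++i) D[i][0] = go + ge * (i - 1);
  for (int j = 1; j <= m; ++j) I[0][j] = go + ge * (j - 1);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int prev = std::max(M[i - 1][j - 1],
                          std::max(D[i - 1][j - 1], I[i - 1][j - 1]));
      if (prev > NEG / 2) M[i][j] = prev + s(a[i - 1], b[j - 1]);
      D[i][j] = std::max(M[i - 1][j] + go,
                         std::max(D[i - 1][j] + ge, I[i - 1][j] + go));
      I[i][j] = std::max(M[i][j - 1] + go,
                         std::max(I[i][j - 1] + ge, D[i][j - 1] + go));
    }
  }
  int score = std::max(M[n][m], std::max(D[n][m], I[n][m]));
  // traceback states: 0 = M (diagonal), 1 = I (gap in a), 2 = D (gap in b);
  // preference order 0 > 1 > 2 applied wherever scores tie.
  std::vector<int> path;
  int i = n, j = m, state;
  if (M[n][m] == score) state = 0;
  else if (I[n][m] == score) state = 1;
  else state = 2;
  while (i > 0 || j > 0) {
    if (state == 0) {
      path.push_back(0);
      int prev = M[i][j] - s(a[i - 1], b[j - 1]);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M[i][j] == prev) state = 0;
      else if (I[i][j] == prev) state = 1;
      else state = 2;
    } else if (state == 1) {
      path.push_back(1);
      int cur = I[i][j];
      --j;
      if (M[i][j] + go == cur) state = 0;
      else if (I[i][j] + ge == cur) state = 1;
      else state = 2;
    } else {
      path.push_back(2);
      int cur = D[i][j];
      --i;
      if (M[i][j] + go == cur) state = 0;
      else if (D[i][j] + ge == cur) state = 2;
      else state = 1;
    }
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["score"] = score, _["path"] = wrap(path));
}
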