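#include <Rcpp.h>
using namespace Rcpp;

// Three-state affine-gap global alignment (Gotoh) over a precomputed
// cell-score matrix S (n x m): S(i-1, j-1) is the score for aligning
// position i of A with position j of B.  Works for single sequences and
// for profiles alike, since the caller supplies the match scores.
//
// Conventions (fixed so results are reproducible across platforms):
//   * a gap of length k costs open + k * extend (open, extend <= 0);
//   * terminal gaps are penalized exactly like internal ones;
//   * traceback ties prefer M (match/mismatch) over D (gap in B,
//     consuming A) over I (gap in A, consuming B), both when choosing
//     the final state and at every predecessor choice.
//
// Returns the optimal score plus two 1-based index vectors giving, for
// each alignment column, the consumed position of A and of B (0 = gap).

static const double NEG_INF = -1e300;

// [[Rcpp::export(name = ".affine_dp")]]
List affine_dp(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  if (n < 1 || m < 1) stop("empty score matrix");

  NumericMatrix M(n + 1, m + 1), D(n + 1, m + 1), I(n + 1, m + 1);
  // traceback: which predecessor state fed each cell (0=M, 1=D, 2=I)
  IntegerMatrix tM(n + 1, m + 1), tD(n + 1, m + 1), tI(n + 1, m + 1);

  M(0, 0) = 0.0;
  D(0, 0) = NEG_INF;
  I(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF;
    I(i, 0) = NEG_INF;
    D(i, 0) = gap_open + i * gap_extend;
    tD(i, 0) = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF;
    D(0, j) = NEG_INF;
    I(0, j) = gap_open + j * gap_extend;
    tI(0, j) = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: consume one of each
      double bm = M(i - 1, j - 1); int sm = 0;
      if (D(i - 1, j - 1) > bm) { bm = D(i - 1, j - 1); sm = 1; }
      if (I(i - 1, j - 1) > bm) { bm = I(i - 1, j - 1); sm = 2; }
      M(i, j) = bm + S(i - 1, j - 1);
      tM(i, j) = sm;
      // D: consume A only (gap in B)
      double bd = M(i - 1, j) + gap_open + gap_extend; int sd = 0;
      if (D(i - 1, j) + gap_extend > bd) { bd = D(i - 1, j) + gap_extend; sd = 1; }
      if (I(i - 1, j) + gap_open + gap_extend > bd) {
        bd = I(i - 1, j) + gap_open + gap_extend; sd = 2;
      }
      D(i, j) = bd;
      tD(i, j) = sd;
      // I: consume B only (gap in A)
      double bi = M(i, j - 1) + gap_open + gap_extend; int si = 0;
      if (D(i, j - 1) + gap_open + gap_extend > bi) {
        bi = D(i, j - 1) + gap_open + gap_extend; si = 1;
      }
      if (I(i, j - 1) + gap_extend > bi) { bi = I(i, j - 1) + gap_extend; si = 2; }
      I(i, j) = bi;
      tI(i, j) = si;
    }
  }

  int state = 0;
  double best = M(n, m);
  if (D(n, m) > best) { best = D(n, m); state = 1; }
  if (I(n, m) > best) { best = I(n, m); state = 2; }

  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ai.push_back(i); bi.push_back(j);
      state = tM(i, j); --i; --j;
    } else if (state == 1) {
      ai.push_back(i); bi.push_back(0);
      state = tD(i, j); --i;
    } else {
      ai.push_back(0); bi.push_back(j);
      state = tI(i, j); --j;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());

  return List::create(_["score"] = best,
                      _["a_index"] = wrap(ai),
                      _["b_index"] = wrap(bi));
}
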