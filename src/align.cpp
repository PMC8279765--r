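#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Smith-Waterman local alignment, affine gaps.
// a, b: 1-based residue indices into the substitution matrix S.
// A gap of length g costs gap_open + (g - 1) * gap_ext.
// Returns the best local score (0 if nothing scores positive).
// [[Rcpp::export]]
double sw_score_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                    double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e300;
  std::vector<double> M_prev(m + 1, NEG), X_prev(m + 1, NEG);
  std::vector<double> M_cur(m + 1, NEG), X_cur(m + 1, NEG);
  std::vector<double> Y(m + 1, NEG); // gap in a, current row
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    std::fill(Y.begin(), Y.end(), NEG);
    M_cur[0] = NEG; X_cur[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      double h_diag = std::max(0.0, std::max(M_prev[j - 1],
                       std::max(X_prev[j - 1], Y[j - 1])));
      M_cur[j] = S(a[i - 1] - 1, b[j - 1] - 1) + h_diag;
      X_cur[j] = std::max(M_prev[j] - gap_open, X_prev[j] - gap_ext);
      Y[j] = std::max(M_cur[j - 1] - gap_open, Y[j - 1] - gap_ext);
      if (M_cur[j] > best) best = M_cur[j];
    }
    std::swap(M_prev, M_cur);
    std::swap(X_prev, X_cur);
  }
  return best;
}

// Global / semi-global alignment of two profiles with affine gaps.
// S: precomputed column-pair scores (n x m). free_ends = TRUE leaves
// terminal gaps unpenalised (appropriate for progressive MSA merging).
// Returns 0-based column paths; 0 marks a gap.
// [[Rcpp::export]]
List nw_profile_cpp(NumericMatrix S, double gap_open, double gap_ext,
                    bool free_ends) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e300;
  const size_t W = (size_t)(m + 1);
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
                      Y((n + 1) * W, NEG);
  // traceback: predecessor state (0=M,1=X,2=Y)
  std::vector<signed char> tM((n + 1) * W, -1), tX((n + 1) * W, -1),
                           tY((n + 1) * W, -1);
  auto at = [W](int i, int j) { return (size_t)i * W + (size_t)j; };
  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = free_ends ? 0.0 : -(gap_open + (i - 1) * gap_ext);
    tX[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = free_ends ? 0.0 : -(gap_open + (j - 1) * gap_ext);
    tY[at(0, j)] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double m0 = M[at(i - 1, j - 1)], m1 = X[at(i - 1, j - 1)],
             m2 = Y[at(i - 1, j - 1)];
      int bi = 0; double bv = m0;
      if (m1 > bv) { bv = m1; bi = 1; }
      if (m2 > bv) { bv = m2; bi = 2; }
      M[at(i, j)] = S(i - 1, j - 1) + bv;
      tM[at(i, j)] = (signed char)bi;
      double xo = M[at(i - 1, j)] - gap_open, xe = X[at(i - 1, j)] - gap_ext;
      if (xo >= xe) { X[at(i, j)] = xo; tX[at(i, j)] = 0; }
      else          { X[at(i, j)] = xe; tX[at(i, j)] = 1; }
      double yo = M[at(i, j - 1)] - gap_open, ye = Y[at(i, j - 1)] - gap_ext;
      if (yo >= ye) { Y[at(i, j)] = yo; tY[at(i, j)] = 0; }
      else          { Y[at(i, j)] = ye; tY[at(i, j)] = 2; }
    }
  }
  int ei = n, ej = m, es = 0;
  double bestv = M[at(n, m)];
  if (X[at(n, m)] > bestv) { bestv = X[at(n, m)]; es = 1; }
  if (Y[at(n, m)] > bestv) { bestv = Y[at(n, m)]; es = 2; }
  if (free_ends) {
    for (int i = 0; i <= n; ++i)
      for (int s = 0; s < 3; ++s) {
        double v = (s == 0 ? M : (s == 1 ? X : Y))[at(i, m)];
        if (v > bestv) { bestv = v; ei = i; ej = m; es = s; }
      }
    for (int j = 0; j <= m; ++j)
      for (int s = 0; s < 3; ++s) {
        double v = (s == 0 ? M : (s == 1 ? X : Y))[at(n, j)];
        if (v > bestv) { bestv = v; ei = n; ej = j; es = s; }
      }
  }
  std::vector<int> pa, pb;
  for (int i = n; i > ei; --i) { pa.push_back(i); pb.push_back(0); }
  for (int j = m; j > ej; --j) { pa.push_back(0); pb.push_back(j); }
  int i = ei, j = ej, s = es;
  while (i > 0 || j > 0) {
    if (s == 0) {
      signed char p = tM[at(i, j)];
      pa.push_back(i); pb.push_back(j);
      --i; --j; s = p;
    } else if (s == 1) {
      signed char p = tX[at(i, j)];
      pa.push_back(i); pb.push_back(0);
      --i; s = p;
    } else {
      signed char p = tY[at(i, j)];
      pa.push_back(0); pb.push_back(j);
      --j; s = p;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = bestv,
                      _["a"] = IntegerVector(pa.begin(), pa.end()),
                      _["b"] = IntegerVector(pb.begin(), pb.end()));
}
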