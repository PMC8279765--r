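#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// log2(2^a + 2^b), safe for -inf
static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double hi = std::max(a, b), lo = std::min(a, b);
  return hi + std::log1p(std::exp2(lo - hi)) / M_LN2;
}

// Local (uniform entry/exit over match states) profile-HMM Viterbi + forward.
//
// lem : K x 20 match log2-odds emissions (log2(e/bg)); residue index 0 = X
//       scores 0 (background).
// lei : K x 20 insert log2-odds (rows 1..K-1 used; row K ignored).
// ltr : (K-1) x 7 log2 transitions, columns MM, MI, MD, IM, II, DM, DD.
// x   : residue indices, 0..20 (0 = ambiguous X).
//
// Paths enter at any match state (log2 1/K) and exit from any match state
// (log2 1/K); residues outside the aligned span score 0 in log-odds.
// Deletes are interior only. Returns viterbi bits, forward bits and the
// Viterbi path as a matrix with columns (state 1=M/2=I/3=D, node, seqpos).
// [[Rcpp::export]]
List hmm_score_cpp(NumericMatrix lem, NumericMatrix lei, NumericMatrix ltr,
                   IntegerVector x) {
  const int K = lem.nrow(), L = x.size();
  const double NEG = R_NegInf;
  const double lK = -std::log2((double)K);
  auto emM = [&](int k, int i) { // k,i 1-based
    int r = x[i - 1];
    return r == 0 ? 0.0 : lem(k - 1, r - 1);
  };
  auto emI = [&](int k, int i) {
    int r = x[i - 1];
    return r == 0 ? 0.0 : lei(k - 1, r - 1);
  };
  // Viterbi with traceback
  std::vector<double> vm((size_t)K * L, NEG), vi((size_t)K * L, NEG),
                      vd((size_t)K * L, NEG);
  // predecessor code: 0 entry, 1 from M, 2 from I, 3 from D
  std::vector<signed char> pm((size_t)K * L, -1), pi_((size_t)K * L, -1),
                           pd((size_t)K * L, -1);
  auto at = [L](int k, int i) { return (size_t)(k - 1) * L + (i - 1); };
  // forward
  std::vector<double> fm((size_t)K * L, NEG), fi((size_t)K * L, NEG),
                      fd((size_t)K * L, NEG);
  double vbest = NEG; int vbk = -1, vbi = -1;
  double fsum = NEG;
  for (int i = 1; i <= L; ++i) {
    for (int k = 1; k <= K; ++k) {
      // M_k emits x_i
      double cand = lK; signed char who = 0; // fresh entry
      double facc = lK;
      if (k > 1 && i > 1) {
        double a = vm[at(k - 1, i - 1)] + ltr(k - 2, 0);
        if (a > cand) { cand = a; who = 1; }
        double b = vi[at(k - 1, i - 1)] + ltr(k - 2, 3);
        if (b > cand) { cand = b; who = 2; }
        double c = vd[at(k - 1, i - 1)] + ltr(k - 2, 5);
        if (c > cand) { cand = c; who = 3; }
        facc = lse2(facc, fm[at(k - 1, i - 1)] + ltr(k - 2, 0));
        facc = lse2(facc, fi[at(k - 1, i - 1)] + ltr(k - 2, 3));
        facc = lse2(facc, fd[at(k - 1, i - 1)] + ltr(k - 2, 5));
      }
      double e = emM(k, i);
      vm[at(k, i)] = e + cand; pm[at(k, i)] = who;
      fm[at(k, i)] = e + facc;
      double vexit = vm[at(k, i)] + lK;
      if (vexit > vbest) { vbest = vexit; vbk = k; vbi = i; }
      fsum = lse2(fsum, fm[at(k, i)] + lK);
      // I_k emits x_i (k < K, i > 1)
      if (k < K && i > 1) {
        double a = vm[at(k, i - 1)] + ltr(k - 1, 1);
        double b = vi[at(k, i - 1)] + ltr(k - 1, 4);
        double ei_ = emI(k, i);
        if (a >= b) { vi[at(k, i)] = ei_ + a; pi_[at(k, i)] = 1; }
        else        { vi[at(k, i)] = ei_ + b; pi_[at(k, i)] = 2; }
        fi[at(k, i)] = ei_ + lse2(fm[at(k, i - 1)] + ltr(k - 1, 1),
                                  fi[at(k, i - 1)] + ltr(k - 1, 4));
      }
      // D_k silent (k > 1): same i
      if (k > 1) {
        double a = vm[at(k - 1, i)] + ltr(k - 2, 2);
        double b = vd[at(k - 1, i)] + ltr(k - 2, 6);
        if (a >= b) { vd[at(k, i)] = a; pd[at(k, i)] = 1; }
        else        { vd[at(k, i)] = b; pd[at(k, i)] = 3; }
        fd[at(k, i)] = lse2(fm[at(k - 1, i)] + ltr(k - 2, 2),
                            fd[at(k - 1, i)] + ltr(k - 2, 6));
      }
    }
  }
  // Viterbi traceback
  std::vector<int> ps, pk, pp;
  if (vbk > 0) {
    int st = 1, k = vbk, i = vbi; // 1=M,2=I,3=D
    while (true) {
      ps.push_back(st); pk.push_back(k); pp.push_back(st == 3 ? 0 : i);
      signed char who;
      if (st == 1)      who = pm[at(k, i)];
      else if (st == 2) who = pi_[at(k, i)];
      else              who = pd[at(k, i)];
      if (st == 1) {
        if (who == 0) break;
        if (who == 2) { st = 2; --k; --i; }
        else if (who == 3) { st = 3; --k; --i; }
        else { st = 1; --k; --i; }
      } else if (st == 2) {
        st = (who == 1) ? 1 : 2; --i;
      } else {
        st = (who == 1) ? 1 : 3; --k;
      }
    }
    std::reverse(ps.begin(), ps.end());
    std::reverse(pk.begin(), pk.end());
    std::reverse(pp.begin(), pp.end());
  }
  IntegerMatrix path(ps.size(), 3);
  for (size_t r = 0; r < ps.size(); ++r) {
    path(r, 0) = ps[r]; path(r, 1) = pk[r]; path(r, 2) = pp[r];
  }
  colnames(path) = CharacterVector::create("state", "node", "pos");
  return List::create(_["viterbi_bits"] = vbest,
                      _["forward_bits"] = fsum,
                      _["path"] = path);
}
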