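#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-point recombination-fraction estimation for CP-population marker
// pairs by EM over the four inheritance states (AC, AD, BC, BD) at each
// locus.  Observations are integer class indices into each marker's own
// phenotype alphabet (0 = missing); `cmaps` gives, per marker, the class
// emitted by each state under the reference phase (0 = the state emits a
// missing observation, e.g. OO).  All four relative phase assignments
// (flip of either parent's homolog labelling at the second marker) are
// fitted and the maximum-likelihood one returned.

struct EStep {
  double ll;
  double esw;   // expected total parental homolog switches
};

static EStep estep(double r, const std::vector<double>& N,
                   int K1, int K2,
                   const int* cm1, const int* cm2, const int* sm) {
  EStep out{0.0, 0.0};
  double tr[3];
  tr[0] = (1 - r) * (1 - r);
  tr[1] = r * (1 - r);
  tr[2] = r * r;
  for (int c1 = 0; c1 <= K1; ++c1) {
    for (int c2 = 0; c2 <= K2; ++c2) {
      double n = N[c1 * (K2 + 1) + c2];
      if (n == 0.0) continue;
      double wsum = 0.0, swsum = 0.0;
      for (int s1 = 0; s1 < 4; ++s1) {
        if (c1 != 0 && cm1[s1] != c1) continue;
        for (int s2 = 0; s2 < 4; ++s2) {
          if (c2 != 0 && cm2[sm[s2]] != c2) continue;
          int d = (int)(s1 / 2 != s2 / 2) + (int)(s1 % 2 != s2 % 2);
          wsum += 0.25 * tr[d];
          swsum += 0.25 * tr[d] * d;
        }
      }
      if (wsum <= 0.0) { out.ll = R_NegInf; return out; }
      out.ll += n * std::log(wsum);
      out.esw += n * swsum / wsum;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_pair_em(IntegerMatrix obs, IntegerMatrix cmaps,
                 IntegerVector nclasses, IntegerMatrix pairs,
                 double r_init, int max_iter, double tol,
                 double r_min, double r_max) {
  int npairs = pairs.nrow(), o = obs.ncol();
  NumericVector rhat(npairs), lod(npairs), loglik(npairs);
  IntegerVector flip_lat(npairs), flip_moy(npairs);
  for (int p = 0; p < npairs; ++p) {
    int i = pairs(p, 0) - 1, j = pairs(p, 1) - 1;
    int K1 = nclasses[i], K2 = nclasses[j];
    std::vector<double> N((K1 + 1) * (K2 + 1), 0.0);
    double total = 0.0;
    for (int k = 0; k < o; ++k) {
      int c1 = obs(i, k), c2 = obs(j, k);
      N[c1 * (K2 + 1) + c2] += 1.0;
      total += 1.0;
    }
    int cm1[4], cm2[4];
    for (int s = 0; s < 4; ++s) { cm1[s] = cmaps(i, s); cm2[s] = cmaps(j, s); }
    double best_ll = R_NegInf, best_r = NA_REAL;
    int best_fl = 0, best_fm = 0;
    double ll_null = NA_REAL;
    for (int fl = 0; fl < 2; ++fl) {
      for (int fm = 0; fm < 2; ++fm) {
        int sm[4];
        for (int s = 0; s < 4; ++s) {
          int l = s / 2, m = s % 2;
          if (fl) l = 1 - l;
          if (fm) m = 1 - m;
          sm[s] = 2 * l + m;
        }
        if (fl == 0 && fm == 0) {
          EStep e0 = estep(0.5, N, K1, K2, cm1, cm2, sm);
          ll_null = e0.ll;  // at r = 0.5 the loci are independent: the
        }                   // likelihood does not depend on the phase
        double r = r_init;
        for (int it = 0; it < max_iter; ++it) {
          EStep e = estep(r, N, K1, K2, cm1, cm2, sm);
          if (!R_FINITE(e.ll)) { r = NA_REAL; break; }
          double rnew = e.esw / (2.0 * total);
          if (rnew < r_min) rnew = r_min;
          if (rnew > r_max) rnew = r_max;
          bool done = std::fabs(rnew - r) < tol;
          r = rnew;
          if (done) break;
        }
        if (!R_FINITE(r)) continue;
        EStep ef = estep(r, N, K1, K2, cm1, cm2, sm);
        if (ef.ll > best_ll) {
          best_ll = ef.ll; best_r = r; best_fl = fl; best_fm = fm;
        }
      }
    }
    rhat[p] = best_r;
    loglik[p] = best_ll;
    lod[p] = R_FINITE(best_ll) ? (best_ll - ll_null) / std::log(10.0) : NA_REAL;
    flip_lat[p] = best_fl;
    flip_moy[p] = best_fm;
  }
  return List::create(_["rhat"] = rhat, _["lod"] = lod,
                      _["loglik"] = loglik, _["flip_lat"] = flip_lat,
                      _["flip_moy"] = flip_moy);
}

// Viterbi total-recombination count for a candidate marker order, vectorised
// across offspring.  obs: m x o class indices (0 = missing) already in the
// candidate order; cmaps: m x 4 emitted class per state (phased); rk: m-1
// inter-marker recombination fractions; eps: genotyping error rate.
// Returns the total number of parental homolog switches along the Viterbi
// paths of all offspring.
// [[Rcpp::export]]
double cpp_viterbi_recombinations(IntegerMatrix obs, IntegerMatrix cmaps,
                                  IntegerVector nclasses, NumericVector rk,
                                  double eps) {
  int m = obs.nrow(), o = obs.ncol();
  if (m == 0) return 0.0;
  std::vector<double> delta(4), ndelta(4);
  std::vector<int> psi(4 * (m > 1 ? m - 1 : 1));
  double total = 0.0;
  for (int k = 0; k < o; ++k) {
    // initial
    for (int s = 0; s < 4; ++s) {
      int c = obs(0, k);
      double e = 1.0;
      if (c != 0) {
        int K = nclasses[0];
        e = (cmaps(0, s) == c) ? (1.0 - eps) : (K > 1 ? eps / (K - 1) : eps);
      }
      delta[s] = std::log(0.25) + std::log(e);
    }
    for (int t = 1; t < m; ++t) {
      double r = rk[t - 1];
      double lt[3];
      lt[0] = std::log((1 - r) * (1 - r));
      lt[1] = std::log(r * (1 - r));
      lt[2] = std::log(r * r);
      int c = obs(t, k);
      int K = nclasses[t];
      for (int s = 0; s < 4; ++s) {
        double best = R_NegInf; int arg = 0;
        for (int sp = 0; sp < 4; ++sp) {
          int d = (int)(sp / 2 != s / 2) + (int)(sp % 2 != s % 2);
          double v = delta[sp] + lt[d];
          if (v > best) { best = v; arg = sp; }
        }
        double e = 1.0;
        if (c != 0)
          e = (cmaps(t, s) == c) ? (1.0 - eps) : (K > 1 ? eps / (K - 1) : eps);
        ndelta[s] = best + std::log(e);
        psi[4 * (t - 1) + s] = arg;
      }
      delta = ndelta;
    }
    int s = 0;
    double best = delta[0];
    for (int q = 1; q < 4; ++q) if (delta[q] > best) { best = delta[q]; s = q; }
    for (int t = m - 1; t >= 1; --t) {
      int sp = psi[4 * (t - 1) + s];
      total += (int)(sp / 2 != s / 2) + (int)(sp % 2 != s % 2);
      s = sp;
    }
  }
  return total;
}
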