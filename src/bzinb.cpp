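// Joint pmf and log-likelihood of the shared-component Poisson-Gamma mixture
// (BNB) and its zero-masked extension (BZINB), computed via the finite-sum
// decomposition in log space.
//
// Model: R0 ~ Gamma(a0, scale b1), R1 ~ Gamma(a1, b1), R2 ~ Gamma(a2, b1),
// X1 | R ~ Pois(R0 + R1), X2 | R ~ Pois(delta * (R0 + R2)), delta = b2 / b1.
// Splitting X1 = U1 + V1, X2 = U2 + V2 (U from the shared component) gives
//   P(U1=u1, U2=u2) = delta^{u2} / (u1! u2!) * Gamma(a0+s) / Gamma(a0)
//                     * b1^{-a0} * (1 + delta + 1/b1)^{-(a0+s)},  s = u1+u2,
// and V1 ~ NB(a1, 1/(1+b1)), V2 ~ NB(a2, 1/(1+b2)), all independent, so the
// joint pmf is a double convolution sum of at most (x1+1)(x2+1) terms.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct BnbTables {
  double a0, a1, a2, b1, b2;
  double ldelta;   // log(b2/b1)
  double lb1;      // log(b1)
  double c;        // log(1 + b1 + b2)
  std::vector<double> lgam0;  // lgamma(a0+s) - lgamma(a0), s = 0..S
  std::vector<double> lfact;  // log(s!)
  std::vector<double> lnb1;   // log NB(a1, 1/(1+b1)) pmf at 0..M1
  std::vector<double> lnb2;   // log NB(a2, 1/(1+b2)) pmf at 0..M2

  BnbTables(double a0_, double a1_, double a2_, double b1_, double b2_,
            int m1, int m2)
      : a0(a0_), a1(a1_), a2(a2_), b1(b1_), b2(b2_) {
    ldelta = std::log(b2) - std::log(b1);
    lb1 = std::log(b1);
    c = std::log1p(b1 + b2);
    int S = m1 + m2;
    lgam0.resize(S + 1);
    lfact.resize(S + 1);
    lgam0[0] = 0.0;
    lfact[0] = 0.0;
    for (int s = 1; s <= S; ++s) {
      lgam0[s] = lgam0[s - 1] + std::log(a0 + s - 1);
      lfact[s] = lfact[s - 1] + std::log((double)s);
    }
    lnb1.resize(m1 + 1);
    lnb2.resize(m2 + 1);
    double p1 = 1.0 / (1.0 + b1), p2 = 1.0 / (1.0 + b2);
    for (int v = 0; v <= m1; ++v) lnb1[v] = R::dnbinom(v, a1, p1, 1);
    for (int v = 0; v <= m2; ++v) lnb2[v] = R::dnbinom(v, a2, p2, 1);
  }

  // log joint pmf at a single (x1, x2), online log-sum-exp over the grid
  double logpmf(int x1, int x2) const {
    double m = R_NegInf, sum = 0.0;
    for (int u1 = 0; u1 <= x1; ++u1) {
      double base1 = -lfact[u1] + lnb1[x1 - u1];
      for (int u2 = 0; u2 <= x2; ++u2) {
        int s = u1 + u2;
        double lw = lgam0[s] + s * lb1 - (a0 + s) * c + u2 * ldelta -
                    lfact[u2] + base1 + lnb2[x2 - u2];
        if (lw == R_NegInf) continue;
        if (lw > m) {
          sum = sum * std::exp(m - lw) + 1.0;
          m = lw;
        } else {
          sum += std::exp(lw - m);
        }
      }
    }
    if (m == R_NegInf) return R_NegInf;
    return m + std::log(sum);
  }
};

inline int vec_max(const IntegerVector& x) {
  int m = 0;
  for (int i = 0; i < x.size(); ++i) if (x[i] > m) m = x[i];
  return m;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_bnb_logpmf(IntegerVector x1, IntegerVector x2, double a0,
                             double a1, double a2, double b1, double b2) {
  int n = x1.size();
  BnbTables tab(a0, a1, a2, b1, b2, vec_max(x1), vec_max(x2));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = tab.logpmf(x1[i], x2[i]);
  return out;
}

// Weighted negative log-likelihood over unique observed pairs.
// [[Rcpp::export]]
double cpp_bnb_negloglik(IntegerVector x1, IntegerVector x2, NumericVector w,
                         double a0, double a1, double a2, double b1,
                         double b2) {
  BnbTables tab(a0, a1, a2, b1, b2, vec_max(x1), vec_max(x2));
  double nll = 0.0;
  for (int i = 0; i < x1.size(); ++i) {
    double lp = tab.logpmf(x1[i], x2[i]);
    if (!R_finite(lp)) return R_PosInf;
    nll -= w[i] * lp;
  }
  return nll;
}

// [[Rcpp::export]]
NumericVector cpp_bzinb_logpmf(IntegerVector y1, IntegerVector y2, double a0,
                               double a1, double a2, double b1, double b2,
                               double pi1, double pi2, double pi3,
                               double pi4) {
  int n = y1.size();
  int m1 = vec_max(y1), m2 = vec_max(y2);
  BnbTables tab(a0, a1, a2, b1, b2, m1, m2);
  double p1 = 1.0 / (1.0 + b1), p2 = 1.0 / (1.0 + b2);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double comp[4];
    int k = 0;
    if (pi1 > 0) comp[k++] = std::log(pi1) + tab.logpmf(y1[i], y2[i]);
    if (pi2 > 0 && y2[i] == 0)
      comp[k++] = std::log(pi2) + R::dnbinom(y1[i], a0 + a1, p1, 1);
    if (pi3 > 0 && y1[i] == 0)
      comp[k++] = std::log(pi3) + R::dnbinom(y2[i], a0 + a2, p2, 1);
    if (pi4 > 0 && y1[i] == 0 && y2[i] == 0) comp[k++] = std::log(pi4);
    double m = R_NegInf;
    for (int j = 0; j < k; ++j) if (comp[j] > m) m = comp[j];
    if (m == R_NegInf) {
      out[i] = R_NegInf;
      continue;
    }
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += std::exp(comp[j] - m);
    out[i] = m + std::log(s);
  }
  return out;
}

// [[Rcpp::export]]
double cpp_bzinb_negloglik(IntegerVector y1, IntegerVector y2, NumericVector w,
                           double a0, double a1, double a2, double b1,
                           double b2, double pi1, double pi2, double pi3,
                           double pi4) {
  NumericVector lp = cpp_bzinb_logpmf(y1, y2, a0, a1, a2, b1, b2, pi1, pi2,
                                      pi3, pi4);
  double nll = 0.0;
  for (int i = 0; i < lp.size(); ++i) {
    if (!R_finite(lp[i])) return R_PosInf;
    nll -= w[i] * lp[i];
  }
  return nll;
}
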