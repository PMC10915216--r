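// Single-site Gibbs samplers for marker-effect models (Bayesian ridge
// regression with correlated bivariate effects; Bayes A / Bayes B with
// per-SNP variances and optional spike at zero). The per-SNP sweep is the
// hot loop, hence compiled; all randomness goes through R's RNG so R-level
// set.seed() controls reproducibility.
#include <Rcpp.h>
using namespace Rcpp;

// ---- small fixed-size helpers (2x2, stored as a11, a12, a22) ----
static inline void inv2(const double a11, const double a12, const double a22,
                        double &i11, double &i12, double &i22) {
  double det = a11 * a22 - a12 * a12;
  i11 = a22 / det; i12 = -a12 / det; i22 = a11 / det;
}

// lower Cholesky of [[a11,a12],[a12,a22]]
static inline void chol2(const double a11, const double a12, const double a22,
                         double &l11, double &l21, double &l22) {
  l11 = std::sqrt(a11);
  l21 = a12 / l11;
  double d = a22 - l21 * l21;
  l22 = std::sqrt(d > 0 ? d : 0.0);
}

// inverse-Wishart(nu, S) draw for a 2x2 scale S via Bartlett on S^{-1}
static void riwish2(const double nu, const double s11, const double s12,
                    const double s22, double &o11, double &o12, double &o22) {
  double p11, p12, p22;            // S^{-1}
  inv2(s11, s12, s22, p11, p12, p22);
  double l11, l21, l22;            // chol of S^{-1}
  chol2(p11, p12, p22, l11, l21, l22);
  // Bartlett factor A (lower): diag sqrt(chisq), offdiag N(0,1)
  double a11 = std::sqrt(R::rchisq(nu));
  double a21 = R::rnorm(0.0, 1.0);
  double a22 = std::sqrt(R::rchisq(nu - 1.0));
  // T = L * A (lower); W = T T'
  double t11 = l11 * a11;
  double t21 = l21 * a11 + l22 * a21;
  double t22 = l22 * a22;
  double w11 = t11 * t11;
  double w12 = t11 * t21;
  double w22 = t21 * t21 + t22 * t22;
  inv2(w11, w12, w22, o11, o12, o22);
}

// Bivariate Bayesian ridge regression: Y (n x 2) = 1 mu' + X B + E,
// rows of B iid MVN(0, Vb), Vb ~ IW(nu0, S0), E rows iid MVN(0, R0),
// R0 ~ IW(nue, Se). X must be column-centered.
// [[Rcpp::export]]
List brr_biv_gibbs(const NumericMatrix X, const NumericMatrix Y,
                   const int n_iter, const int burn_in,
                   const double nu0, const NumericVector S0,
                   const double nue, const NumericVector Se) {
  const int n = X.nrow(), m = X.ncol();
  NumericVector xtx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  NumericMatrix B(m, 2), Bsum(m, 2), E(n, 2);
  double mu1 = 0.0, mu2 = 0.0, mu1s = 0.0, mu2s = 0.0;
  double vb11 = S0[0], vb12 = S0[1], vb22 = S0[2];
  double r11 = Se[0], r12 = Se[1], r22 = Se[2];
  double vb11s = 0, vb12s = 0, vb22s = 0, r11s = 0, r12s = 0, r22s = 0;
  for (int i = 0; i < n; ++i) { E(i, 0) = Y(i, 0); E(i, 1) = Y(i, 1); }
  {
    double m1 = 0, m2 = 0;
    for (int i = 0; i < n; ++i) { m1 += E(i, 0); m2 += E(i, 1); }
    mu1 = m1 / n; mu2 = m2 / n;
    for (int i = 0; i < n; ++i) { E(i, 0) -= mu1; E(i, 1) -= mu2; }
  }
  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    double ri11, ri12, ri22, bi11, bi12, bi22;
    inv2(r11, r12, r22, ri11, ri12, ri22);
    inv2(vb11, vb12, vb22, bi11, bi12, bi22);
    for (int j = 0; j < m; ++j) {
      double xe1 = 0.0, xe2 = 0.0;
      for (int i = 0; i < n; ++i) {
        xe1 += X(i, j) * E(i, 0);
        xe2 += X(i, j) * E(i, 1);
      }
      const double b1o = B(j, 0), b2o = B(j, 1);
      xe1 += xtx[j] * b1o;        // X_j' (E + x_j b_j')
      xe2 += xtx[j] * b2o;
      const double rhs1 = ri11 * xe1 + ri12 * xe2;
      const double rhs2 = ri12 * xe1 + ri22 * xe2;
      double p11 = xtx[j] * ri11 + bi11;
      double p12 = xtx[j] * ri12 + bi12;
      double p22 = xtx[j] * ri22 + bi22;
      double c11, c12, c22, l11, l21, l22;
      inv2(p11, p12, p22, c11, c12, c22);
      chol2(c11, c12, c22, l11, l21, l22);
      const double z1 = R::rnorm(0, 1), z2 = R::rnorm(0, 1);
      const double b1 = c11 * rhs1 + c12 * rhs2 + l11 * z1;
      const double b2 = c12 * rhs1 + c22 * rhs2 + l21 * z1 + l22 * z2;
      const double d1 = b1 - b1o, d2 = b2 - b2o;
      if (d1 != 0.0 || d2 != 0.0) {
        for (int i = 0; i < n; ++i) {
          E(i, 0) -= X(i, j) * d1;
          E(i, 1) -= X(i, j) * d2;
        }
      }
      B(j, 0) = b1; B(j, 1) = b2;
    }
    // effect covariance
    double sb11 = S0[0], sb12 = S0[1], sb22 = S0[2];
    for (int j = 0; j < m; ++j) {
      sb11 += B(j, 0) * B(j, 0);
      sb12 += B(j, 0) * B(j, 1);
      sb22 += B(j, 1) * B(j, 1);
    }
    riwish2(nu0 + m, sb11, sb12, sb22, vb11, vb12, vb22);
    // residual covariance
    double se11 = Se[0], se12 = Se[1], se22 = Se[2];
    for (int i = 0; i < n; ++i) {
      se11 += E(i, 0) * E(i, 0);
      se12 += E(i, 0) * E(i, 1);
      se22 += E(i, 1) * E(i, 1);
    }
    riwish2(nue + n, se11, se12, se22, r11, r12, r22);
    // means (flat prior)
    {
      double m1 = 0, m2 = 0;
      for (int i = 0; i < n; ++i) { m1 += E(i, 0); m2 += E(i, 1); }
      m1 /= n; m2 /= n;
      double l11, l21, l22;
      chol2(r11 / n, r12 / n, r22 / n, l11, l21, l22);
      const double z1 = R::rnorm(0, 1), z2 = R::rnorm(0, 1);
      const double d1 = m1 + l11 * z1, d2 = m2 + l21 * z1 + l22 * z2;
      mu1 += d1; mu2 += d2;
      for (int i = 0; i < n; ++i) { E(i, 0) -= d1; E(i, 1) -= d2; }
    }
    if (!R_finite(vb11) || !R_finite(r11))
      stop("divergent chain: non-finite draw at iteration %d", it + 1);
    if (it >= burn_in) {
      ++kept;
      for (int j = 0; j < m; ++j) {
        Bsum(j, 0) += B(j, 0); Bsum(j, 1) += B(j, 1);
      }
      mu1s += mu1; mu2s += mu2;
      vb11s += vb11; vb12s += vb12; vb22s += vb22;
      r11s += r11; r12s += r12; r22s += r22;
    }
  }
  for (int j = 0; j < m; ++j) { Bsum(j, 0) /= kept; Bsum(j, 1) /= kept; }
  return List::create(
    _["b"] = Bsum,
    _["mu"] = NumericVector::create(mu1s / kept, mu2s / kept),
    _["Vb"] = NumericVector::create(vb11s / kept, vb12s / kept, vb22s / kept),
    _["R0"] = NumericVector::create(r11s / kept, r12s / kept, r22s / kept));
}

// Univariate Bayes A (pi = 0) / Bayes B: y = mu + X b + e with per-SNP
// effect variances v_j ~ scaled-inv-chi2(nu, S); with probability pi an
// effect is exactly zero (indicator sampled with b_j integrated out).
// X must be column-centered.
// [[Rcpp::export]]
List bayes_ab_gibbs(const NumericMatrix X, const NumericVector y,
                    const int n_iter, const int burn_in,
                    const double pi0, const double nu, const double S,
                    const double nue, const double Se) {
  const int n = X.nrow(), m = X.ncol();
  NumericVector xtx(m), b(m), bsum(m), incl_sum(m), vj(m), e(n);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
    vj[j] = nu * S / (nu - 2.0);   // prior mean
  }
  double mu = Rcpp::mean(y), ve = Se * nue / (nue - 2.0);
  double mus = 0.0, ves = 0.0;
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    for (int j = 0; j < m; ++j) {
      if (xtx[j] <= 0.0) { b[j] = 0.0; continue; }
      double xe = 0.0;
      for (int i = 0; i < n; ++i) xe += X(i, j) * e[i];
      const double bo = b[j];
      const double rhs = xe + xtx[j] * bo;
      bool include = true;
      if (pi0 > 0.0) {
        const double v0 = xtx[j] * ve;
        const double v1 = v0 + xtx[j] * xtx[j] * vj[j];
        const double logbf = 0.5 * (std::log(v0 / v1) +
                                    rhs * rhs * (1.0 / v0 - 1.0 / v1));
        const double p1 = (1.0 - pi0) /
          ((1.0 - pi0) + pi0 * std::exp(-logbf));
        include = R::unif_rand() < p1;
      }
      double bn = 0.0;
      if (include) {
        const double c = xtx[j] + ve / vj[j];
        bn = rhs / c + R::rnorm(0, 1) * std::sqrt(ve / c);
      }
      if (bn != bo) {
        const double d = bn - bo;
        for (int i = 0; i < n; ++i) e[i] -= X(i, j) * d;
      }
      b[j] = bn;
      // per-SNP variance: conditional if in the model, prior draw otherwise
      if (include) {
        vj[j] = (nu * S + bn * bn) / R::rchisq(nu + 1.0);
      } else {
        vj[j] = nu * S / R::rchisq(nu);
      }
      if (it >= burn_in && include) incl_sum[j] += 1.0;
    }
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    ve = (nue * Se + sse) / R::rchisq(nue + n);
    double d = 0.0;
    for (int i = 0; i < n; ++i) d += e[i];
    d = d / n + R::rnorm(0, 1) * std::sqrt(ve / n);
    mu += d;
    for (int i = 0; i < n; ++i) e[i] -= d;
    if (!R_finite(ve)) {
      stop("divergent chain: non-finite draw at iteration %d", it + 1);
    }
    if (it >= burn_in) {
      ++kept;
      for (int j = 0; j < m; ++j) bsum[j] += b[j];
      mus += mu; ves += ve;
    }
  }
  for (int j = 0; j < m; ++j) { bsum[j] /= kept; incl_sum[j] /= kept; }
  return List::create(_["b"] = bsum, _["inclusion"] = incl_sum,
                      _["mu"] = mus / kept, _["ve"] = ves / kept);
}
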