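// Polya-Gamma sampling.
//
// PG(b, z) variates via Devroye's exact alternating-series rejection sampler
// for unit shape (summed for integer b), and a truncated sum-of-gammas
// representation with a closed-form tail-mean correction for fractional
// shape. All randomness comes from R's RNG so draws are governed by set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static const double T_TRUNC = 2.0 / M_PI;

static double exprnd() { return R::exp_rand(); }

// Piecewise coefficients a_n(x) of the Jacobi density series.
static double aterm(int n, double x, double t) {
  double f;
  double nh = n + 0.5;
  if (x <= t) {
    // log(pi) + log(n+1/2) + 1.5*log(2/(pi x)) - 2(n+1/2)^2/x
    f = std::log(M_PI) + std::log(nh) +
        1.5 * (std::log(2.0 / M_PI) - std::log(x)) - 2.0 * nh * nh / x;
  } else {
    f = std::log(M_PI) + std::log(nh) - x * M_PI * M_PI * 0.5 * nh * nh;
  }
  return std::exp(f);
}

// Gamma(1/2) tail sampler used by the truncated inverse-Gaussian branch.
static double truncgamma() {
  double c = M_PI_2;
  double X, gX;
  for (;;) {
    X = exprnd() * 2.0 + c;
    gX = std::sqrt(M_PI / (2.0 * X));
    if (R::unif_rand() <= gX) return X;
  }
}

// Inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, t).
static double tinvgauss(double z, double t) {
  double X;
  double mu = 1.0 / z;
  if (mu > t) {
    for (;;) {
      double u = R::unif_rand();
      X = 1.0 / truncgamma();
      if (std::log(u) < -z * z * 0.5 * X) return X;
    }
  } else {
    X = t + 1.0;
    while (X >= t) {
      double Y = R::norm_rand();
      Y *= Y;
      double w = mu + 0.5 * mu * mu * Y;
      X = w - std::sqrt(w * w - mu * mu);
      if (R::unif_rand() > mu / (mu + X)) X = mu * mu / X;
    }
    return X;
  }
}

// One PG(1, z) draw (Devroye 2009).
static double samplepg1(double z) {
  z = std::fabs(z) * 0.5;
  double t = T_TRUNC;
  double K = z * z / 2.0 + M_PI * M_PI / 8.0;
  double logA = std::log(4.0) - std::log(M_PI) - z;
  double logK = std::log(K);
  double Kt = K * t;
  double w = std::sqrt(M_PI_2);

  double logf1 = logA + R::pnorm(w * (t * z - 1.0), 0.0, 1.0, 1, 1) + logK + Kt;
  double logf2 = logA + 2.0 * z + R::pnorm(-w * (t * z + 1.0), 0.0, 1.0, 1, 1) +
                 logK + Kt;
  double p_over_q = std::exp(logf1) + std::exp(logf2);
  double ratio = 1.0 / (1.0 + p_over_q);

  double X;
  for (;;) {
    double u = R::unif_rand();
    if (u < ratio) {
      X = t + exprnd() / K;
    } else {
      X = tinvgauss(z, t);
    }
    // Accept/reject by the alternating series (squeeze from both sides).
    double Sn = aterm(0, X, t);
    double U = R::unif_rand() * Sn;
    int asgn = -1;
    bool even = false;
    int i = 1;
    for (;;) {
      Sn += asgn * aterm(i, X, t);
      if (!even && U <= Sn) return X * 0.25;
      if (even && U > Sn) break;
      even = !even;
      asgn = -asgn;
      ++i;
    }
  }
}

// Fractional-shape draw via the weighted infinite sum of gammas,
// PG(b,z) = (2*pi^2)^{-1} sum_k g_k / ((k-1/2)^2 + z^2/(4*pi^2)), g_k ~ Ga(b,1),
// truncated at nterm terms with the tail replaced by its expectation.
static double samplepg_frac(double b, double z, int nterm) {
  double c2 = z * z / (4.0 * M_PI * M_PI);
  double acc = 0.0;
  for (int k = 1; k <= nterm; ++k) {
    double d = (k - 0.5) * (k - 0.5) + c2;
    acc += R::rgamma(b, 1.0) / d;
  }
  double c = std::sqrt(c2);
  double tail;
  if (c > 1e-8) {
    tail = b * (M_PI_2 - std::atan(nterm / c)) / c;
  } else {
    tail = b / (double)nterm;
  }
  return (acc + tail) / (2.0 * M_PI * M_PI);
}

// [[Rcpp::export]]
NumericVector rpg_cpp(NumericVector b, NumericVector z) {
  R_xlen_t n = b.size();
  NumericVector out(n);
  const int nterm = 200;
  for (R_xlen_t i = 0; i < n; ++i) {
    double bi = b[i], zi = z[i];
    if (bi <= 0.0) { out[i] = 0.0; continue; }
    double ip;
    double frac = std::modf(bi, &ip);
    double x = 0.0;
    int m = (int)ip;
    if (m <= 50) {
      for (int k = 0; k < m; ++k) x += samplepg1(zi);
    } else {
      // large integer shape: series draw is accurate and O(nterm)
      x += samplepg_frac((double)m, zi, nterm);
    }
    if (frac > 0.0) x += samplepg_frac(frac, zi, nterm);
    out[i] = x;
  }
  return out;
}
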