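#include <Rcpp.h>
using namespace Rcpp;

// Polya-Gamma PG(b, z) random draws.
//
// PG(1, z) uses the alternating-series rejection sampler of Devroye (2009)
// in the form given by Polson, Scott & Windle (2013).  PG(b, z) for integer
// b is the sum of b independent PG(1, z) draws; for large b a moment-matched
// Gaussian is used (the relative skewness of the sum decays as 1/sqrt(b)).
// All randomness comes from R's RNG so draws are reproducible via set.seed().

static const double TRUNC = 0.64;  // series truncation point of Devroye

// piecewise coefficients a_n(x) of the Jacobi J*(1,0) density series
static double aterm(int n, double x) {
  double h = n + 0.5;
  if (x <= TRUNC)
    return M_PI * h * std::pow(2.0 / (M_PI * x), 1.5) * std::exp(-2.0 * h * h / x);
  return M_PI * h * std::exp(-0.5 * h * h * M_PI * M_PI * x);
}

// CDF at x of the inverse-Gaussian(mu = 1/z, lambda = 1); parameterised by z
// so that z = 0 (mu = infinity) stays valid
static double pigauss(double x, double z) {
  double rx = 1.0 / std::sqrt(x);
  double p  = R::pnorm(rx * (x * z - 1.0), 0.0, 1.0, 1, 0);
  double lq = 2.0 * z + R::pnorm(-rx * (x * z + 1.0), 0.0, 1.0, 1, 1);
  return p + std::exp(lq);
}

// draw from IG(1/z, 1) truncated to (0, TRUNC)
static double rtigauss(double z) {
  const double t = TRUNC;
  double X;
  if (z < 1.0 / t) {            // mu > t: rejection from the scaled stable tail
    for (;;) {
      double E1 = R::exp_rand(), E2 = R::exp_rand();
      while (E1 * E1 > 2.0 * E2 / t) {
        E1 = R::exp_rand(); E2 = R::exp_rand();
      }
      X = t / ((1.0 + t * E1) * (1.0 + t * E1));
      if (R::unif_rand() <= std::exp(-0.5 * z * z * X)) return X;
    }
  } else {                      // mu <= t: sample IG(mu,1) until below t
    double mu = 1.0 / z;
    for (;;) {
      double Y = R::norm_rand(); Y *= Y;
      double muY = mu * Y;
      X = mu + 0.5 * mu * (muY - std::sqrt(4.0 * muY + muY * muY));
      if (R::unif_rand() > mu / (mu + X)) X = mu * mu / X;
      if (X < t) return X;
    }
  }
}

// mean and variance of PG(b, z)
static void pg_moments(double b, double z, double *m, double *v) {
  z = std::fabs(z);
  if (z < 1e-4) {
    *m = 0.25 * b;
    *v = b / 24.0;
  } else if (z > 33.0) {        // asymptotics, safe from overflow for any z
    *m = b / (2.0 * z);
    *v = b / (2.0 * z * z * z);
  } else {
    double ch = std::cosh(0.5 * z);
    *m = b * std::tanh(0.5 * z) / (2.0 * z);
    *v = b * (std::sinh(z) - z) / (4.0 * z * z * z * ch * ch);
  }
}

// one exact PG(1, z) draw
static double rpg1(double z) {
  double zz = 0.5 * std::fabs(z);
  if (zz > 50.0) {              // numerically extreme tilt: moment draw
    double m, v;
    pg_moments(1.0, z, &m, &v);
    double x = m + std::sqrt(v) * R::norm_rand();
    return x > 1e-14 ? x : 1e-14;
  }
  double K = 0.125 * M_PI * M_PI + 0.5 * zz * zz;
  double p = (M_PI / (2.0 * K)) * std::exp(-K * TRUNC);
  double q = 2.0 * std::exp(-zz) * pigauss(TRUNC, zz);
  for (;;) {
    double X;
    if (R::unif_rand() < p / (p + q)) X = TRUNC + R::exp_rand() / K;
    else                              X = rtigauss(zz);
    double S = aterm(0, X);
    double Y = R::unif_rand() * S;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) { S -= aterm(n, X); if (Y <= S) return 0.25 * X; }
      else            { S += aterm(n, X); if (Y >  S) break; }
    }
  }
}

// [[Rcpp::export(name = ".rpg_cpp")]]
NumericVector rpg_cpp(NumericVector b, NumericVector z, int exact_max = 170) {
  R_xlen_t n = b.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double bi = b[i], zi = z[i];
    if (!(bi > 0)) { out[i] = 0.0; continue; }
    if (bi <= exact_max) {
      int nb = (int) std::lround(bi);
      double s = 0.0;
      for (int j = 0; j < nb; ++j) s += rpg1(zi);
      out[i] = s;
    } else {
      double m, v;
      pg_moments(bi, zi, &m, &v);
      double x = m + std::sqrt(v) * R::norm_rand();
      out[i] = x > 1e-12 ? x : 1e-12;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".pg_moments_cpp")]]
NumericMatrix pg_moments_cpp(NumericVector b, NumericVector z) {
  R_xlen_t n = b.size();
  NumericMatrix out(n, 2);
  for (R_xlen_t i = 0; i < n; ++i) {
    double m, v;
    pg_moments(b[i], z[i], &m, &v);
    out(i, 0) = m; out(i, 1) = v;
  }
  return out;
}
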