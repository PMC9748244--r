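#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gaussian product-kernel density estimate evaluated at query points.
// ref:   n x d matrix of reference (accepted) points
// h:     length-d vector of per-dimension bandwidths (all > 0)
// query: m x d matrix of evaluation points
// Returns length-m vector of densities.
//
// Pairs with squared scaled distance above QCUT contribute < exp(-27.5)
// ~ 1e-12 relative and are skipped before the exponential.
// [[Rcpp::export]]
NumericVector kde_gauss_eval(NumericMatrix ref, NumericVector h,
                             NumericMatrix query) {
  const int n = ref.nrow(), d = ref.ncol(), m = query.nrow();
  if (h.size() != d) stop("bandwidth length must equal dimension");
  if (query.ncol() != d) stop("query dimension mismatch");
  double norm = n * std::pow(2.0 * M_PI, d / 2.0);
  for (int k = 0; k < d; ++k) {
    if (h[k] <= 0) stop("bandwidths must be positive");
    norm *= h[k];
  }
  const double QCUT = 55.0;
  // pre-scale coordinates by bandwidth, laid out point-major
  std::vector<double> rs((size_t)n * d), qs((size_t)m * d);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) rs[(size_t)i * d + k] = ref(i, k) / h[k];
  for (int j = 0; j < m; ++j)
    for (int k = 0; k < d; ++k) qs[(size_t)j * d + k] = query(j, k) / h[k];
  NumericVector out(m);
  std::vector<double> near;
  near.reserve(n);
  for (int j = 0; j < m; ++j) {
    const double *q = &qs[(size_t)j * d];
    near.clear();
    if (d == 3) {                       // hot path: 3-D niche space
      const double q0 = q[0], q1 = q[1], q2 = q[2];
      for (int i = 0; i < n; ++i) {
        const double *r = &rs[(size_t)i * 3];
        double z0 = q0 - r[0], z1 = q1 - r[1], z2 = q2 - r[2];
        double s = z0 * z0 + z1 * z1 + z2 * z2;
        if (s < QCUT) near.push_back(s);
      }
    } else {
      for (int i = 0; i < n; ++i) {
        const double *r = &rs[(size_t)i * d];
        double s = 0.0;
        for (int k = 0; k < d; ++k) {
          double z = q[k] - r[k];
          s += z * z;
        }
        if (s < QCUT) near.push_back(s);
      }
    }
    double acc = 0.0;
    for (size_t t = 0; t < near.size(); ++t)
      acc += std::exp(-0.5 * near[t]);
    out[j] = acc / norm;
  }
  return out;
}

// Minimum Euclidean distance between any row of a and any row of b.
// [[Rcpp::export]]
double min_cross_distance(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow(), d = a.ncol();
  if (b.ncol() != d) stop("dimension mismatch");
  if (na == 0 || nb == 0) stop("empty point set");
  std::vector<double> av((size_t)na * d), bv((size_t)nb * d);
  for (int i = 0; i < na; ++i)
    for (int k = 0; k < d; ++k) av[(size_t)i * d + k] = a(i, k);
  for (int j = 0; j < nb; ++j)
    for (int k = 0; k < d; ++k) bv[(size_t)j * d + k] = b(j, k);
  double best = R_PosInf;
  for (int i = 0; i < na; ++i) {
    const double *p = &av[(size_t)i * d];
    for (int j = 0; j < nb; ++j) {
      const double *q = &bv[(size_t)j * d];
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double z = p[k] - q[k];
        s += z * z;
      }
      if (s < best) best = s;
    }
  }
  return std::sqrt(best);
}
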