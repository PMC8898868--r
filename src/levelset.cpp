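#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

// separable Gaussian smoothing, reflect boundary, kernel truncated at
// radius ceil(3*sigma)
// [[Rcpp::export]]
NumericMatrix gauss_smooth_cpp(NumericMatrix x, double sigma) {
  const int nr = x.nrow(), nc = x.ncol();
  const int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)          // along rows
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d)
        acc += k[d + r] * x(reflect_idx(i + d, nr), j);
      tmp(i, j) = acc;
    }
  for (int j = 0; j < nc; ++j)          // along columns
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d)
        acc += k[d + r] * tmp(i, reflect_idx(j + d, nc));
      out(i, j) = acc;
    }
  return out;
}

static inline double heaviside(double z, double eps) {
  return 0.5 * (1.0 + M_2_PI * std::atan(z / eps));
}

// SPF level-set evolution; see evolveLevelSet() for the scheme.  `domain`
// may be R_NilValue for an unrestricted run.
// [[Rcpp::export]]
NumericMatrix evolve_cpp(NumericMatrix image, NumericMatrix phi0,
                         double alpha, double epsilon, double dt,
                         double sigmaG, int maxIters, double tol,
                         bool binarize, bool curvature,
                         Nullable<LogicalMatrix> domain) {
  const int nr = image.nrow(), nc = image.ncol();
  const int npix = nr * nc;
  const bool hasDom = domain.isNotNull();
  LogicalMatrix dom = hasDom ? LogicalMatrix(domain) : LogicalMatrix(0, 0);

  NumericMatrix phi = clone(phi0);
  if (hasDom)
    for (int t = 0; t < npix; ++t) if (!dom[t]) phi[t] = -1.0;
  std::vector<int> prevMask(npix);
  for (int t = 0; t < npix; ++t) prevMask[t] = phi[t] > 0;

  NumericMatrix spf(nr, nc);

  for (int it = 1; it <= maxIters; ++it) {
    // region means under the smoothed Heaviside (restricted to the domain)
    double s1 = 0, s2 = 0, w1 = 0, w2 = 0;
    for (int t = 0; t < npix; ++t) {
      if (hasDom && !dom[t]) continue;
      const double h = heaviside(phi[t], epsilon);
      s1 += image[t] * h;        w1 += h;
      s2 += image[t] * (1 - h);  w2 += 1 - h;
    }
    if (w1 < 1e-12) stop("degenerate interior region (zero weight)");
    if (w2 < 1e-12) stop("degenerate exterior region (zero weight)");
    const double mid = (s1 / w1 + s2 / w2) / 2.0;

    double mx = 0.0;
    for (int t = 0; t < npix; ++t) {
      spf[t] = (hasDom && !dom[t]) ? 0.0 : image[t] - mid;
      const double a = std::fabs(spf[t]);
      if (a > mx) mx = a;
    }
    // deviations at rounding-noise scale are a constant region, not force
    if (mx > 1e-12) for (int t = 0; t < npix; ++t) spf[t] /= mx;
    else            for (int t = 0; t < npix; ++t) spf[t] = 0.0;

    // upwind |grad phi| keyed to the sign of alpha * spf
    NumericMatrix upd(nr, nc);
    for (int j = 0; j < nc; ++j) {
      const int jm = j > 0 ? j - 1 : 0, jp = j < nc - 1 ? j + 1 : nc - 1;
      for (int i = 0; i < nr; ++i) {
        const int im = i > 0 ? i - 1 : 0, ip = i < nr - 1 ? i + 1 : nr - 1;
        const double F = alpha * spf(i, j);
        if (F == 0.0) continue;
        const double dpr = phi(ip, j) - phi(i, j);
        const double dmr = phi(i, j) - phi(im, j);
        const double dpc = phi(i, jp) - phi(i, j);
        const double dmc = phi(i, j) - phi(i, jm);
        double g;
        if (F > 0) {
          const double a1 = std::max(dmr, 0.0), a2 = std::min(dpr, 0.0);
          const double a3 = std::max(dmc, 0.0), a4 = std::min(dpc, 0.0);
          g = std::sqrt(a1 * a1 + a2 * a2 + a3 * a3 + a4 * a4);
        } else {
          const double a1 = std::min(dmr, 0.0), a2 = std::max(dpr, 0.0);
          const double a3 = std::min(dmc, 0.0), a4 = std::max(dpc, 0.0);
          g = std::sqrt(a1 * a1 + a2 * a2 + a3 * a3 + a4 * a4);
        }
        upd(i, j) = dt * F * g;
      }
    }

    if (curvature) {
      // central-difference curvature div(grad phi / |grad phi|)
      const double eps2 = 1e-8;
      NumericMatrix nx(nr, nc), ny(nr, nc);
      for (int j = 0; j < nc; ++j) {
        const int jm = j > 0 ? j - 1 : 0, jp = j < nc - 1 ? j + 1 : nc - 1;
        for (int i = 0; i < nr; ++i) {
          const int im = i > 0 ? i - 1 : 0, ip = i < nr - 1 ? i + 1 : nr - 1;
          const double pr = (phi(ip, j) - phi(im, j)) / 2.0;
          const double pc = (phi(i, jp) - phi(i, jm)) / 2.0;
          const double g = std::sqrt(pr * pr + pc * pc) + eps2;
          nx(i, j) = pr / g;
          ny(i, j) = pc / g;
        }
      }
      for (int j = 0; j < nc; ++j) {
        const int jm = j > 0 ? j - 1 : 0, jp = j < nc - 1 ? j + 1 : nc - 1;
        for (int i = 0; i < nr; ++i) {
          const int im = i > 0 ? i - 1 : 0, ip = i < nr - 1 ? i + 1 : nr - 1;
          const double kappa = (nx(ip, j) - nx(im, j)) / 2.0 +
                               (ny(i, jp) - ny(i, jm)) / 2.0;
          upd(i, j) += dt * spf(i, j) * kappa;
        }
      }
    }

    for (int t = 0; t < npix; ++t) {
      phi[t] += upd[t];
      if (!std::isfinite(phi[t]))
        stop("level-set field became non-finite at sweep %d; reduce dt or alpha",
             it);
    }
    phi = gauss_smooth_cpp(phi, sigmaG);
    if (binarize)
      for (int t = 0; t < npix; ++t) phi[t] = phi[t] > 0 ? 1.0 : -1.0;
    if (hasDom)
      for (int t = 0; t < npix; ++t) if (!dom[t]) phi[t] = -1.0;

    int changed = 0;
    for (int t = 0; t < npix; ++t) {
      const int m = phi[t] > 0;
      changed += m != prevMask[t];
      prevMask[t] = m;
    }
    if (it > 1 && (double)changed / npix <= tol) break;
  }
  return phi;
}
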