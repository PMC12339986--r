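#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Grid-bucketed enumeration of unordered pairs with d <= rmax.
// [[Rcpp::export]]
List cpp_close_pairs(NumericVector x, NumericVector y, double rmax) {
  int n = x.size();
  std::vector<int> ii, jj;
  std::vector<double> dd;
  if (n < 2 || rmax <= 0) {
    return List::create(_["i"] = IntegerVector(0), _["j"] = IntegerVector(0),
                        _["d"] = NumericVector(0));
  }
  double xmin = *std::min_element(x.begin(), x.end());
  double ymin = *std::min_element(y.begin(), y.end());
  double xmax = *std::max_element(x.begin(), x.end());
  double ymax = *std::max_element(y.begin(), y.end());
  double cell = rmax;
  int ncx = std::max(1, (int)std::floor((xmax - xmin) / cell) + 1);
  int ncy = std::max(1, (int)std::floor((ymax - ymin) / cell) + 1);
  // bucket point indices
  std::vector< std::vector<int> > buckets((size_t)ncx * ncy);
  std::vector<int> bx(n), by(n);
  for (int k = 0; k < n; k++) {
    int cx = std::min(ncx - 1, (int)std::floor((x[k] - xmin) / cell));
    int cy = std::min(ncy - 1, (int)std::floor((y[k] - ymin) / cell));
    bx[k] = cx; by[k] = cy;
    buckets[(size_t)cy * ncx + cx].push_back(k);
  }
  double r2 = rmax * rmax;
  for (int k = 0; k < n; k++) {
    for (int dy = -1; dy <= 1; dy++) {
      int cy = by[k] + dy;
      if (cy < 0 || cy >= ncy) continue;
      for (int dx = -1; dx <= 1; dx++) {
        int cx = bx[k] + dx;
        if (cx < 0 || cx >= ncx) continue;
        const std::vector<int>& b = buckets[(size_t)cy * ncx + cx];
        for (size_t m = 0; m < b.size(); m++) {
          int j = b[m];
          if (j <= k) continue;
          double ddx = x[k] - x[j], ddy = y[k] - y[j];
          double d2 = ddx * ddx + ddy * ddy;
          if (d2 <= r2) {
            ii.push_back(k + 1); jj.push_back(j + 1); dd.push_back(std::sqrt(d2));
          }
        }
      }
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj), _["d"] = wrap(dd));
}

// Ordered cross pairs (one point from each set) with d <= rmax.
// [[Rcpp::export]]
List cpp_cross_pairs(NumericVector x1, NumericVector y1,
                     NumericVector x2, NumericVector y2, double rmax) {
  int n1 = x1.size(), n2 = x2.size();
  std::vector<int> ii, jj;
  std::vector<double> dd;
  if (n1 == 0 || n2 == 0 || rmax <= 0) {
    return List::create(_["i"] = IntegerVector(0), _["j"] = IntegerVector(0),
                        _["d"] = NumericVector(0));
  }
  double xmin = x2[0], ymin = y2[0], xmax = x2[0], ymax = y2[0];
  for (int k = 0; k < n2; k++) {
    xmin = std::min(xmin, x2[k]); xmax = std::max(xmax, x2[k]);
    ymin = std::min(ymin, y2[k]); ymax = std::max(ymax, y2[k]);
  }
  double cell = rmax;
  int ncx = std::max(1, (int)std::floor((xmax - xmin) / cell) + 1);
  int ncy = std::max(1, (int)std::floor((ymax - ymin) / cell) + 1);
  std::vector< std::vector<int> > buckets((size_t)ncx * ncy);
  for (int k = 0; k < n2; k++) {
    int cx = std::min(ncx - 1, std::max(0, (int)std::floor((x2[k] - xmin) / cell)));
    int cy = std::min(ncy - 1, std::max(0, (int)std::floor((y2[k] - ymin) / cell)));
    buckets[(size_t)cy * ncx + cx].push_back(k);
  }
  double r2 = rmax * rmax;
  for (int k = 0; k < n1; k++) {
    int cxk = (int)std::floor((x1[k] - xmin) / cell);
    int cyk = (int)std::floor((y1[k] - ymin) / cell);
    for (int dy = -1; dy <= 1; dy++) {
      int cy = cyk + dy;
      if (cy < 0 || cy >= ncy) continue;
      for (int dx = -1; dx <= 1; dx++) {
        int cx = cxk + dx;
        if (cx < 0 || cx >= ncx) continue;
        const std::vector<int>& b = buckets[(size_t)cy * ncx + cx];
        for (size_t m = 0; m < b.size(); m++) {
          int j = b[m];
          double ddx = x1[k] - x2[j], ddy = y1[k] - y2[j];
          double d2 = ddx * ddx + ddy * ddy;
          if (d2 <= r2) {
            ii.push_back(k + 1); jj.push_back(j + 1); dd.push_back(std::sqrt(d2));
          }
        }
      }
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj), _["d"] = wrap(dd));
}

// Epanechnikov kernel sum S(r_k) = sum_p w_p * K_h(r_k - d_p) on a uniform
// grid r_k = r0 + k*dr, k = 0..nr-1, with optional reflection at r = 0
// (adds K_h(r_k + d_p)) so no kernel mass leaks to negative distances.
// [[Rcpp::export]]
NumericVector cpp_kernel_sum(NumericVector d, NumericVector w, double r0,
                             double dr, int nr, double h, bool reflect) {
  NumericVector out(nr);
  int np = d.size();
  double c = 0.75 / h;
  for (int p = 0; p < np; p++) {
    double dp = d[p], wp = w[p];
    // direct term: grid indices with |r - dp| < h
    int k0 = (int)std::ceil((dp - h - r0) / dr);
    int k1 = (int)std::floor((dp + h - r0) / dr);
    if (k0 < 0) k0 = 0;
    if (k1 > nr - 1) k1 = nr - 1;
    for (int k = k0; k <= k1; k++) {
      double u = (r0 + k * dr - dp) / h;
      double kv = 1.0 - u * u;
      if (kv > 0) out[k] += wp * c * kv;
    }
    if (reflect) {
      // mirror term at -dp: indices with |r + dp| < h
      int m0 = (int)std::ceil((-dp - h - r0) / dr);
      int m1 = (int)std::floor((-dp + h - r0) / dr);
      if (m0 < 0) m0 = 0;
      if (m1 > nr - 1) m1 = nr - 1;
      for (int k = m0; k <= m1; k++) {
        double u = (r0 + k * dr + dp) / h;
        double kv = 1.0 - u * u;
        if (kv > 0) out[k] += wp * c * kv;
      }
    }
  }
  return out;
}

// Brute-force nearest neighbour (index and distance) per point.
// [[Rcpp::export]]
List cpp_nn(NumericVector x, NumericVector y) {
  int n = x.size();
  IntegerVector which(n);
  NumericVector dist(n);
  for (int i = 0; i < n; i++) {
    double best = R_PosInf;
    int bj = NA_INTEGER;
    for (int j = 0; j < n; j++) {
      if (j == i) continue;
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d2 = dx * dx + dy * dy;
      if (d2 < best) { best = d2; bj = j + 1; }
    }
    which[i] = bj;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["which"] = which, _["dist"] = dist);
}

static bool point_in_ring(double px, double py, const NumericVector& vx,
                          const NumericVector& vy) {
  int m = vx.size();
  bool inside = false;
  for (int i = 0, j = m - 1; i < m; j = i++) {
    double xi = vx[i], yi = vy[i], xj = vx[j], yj = vy[j];
    if (((yi > py) != (yj > py)) &&
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi))
      inside = !inside;
  }
  return inside;
}

// Even-odd point-in-polygon for many query points (boundary not special-cased;
// callers treat near-boundary points separately where it matters).
// [[Rcpp::export]]
LogicalVector cpp_in_poly(NumericVector px, NumericVector py,
                          NumericVector vx, NumericVector vy) {
  int n = px.size();
  LogicalVector out(n);
  for (int i = 0; i < n; i++) out[i] = point_in_ring(px[i], py[i], vx, vy);
  return out;
}

// Fixed-n Metropolis shift chain for pairwise-interaction Gibbs processes in
// a polygonal window. family: 0 = hard core (h = 0 below hc), 1 = soft core
// (log h(d) = -(sigma/d)^(2/kappa)). Optional log-linear trend bx*x + by*y
// enters the acceptance ratio. Proposals relocate one random point to a
// uniform draw from the window (rejection-sampled from the bbox).
// [[Rcpp::export]]
List cpp_gibbs_chain(NumericVector x0, NumericVector y0, NumericVector vx,
                     NumericVector vy, int family, double hc, double sc_sigma,
                     double sc_kappa, double bx, double by, int n_steps) {
  int n = x0.size();
  NumericVector x = clone(x0), y = clone(y0);
  double xmin = *std::min_element(vx.begin(), vx.end());
  double xmax = *std::max_element(vx.begin(), vx.end());
  double ymin = *std::min_element(vy.begin(), vy.end());
  double ymax = *std::max_element(vy.begin(), vy.end());
  double expo = (family == 1) ? 2.0 / sc_kappa : 0.0;
  GetRNGstate();
  for (int s = 0; s < n_steps; s++) {
    int i = (int)std::floor(unif_rand() * n);
    if (i >= n) i = n - 1;
    // propose uniform point in window
    double px, py;
    int guard = 0;
    do {
      px = xmin + unif_rand() * (xmax - xmin);
      py = ymin + unif_rand() * (ymax - ymin);
      guard++;
    } while (!point_in_ring(px, py, vx, vy) && guard < 10000);
    if (guard >= 10000) continue;
    double dlog = 0.0;
    bool reject = false;
    for (int j = 0; j < n && !reject; j++) {
      if (j == i) continue;
      double dxn = px - x[j], dyn = py - y[j];
      double dn = std::sqrt(dxn * dxn + dyn * dyn);
      double dxo = x[i] - x[j], dyo = y[i] - y[j];
      double dold = std::sqrt(dxo * dxo + dyo * dyo);
      if (family == 0) {
        if (dn < hc) reject = true;
      } else {
        double tn = (dn > 0) ? std::pow(sc_sigma / dn, expo) : R_PosInf;
        double told = (dold > 0) ? std::pow(sc_sigma / dold, expo) : R_PosInf;
        dlog += (std::isfinite(told) ? told : 1e300) -
                (std::isfinite(tn) ? tn : 1e300);
      }
    }
    if (reject) continue;
    dlog += bx * (px - x[i]) + by * (py - y[i]);
    if (dlog >= 0 || unif_rand() < std::exp(dlog)) {
      x[i] = px; y[i] = py;
    }
  }
  PutRNGstate();
  return List::create(_["x"] = x, _["y"] = y);
}
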