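#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Brute-force Delaunay triangulation by the empty-circumcircle criterion.
// Point sets here are small (tens of provisioning start points per
// subject), so the O(n^4) check is simple and fast enough; callers apply a
// tiny deterministic symbolic perturbation beforehand so cocircular
// configurations (e.g. rectangles) triangulate uniquely.
// Returns an integer matrix of 1-based vertex index triples together with
// each triangle's circumradius.

// [[Rcpp::export(name = ".delaunay_cpp")]]
List delaunay_cpp(NumericVector xs, NumericVector ys) {
  const int n = xs.size();
  std::vector<int> ia, ib, ic;
  std::vector<double> rad;
  for (int i = 0; i < n - 2; ++i)
    for (int j = i + 1; j < n - 1; ++j)
      for (int k = j + 1; k < n; ++k) {
        double ax = xs[i], ay = ys[i], bx = xs[j], by = ys[j],
               cx = xs[k], cy = ys[k];
        double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
        if (d == 0.0) continue;  // collinear
        double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by,
               c2 = cx * cx + cy * cy;
        double ux = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
        double uy = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
        double r2 = (ax - ux) * (ax - ux) + (ay - uy) * (ay - uy);
        bool empty = true;
        for (int m = 0; m < n; ++m) {
          if (m == i || m == j || m == k) continue;
          double dm = (xs[m] - ux) * (xs[m] - ux) + (ys[m] - uy) * (ys[m] - uy);
          if (dm < r2 * (1.0 - 1e-12)) { empty = false; break; }
        }
        if (empty) {
          ia.push_back(i + 1); ib.push_back(j + 1); ic.push_back(k + 1);
          rad.push_back(std::sqrt(r2));
        }
      }
  return List::create(_["i"] = wrap(ia), _["j"] = wrap(ib),
                      _["k"] = wrap(ic), _["circumradius"] = wrap(rad));
}
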