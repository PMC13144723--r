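#include <Rcpp.h>
using namespace Rcpp;

// Exact 1-D total-variation denoising (fused lasso signal approximator):
//   minimize 0.5 * sum_i (y_i - b_i)^2 + lambda * sum_i |b_{i+1} - b_i|
// Direct non-iterative algorithm (taut-string style with running bounds),
// O(n) typical. Returns the exact minimizer.
//
// [[Rcpp::export]]
NumericVector tv1d_denoise_cpp(NumericVector y, double lambda) {
  int n = y.size();
  NumericVector x(n);
  if (n == 0) return x;
  if (n == 1 || lambda <= 0) { for (int i = 0; i < n; i++) x[i] = y[i]; return x; }

  int k = 0, k0 = 0, kplus = 0, kminus = 0;
  double vmin = y[0] - lambda, vmax = y[0] + lambda;
  double umin = lambda, umax = -lambda;

  for (;;) {
    if (k == n - 1) {
      if (umin < 0) {            // negative jump necessary
        do { x[k0++] = vmin; } while (k0 <= kminus);
        vmin = y[k0];
        umin = lambda;
        kminus = k = k0;
        umax = vmin + umin - vmax;
      } else if (umax > 0) {     // positive jump necessary
        do { x[k0++] = vmax; } while (k0 <= kplus);
        vmax = y[k0];
        umax = -lambda;
        kplus = k = k0;
        umin = vmax + umax - vmin;
      } else {
        vmin += umin / (k - k0 + 1);
        for (int i = k0; i <= k; i++) x[i] = vmin;
        return x;
      }
      if (k == n - 1) { x[k] = vmin + umin; return x; }
      continue;
    }
    // accumulate
    if (y[k + 1] + umin < vmin - lambda) {          // negative jump
      do { x[k0++] = vmin; } while (k0 <= kminus);
      k = kplus = kminus = k0;
      vmin = y[k]; vmax = y[k] + 2 * lambda;
      umin = lambda; umax = -lambda;
    } else if (y[k + 1] + umax > vmax + lambda) {   // positive jump
      do { x[k0++] = vmax; } while (k0 <= kplus);
      k = kplus = kminus = k0;
      vmin = y[k] - 2 * lambda; vmax = y[k];
      umin = lambda; umax = -lambda;
    } else {                                        // no jump
      k++;
      umin += y[k] - vmin;
      umax += y[k] - vmax;
      if (umin >= lambda) {
        vmin += (umin - lambda) / (k - k0 + 1);
        umin = lambda;
        kminus = k;
      }
      if (umax <= -lambda) {
        vmax += (umax + lambda) / (k - k0 + 1);
        umax = -lambda;
        kplus = k;
      }
    }
  }
}

// Count self-crossings of a 2-D polyline: number of unordered segment pairs
// that intersect, excluding pairs sharing an endpoint (adjacent segments).
// Vectorized production path; tests compare against a plain double loop.
//
// [[Rcpp::export]]
int polyline_crossings_cpp(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n < 4) return 0;
  int m = n - 1; // segments
  int count = 0;
  for (int i = 0; i < m; i++) {
    double ax = x[i], ay = y[i], bx = x[i + 1], by = y[i + 1];
    for (int j = i + 2; j < m; j++) {
      double cx = x[j], cy = y[j], dx = x[j + 1], dy = y[j + 1];
      double d1 = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
      double d2 = (bx - ax) * (dy - ay) - (by - ay) * (dx - ax);
      double d3 = (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx);
      double d4 = (dx - cx) * (by - cy) - (dy - cy) * (bx - cx);
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
        count++;
    }
  }
  return count;
}
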