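#include <Rcpp.h>
using namespace Rcpp;

// Lower convex hull of (x, y), x strictly increasing. Returns indices of the
// hull vertices (0-based), always including both endpoints. Andrew's
// monotone-chain; collinear interior points are dropped.
static std::vector<int> lower_hull(const double* x, const double* y, int m) {
  std::vector<int> h;
  h.reserve(m);
  for (int i = 0; i < m; ++i) {
    while (h.size() >= 2) {
      int a = h[h.size() - 2], b = h[h.size() - 1];
      // keep b only if it lies strictly below the chord a -> i
      double cross = (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a]);
      if (cross <= 0) h.pop_back(); else break;
    }
    h.push_back(i);
  }
  return h;
}

static void hull_baseline(const double* x, const double* y, int m, double* out) {
  std::vector<int> h = lower_hull(x, y, m);
  int seg = 0;
  for (int i = 0; i < m; ++i) {
    while (seg + 1 < (int)h.size() - 1 && x[h[seg + 1]] <= x[i]) ++seg;
    int a = h[seg], b = h[seg + 1 < (int)h.size() ? seg + 1 : seg];
    if (a == b) { out[i] = y[a]; continue; }
    double t = (x[i] - x[a]) / (x[b] - x[a]);
    out[i] = y[a] + t * (y[b] - y[a]);
  }
  // hull vertices are exact anchors
  for (size_t k = 0; k < h.size(); ++k) out[h[k]] = y[h[k]];
}

// [[Rcpp::export(name = ".rubberband_cpp")]]
NumericVector rubberband_cpp(NumericVector axis, NumericVector values) {
  int m = axis.size();
  NumericVector out(m);
  hull_baseline(axis.begin(), values.begin(), m, out.begin());
  return out;
}

// Batch metrics over pixels: Y is n_pixels x m (segment values per pixel),
// axis length m. Each row is baseline-corrected by its rubber-band lower hull,
// then max, center of gravity and trapezoidal area are computed.
// Degenerate cog (zero corrected mass) is returned as NA and resolved in R.
// [[Rcpp::export(name = ".region_metrics_cpp")]]
NumericMatrix region_metrics_cpp(NumericMatrix Y, NumericVector axis) {
  int n = Y.nrow(), m = Y.ncol();
  NumericMatrix out(n, 3);
  std::vector<double> row(m), base(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) row[j] = Y(i, j);
    hull_baseline(axis.begin(), row.data(), m, base.data());
    double maxabs = 0;
    for (int j = 0; j < m; ++j)
      if (std::abs(row[j]) > maxabs) maxabs = std::abs(row[j]);
    double mx = 0, sA = 0, sxA = 0, area = 0;
    double prev = row[0] - base[0];
    if (prev < 0) prev = 0;
    sA = prev; sxA = axis[0] * prev; mx = prev;
    for (int j = 1; j < m; ++j) {
      double c = row[j] - base[j];
      if (c < 0) c = 0;
      if (c > mx) mx = c;
      sA += c;
      sxA += axis[j] * c;
      area += 0.5 * (c + prev) * (axis[j] - axis[j - 1]);
      prev = c;
    }
    // corrected mass indistinguishable from interpolation round-off counts
    // as zero: the center of gravity is then undefined (NA, resolved upstream)
    double tol = 1e-12 * m * (maxabs + 1.0);
    out(i, 0) = mx;
    out(i, 1) = sA > tol ? sxA / sA : NA_REAL;
    out(i, 2) = area;
  }
  return out;
}

// Majority filter on an integer label image. Background (0) never votes and
// is never overwritten. Ties keep the center pixel's label. Window odd.
// [[Rcpp::export(name = ".majority_filter_cpp")]]
IntegerMatrix majority_filter_cpp(IntegerMatrix mask, int window) {
  int H = mask.nrow(), W = mask.ncol(), r = window / 2;
  IntegerMatrix out(H, W);
  int maxlab = 0;
  for (int i = 0; i < H * W; ++i) if (mask[i] > maxlab) maxlab = mask[i];
  std::vector<int> votes(maxlab + 1);
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      int centre = mask(i, j);
      if (centre == 0) { out(i, j) = 0; continue; }
      std::fill(votes.begin(), votes.end(), 0);
      for (int di = -r; di <= r; ++di) {
        int ii = i + di;
        if (ii < 0 || ii >= H) continue;
        for (int dj = -r; dj <= r; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= W) continue;
          int v = mask(ii, jj);
          if (v > 0) ++votes[v];
        }
      }
      int best = centre, bestn = votes[centre];
      for (int v = 1; v <= maxlab; ++v)
        if (votes[v] > bestn) { best = v; bestn = votes[v]; }
      out(i, j) = best;
    }
  }
  return out;
}
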