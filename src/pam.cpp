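#include <Rcpp.h>
using namespace Rcpp;

// Total cost of a medoid set: sum over samples of the distance to the
// nearest medoid. d is the full n x n distance matrix (column-major).
static double medoid_cost(const NumericMatrix& d, const std::vector<int>& med) {
  const int n = d.nrow();
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (size_t m = 0; m < med.size(); ++m) {
      double v = d(i, med[m]);
      if (v < best) best = v;
    }
    total += best;
  }
  return total;
}

// nearest / second-nearest medoid distance (and nearest medoid position)
static void update_nearest(const NumericMatrix& d, const std::vector<int>& med,
                           std::vector<double>& d1, std::vector<int>& n1,
                           std::vector<double>& d2) {
  const int n = d.nrow();
  const int k = (int)med.size();
  for (int i = 0; i < n; ++i) {
    double b1 = R_PosInf, b2 = R_PosInf;
    int a1 = 0;
    for (int m = 0; m < k; ++m) {
      double v = d(i, med[m]);
      if (v < b1) { b2 = b1; b1 = v; a1 = m; }
      else if (v < b2) { b2 = v; }
    }
    d1[i] = b1; n1[i] = a1; d2[i] = b2;
  }
}

// Classic PAM: greedy BUILD seeding followed by best-improvement SWAP,
// accepting only strictly cost-decreasing swaps (deltas computed from the
// nearest/second-nearest decomposition). Fully deterministic: all ties
// break towards the lowest sample index (lowest medoid slot first in SWAP),
// and samples are assigned to the nearest medoid (ties to the lowest-index
// medoid).
// [[Rcpp::export(name = ".pam_core")]]
List pam_core(NumericMatrix d, int k) {
  const int n = d.nrow();
  if (k < 1 || k > n) stop("k must be in [1, n]");

  std::vector<bool> is_med(n, false);
  std::vector<int> med;
  med.reserve(k);

  // BUILD: first medoid minimizes total distance to all samples
  {
    double best = R_PosInf;
    int arg = 0;
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += d(i, j);
      if (s < best) { best = s; arg = j; }
    }
    med.push_back(arg);
    is_med[arg] = true;
  }
  std::vector<double> nearest(n);
  for (int i = 0; i < n; ++i) nearest[i] = d(i, med[0]);

  while ((int)med.size() < k) {
    double best_gain = -1.0;
    int arg = -1;
    for (int j = 0; j < n; ++j) {
      if (is_med[j]) continue;
      double gain = 0.0;
      for (int i = 0; i < n; ++i) {
        double diff = nearest[i] - d(i, j);
        if (diff > 0) gain += diff;
      }
      if (gain > best_gain) { best_gain = gain; arg = j; }
    }
    med.push_back(arg);
    is_med[arg] = true;
    for (int i = 0; i < n; ++i)
      if (d(i, arg) < nearest[i]) nearest[i] = d(i, arg);
  }

  double build_cost = medoid_cost(d, med);
  double cost = build_cost;

  // SWAP: repeat the best strictly cost-decreasing exchange of a medoid
  // with a non-medoid. For each candidate j the deltas for removing every
  // medoid are accumulated in one pass over the samples:
  //   i not served by m:  min(0, d(i,j) - d1[i])
  //   i served by m:      min(d(i,j), d2[i]) - d1[i]
  if (k < n && k >= 1) {
    std::vector<double> d1(n), d2(n);
    std::vector<int> n1(n);
    std::vector<double> delta(k);
    bool improved = true;
    while (improved) {
      improved = false;
      update_nearest(d, med, d1, n1, d2);
      double best_delta = -1e-12;
      int best_m = -1, best_j = -1;
      for (int j = 0; j < n; ++j) {
        if (is_med[j]) continue;
        double base = 0.0;
        std::fill(delta.begin(), delta.end(), 0.0);
        for (int i = 0; i < n; ++i) {
          double dij = d(i, j);
          double shared = dij < d1[i] ? dij - d1[i] : 0.0;
          base += shared;
          double own = (dij < d2[i] ? dij : d2[i]) - d1[i];
          delta[n1[i]] += own - shared;
        }
        for (int m = 0; m < k; ++m) {
          double dt = base + delta[m];
          if (dt < best_delta) { best_delta = dt; best_m = m; best_j = j; }
        }
      }
      if (best_m >= 0) {
        is_med[med[best_m]] = false;
        med[best_m] = best_j;
        is_med[best_j] = true;
        cost = medoid_cost(d, med);  // recompute: no float drift
        improved = true;
      }
    }
  }

  std::sort(med.begin(), med.end());

  // assignment: nearest medoid, ties to the lowest-index medoid
  IntegerVector assignment(n);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int arg = 0;
    for (int m = 0; m < k; ++m) {
      double v = d(i, med[m]);
      if (v < best) { best = v; arg = m; }
    }
    assignment[i] = arg + 1;
    total += best;
  }

  IntegerVector medoids(k);
  for (int m = 0; m < k; ++m) medoids[m] = med[m] + 1;

  return List::create(_["medoids"] = medoids,
                      _["assignment"] = assignment,
                      _["total_cost"] = total,
                      _["build_cost"] = build_cost);
}
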