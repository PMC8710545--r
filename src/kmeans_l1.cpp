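#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// L1 (Manhattan) k-means with k-means++ initialization and coordinate-wise
// median centroid updates.  Points are passed as COLUMNS (p x n matrix) so
// each point is contiguous in memory.  Uses R's RNG, so results are
// reproducible under set.seed() on the R side.

static inline double l1_dist(const double* x, const double* c, int p) {
  double d = 0.0;
  for (int j = 0; j < p; ++j) d += std::fabs(x[j] - c[j]);
  return d;
}

// Partial-distance variant: abandons (returning a value >= bound) once the
// running sum exceeds `bound`.  Used where only the minimum matters; the
// minimal distance itself is always computed exactly.
static inline double l1_dist_bounded(const double* x, const double* c, int p,
                                     double bound) {
  double d = 0.0;
  int j = 0;
  while (j < p) {
    const int stop = (j + 32 < p) ? j + 32 : p;
    for (; j < stop; ++j) d += std::fabs(x[j] - c[j]);
    if (d >= bound) return d;
  }
  return d;
}

static double col_median(std::vector<double>& v) {
  const size_t n = v.size();
  const size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + h);
    m = 0.5 * (m + lo);
  }
  return m;
}

// k-means++ seeding: first centroid uniform, then proportional to L1
// distance to the nearest chosen centroid.
static std::vector<std::vector<double> > kmeanspp(const double* X, int n, int p,
                                                  int K) {
  std::vector<std::vector<double> > cent;
  int first = (int)std::floor(unif_rand() * n);
  if (first >= n) first = n - 1;
  cent.push_back(std::vector<double>(X + (size_t)first * p,
                                     X + (size_t)(first + 1) * p));
  std::vector<double> dmin(n);
  for (int i = 0; i < n; ++i)
    dmin[i] = l1_dist(X + (size_t)i * p, cent[0].data(), p);
  for (int k = 1; k < K; ++k) {
    double tot = 0.0;
    for (int i = 0; i < n; ++i) tot += dmin[i];
    int pick;
    if (tot <= 0.0) {
      pick = (int)std::floor(unif_rand() * n);
      if (pick >= n) pick = n - 1;
    } else {
      double u = unif_rand() * tot, acc = 0.0;
      pick = n - 1;
      for (int i = 0; i < n; ++i) { acc += dmin[i]; if (acc >= u) { pick = i; break; } }
    }
    cent.push_back(std::vector<double>(X + (size_t)pick * p,
                                       X + (size_t)(pick + 1) * p));
    const double* ck = cent.back().data();
    for (int i = 0; i < n; ++i) {
      double d = l1_dist_bounded(X + (size_t)i * p, ck, p, dmin[i]);
      if (d < dmin[i]) dmin[i] = d;
    }
  }
  return cent;
}

// Xt: p x n matrix (points in columns).  Returns 1-based assignments, K x p
// centroid matrix, and total L1 inertia of the best of n_init replicates.
// [[Rcpp::export(name = ".kmeans_l1_cpp")]]
List kmeans_l1_cpp(NumericMatrix Xt, int K, int n_init, int max_iter) {
  const int p = Xt.nrow(), n = Xt.ncol();
  if (K < 1 || K > n) stop("K must lie in [1, n_points]");
  const double* X = REAL(Xt);
  RNGScope scope;

  IntegerVector best_assign(n);
  NumericMatrix best_cent(K, p);
  double best_inertia = R_PosInf;

  std::vector<int> assign(n), prev(n), counts(K);
  std::vector<double> dist_to_assigned(n);

  for (int init = 0; init < n_init; ++init) {
    std::vector<std::vector<double> > cent = kmeanspp(X, n, p, K);
    std::fill(prev.begin(), prev.end(), -1);
    for (int iter = 0; iter < max_iter; ++iter) {
      // assignment step
      for (int i = 0; i < n; ++i) {
        const double* xi = X + (size_t)i * p;
        double dbest = R_PosInf; int kbest = 0;
        for (int k = 0; k < K; ++k) {
          double d = l1_dist_bounded(xi, cent[k].data(), p, dbest);
          if (d < dbest) { dbest = d; kbest = k; }
        }
        assign[i] = kbest;
        dist_to_assigned[i] = dbest;
      }
      // empty clusters: re-seed at the point farthest (L1) from its centroid
      std::fill(counts.begin(), counts.end(), 0);
      for (int i = 0; i < n; ++i) counts[assign[i]]++;
      bool reseeded = false;
      for (int k = 0; k < K; ++k) {
        if (counts[k] == 0) {
          int far = 0; double dmax = -1.0;
          for (int i = 0; i < n; ++i)
            if (counts[assign[i]] > 1 && dist_to_assigned[i] > dmax) {
              dmax = dist_to_assigned[i]; far = i;
            }
          counts[assign[far]]--;
          assign[far] = k;
          counts[k] = 1;
          cent[k].assign(X + (size_t)far * p, X + (size_t)(far + 1) * p);
          reseeded = true;
        }
      }
      if (!reseeded && assign == prev) break;
      prev = assign;
      // update step: coordinate-wise medians
      std::vector<std::vector<int> > members(K);
      for (int i = 0; i < n; ++i) members[assign[i]].push_back(i);
      std::vector<double> col;
      for (int k = 0; k < K; ++k) {
        if (members[k].empty()) continue;
        col.resize(members[k].size());
        for (int j = 0; j < p; ++j) {
          for (size_t m = 0; m < members[k].size(); ++m)
            col[m] = X[(size_t)members[k][m] * p + j];
          cent[k][j] = col_median(col);
        }
      }
    }
    // final assignment and inertia under the final centroids
    double inertia = 0.0;
    for (int i = 0; i < n; ++i) {
      const double* xi = X + (size_t)i * p;
      double dbest = R_PosInf; int kbest = 0;
      for (int k = 0; k < K; ++k) {
        double d = l1_dist_bounded(xi, cent[k].data(), p, dbest);
        if (d < dbest) { dbest = d; kbest = k; }
      }
      assign[i] = kbest;
      inertia += dbest;
    }
    if (inertia < best_inertia) {
      best_inertia = inertia;
      for (int i = 0; i < n; ++i) best_assign[i] = assign[i] + 1;
      for (int k = 0; k < K; ++k)
        for (int j = 0; j < p; ++j) best_cent(k, j) = cent[k][j];
    }
  }
  return List::create(_["assignments"] = best_assign,
                      _["centroids"] = best_cent,
                      _["inertia"] = best_inertia);
}

// Per-row L1 distance from rows of X (n x p) to a centroid vector.
// [[Rcpp::export(name = ".l1_rowdist_cpp")]]
NumericVector l1_rowdist_cpp(NumericMatrix X, NumericVector c) {
  const int n = X.nrow(), p = X.ncol();
  if (c.size() != p) stop("dimension mismatch");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double d = 0.0;
    for (int j = 0; j < p; ++j) d += std::fabs(X(i, j) - c[j]);
    out[i] = d;
  }
  return out;
}
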