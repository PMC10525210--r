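#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// 1-nearest-neighbour by squared Euclidean distance; ties go to the lowest
// training-row index (strict '<' keeps the first minimum).
// [[Rcpp::export(name = ".knn1_cpp")]]
IntegerVector knn1_cpp(NumericMatrix train, IntegerVector y, NumericMatrix query) {
  const int n = train.nrow(), d = train.ncol(), m = query.nrow();
  if (query.ncol() != d) stop("dimension mismatch between train and query");
  IntegerVector out(m);
  for (int q = 0; q < m; ++q) {
    double best = R_PosInf;
    int best_i = -1;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int r = 0; r < d; ++r) {
        const double diff = train(i, r) - query(q, r);
        s += diff * diff;
        if (s >= best) break;
      }
      if (s < best) { best = s; best_i = i; }
    }
    out[q] = y[best_i];
  }
  return out;
}

// Deterministic multiclass ReliefF: one pass over ALL instances; k nearest
// hits and k nearest misses per other class under Manhattan distance on
// min-max scaled features; miss terms weighted by P(class)/(1 - P(own)).
// Distance ties break by ascending instance index. Final weights / n.
// [[Rcpp::export(name = ".relieff_cpp")]]
NumericVector relieff_cpp(NumericMatrix xs, IntegerVector y, int k_hits,
                          NumericVector priors) {
  const int n = xs.nrow(), d = xs.ncol();
  const int n_class = priors.size();
  NumericVector w(d);
  std::vector<std::pair<double, int> > ord(n);
  std::vector<double> acc(d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double dist = 0.0;
      for (int r = 0; r < d; ++r) dist += std::abs(xs(i, r) - xs(j, r));
      ord[j] = std::make_pair(dist, j);
    }
    std::sort(ord.begin(), ord.end());
    const int yi = y[i] - 1;
    for (int c = 0; c < n_class; ++c) {
      int taken = 0;
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int t = 0; t < n && taken < k_hits; ++t) {
        const int j = ord[t].second;
        if (j == i || y[j] - 1 != c) continue;
        for (int r = 0; r < d; ++r) acc[r] += std::abs(xs(i, r) - xs(j, r));
        ++taken;
      }
      if (taken == 0) continue;
      const double scale = (c == yi) ? -1.0
                                     : priors[c] / (1.0 - priors[yi]);
      for (int r = 0; r < d; ++r) w[r] += scale * acc[r] / taken;
    }
  }
  for (int r = 0; r < d; ++r) w[r] /= n;
  return w;
}

// Objective and softmax assignment probabilities for diagonal-weight NCA.
// dist_ij = sum_r w_r^2 |x_ir - x_jr|; p_ij = exp(-dist_ij) / sum_{l!=i};
// p_i = sum over same-class j of p_ij; objective = sum_i p_i - lambda*sum w^2.
// xt is sample-major (d contiguous values per sample). Exploits symmetry of
// the distance matrix; kmat/pvec are filled when non-null.
static double nca_objective(const std::vector<double>& xt, int n, int d,
                            const IntegerVector& y,
                            const std::vector<double>& w2, double lambda,
                            std::vector<double>* kmat,
                            std::vector<double>* srow,
                            std::vector<double>* pvec) {
  std::vector<double> kloc;
  std::vector<double>& K = kmat ? *kmat : kloc;
  K.assign((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    const double* xi = &xt[(size_t)i * d];
    for (int j = i + 1; j < n; ++j) {
      const double* xj = &xt[(size_t)j * d];
      double dist = 0.0;
      for (int r = 0; r < d; ++r) dist += w2[r] * std::abs(xi[r] - xj[r]);
      const double k = std::exp(-dist);
      K[(size_t)i * n + j] = k;
      K[(size_t)j * n + i] = k;
    }
  }
  double obj = 0.0;
  for (int i = 0; i < n; ++i) {
    double s = 0.0, same = 0.0;
    const double* Ki = &K[(size_t)i * n];
    for (int j = 0; j < n; ++j) s += Ki[j];
    for (int j = 0; j < n; ++j) if (y[j] == y[i] && j != i) same += Ki[j];
    const double pi = (s > 0.0) ? same / s : 0.0;
    if (srow) (*srow)[i] = s;
    if (pvec) (*pvec)[i] = pi;
    obj += pi;
  }
  double reg = 0.0;
  for (int r = 0; r < d; ++r) reg += w2[r];
  return obj - lambda * reg;
}

// Diagonal-weight NCA by full-batch gradient ascent with adaptive step
// control (shrink on objective decrease). Deterministic: initialization
// w = 1, no sampling.
// [[Rcpp::export(name = ".nca_cpp")]]
List nca_cpp(NumericMatrix x, IntegerVector y, double lambda, double alpha,
             int max_iter, double tol) {
  const int n = x.nrow(), d = x.ncol();
  std::vector<double> xt((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int r = 0; r < d; ++r) xt[(size_t)i * d + r] = x(i, r);
  std::vector<double> w(d, 1.0), w2(d, 1.0), w_new(d), w2_new(d);
  std::vector<double> K((size_t)n * n), srow(n), pvec(n), grad(d);
  double obj = nca_objective(xt, n, d, y, w2, lambda, &K, &srow, &pvec);
  const double obj0 = obj;
  int it = 0;
  for (; it < max_iter; ++it) {
    // grad_r = 2 w_r * [ sum_ij (p_i - same_ij) p_ij |x_ir-x_jr| ] - 2 lambda w_r,
    // folded over the symmetric pair (i,j),(j,i).
    std::fill(grad.begin(), grad.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double* xi = &xt[(size_t)i * d];
      const double* Ki = &K[(size_t)i * n];
      for (int j = i + 1; j < n; ++j) {
        const double k = Ki[j];
        if (k == 0.0) continue;
        const bool same = (y[j] == y[i]);
        const double pij = (srow[i] > 0.0) ? k / srow[i] : 0.0;
        const double pji = (srow[j] > 0.0) ? k / srow[j] : 0.0;
        const double coef = (pvec[i] - (same ? 1.0 : 0.0)) * pij
                          + (pvec[j] - (same ? 1.0 : 0.0)) * pji;
        if (coef == 0.0) continue;
        const double* xj = &xt[(size_t)j * d];
        for (int r = 0; r < d; ++r) grad[r] += coef * std::abs(xi[r] - xj[r]);
      }
    }
    for (int r = 0; r < d; ++r) grad[r] = 2.0 * w[r] * grad[r] - 2.0 * lambda * w[r];
    // shrink the step until the objective does not decrease
    double obj_new = -HUGE_VAL;
    int tries = 0;
    for (; tries < 30; ++tries) {
      for (int r = 0; r < d; ++r) {
        w_new[r] = w[r] + alpha * grad[r];
        w2_new[r] = w_new[r] * w_new[r];
      }
      obj_new = nca_objective(xt, n, d, y, w2_new, lambda, &K, &srow, &pvec);
      if (obj_new >= obj) break;
      alpha *= 0.5;
    }
    if (obj_new < obj) {  // no ascent at any step size: restore state and stop
      nca_objective(xt, n, d, y, w2, lambda, &K, &srow, &pvec);
      break;
    }
    const double improve = obj_new - obj;
    w.swap(w_new);
    w2.swap(w2_new);
    obj = obj_new;
    alpha *= 1.1;
    if (improve <= tol * (std::abs(obj) + 1e-12)) { ++it; break; }
  }
  NumericVector w_out(d), scores(d);
  for (int r = 0; r < d; ++r) { w_out[r] = w[r]; scores[r] = w2[r]; }
  return List::create(_["w"] = w_out, _["scores"] = scores,
                      _["objective"] = obj, _["objective0"] = obj0,
                      _["iterations"] = it);
}
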