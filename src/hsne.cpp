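// Random-walk machinery for the multi-scale landmark hierarchy and an
// exact landmark-weighted t-SNE. All stochastic routines take an explicit
// seed and use a private mt19937_64 stream, so results are reproducible
// independent of R's RNG state.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// sample a neighbor slot by weight from cumulative weights cw[0..k-1]
static inline int sample_slot(const double *cw, int k, double u) {
  const double total = cw[k - 1];
  if (total <= 0.0) return (int)(u * k) % k;  // degenerate: uniform
  const double target = u * total;
  int lo = 0, hi = k - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cw[mid] < target) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// Visit counts from n_walks random walks of length walk_len started at
// every node. neighbors: n x k (0-based), cumw: n x k cumulative weights.
// [[Rcpp::export]]
NumericVector cpp_walk_visits(IntegerMatrix neighbors, NumericMatrix cumw,
                              int n_walks, int walk_len, double seed) {
  const int n = neighbors.nrow(), k = neighbors.ncol();
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<double> visits(n, 0.0);
  std::vector<int> nb(n * k);
  std::vector<double> cw(n * k);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < k; ++j) {
      nb[i * k + j] = neighbors(i, j);
      cw[i * k + j] = cumw(i, j);
    }
  for (int start = 0; start < n; ++start) {
    for (int w = 0; w < n_walks; ++w) {
      int cur = start;
      for (int step = 0; step < walk_len; ++step) {
        int slot = sample_slot(&cw[cur * k], k, unif(rng));
        cur = nb[cur * k + slot];
        visits[cur] += 1.0;
      }
    }
  }
  return wrap(visits);
}

// Monte-Carlo area of influence: from every node run n_walks walks until a
// landmark is hit (or max_steps). Returns triplets (node, landmark, count).
// landmark_of[i] >= 0 gives the landmark id of node i, -1 otherwise.
// Landmark nodes absorb immediately into themselves.
// [[Rcpp::export]]
List cpp_absorb_walks(IntegerMatrix neighbors, NumericMatrix cumw,
                      IntegerVector landmark_of, int n_walks, int max_steps,
                      double seed) {
  const int n = neighbors.nrow(), k = neighbors.ncol();
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<int> nb(n * k);
  std::vector<double> cw(n * k);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < k; ++j) {
      nb[i * k + j] = neighbors(i, j);
      cw[i * k + j] = cumw(i, j);
    }
  std::vector<int> out_i, out_j;
  std::vector<double> out_x;
  std::unordered_map<int, int> counts;
  for (int start = 0; start < n; ++start) {
    if (landmark_of[start] >= 0) {
      out_i.push_back(start);
      out_j.push_back(landmark_of[start]);
      out_x.push_back((double)n_walks);
      continue;
    }
    counts.clear();
    for (int w = 0; w < n_walks; ++w) {
      int cur = start;
      for (int step = 0; step < max_steps; ++step) {
        int slot = sample_slot(&cw[cur * k], k, unif(rng));
        cur = nb[cur * k + slot];
        if (landmark_of[cur] >= 0) { counts[landmark_of[cur]] += 1; break; }
      }
    }
    for (auto &kv : counts) {
      out_i.push_back(start);
      out_j.push_back(kv.first);
      out_x.push_back((double)kv.second);
    }
  }
  return List::create(_["i"] = wrap(out_i), _["j"] = wrap(out_j),
                      _["x"] = wrap(out_x));
}

// Exact weighted t-SNE gradient descent on a dense joint probability
// matrix P (symmetric, sums to 1; point weights are already folded into
// P). Weights w give each point multiplicity semantics: a landmark of
// mass w behaves as w coincident points, scaling its contribution to the
// repulsive normalization Z = sum w_i w_j q_ij as well as to attraction.
// Deterministic given Y0. Standard schedule: early exaggeration for the
// first exag_iters iterations, momentum 0.5 then 0.8, adaptive gains.
// The O(n^2) kernel is hand-fused over the upper triangle to avoid
// allocating n x n temporaries each iteration.
// [[Rcpp::export]]
arma::mat cpp_tsne(const arma::mat &P, const arma::vec &w,
                   const arma::mat &Y0, int iters,
                   double exaggeration, int exag_iters, double eta) {
  const int n = Y0.n_rows;
  arma::mat Y = Y0;
  arma::mat dY(n, 2, arma::fill::zeros);
  arma::mat gains(n, 2, arma::fill::ones);
  arma::mat grad(n, 2);
  arma::mat num(n, n, arma::fill::zeros);
  const double min_gain = 0.01;
  double momentum = 0.5;
  std::vector<double> yx(n), yy(n);
  for (int it = 0; it < iters; ++it) {
    const double exag = (it < exag_iters) ? exaggeration : 1.0;
    if (it == 250) momentum = 0.8;
    for (int i = 0; i < n; ++i) { yx[i] = Y(i, 0); yy[i] = Y(i, 1); }
    double Z = 0.0;
    for (int i = 0; i < n; ++i) {
      const double xi = yx[i], yi = yy[i], wi = w[i];
      for (int j = i + 1; j < n; ++j) {
        const double dx = xi - yx[j], dy = yi - yy[j];
        const double q = 1.0 / (1.0 + dx * dx + dy * dy);
        num(j, i) = q;
        Z += 2.0 * wi * w[j] * q;
      }
    }
    if (Z < 1e-12) Z = 1e-12;
    const double invZ = 1.0 / Z;
    grad.zeros();
    for (int i = 0; i < n; ++i) {
      const double xi = yx[i], yi = yy[i], wi = w[i];
      double gix = 0.0, giy = 0.0;
      for (int j = i + 1; j < n; ++j) {
        const double q = num(j, i);
        const double pq = (exag * P(j, i) - wi * w[j] * q * invZ) * q;
        const double dx = xi - yx[j], dy = yi - yy[j];
        const double gx = 4.0 * pq * dx, gy = 4.0 * pq * dy;
        gix += gx; giy += gy;
        grad(j, 0) -= gx;
        grad(j, 1) -= gy;
      }
      grad(i, 0) += gix;
      grad(i, 1) += giy;
    }
    // per-point step = force / mass: a landmark acting as w coincident
    // points accumulates w-fold forces but each copy moves by the
    // per-copy gradient, keeping heavy landmarks stable
    for (int i = 0; i < n; ++i) for (int c = 0; c < 2; ++c) {
      const double g = grad(i, c) / w[i], v = dY(i, c);
      double gain = gains(i, c);
      gain = ((g > 0) != (v > 0)) ? gain + 0.2 : gain * 0.8;
      if (gain < min_gain) gain = min_gain;
      gains(i, c) = gain;
      dY(i, c) = momentum * v - eta * gain * g;
      Y(i, c) += dY(i, c);
    }
    Y.each_row() -= arma::mean(Y, 0);
  }
  return Y;
}
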