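#include <Rcpp.h>
using namespace Rcpp;

// log(1 + exp(x)) without overflow
static inline double softplus(double x) {
  if (x > 0) return x + std::log1p(std::exp(-x));
  return std::log1p(std::exp(x));
}

static inline double sigmoid(double x) {
  if (x >= 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// one alias-table draw; prob/alias are 0-based
static inline int alias_draw(const NumericVector &prob,
                             const IntegerVector &alias) {
  int m = prob.size();
  int k = (int)(unif_rand() * m);
  if (k >= m) k = m - 1;
  if (unif_rand() > prob[k]) k = alias[k];
  return k;
}

// LINE negative-sampling SGD. All RNG goes through R's generator so a single
// set.seed() upstream makes the run bitwise reproducible.
// [[Rcpp::export]]
List line_sgd_cpp(IntegerVector ei, IntegerVector ej, NumericVector eprob,
                  IntegerVector ealias, IntegerVector neg_nodes,
                  NumericVector nprob, IntegerVector nalias, int n_nodes,
                  int dim, bool second_order, double n_samples, int n_neg,
                  double lr, int n_loss_bins) {
  RNGScope scope;
  long long S = (long long)n_samples;

  NumericMatrix U(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < dim; ++d) U(i, d) = (unif_rand() - 0.5) / dim;
  // second order: separate context vectors, zero-initialized (LINE's scheme);
  // first order: contexts are the vertex vectors themselves (shared storage)
  NumericMatrix V = second_order ? NumericMatrix(n_nodes, dim) : U;

  NumericVector loss_sum(n_loss_bins);
  NumericVector loss_cnt(n_loss_bins);
  std::vector<double> err(dim);

  for (long long s = 0; s < S; ++s) {
    double frac = (double)s / (double)S;
    double lr_s = lr * (1.0 - 0.99 * frac);

    int e = alias_draw(eprob, ealias);
    int src = ei[e], dst = ej[e];
    if (unif_rand() < 0.5) std::swap(src, dst);

    std::fill(err.begin(), err.end(), 0.0);
    double sample_loss = 0.0;

    for (int t = 0; t <= n_neg; ++t) {
      int target;
      double label;
      if (t == 0) {
        target = dst;
        label = 1.0;
      } else {
        int tries = 0;
        do {
          target = neg_nodes[alias_draw(nprob, nalias)];
        } while ((target == dst || target == src) && ++tries < 10);
        label = 0.0;
      }
      double x = 0.0;
      for (int d = 0; d < dim; ++d) x += U(src, d) * V(target, d);
      sample_loss += (label > 0.5) ? softplus(-x) : softplus(x);
      double g = (label - sigmoid(x)) * lr_s;
      for (int d = 0; d < dim; ++d) {
        err[d] += g * V(target, d);
        V(target, d) += g * U(src, d);
      }
    }
    for (int d = 0; d < dim; ++d) U(src, d) += err[d];

    int b = (int)((double)s * n_loss_bins / (double)S);
    if (b >= n_loss_bins) b = n_loss_bins - 1;
    loss_sum[b] += sample_loss;
    loss_cnt[b] += 1.0;
  }

  NumericVector hist(n_loss_bins);
  for (int b = 0; b < n_loss_bins; ++b)
    hist[b] = loss_cnt[b] > 0 ? loss_sum[b] / loss_cnt[b] : NA_REAL;

  return List::create(_["embedding"] = U, _["context"] = V,
                      _["loss_history"] = hist);
}
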