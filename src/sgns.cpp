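#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Skip-gram with negative sampling trained by SGD over (center, context)
// pairs extracted from the walk corpus. Negatives are drawn from the
// unigram distribution raised to 0.75 via an alias table. Single-threaded;
// all randomness comes from R's RNG stream, so a set.seed() before the call
// makes training exactly reproducible.

static inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

struct Alias {
  std::vector<double> prob;
  std::vector<int> alias;
  void build(const std::vector<double> &p) {
    int k = p.size();
    prob.assign(k, 0.0); alias.assign(k, 0);
    std::vector<double> scaled(k);
    std::vector<int> small, large;
    for (int i = 0; i < k; ++i) {
      scaled[i] = p[i] * k;
      if (scaled[i] < 1.0) small.push_back(i); else large.push_back(i);
    }
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = scaled[s]; alias[s] = l;
      scaled[l] = (scaled[l] + scaled[s]) - 1.0;
      if (scaled[l] < 1.0) small.push_back(l); else large.push_back(l);
    }
    while (!large.empty()) { prob[large.back()] = 1.0; alias[large.back()] = large.back(); large.pop_back(); }
    while (!small.empty()) { prob[small.back()] = 1.0; alias[small.back()] = small.back(); small.pop_back(); }
  }
  inline int draw() const {
    int k = prob.size();
    int j = (int)(unif_rand() * k);
    if (j >= k) j = k - 1;
    return (unif_rand() < prob[j]) ? j : alias[j];
  }
};

// walks: list of integer vectors with 1-based node indices in [1, n_nodes]
// [[Rcpp::export]]
List cpp_train_sgns(List walks, int n_nodes, int dim, int window,
                    int negatives, int epochs, double lr0) {
  // unigram counts -> smoothed noise distribution
  std::vector<double> counts(n_nodes, 0.0);
  R_xlen_t n_walks = walks.size();
  double total_pairs_d = 0.0;
  for (R_xlen_t w = 0; w < n_walks; ++w) {
    IntegerVector wk = walks[w];
    int L = wk.size();
    for (int i = 0; i < L; ++i) counts[wk[i] - 1] += 1.0;
    for (int i = 0; i < L; ++i) {
      int lo = std::max(0, i - window), hi = std::min(L - 1, i + window);
      total_pairs_d += (hi - lo);  // contexts excluding the center itself
    }
  }
  std::vector<double> noise(n_nodes);
  double z = 0.0;
  for (int i = 0; i < n_nodes; ++i) { noise[i] = std::pow(counts[i], 0.75); z += noise[i]; }
  for (int i = 0; i < n_nodes; ++i) noise[i] /= z;
  Alias noise_tab;
  noise_tab.build(noise);

  // vectors stored contiguously per node: node i occupies [i*dim, (i+1)*dim)
  std::vector<double> W(static_cast<size_t>(n_nodes) * dim);  // center vectors
  std::vector<double> C(static_cast<size_t>(n_nodes) * dim, 0.0);  // context
  double init = 0.5 / dim;
  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < dim; ++d)
      W[static_cast<size_t>(i) * dim + d] = (unif_rand() * 2.0 - 1.0) * init;

  double total_updates = total_pairs_d * epochs;
  if (total_updates < 1.0) total_updates = 1.0;
  double lr_min = lr0 * 0.01;
  double processed = 0.0;
  NumericVector epoch_loss(epochs);
  std::vector<double> grad_c(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    double loss_sum = 0.0;
    double n_pairs = 0.0;
    for (R_xlen_t w = 0; w < n_walks; ++w) {
      IntegerVector wk = walks[w];
      int L = wk.size();
      for (int i = 0; i < L; ++i) {
        int center = wk[i] - 1;
        int lo = std::max(0, i - window), hi = std::min(L - 1, i + window);
        double *wc = &W[static_cast<size_t>(center) * dim];
        for (int j = lo; j <= hi; ++j) {
          if (j == i) continue;
          int ctx = wk[j] - 1;
          double lr = lr0 * (1.0 - processed / total_updates);
          if (lr < lr_min) lr = lr_min;
          processed += 1.0;
          std::fill(grad_c.begin(), grad_c.end(), 0.0);
          double pair_loss = 0.0;
          // positive pair
          {
            double *vc = &C[static_cast<size_t>(ctx) * dim];
            double s = 0.0;
            for (int d = 0; d < dim; ++d) s += wc[d] * vc[d];
            double sig = sigmoid(s);
            pair_loss -= std::log(std::max(sig, 1e-12));
            double g = lr * (1.0 - sig);
            for (int d = 0; d < dim; ++d) {
              grad_c[d] += g * vc[d];
              vc[d] += g * wc[d];
            }
          }
          // negatives
          for (int k = 0; k < negatives; ++k) {
            int neg = noise_tab.draw();
            if (neg == ctx) continue;
            double *vn = &C[static_cast<size_t>(neg) * dim];
            double s = 0.0;
            for (int d = 0; d < dim; ++d) s += wc[d] * vn[d];
            double sig = sigmoid(s);
            pair_loss -= std::log(std::max(1.0 - sig, 1e-12));
            double g = -lr * sig;
            for (int d = 0; d < dim; ++d) {
              grad_c[d] += g * vn[d];
              vn[d] += g * wc[d];
            }
          }
          for (int d = 0; d < dim; ++d) wc[d] += grad_c[d];
          loss_sum += pair_loss;
          n_pairs += 1.0;
        }
      }
    }
    epoch_loss[ep] = (n_pairs > 0) ? loss_sum / n_pairs : 0.0;
  }
  NumericMatrix Wout(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < dim; ++d)
      Wout(i, d) = W[static_cast<size_t>(i) * dim + d];
  return List::create(_["vectors"] = Wout, _["epoch_loss"] = epoch_loss,
                      _["n_pairs_per_epoch"] = total_pairs_d);
}
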