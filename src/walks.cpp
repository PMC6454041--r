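#include <Rcpp.h>
using namespace Rcpp;

// Adjacency is CSR over 1-based node indices: neighbours of node i (1-based)
// are adj_idx[adj_ptr[i-1] .. adj_ptr[i]-1], sorted ascending, with weights
// adj_wt in the same positions. All sampling uses R's RNG stream so results
// are reproducible via set.seed().

static inline bool sorted_contains(const int *v, int lo, int hi, int x) {
  while (lo < hi) {
    int mid = lo + (hi - lo) / 2;
    if (v[mid] == x) return true;
    if (v[mid] < x) lo = mid + 1; else hi = mid;
  }
  return false;
}

// sample index in [0, k) proportional to mass[0..k)
static inline int sample_mass(const double *mass, int k, double total) {
  double u = unif_rand() * total;
  double acc = 0.0;
  for (int i = 0; i < k; ++i) {
    acc += mass[i];
    if (u <= acc) return i;
  }
  return k - 1;
}

// [[Rcpp::export]]
List cpp_generate_walks(IntegerVector adj_ptr, IntegerVector adj_idx,
                        NumericVector adj_wt, int walk_length,
                        int walks_per_node, double p, double q) {
  int n = adj_ptr.size() - 1;
  const int *ptr = adj_ptr.begin();
  const int *idx = adj_idx.begin();
  const double *wt = adj_wt.begin();
  List out(static_cast<R_xlen_t>(n) * walks_per_node);
  std::vector<double> mass;
  std::vector<int> walk;
  R_xlen_t w_i = 0;
  for (int u = 1; u <= n; ++u) {
    for (int r = 0; r < walks_per_node; ++r) {
      walk.clear();
      walk.push_back(u);
      int deg_u = ptr[u] - ptr[u - 1];
      if (deg_u > 0) {
        int prev = 0, cur = u;
        while ((int)walk.size() < walk_length) {
          int lo = ptr[cur - 1], hi = ptr[cur];
          int deg = hi - lo;
          if (deg == 0) break;  // unreachable in a simple undirected graph after step 1
          int nxt;
          if (prev == 0) {
            // first-order step: proportional to edge weight
            mass.assign(wt + lo, wt + hi);
          } else {
            mass.resize(deg);
            int plo = ptr[prev - 1], phi = ptr[prev];
            for (int j = 0; j < deg; ++j) {
              int x = idx[lo + j];
              double a;
              if (x == prev) a = 1.0 / p;
              else if (sorted_contains(idx, plo, phi, x)) a = 1.0;
              else a = 1.0 / q;
              mass[j] = a * wt[lo + j];
            }
          }
          double total = 0.0;
          for (double m : mass) total += m;
          nxt = idx[lo + sample_mass(mass.data(), deg, total)];
          walk.push_back(nxt);
          prev = cur;
          cur = nxt;
        }
      }
      out[w_i++] = IntegerVector(walk.begin(), walk.end());
    }
  }
  return out;
}

// ---- Vose alias method ------------------------------------------------

// [[Rcpp::export]]
List cpp_alias_build(NumericVector probs) {
  int k = probs.size();
  NumericVector prob(k);
  IntegerVector alias(k);
  std::vector<double> scaled(k);
  std::vector<int> small, large;
  for (int i = 0; i < k; ++i) {
    scaled[i] = probs[i] * k;
    if (scaled[i] < 1.0) small.push_back(i); else large.push_back(i);
  }
  while (!small.empty() && !large.empty()) {
    int s = small.back(); small.pop_back();
    int l = large.back(); large.pop_back();
    prob[s] = scaled[s];
    alias[s] = l + 1;  // 1-based
    scaled[l] = (scaled[l] + scaled[s]) - 1.0;
    if (scaled[l] < 1.0) small.push_back(l); else large.push_back(l);
  }
  while (!large.empty()) { prob[large.back()] = 1.0; alias[large.back()] = large.back() + 1; large.pop_back(); }
  while (!small.empty()) { prob[small.back()] = 1.0; alias[small.back()] = small.back() + 1; small.pop_back(); }
  return List::create(_["prob"] = prob, _["alias"] = alias);
}

// [[Rcpp::export]]
IntegerVector cpp_alias_sample(NumericVector prob, IntegerVector alias, int n) {
  int k = prob.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int j = (int)(unif_rand() * k);
    if (j >= k) j = k - 1;
    out[i] = (unif_rand() < prob[j]) ? (j + 1) : alias[j];
  }
  return out;
}
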