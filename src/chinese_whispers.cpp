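#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Chinese whispers label propagation on an undirected weighted graph.
// Nodes adopt the label with the maximal summed edge weight among their
// neighbors; node order is reshuffled every iteration and ties are broken
// uniformly at random. All randomness comes from R's RNG so results are
// reproducible under set.seed(). Isolated nodes keep their own label.
//
// edges_i / edges_j are 1-based node indices, one entry per undirected edge.
// [[Rcpp::export(name = ".cw_propagate")]]
IntegerVector cw_propagate(int n, IntegerVector edges_i, IntegerVector edges_j,
                           NumericVector w, int max_iter) {
  size_t m = edges_i.size();
  // build CSR adjacency (both directions)
  std::vector<int> deg(n, 0);
  for (size_t e = 0; e < m; ++e) {
    ++deg[edges_i[e] - 1];
    ++deg[edges_j[e] - 1];
  }
  std::vector<size_t> ptr(n + 1, 0);
  for (int v = 0; v < n; ++v) ptr[v + 1] = ptr[v] + deg[v];
  std::vector<int> adj(2 * m);
  std::vector<double> aw(2 * m);
  std::vector<size_t> fill(ptr.begin(), ptr.end() - 1);
  for (size_t e = 0; e < m; ++e) {
    int a = edges_i[e] - 1, b = edges_j[e] - 1;
    adj[fill[a]] = b; aw[fill[a]++] = w[e];
    adj[fill[b]] = a; aw[fill[b]++] = w[e];
  }

  std::vector<int> label(n);
  for (int v = 0; v < n; ++v) label[v] = v;
  std::vector<double> score(n, 0.0);
  std::vector<char> seen(n, 0);
  std::vector<int> touched;
  touched.reserve(64);
  std::vector<int> order(n);
  for (int v = 0; v < n; ++v) order[v] = v;

  RNGScope scope;
  for (int it = 0; it < max_iter; ++it) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int v = n - 1; v > 0; --v) {
      int j = (int)(unif_rand() * (v + 1));
      if (j > v) j = v;
      std::swap(order[v], order[j]);
    }
    int changes = 0;
    for (int oi = 0; oi < n; ++oi) {
      int v = order[oi];
      if (ptr[v] == ptr[v + 1]) continue;
      touched.clear();
      for (size_t k = ptr[v]; k < ptr[v + 1]; ++k) {
        int lab = label[adj[k]];
        if (!seen[lab]) { seen[lab] = 1; touched.push_back(lab); }
        score[lab] += aw[k];
      }
      // pick max, random tie-break (reservoir)
      double best = -1.0;
      int bestlab = label[v];
      int nties = 0;
      for (int lab : touched) {
        double s = score[lab];
        if (s > best) {
          best = s; bestlab = lab; nties = 1;
        } else if (s == best) {
          ++nties;
          if (unif_rand() < 1.0 / nties) bestlab = lab;
        }
      }
      for (int lab : touched) { score[lab] = 0.0; seen[lab] = 0; }
      if (bestlab != label[v]) {
        label[v] = bestlab;
        ++changes;
      }
    }
    if (changes == 0) break;
  }
  IntegerVector out(n);
  for (int v = 0; v < n; ++v) out[v] = label[v] + 1;
  return out;
}
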