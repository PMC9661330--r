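#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Max-statistic of the permutation null: for each permutation (column of
// the t matrix), find sign-consistent connected clusters among the
// suprathreshold voxels and return the largest |sum of t| over clusters.
// Adjacency is a list of 1-based neighbour index vectors per voxel.
// [[Rcpp::export]]
NumericVector null_max_cluster_sums(NumericMatrix t, double thr, List adj) {
  const int V = t.nrow(), P = t.ncol();
  std::vector< std::vector<int> > nb(V);
  for (int v = 0; v < V; ++v) {
    IntegerVector a = adj[v];
    nb[v].assign(a.begin(), a.end());
  }
  NumericVector out(P);
  std::vector<int> state(V, -1);   // id of the permutation that visited v
  std::vector<int> stack;
  stack.reserve(V);
  for (int p = 0; p < P; ++p) {
    double best = 0.0;
    for (int s = 0; s < V; ++s) {
      const double ts = t(s, p);
      if (state[s] == p || (ts < thr && ts > -thr)) continue;
      const bool pos = ts >= thr;
      double sum = 0.0;
      stack.clear();
      stack.push_back(s);
      state[s] = p;
      while (!stack.empty()) {
        const int v = stack.back();
        stack.pop_back();
        sum += t(v, p);
        for (size_t k = 0; k < nb[v].size(); ++k) {
          const int u = nb[v][k] - 1;
          if (state[u] == p) continue;
          const double tu = t(u, p);
          if (pos ? (tu >= thr) : (tu <= -thr)) {
            state[u] = p;
            stack.push_back(u);
          }
        }
      }
      if (std::fabs(sum) > best) best = std::fabs(sum);
    }
    out[p] = best;
  }
  return out;
}
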