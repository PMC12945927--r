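#include <Rcpp.h>
using namespace Rcpp;

// Maslov-Sneppen double-edge swaps on an undirected edge list.
// Edge weights are carried by row index: endpoints are rewired in place so
// each weight travels with its (relabelled) edge. Swaps creating self-loops
// or multi-edges are rejected; the degree sequence is invariant.
//
// edges: E x 2 integer matrix, 1-based node indices.
// Uses R's RNG so results respect set.seed().
// [[Rcpp::export]]
IntegerMatrix rewire_edges_cpp(IntegerMatrix edges, int n_nodes,
                               int n_attempts) {
  int ne = edges.nrow();
  if (ne < 2) return edges;
  IntegerMatrix out = clone(edges);
  // adjacency presence, 0-based flat index
  std::vector<char> adj((size_t)n_nodes * n_nodes, 0);
  for (int e = 0; e < ne; ++e) {
    int a = out(e, 0) - 1, b = out(e, 1) - 1;
    adj[(size_t)a * n_nodes + b] = 1;
    adj[(size_t)b * n_nodes + a] = 1;
  }
  for (int it = 0; it < n_attempts; ++it) {
    int e1 = (int)(unif_rand() * ne);
    int e2 = (int)(unif_rand() * ne);
    if (e1 == e2) continue;
    int a = out(e1, 0) - 1, b = out(e1, 1) - 1;
    int c = out(e2, 0) - 1, d = out(e2, 1) - 1;
    if (unif_rand() < 0.5) { int tmp = c; c = d; d = tmp; }
    // propose (a,b),(c,d) -> (a,d),(c,b)
    if (a == d || c == b) continue;
    if (a == c || b == d) continue; // would duplicate the other new edge
    if (adj[(size_t)a * n_nodes + d] || adj[(size_t)c * n_nodes + b])
      continue;
    adj[(size_t)a * n_nodes + b] = adj[(size_t)b * n_nodes + a] = 0;
    adj[(size_t)c * n_nodes + d] = adj[(size_t)d * n_nodes + c] = 0;
    adj[(size_t)a * n_nodes + d] = adj[(size_t)d * n_nodes + a] = 1;
    adj[(size_t)c * n_nodes + b] = adj[(size_t)b * n_nodes + c] = 1;
    out(e1, 0) = a + 1;
    out(e1, 1) = d + 1;
    out(e2, 0) = c + 1;
    out(e2, 1) = b + 1;
  }
  return out;
}
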