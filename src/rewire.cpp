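#include <Rcpp.h>
using namespace Rcpp;

// Maslov-Sneppen double-edge swaps on an undirected simple graph.
// Edges are given as 1-based endpoint vectors (i < j) with weights; weights
// travel with their edge. Degree sequence is preserved exactly. Uses R's RNG
// so seeding happens on the R side.
//
// [[Rcpp::export(name = ".rewireEdgesCpp")]]
List rewireEdgesCpp(IntegerVector ei, IntegerVector ej, NumericVector w,
                    int nNodes, int nAttempts) {
  int K = ei.size();
  std::vector<int> a(K), b(K);
  std::vector<char> adj((size_t)nNodes * nNodes, 0);
  for (int e = 0; e < K; ++e) {
    a[e] = ei[e] - 1;
    b[e] = ej[e] - 1;
    adj[(size_t)a[e] * nNodes + b[e]] = 1;
    adj[(size_t)b[e] * nNodes + a[e]] = 1;
  }
  int done = 0;
  for (int it = 0; it < nAttempts; ++it) {
    int e1 = (int)(unif_rand() * K);
    int e2 = (int)(unif_rand() * K);
    if (e1 == e2) continue;
    int x1 = a[e1], y1 = b[e1];
    int x2 = a[e2], y2 = b[e2];
    if (unif_rand() < 0.5) std::swap(x2, y2);
    // proposed: (x1, y2) and (x2, y1)
    if (x1 == y2 || x2 == y1 || x1 == x2 || y1 == y2) continue;
    if (adj[(size_t)x1 * nNodes + y2] || adj[(size_t)x2 * nNodes + y1])
      continue;
    adj[(size_t)x1 * nNodes + y1] = 0;
    adj[(size_t)y1 * nNodes + x1] = 0;
    adj[(size_t)x2 * nNodes + y2] = 0;
    adj[(size_t)y2 * nNodes + x2] = 0;
    adj[(size_t)x1 * nNodes + y2] = 1;
    adj[(size_t)y2 * nNodes + x1] = 1;
    adj[(size_t)x2 * nNodes + y1] = 1;
    adj[(size_t)y1 * nNodes + x2] = 1;
    a[e1] = x1; b[e1] = y2;
    a[e2] = x2; b[e2] = y1;
    ++done;
  }
  IntegerVector oi(K), oj(K);
  for (int e = 0; e < K; ++e) {
    oi[e] = std::min(a[e], b[e]) + 1;
    oj[e] = std::max(a[e], b[e]) + 1;
  }
  return List::create(_["i"] = oi, _["j"] = oj, _["w"] = w,
                      _["nSwaps"] = done);
}
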