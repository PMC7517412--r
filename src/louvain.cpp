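#include <Rcpp.h>
using namespace Rcpp;

// One level of Louvain local moving on a dense weighted adjacency matrix.
// W: symmetric, non-negative, self-loop weights on the diagonal allowed
//    (they arise from aggregation and stay with their node).
// order: 1-based node visiting order, reused across sweeps; supplying it
//    from R keeps all randomness in R's RNG stream.
// Returns a 1-based community membership vector (ids not contiguous).
// [[Rcpp::export(name = ".louvain_local_move")]]
IntegerVector louvain_local_move(NumericMatrix W, IntegerVector order) {
  const int n = W.nrow();
  std::vector<int> comm(n);
  std::vector<double> k(n, 0.0), tot(n, 0.0);
  double m2 = 0.0;
  for (int i = 0; i < n; ++i) {
    comm[i] = i;
    for (int j = 0; j < n; ++j) k[i] += W(i, j);
    tot[i] = k[i];
    m2 += k[i];
  }
  if (m2 <= 0.0) return IntegerVector(comm.begin(), comm.end());

  std::vector<double> wcomm(n, 0.0);
  std::vector<int> touched;
  touched.reserve(n);
  bool moved = true;
  int sweeps = 0;
  while (moved && sweeps < 1000) {
    moved = false;
    ++sweeps;
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi] - 1;
      int ci = comm[i];
      // weights from i to each neighbouring community (self-loop excluded:
      // it travels with i and cancels in the comparison)
      touched.clear();
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double w = W(i, j);
        if (w <= 0.0) continue;
        int cj = comm[j];
        if (wcomm[cj] == 0.0) touched.push_back(cj);
        wcomm[cj] += w;
      }
      tot[ci] -= k[i];
      double own = wcomm[ci] - k[i] * tot[ci] / m2;
      double best = own;
      int best_c = ci;
      for (size_t t = 0; t < touched.size(); ++t) {
        int c = touched[t];
        if (c == ci) continue;
        double gain = wcomm[c] - k[i] * tot[c] / m2;
        if (gain > best + 1e-12 ||
            (gain > best - 1e-12 && c < best_c && gain > own + 1e-12)) {
          best = gain;
          best_c = c;
        }
      }
      tot[best_c] += k[i];
      if (best_c != ci) {
        comm[i] = best_c;
        moved = true;
      }
      for (size_t t = 0; t < touched.size(); ++t) wcomm[touched[t]] = 0.0;
      wcomm[ci] = 0.0;
    }
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = comm[i] + 1;
  return out;
}
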