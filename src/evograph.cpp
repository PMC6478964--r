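#include <Rcpp.h>
#include <cstdint>
#include <functional>
#include <vector>
using namespace Rcpp;

typedef unsigned __int128 u128;
typedef long long i64;

static i64 gcd_ll(i64 a, i64 b) {
  while (b) { i64 t = a % b; a = b; b = t; }
  return a;
}

// Number of unlabeled simple graphs on n nodes via the cycle index of the
// pair action of S_n: g_n = (1/n!) * sum over cycle types of
//   (#permutations of that type) * 2^(#cycles of the induced pair permutation).
// The sum reaches n! * g_n (~4e16 already at n = 11), so it is accumulated in
// 128-bit integers and divided exactly at the end.
static i64 unlabeled_graph_count(int n) {
  u128 nfact = 1;
  for (int i = 2; i <= n; i++) nfact *= (u128)i;
  u128 total = 0;
  std::vector<int> parts;
  std::function<void(int, int)> rec = [&](int rem, int maxp) {
    if (rem == 0) {
      int m = (int)parts.size();
      // permutations of this cycle type: n! / (prod k^{a_k} * prod a_k!)
      u128 denom = 1;
      for (int i = 0; i < m;) {
        int j = i;
        while (j < m && parts[j] == parts[i]) j++;
        int mult = j - i, len = parts[i];
        for (int t = 0; t < mult; t++) denom *= (u128)len;
        for (int t = 2; t <= mult; t++) denom *= (u128)t;
        i = j;
      }
      // cycles of the induced action on unordered pairs
      long c2 = 0;
      for (int i = 0; i < m; i++) {
        c2 += parts[i] / 2;
        for (int j = i + 1; j < m; j++) c2 += (long)gcd_ll(parts[i], parts[j]);
      }
      u128 term = nfact / denom;
      term <<= c2;
      total += term;
      return;
    }
    for (int p = std::min(rem, maxp); p >= 1; p--) {
      parts.push_back(p);
      rec(rem - p, p);
      parts.pop_back();
    }
  };
  rec(n, n);
  return (i64)(total / nfact);
}

// Counts of unlabeled simple graphs and connected unlabeled simple graphs for
// sizes 1..n. Connected counts obtained from the inverse Euler transform:
//   b_k = k*g_k - sum_{j<k} b_j g_{k-j},  b_k = sum_{d|k} d*c_d.
// All arithmetic is exact in 64-bit integers for n <= 13.
// [[Rcpp::export]]
NumericMatrix graph_counts_cpp(int n) {
  if (n < 1) stop("n must be >= 1");
  if (n > 13) stop("exact counts supported up to n = 13");
  std::vector<i64> g(n + 1, 0), b(n + 1, 0), c(n + 1, 0);
  g[0] = 1;
  for (int k = 1; k <= n; k++) g[k] = unlabeled_graph_count(k);
  for (int k = 1; k <= n; k++) {
    i64 s = 0;
    for (int j = 1; j < k; j++) s += b[j] * g[k - j];
    b[k] = (i64)k * g[k] - s;
    i64 t = 0;
    for (int d = 1; d < k; d++)
      if (k % d == 0) t += (i64)d * c[d];
    c[k] = (b[k] - t) / k;
  }
  NumericMatrix out(n, 2);
  for (int k = 1; k <= n; k++) {
    out(k - 1, 0) = (double)g[k];
    out(k - 1, 1) = (double)c[k];
  }
  colnames(out) = CharacterVector::create("all", "connected");
  return out;
}

// Monte Carlo Moran process on a graph given as a 0-based adjacency list.
// rule: 0 = Bd, 1 = dB. Every elementary update counts one step, including
// self-replacements. Uses R's RNG stream.
// [[Rcpp::export]]
List moran_sim_cpp(List adj, double r, int rule, int reps, double max_steps) {
  int n = adj.size();
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; i++) nb[i] = as<std::vector<int>>(adj[i]);
  int n_fixed = 0;
  double t_sum = 0, t_sumsq = 0;
  for (int rep = 0; rep < reps; rep++) {
    std::vector<char> mut(n, 0);
    int start = (int)(unif_rand() * n);
    if (start >= n) start = n - 1;
    mut[start] = 1;
    int nm = 1;
    double steps = 0;
    while (nm > 0 && nm < n) {
      steps += 1;
      if (steps > max_steps) stop("simulation exceeded max_steps");
      if (rule == 0) {  // Birth-death
        double F = r * nm + (n - nm);
        double u = unif_rand() * F;
        int repro = 0;
        if (u < r * nm) {
          int idx = (int)(u / r);
          if (idx >= nm) idx = nm - 1;
          int cnt = 0;
          for (int i = 0; i < n; i++)
            if (mut[i]) { if (cnt == idx) { repro = i; break; } cnt++; }
        } else {
          int idx = (int)(u - r * nm);
          if (idx >= n - nm) idx = n - nm - 1;
          int cnt = 0;
          for (int i = 0; i < n; i++)
            if (!mut[i]) { if (cnt == idx) { repro = i; break; } cnt++; }
        }
        const std::vector<int>& nbr = nb[repro];
        int tgt = nbr[(int)(unif_rand() * nbr.size()) % (int)nbr.size()];
        if (mut[tgt] != mut[repro]) {
          if (mut[repro]) { mut[tgt] = 1; nm++; } else { mut[tgt] = 0; nm--; }
        }
      } else {  // death-Birth
        int dead = (int)(unif_rand() * n);
        if (dead >= n) dead = n - 1;
        const std::vector<int>& nbr = nb[dead];
        double W = 0;
        for (int x : nbr) W += mut[x] ? r : 1.0;
        double u = unif_rand() * W;
        int parent = nbr[0];
        for (int x : nbr) {
          u -= mut[x] ? r : 1.0;
          if (u <= 0) { parent = x; break; }
        }
        if (mut[dead] != mut[parent]) {
          if (mut[parent]) { mut[dead] = 1; nm++; } else { mut[dead] = 0; nm--; }
        }
      }
    }
    if (nm == n) {
      n_fixed++;
      t_sum += steps;
      t_sumsq += steps * steps;
    }
  }
  return List::create(_["n_fixed"] = n_fixed, _["t_sum"] = t_sum,
                      _["t_sumsq"] = t_sumsq);
}

// Row-wise connectivity of graphs encoded as edge indicator vectors over the
// column-major upper triangle (pairs given 1-based). Bitmask BFS; n <= 31.
// [[Rcpp::export]]
LogicalVector connected_rows_cpp(LogicalMatrix bits, IntegerMatrix pairs, int n) {
  if (n < 1 || n > 31) stop("n out of range");
  int m = bits.nrow(), np = bits.ncol();
  LogicalVector out(m);
  std::vector<uint32_t> adjm(n);
  uint32_t all = (uint32_t)((1u << n) - 1u);
  for (int row = 0; row < m; row++) {
    std::fill(adjm.begin(), adjm.end(), 0u);
    int ne = 0;
    for (int k = 0; k < np; k++) {
      if (bits(row, k)) {
        int i = pairs(k, 0) - 1, j = pairs(k, 1) - 1;
        adjm[i] |= (1u << j);
        adjm[j] |= (1u << i);
        ne++;
      }
    }
    if (n > 1 && ne < n - 1) { out[row] = false; continue; }
    uint32_t vis = 1u, frontier = 1u;
    while (frontier) {
      uint32_t nxt = 0;
      for (int v = 0; v < n; v++)
        if (frontier & (1u << v)) nxt |= adjm[v];
      nxt &= ~vis;
      vis |= nxt;
      frontier = nxt;
    }
    out[row] = (vis == all);
  }
  return out;
}
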