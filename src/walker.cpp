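#include <Rcpp.h>
#include <cstdint>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Portable deterministic RNG: xorshift-free, plain mt19937_64 with a manual
// uniform so results do not depend on the standard library's distribution
// implementation.
namespace {

inline double unif01(std::mt19937_64 &rng) {
  // 53-bit mantissa draw in [0, 1)
  return (rng() >> 11) * (1.0 / 9007199254740992.0);
}

inline bool is_adjacent(const IntegerVector &offsets, const IntegerVector &idx,
                        int u, int v) {
  if (u < 0) return false;
  const int lo = offsets[u], hi = offsets[u + 1];
  return std::binary_search(idx.begin() + lo, idx.begin() + hi, v);
}

} // namespace

// Restart random walk over a CSR adjacency with node2vec-style in-out bias.
// Nodes, offsets and idx are 0-based; neighbour lists must be sorted by index.
// Returns the full visit sequence (start first), banked per-node counts
// (start excluded from banking), and whether the per-type quota was unmet.
// [[Rcpp::export(name = ".rrw_walk_cpp")]]
List rrw_walk_cpp(IntegerVector offsets, IntegerVector idx, NumericVector wts,
                  IntegerVector node_type, int start, double p, double q,
                  int collect_size, int min_per_type, int max_steps,
                  double seed) {
  const int n = node_type.size();
  std::mt19937_64 rng(static_cast<std::uint64_t>(seed));
  std::vector<int> counts(n, 0);
  std::vector<int> type_counts(3, 0);
  std::vector<int> seq;
  seq.reserve(std::min(max_steps + 1, collect_size * 4 + 16));
  seq.push_back(start);

  int cur = start, prev = -1;
  int banked = 0, steps = 0;
  std::vector<double> cw; // cumulative weights scratch

  auto quota_met = [&]() {
    if (banked < collect_size) return false;
    for (int t = 0; t < 3; ++t)
      if (type_counts[t] < min_per_type) return false;
    return true;
  };

  while (steps < max_steps && !quota_met()) {
    ++steps;
    if (unif01(rng) < p) {
      cur = start;
      prev = -1;
      seq.push_back(cur);
      continue;
    }
    const int lo = offsets[cur], hi = offsets[cur + 1];
    const int deg = hi - lo;
    if (deg == 0) break; // dead end (isolated start is rejected upstream)
    cw.resize(deg);
    double acc = 0.0;
    for (int j = 0; j < deg; ++j) {
      const int nb = idx[lo + j];
      double w = wts[lo + j];
      if (q != 1.0 && prev >= 0 && nb != prev && !is_adjacent(offsets, idx, prev, nb))
        w /= q;
      acc += w;
      cw[j] = acc;
    }
    const double u = unif01(rng) * acc;
    const int pick = static_cast<int>(
        std::lower_bound(cw.begin(), cw.end(), u) - cw.begin());
    const int nxt = idx[lo + std::min(pick, deg - 1)];
    prev = cur;
    cur = nxt;
    seq.push_back(cur);
    if (cur != start) {
      ++counts[cur];
      ++banked;
      ++type_counts[node_type[cur] - 1];
    }
  }

  return List::create(_["sequence"] = wrap(seq),
                      _["counts"] = wrap(counts),
                      _["banked"] = banked,
                      _["steps"] = steps,
                      _["flagged"] = !quota_met());
}
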