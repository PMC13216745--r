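#include <Rcpp.h>
#include <cmath>
#include <stdint.h>
using namespace Rcpp;

// xorshift128+ : fast local RNG for the inner Metropolis loop, seeded from
// R's RNG so runs remain reproducible under set.seed()
struct FastRng {
  uint64_t s0, s1;
  explicit FastRng() {
    s0 = ((uint64_t)(unif_rand() * 4294967296.0) << 32) ^
         (uint64_t)(unif_rand() * 4294967296.0);
    s1 = ((uint64_t)(unif_rand() * 4294967296.0) << 32) ^
         (uint64_t)(unif_rand() * 4294967296.0);
    if (s0 == 0 && s1 == 0) s1 = 0x9E3779B97F4A7C15ULL;
  }
  inline uint64_t next() {
    uint64_t x = s0;
    const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  inline double uniform() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  inline int below(int n) { return (int)(uniform() * n) % n; }
};

// locate the decay bin of a distance; -1 outside the edge range
static inline int dist_bin(double d, const double *edges, int m) {
  if (d < edges[0] || d > edges[m - 1]) return -1;
  int lo = 0, hi = m - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (edges[mid] <= d) lo = mid; else hi = mid;
  }
  return lo; // 0 .. m-2
}

// Metropolis partner-swap shuffle of one chromosome's cis pairs.
//
// Proposal: pick two pairs (a1,a2),(b1,b2) uniformly, propose the partner
// exchange (a1,b2),(b1,a2).  Acceptance ratio is the product of per-pair
// weights w(bin(distance)); the weight vector is supplied by the caller
// (target decay mass divided by the configuration availability of the bin),
// so the chain's stationary pair-distance histogram matches the target
// decay while endpoint marginals are preserved exactly by construction.
// A proposal whose numerator and denominator weights are both zero is
// rejected and counted.  Uses R's RNG.
// [[Rcpp::export]]
List shuffle_pairs_cpp(NumericVector pos1, NumericVector pos2,
                       NumericVector edges, NumericVector weight,
                       int n_sweeps, int props_per_contact) {
  int n = pos1.size();
  NumericVector p1 = clone(pos1), p2 = clone(pos2);
  // interleaved pair storage: both endpoints of a pair share a cache line
  std::vector<double> pr(2 * (size_t)n);
  for (int t = 0; t < n; ++t) { pr[2 * (size_t)t] = pos1[t]; pr[2 * (size_t)t + 1] = pos2[t]; }
  double *P = pr.data();
  std::vector<double> ed(edges.begin(), edges.end());
  std::vector<double> wt(weight.begin(), weight.end());
  const double *E = ed.data(), *W = wt.data();
  const int EM = (int)ed.size();
  // geometric edges (the default decay binning) admit an O(1) bin lookup
  // from log2(d/edges[0]) / log2(ratio)
  bool geometric = EM >= 2;
  const double ratio = EM >= 2 ? ed[1] / ed[0] : 2.0;
  for (int t = 1; t < EM; ++t)
    if (std::fabs(ed[t] / ed[t - 1] - ratio) > 1e-9 * ratio) { geometric = false; break; }
  const double inv_l2r = 1.0 / std::log2(ratio);
  const double e0 = ed[0], etop = ed[EM - 1];
  const int nbins = EM - 1;
  NumericVector acc_rate(n_sweeps);
  double n_zero = 0.0;
  if (n < 2) {
    return List::create(_["pos1"] = p1, _["pos2"] = p2,
                        _["acceptance"] = acc_rate, _["n_zero_rejected"] = n_zero);
  }
  FastRng rng;
  // weight lookup; -1 bin => weight 0
  for (int s = 0; s < n_sweeps; ++s) {
    double n_prop = (double)n * props_per_contact;
    long long accepted = 0, total = 0;
    const int B = 64;
    int ib[B], jb[B];
    for (long long t0 = 0; t0 < (long long)n_prop; t0 += B) {
      int m = (int)std::min((long long)B, (long long)n_prop - t0);
      // draw a batch of proposals and prefetch their pair slots; the
      // accept/reject work below then runs without memory stalls
      for (int t = 0; t < m; ++t) {
        ib[t] = rng.below(n);
        jb[t] = rng.below(n);
#if defined(__GNUC__)
        __builtin_prefetch(&P[2 * (size_t)ib[t]]);
        __builtin_prefetch(&P[2 * (size_t)jb[t]]);
#endif
      }
      for (int t = 0; t < m; ++t) {
      int i = ib[t];
      int j = jb[t];
      if (i == j) continue;
      ++total;
      double a1 = P[2*(size_t)i], a2 = P[2*(size_t)i+1], b1 = P[2*(size_t)j], b2 = P[2*(size_t)j+1];
      double dold1 = a2 - a1, dold2 = b2 - b1;
      // the four endpoints admit two alternative re-matchings; proposing
      // one of the two uniformly keeps the proposal kernel symmetric under
      // the canonical pos1 <= pos2 relabelling (reversibility)
      double n1, n2, m1, m2;
      if (rng.uniform() < 0.5) { n1 = a1; n2 = b2; m1 = b1; m2 = a2; }
      else                   { n1 = a1; n2 = b1; m1 = a2; m2 = b2; }
      double dnew1 = std::fabs(n2 - n1), dnew2 = std::fabs(m2 - m1);
      int bn1, bn2, bo1, bo2;
      if (geometric) {
        bn1 = (dnew1 < e0 || dnew1 > etop) ? -1 :
          std::min((int)(std::log2(dnew1 / e0) * inv_l2r), nbins - 1);
        bn2 = (dnew2 < e0 || dnew2 > etop) ? -1 :
          std::min((int)(std::log2(dnew2 / e0) * inv_l2r), nbins - 1);
        bo1 = (dold1 < e0 || dold1 > etop) ? -1 :
          std::min((int)(std::log2(dold1 / e0) * inv_l2r), nbins - 1);
        bo2 = (dold2 < e0 || dold2 > etop) ? -1 :
          std::min((int)(std::log2(dold2 / e0) * inv_l2r), nbins - 1);
      } else {
        bn1 = dist_bin(dnew1, E, EM); bn2 = dist_bin(dnew2, E, EM);
        bo1 = dist_bin(dold1, E, EM); bo2 = dist_bin(dold2, E, EM);
      }
      double wn1 = bn1 < 0 ? 0.0 : W[bn1];
      double wn2 = bn2 < 0 ? 0.0 : W[bn2];
      double num = wn1 * wn2;
      double wo1 = bo1 < 0 ? 0.0 : W[bo1];
      double wo2 = bo2 < 0 ? 0.0 : W[bo2];
      double den = wo1 * wo2;
      bool accept;
      if (num == 0.0 && den == 0.0) { n_zero += 1.0; accept = false; }
      else if (den == 0.0) accept = true;
      else {
        double ratio = num / den;
        accept = (ratio >= 1.0) || (rng.uniform() < ratio);
      }
      if (accept) {
        if (n2 < n1) std::swap(n1, n2);
        if (m2 < m1) std::swap(m1, m2);
        P[2*(size_t)i] = n1; P[2*(size_t)i+1] = n2;
        P[2*(size_t)j] = m1; P[2*(size_t)j+1] = m2;
        ++accepted;
      }
      }
    }
    acc_rate[s] = total > 0 ? (double)accepted / (double)total : 0.0;
  }
  for (int t = 0; t < n; ++t) { p1[t] = pr[2 * (size_t)t]; p2[t] = pr[2 * (size_t)t + 1]; }
  return List::create(_["pos1"] = p1, _["pos2"] = p2,
                      _["acceptance"] = acc_rate, _["n_zero_rejected"] = n_zero);
}
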