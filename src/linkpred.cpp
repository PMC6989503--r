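// Leave-one-out ranking for the neighbourhood-based similarity indices.
//
// For every edge e = (u,v): remove it, score ALL non-adjacent pairs of the
// reduced graph (the candidate set, which contains e itself), and record the
// descending-score rank of e.  All six local indices share the expensive
// neighbourhood intersection, so they are ranked in a single sweep.
// Ties are resolved either by a seeded uniform-random order within the tie
// block (giving the uniform rank distribution expected of Erdos-Renyi
// graphs) or by the deterministic mid-rank  r = higher + (tied+1)/2.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

const int NALG = 6; // cn, ra, aa, jaccard, salton, pa

struct Ctx {
  int N, W;
  std::vector<uint64_t> adj; // N * W words
  std::vector<int> deg;
  std::vector<double> wra, waa;

  inline uint64_t *row(int v) { return &adj[(size_t)v * W]; }
  inline bool has(int x, int y) { return (row(x)[y >> 6] >> (y & 63)) & 1ull; }
  inline void setw(int z) {
    wra[z] = deg[z] > 0 ? 1.0 / deg[z] : 0.0;
    waa[z] = deg[z] > 1 ? 1.0 / std::log((double)deg[z]) : 0.0;
  }

  void scores(int x, int y, double *s) {
    const uint64_t *ax = row(x), *ay = row(y);
    int cn = 0;
    double ra = 0.0, aa = 0.0;
    for (int w = 0; w < W; ++w) {
      uint64_t m = ax[w] & ay[w];
      if (!m) continue;
      cn += __builtin_popcountll(m);
      while (m) {
        int z = (w << 6) + __builtin_ctzll(m);
        m &= m - 1;
        ra += wra[z];
        aa += waa[z];
      }
    }
    double kx = deg[x], ky = deg[y];
    s[0] = cn;
    s[1] = ra;
    s[2] = aa;
    s[3] = (kx + ky - cn) > 0 ? cn / (kx + ky - cn) : 0.0;
    s[4] = (kx * ky) > 0 ? cn / std::sqrt(kx * ky) : 0.0;
    s[5] = kx * ky;
  }
};

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_loo_local(int N, IntegerMatrix edges, bool random_ties) {
  int E = edges.nrow(), W = (N + 63) / 64;
  Ctx g;
  g.N = N;
  g.W = W;
  g.adj.assign((size_t)N * W, 0);
  g.deg.assign(N, 0);
  g.wra.assign(N, 0.0);
  g.waa.assign(N, 0.0);
  for (int e = 0; e < E; ++e) {
    int u = edges(e, 0), v = edges(e, 1);
    g.row(u)[v >> 6] |= 1ull << (v & 63);
    g.row(v)[u >> 6] |= 1ull << (u & 63);
    ++g.deg[u];
    ++g.deg[v];
  }
  for (int z = 0; z < N; ++z) g.setw(z);

  NumericMatrix ranks(E, NALG);
  double se[NALG], sc[NALG];

  for (int e = 0; e < E; ++e) {
    int u = edges(e, 0), v = edges(e, 1);
    g.row(u)[v >> 6] &= ~(1ull << (v & 63));
    g.row(v)[u >> 6] &= ~(1ull << (u & 63));
    --g.deg[u];
    --g.deg[v];
    g.setw(u);
    g.setw(v);

    g.scores(u, v, se);
    long higher[NALG] = {0}, tied[NALG] = {0};
    for (int x = 0; x < N; ++x) {
      for (int y = x + 1; y < N; ++y) {
        if (g.has(x, y)) continue;
        g.scores(x, y, sc);
        for (int a = 0; a < NALG; ++a) {
          if (sc[a] > se[a]) ++higher[a];
          else if (sc[a] == se[a]) ++tied[a];
        }
      }
    }
    for (int a = 0; a < NALG; ++a) {
      if (random_ties)
        ranks(e, a) = (double)higher[a] + 1.0 +
                      std::floor(unif_rand() * (double)tied[a]);
      else
        ranks(e, a) = (double)higher[a] + ((double)tied[a] + 1.0) / 2.0;
    }

    g.row(u)[v >> 6] |= 1ull << (v & 63);
    g.row(v)[u >> 6] |= 1ull << (u & 63);
    ++g.deg[u];
    ++g.deg[v];
    g.setw(u);
    g.setw(v);
  }
  colnames(ranks) = CharacterVector::create("cn", "ra", "aa", "jaccard",
                                            "salton", "pa");
  return ranks;
}
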