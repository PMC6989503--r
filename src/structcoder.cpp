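// Two-stage label-free lossless graph compression.
//
// Stage 1 traverses the vertices while maintaining an ordered partition of
// the not-yet-processed vertices into cells of structurally indistinguishable
// vertices (identical adjacency to the processed set).  For the current
// vertex we emit, per cell, the number of its neighbours inside that cell
// (a single bit for singleton cells -> B1, a count for larger cells -> B2),
// then split each cell into neighbour / non-neighbour sub-cells.  Vertex
// labels are never written, so decoding recovers the graph only up to
// isomorphism -- which is exactly what makes the length a structural
// (label-free) quantity.
//
// Stage 2 is an adaptive arithmetic coder.  Counts are coded with a
// Polya/KT composition model (binomial shape, adaptively estimated link
// rate), contexted on the number of processed vertices adjacent to both the
// current vertex and the cell.  The context is what lets the coder exploit
// transitivity / degree heterogeneity in structured graphs while staying
// optimal on Erdos-Renyi graphs, where the context carries no information.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

// ----------------------------------------------------------------- bit I/O
struct BitWriter {
  std::vector<uint8_t> bytes;
  long nbits = 0;
  void push(int bit) {
    if ((nbits & 7) == 0) bytes.push_back(0);
    if (bit) bytes.back() |= (uint8_t)(1u << (nbits & 7));
    ++nbits;
  }
};

struct BitReader {
  const uint8_t *bytes = nullptr;
  long nbits = 0, pos = 0;
  // Reads past the declared end return 0; arithmetic decoding needs a few
  // trailing phantom bits, so overrun itself is not an error.
  int next() {
    if (pos >= nbits) { ++pos; return 0; }
    int b = (bytes[pos >> 3] >> (pos & 7)) & 1;
    ++pos;
    return b;
  }
};

// --------------------------------------------- integer arithmetic coder
const uint32_t TOP = 0x80000000u, QTR = 0x40000000u;

struct ArEncoder {
  BitWriter bw;
  uint32_t low = 0, high = 0xFFFFFFFFu;
  long pending = 0;
  void outbit(int bit) {
    bw.push(bit);
    while (pending) { bw.push(!bit); --pending; }
  }
  void encode(uint32_t cumlo, uint32_t cumhi, uint32_t tot) {
    uint64_t range = (uint64_t)high - low + 1;
    high = low + (uint32_t)(range * cumhi / tot) - 1;
    low  = low + (uint32_t)(range * cumlo / tot);
    for (;;) {
      if (high < TOP) outbit(0);
      else if (low >= TOP) { outbit(1); low -= TOP; high -= TOP; }
      else if (low >= QTR && high < 3u * QTR) { ++pending; low -= QTR; high -= QTR; }
      else break;
      low <<= 1;
      high = (high << 1) | 1u;
    }
  }
  void finish() {
    ++pending;
    outbit(low >= QTR ? 1 : 0);
  }
};

struct ArDecoder {
  BitReader br;
  uint32_t low = 0, high = 0xFFFFFFFFu, code = 0;
  void init() { for (int i = 0; i < 32; ++i) code = (code << 1) | (uint32_t)br.next(); }
  uint32_t target(uint32_t tot) const {
    uint64_t range = (uint64_t)high - low + 1;
    return (uint32_t)((((uint64_t)(code - low) + 1) * tot - 1) / range);
  }
  void update(uint32_t cumlo, uint32_t cumhi, uint32_t tot) {
    uint64_t range = (uint64_t)high - low + 1;
    high = low + (uint32_t)(range * cumhi / tot) - 1;
    low  = low + (uint32_t)(range * cumlo / tot);
    for (;;) {
      if (high < TOP) {}
      else if (low >= TOP) { low -= TOP; high -= TOP; code -= TOP; }
      else if (low >= QTR && high < 3u * QTR) { low -= QTR; high -= QTR; code -= QTR; }
      else break;
      low <<= 1;
      high = (high << 1) | 1u;
      code = (code << 1) | (uint32_t)br.next();
    }
  }
};

// --------------------------------------- adaptive composition count model
// Context g in 0..NCTX-1: number of processed common neighbours of the
// current vertex and the cell, capped.  Each context keeps Beta-like
// pseudo-counts (KT prior 1/2).  The mass of count c in a cell of size s is
//   w_c  ~  C(s,c) * prod_{j<c}(a+j) * prod_{j<s-c}(b+j)
// (the exchangeable Polya marginal), computed in log space for stability
// and quantized identically on the encode and decode paths.
const int NCTX = 9;
const uint32_t FREQ_TOT = 1u << 22;

struct CountModel {
  double ones[NCTX], zeros[NCTX];
  CountModel() {
    for (int g = 0; g < NCTX; ++g) { ones[g] = 0.0; zeros[g] = 0.0; }
  }
  // cumulative integer frequencies, length s+2: cum[0]=0 .. cum[s+1]=tot
  void freqs(int s, int g, std::vector<uint32_t> &cum) const {
    double a = ones[g] + 0.5, b = zeros[g] + 0.5;
    std::vector<double> lw(s + 1);
    lw[0] = 0.0;
    for (int c = 0; c < s; ++c) {
      // w_{c+1}/w_c = (s-c)/(c+1) * (a+c)/(b+s-c-1)
      lw[c + 1] = lw[c] + std::log((double)(s - c)) - std::log((double)(c + 1))
                        + std::log(a + c) - std::log(b + (double)(s - c - 1));
    }
    double m = lw[0];
    for (int c = 1; c <= s; ++c) if (lw[c] > m) m = lw[c];
    double tot = 0.0;
    std::vector<double> w(s + 1);
    for (int c = 0; c <= s; ++c) { w[c] = std::exp(lw[c] - m); tot += w[c]; }
    uint32_t budget = FREQ_TOT - (uint32_t)(s + 1);
    cum.assign(s + 2, 0);
    for (int c = 0; c <= s; ++c) {
      uint32_t f = 1u + (uint32_t)std::floor(w[c] / tot * (double)budget);
      cum[c + 1] = cum[c] + f;
    }
  }
  void update(int s, int g, int c) {
    ones[g]  += (double)c;
    zeros[g] += (double)(s - c);
  }
};

// ------------------------------------------------------- bitset helpers
inline int popcount_and(const uint64_t *x, const uint64_t *y, int W) {
  int n = 0;
  for (int w = 0; w < W; ++w) n += __builtin_popcountll(x[w] & y[w]);
  return n;
}

struct Cell {
  std::vector<int> mem;       // member vertex ids (encoder) or anon ids (decoder)
  std::vector<uint64_t> P;    // processed-neighbour bitset shared by members
};

// Per-step symbol emission/consumption, shared by the four entry points
// (encode, raw decode, payload decode) through small function objects.
struct Traversal {
  int N, W;
  std::vector<Cell> cells;
  CountModel model;

  explicit Traversal(int n) : N(n), W((n + 63) / 64) {}

  template <typename SymbolFn>
  void run(SymbolFn &&emit) {
    // emit(s, g, cellIndexInfo) -> count c for this cell (encode computes it,
    // decode obtains it from the stream);  this function handles splitting.
    while (!cells.empty()) {
      int v = cells[0].mem.front();
      std::vector<uint64_t> Pv = cells[0].P;
      cells[0].mem.erase(cells[0].mem.begin());
      if (cells[0].mem.empty()) cells.erase(cells.begin());
      std::vector<Cell> next;
      next.reserve(cells.size() + 8);
      for (size_t ci = 0; ci < cells.size(); ++ci) {
        Cell &X = cells[ci];
        int s = (int)X.mem.size();
        int g = popcount_and(Pv.data(), X.P.data(), W);
        if (g >= NCTX) g = NCTX - 1;
        int c = emit(v, s, g, X);
        model.update(s, g, c);
        if (c == 0) {
          next.push_back(std::move(X));
        } else if (c == s) {
          X.P[v >> 6] |= (1ull << (v & 63));
          next.push_back(std::move(X));
        } else {
          Cell nb, rest;
          nb.P = X.P;
          nb.P[v >> 6] |= (1ull << (v & 63));
          rest.P = std::move(X.P);
          nb.mem.assign(X.mem.begin(), X.mem.begin() + c);
          rest.mem.assign(X.mem.begin() + c, X.mem.end());
          next.push_back(std::move(nb));
          next.push_back(std::move(rest));
        }
      }
      cells = std::move(next);
    }
  }
};

void stable_split_encoder(Cell &X, const uint64_t *adjv, std::vector<int> &tmp) {
  // reorder members: neighbours of v first, preserving relative order
  tmp.clear();
  size_t k = 0;
  for (size_t i = 0; i < X.mem.size(); ++i) {
    int u = X.mem[i];
    if (adjv[u >> 6] & (1ull << (u & 63))) X.mem[k++] = u;
    else tmp.push_back(u);
  }
  for (size_t i = 0; i < tmp.size(); ++i) X.mem[k + i] = tmp[i];
}

std::vector<std::vector<uint64_t>> build_adj(int N, const IntegerMatrix &edges) {
  int W = (N + 63) / 64;
  std::vector<std::vector<uint64_t>> adj(N, std::vector<uint64_t>(W, 0));
  for (int e = 0; e < edges.nrow(); ++e) {
    int u = edges(e, 0), v = edges(e, 1);
    adj[u][v >> 6] |= (1ull << (v & 63));
    adj[v][u >> 6] |= (1ull << (u & 63));
  }
  return adj;
}

} // namespace

// [[Rcpp::export]]
List cpp_encode_structure(int N, IntegerMatrix edges, IntegerVector order) {
  // order: permutation of 0..N-1 giving the initial cell order
  auto adj = build_adj(N, edges);
  Traversal tr(N);
  Cell all;
  all.P.assign(tr.W, 0);
  all.mem.assign(order.begin(), order.end());
  tr.cells.push_back(std::move(all));

  std::vector<int> B1, B2, B2s;
  ArEncoder enc1, enc2;
  std::vector<uint32_t> cum;
  std::vector<int> tmp;

  tr.run([&](int v, int s, int g, Cell &X) -> int {
    const uint64_t *adjv = adj[v].data();
    int c = 0;
    for (int u : X.mem)
      if (adjv[u >> 6] & (1ull << (u & 63))) ++c;
    tr.model.freqs(s, g, cum);
    if (s == 1) {
      B1.push_back(c);
      enc1.encode(cum[c], cum[c + 1], cum[s + 1]);
    } else {
      B2.push_back(c);
      B2s.push_back(s);
      enc2.encode(cum[c], cum[c + 1], cum[s + 1]);
    }
    if (c > 0 && c < s) stable_split_encoder(X, adjv, tmp);
    return c;
  });
  enc1.finish();
  enc2.finish();

  return List::create(
    _["n"] = N,
    _["b1"] = wrap(B1),
    _["b2"] = wrap(B2),
    _["b2_cell_sizes"] = wrap(B2s),
    _["payload1"] = RawVector(enc1.bw.bytes.begin(), enc1.bw.bytes.end()),
    _["payload2"] = RawVector(enc2.bw.bytes.begin(), enc2.bw.bytes.end()),
    _["bits1"] = (double)enc1.bw.nbits,
    _["bits2"] = (double)enc2.bw.nbits);
}

// Decode from the raw (stage-1) symbol streams.  Errors on exhausted or
// inconsistent streams; returns an edge matrix of a graph isomorphic to the
// encoded one.
// [[Rcpp::export]]
IntegerMatrix cpp_decode_structure(int N, IntegerVector b1, IntegerVector b2) {
  Traversal tr(N);
  Cell all;
  all.P.assign(tr.W, 0);
  for (int i = 0; i < N; ++i) all.mem.push_back(i);
  tr.cells.push_back(std::move(all));

  size_t i1 = 0, i2 = 0;
  std::vector<std::pair<int,int>> out;
  tr.run([&](int v, int s, int g, Cell &X) -> int {
    int c;
    if (s == 1) {
      if (i1 >= (size_t)b1.size()) stop("corrupt encoding: B1 exhausted");
      c = b1[i1++];
    } else {
      if (i2 >= (size_t)b2.size()) stop("corrupt encoding: B2 exhausted");
      c = b2[i2++];
    }
    if (c < 0 || c > s) stop("corrupt encoding: count %d outside cell of size %d", c, s);
    for (int j = 0; j < c; ++j) out.push_back(std::make_pair(v, X.mem[j]));
    return c; // decoder's neighbours are the first c members; already in place
  });
  if (i1 != (size_t)b1.size() || i2 != (size_t)b2.size())
    stop("corrupt encoding: trailing symbols");
  IntegerMatrix em((int)out.size(), 2);
  for (size_t e = 0; e < out.size(); ++e) {
    em(e, 0) = std::min(out[e].first, out[e].second);
    em(e, 1) = std::max(out[e].first, out[e].second);
  }
  return em;
}

// Decode straight from the arithmetic-coded payloads (full pipeline).
// [[Rcpp::export]]
IntegerMatrix cpp_decode_payloads(int N, RawVector payload1, RawVector payload2,
                                  double bits1, double bits2) {
  Traversal tr(N);
  Cell all;
  all.P.assign(tr.W, 0);
  for (int i = 0; i < N; ++i) all.mem.push_back(i);
  tr.cells.push_back(std::move(all));

  ArDecoder dec1, dec2;
  std::vector<uint8_t> p1(payload1.begin(), payload1.end());
  std::vector<uint8_t> p2(payload2.begin(), payload2.end());
  dec1.br.bytes = p1.data(); dec1.br.nbits = (long)bits1;
  dec2.br.bytes = p2.data(); dec2.br.nbits = (long)bits2;
  dec1.init();
  dec2.init();

  std::vector<uint32_t> cum;
  std::vector<std::pair<int,int>> out;
  tr.run([&](int v, int s, int g, Cell &X) -> int {
    tr.model.freqs(s, g, cum);
    ArDecoder &dec = (s == 1) ? dec1 : dec2;
    uint32_t t = dec.target(cum[s + 1]);
    int c = (int)(std::upper_bound(cum.begin() + 1, cum.end(), t) - cum.begin()) - 1;
    if (c < 0 || c > s) stop("corrupt payload");
    dec.update(cum[c], cum[c + 1], cum[s + 1]);
    for (int j = 0; j < c; ++j) out.push_back(std::make_pair(v, X.mem[j]));
    return c;
  });
  IntegerMatrix em((int)out.size(), 2);
  for (size_t e = 0; e < out.size(); ++e) {
    em(e, 0) = std::min(out[e].first, out[e].second);
    em(e, 1) = std::max(out[e].first, out[e].second);
  }
  return em;
}

// ------------------------------------------------ generic entropy coder
// Adaptive (KT, prior 1/2) arithmetic coder over a finite alphabet 0..K-1.
// Redundancy is O(K log n) bits on top of the empirical entropy.

// [[Rcpp::export]]
List cpp_entropy_code(IntegerVector symbols, int K) {
  std::vector<double> cnt(K, 0.5);
  double tot = 0.5 * K;
  ArEncoder enc;
  std::vector<uint32_t> cum(K + 1);
  for (int i = 0; i < symbols.size(); ++i) {
    int x = symbols[i];
    if (x < 0 || x >= K) stop("symbol outside alphabet");
    uint32_t budget = (1u << 20) - (uint32_t)K;
    cum[0] = 0;
    for (int k = 0; k < K; ++k)
      cum[k + 1] = cum[k] + 1u + (uint32_t)std::floor(cnt[k] / tot * (double)budget);
    enc.encode(cum[x], cum[x + 1], cum[K]);
    cnt[x] += 1.0;
    tot += 1.0;
  }
  enc.finish();
  return List::create(
    _["payload"] = RawVector(enc.bw.bytes.begin(), enc.bw.bytes.end()),
    _["nbits"] = (double)enc.bw.nbits,
    _["n"] = symbols.size(),
    _["alphabet"] = K);
}

// [[Rcpp::export]]
IntegerVector cpp_entropy_decode(RawVector payload, double nbits, int n, int K) {
  std::vector<double> cnt(K, 0.5);
  double tot = 0.5 * K;
  ArDecoder dec;
  std::vector<uint8_t> p(payload.begin(), payload.end());
  dec.br.bytes = p.data();
  dec.br.nbits = (long)nbits;
  dec.init();
  IntegerVector out(n);
  std::vector<uint32_t> cum(K + 1);
  for (int i = 0; i < n; ++i) {
    uint32_t budget = (1u << 20) - (uint32_t)K;
    cum[0] = 0;
    for (int k = 0; k < K; ++k)
      cum[k + 1] = cum[k] + 1u + (uint32_t)std::floor(cnt[k] / tot * (double)budget);
    uint32_t t = dec.target(cum[K]);
    int x = (int)(std::upper_bound(cum.begin() + 1, cum.end(), t) - cum.begin()) - 1;
    dec.update(cum[x], cum[x + 1], cum[K]);
    out[i] = x;
    cnt[x] += 1.0;
    tot += 1.0;
  }
  return out;
}
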