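// Sparse (triplet) kernels for the m/z x ion-mobility matrices.
// Grids are large (10^5 x 10^3 bins) but occupancy is ~10^3-10^4 cells,
// so every operation works on the nonzero triplets with a hash map.
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

static inline int64_t cellkey(int i, int j, int nj) {
  return static_cast<int64_t>(i) * (static_cast<int64_t>(nj) + 3) + j;
}

// reflect an out-of-range 1-based index back into [1, n]
static inline int reflect_idx(int i, int n) {
  while (i < 1 || i > n) {
    if (i < 1) i = 1 - i;
    if (i > n) i = 2 * n + 1 - i;
  }
  return i;
}

// For every nonzero cell, the number of *other* nonzero cells within the
// (2*di+1) x (2*dj+1) box centred on it.
// [[Rcpp::export]]
IntegerVector sparse_neighbor_count(IntegerVector i, IntegerVector j,
                                    int di, int dj, int nj) {
  const int n = i.size();
  std::unordered_set<int64_t> occ;
  occ.reserve(n * 2);
  for (int k = 0; k < n; ++k) occ.insert(cellkey(i[k], j[k], nj));
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    int cnt = 0;
    for (int a = -di; a <= di; ++a) {
      for (int b = -dj; b <= dj; ++b) {
        if (a == 0 && b == 0) continue;
        if (occ.count(cellkey(i[k] + a, j[k] + b, nj))) ++cnt;
      }
    }
    out[k] = cnt;
  }
  return out;
}

// Scatter-form convolution with a (2*ri+1) x (2*rj+1) kernel; out-of-grid
// destinations are reflected back, so total intensity is conserved exactly.
// [[Rcpp::export]]
DataFrame sparse_convolve(IntegerVector i, IntegerVector j, NumericVector x,
                          NumericMatrix kernel, int ni, int nj) {
  const int n = i.size();
  const int ri = (kernel.nrow() - 1) / 2;
  const int rj = (kernel.ncol() - 1) / 2;
  std::unordered_map<int64_t, double> acc;
  acc.reserve(n * kernel.nrow() * kernel.ncol() / 2 + 16);
  for (int k = 0; k < n; ++k) {
    for (int a = -ri; a <= ri; ++a) {
      const int ii = reflect_idx(i[k] + a, ni);
      for (int b = -rj; b <= rj; ++b) {
        const int jj = reflect_idx(j[k] + b, nj);
        acc[cellkey(ii, jj, nj)] += x[k] * kernel(a + ri, b + rj);
      }
    }
  }
  const int m = acc.size();
  IntegerVector oi(m), oj(m);
  NumericVector ox(m);
  int k = 0;
  const int64_t stride = static_cast<int64_t>(nj) + 3;
  for (auto &kv : acc) {
    oi[k] = static_cast<int>(kv.first / stride);
    oj[k] = static_cast<int>(kv.first % stride);
    ox[k] = kv.second;
    ++k;
  }
  return DataFrame::create(_["i"] = oi, _["j"] = oj, _["x"] = ox);
}

// Strict local maxima over the 8-neighbourhood; plateau ties broken toward
// the lower (i, j) cell so exactly one member of a flat top is kept.
// [[Rcpp::export]]
LogicalVector sparse_local_maxima(IntegerVector i, IntegerVector j,
                                  NumericVector x, int nj) {
  const int n = i.size();
  std::unordered_map<int64_t, double> val;
  val.reserve(n * 2);
  for (int k = 0; k < n; ++k) val[cellkey(i[k], j[k], nj)] = x[k];
  LogicalVector out(n);
  for (int k = 0; k < n; ++k) {
    bool is_max = x[k] > 0;
    for (int a = -1; a <= 1 && is_max; ++a) {
      for (int b = -1; b <= 1; ++b) {
        if (a == 0 && b == 0) continue;
        auto it = val.find(cellkey(i[k] + a, j[k] + b, nj));
        if (it == val.end()) continue;  // absent neighbour = 0 < x[k]
        const double nb = it->second;
        if (x[k] < nb ||
            (x[k] == nb && (a < 0 || (a == 0 && b < 0)))) {
          is_max = false;
          break;
        }
      }
    }
    out[k] = is_max;
  }
  return out;
}

// Sum x over duplicate integer-valued keys; result sorted by key.
// Keys are cell indices encoded as doubles (exact below 2^53).
// [[Rcpp::export]]
DataFrame key_collapse(NumericVector key, NumericVector x) {
  const int n = key.size();
  std::unordered_map<int64_t, double> acc;
  acc.reserve(n * 2);
  for (int k = 0; k < n; ++k) acc[static_cast<int64_t>(key[k])] += x[k];
  std::vector<int64_t> keys;
  keys.reserve(acc.size());
  for (auto &kv : acc) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  const int m = keys.size();
  NumericVector ok(m), ox(m);
  for (int k = 0; k < m; ++k) {
    ok[k] = static_cast<double>(keys[k]);
    ox[k] = acc[keys[k]];
  }
  return DataFrame::create(_["key"] = ok, _["x"] = ox);
}

// ---- SHA-1 (needed for the indexedmzML fileChecksum; no digest pkg) ----
namespace {
struct Sha1 {
  uint32_t h[5];
  uint64_t len;
  unsigned char buf[64];
  size_t buflen;
  Sha1() : len(0), buflen(0) {
    h[0] = 0x67452301u; h[1] = 0xEFCDAB89u; h[2] = 0x98BADCFEu;
    h[3] = 0x10325476u; h[4] = 0xC3D2E1F0u;
  }
  static uint32_t rol(uint32_t v, int s) { return (v << s) | (v >> (32 - s)); }
  void block(const unsigned char *p) {
    uint32_t w[80];
    for (int t = 0; t < 16; ++t)
      w[t] = (uint32_t(p[t * 4]) << 24) | (uint32_t(p[t * 4 + 1]) << 16) |
             (uint32_t(p[t * 4 + 2]) << 8) | uint32_t(p[t * 4 + 3]);
    for (int t = 16; t < 80; ++t)
      w[t] = rol(w[t - 3] ^ w[t - 8] ^ w[t - 14] ^ w[t - 16], 1);
    uint32_t a = h[0], b = h[1], c = h[2], d = h[3], e = h[4];
    for (int t = 0; t < 80; ++t) {
      uint32_t f, k;
      if (t < 20)      { f = (b & c) | ((~b) & d);         k = 0x5A827999u; }
      else if (t < 40) { f = b ^ c ^ d;                    k = 0x6ED9EBA1u; }
      else if (t < 60) { f = (b & c) | (b & d) | (c & d);  k = 0x8F1BBCDCu; }
      else             { f = b ^ c ^ d;                    k = 0xCA62C1D6u; }
      uint32_t tmp = rol(a, 5) + f + e + k + w[t];
      e = d; d = c; c = rol(b, 30); b = a; a = tmp;
    }
    h[0] += a; h[1] += b; h[2] += c; h[3] += d; h[4] += e;
  }
  void update(const unsigned char *p, size_t n) {
    len += n;
    while (n > 0) {
      size_t take = std::min(n, 64 - buflen);
      memcpy(buf + buflen, p, take);
      buflen += take; p += take; n -= take;
      if (buflen == 64) { block(buf); buflen = 0; }
    }
  }
  std::string hexdigest() {
    uint64_t bits = len * 8;
    unsigned char pad = 0x80;
    update(&pad, 1);
    unsigned char zero = 0;
    while (buflen != 56) update(&zero, 1);
    unsigned char lenb[8];
    for (int k = 0; k < 8; ++k) lenb[k] = (bits >> (56 - 8 * k)) & 0xFF;
    update(lenb, 8);
    char out[41];
    for (int k = 0; k < 5; ++k) snprintf(out + 8 * k, 9, "%08x", h[k]);
    return std::string(out, 40);
  }
};
}  // namespace

// [[Rcpp::export]]
std::string sha1_hex(RawVector bytes) {
  Sha1 s;
  if (bytes.size() > 0)
    s.update(reinterpret_cast<const unsigned char *>(RAW(bytes)), bytes.size());
  return s.hexdigest();
}
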