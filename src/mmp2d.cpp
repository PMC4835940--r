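// Core engine for the modified two-dimensional multiscale parser (MMP):
// multiscale adaptive dictionary, Lagrangian segmentation-tree optimization,
// hierarchical intra prediction, and context-adaptive arithmetic coding.
//
// The encoder and decoder share dictionary and probability-model state; the
// central contract is that both trajectories are bit-identical after every
// coded 16x16 block.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <cstring>
#include <cstdlib>
#include <vector>
#include <map>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------- scales ---

static inline int ilog2p2(int v) { int l = 0; while ((1 << l) < v) ++l; return l; }
static inline bool validDim(int v) { return v==1 || v==2 || v==4 || v==8 || v==16; }

static int scaleIndexC(int M, int N) {
  int lm = ilog2p2(M), ln = ilog2p2(N);
  if (M == N) return (lm + 1) * (ln + 1);
  if (M > N)  return (lm + 1) * (ln + 1) + (lm - 1) * (lm - ln);
  return (lm + 1) * (ln + 1) + (ln - 1) * (ln - lm) + 1;
}

static int DIMM[26], DIMN[26];
static bool dimsReady = false;
static void initDims() {
  if (dimsReady) return;
  for (int a = 1; a <= 16; a <<= 1)
    for (int b = 1; b <= 16; b <<= 1) {
      int s = scaleIndexC(a, b);
      DIMM[s] = a; DIMN[s] = b;
    }
  dimsReady = true;
}

// Allowed prediction modes per scale, without the internal "no prediction"
// id (35): planar (0) only at scales 4, 9, 16, 25; MFV (1) and the 33
// angular modes (2..34) at every scale above 3.
static std::vector<int> allowedModesC(int s) {
  std::vector<int> v;
  if (s <= 3) return v;
  if (s == 4 || s == 9 || s == 16 || s == 25) v.push_back(0);
  v.push_back(1);
  for (int m = 2; m <= 34; ++m) v.push_back(m);
  return v;
}

// ------------------------------------------------------- adaptive models ---

struct AdaptiveModel {
  std::vector<uint32_t> freq;
  uint64_t total = 0;
  uint64_t thresh = 1u << 14;

  void init(size_t n) { freq.assign(n, 1); total = n; resetThresh(); }
  void resetThresh() { thresh = std::max<uint64_t>(1u << 14, 2 * freq.size()); }
  void addSymbol() { freq.push_back(1); ++total; resetThresh(); }
  double bits(int s) const {
    return std::log2((double)total) - std::log2((double)freq[s]);
  }
  void rescale() {
    total = 0;
    for (auto &f : freq) { f = (f + 1) >> 1; total += f; }
  }
  void update(int s) { ++freq[s]; ++total; if (total >= thresh) rescale(); }
};

// ------------------------------------------------------ arithmetic coder ---

static const uint32_t AC_HALF = 0x80000000u;
static const uint32_t AC_QTR  = 0x40000000u;
static const uint32_t AC_3QTR = 0xC0000000u;

struct BitWriter {
  std::vector<uint8_t> bytes;
  uint8_t cur = 0; int n = 0;
  void put(int b) {
    cur = (uint8_t)((cur << 1) | (b & 1));
    if (++n == 8) { bytes.push_back(cur); cur = 0; n = 0; }
  }
  void flush() { while (n) put(0); }
};

struct ArithEncoder {
  BitWriter bw;
  uint32_t low = 0, high = 0xFFFFFFFFu;
  uint64_t pending = 0;

  void bpf(int b) { bw.put(b); while (pending) { bw.put(!b); --pending; } }

  void encode(AdaptiveModel &m, int s) {
    uint64_t range = (uint64_t)high - low + 1;
    uint64_t cl = 0;
    for (int i = 0; i < s; ++i) cl += m.freq[i];
    uint64_t ch = cl + m.freq[s];
    high = low + (uint32_t)(range * ch / m.total) - 1;
    low  = low + (uint32_t)(range * cl / m.total);
    for (;;) {
      if (high < AC_HALF) bpf(0);
      else if (low >= AC_HALF) { bpf(1); low -= AC_HALF; high -= AC_HALF; }
      else if (low >= AC_QTR && high < AC_3QTR) {
        ++pending; low -= AC_QTR; high -= AC_QTR;
      } else break;
      low <<= 1; high = (high << 1) | 1u;
    }
    m.update(s);
  }

  std::vector<uint8_t> finish() {
    ++pending;
    if (low < AC_QTR) bpf(0); else bpf(1);
    bw.flush();
    return bw.bytes;
  }
};

struct ArithDecoder {
  const uint8_t *p; size_t n, bytepos = 0; int bitpos = 0;
  uint32_t low = 0, high = 0xFFFFFFFFu, value = 0;

  ArithDecoder(const uint8_t *d, size_t len) : p(d), n(len) {
    for (int i = 0; i < 32; ++i) value = (value << 1) | getbit();
  }
  int getbit() {
    if (bytepos >= n) return 0;
    int b = (p[bytepos] >> (7 - bitpos)) & 1;
    if (++bitpos == 8) { bitpos = 0; ++bytepos; }
    return b;
  }
  int decode(AdaptiveModel &m) {
    uint64_t range = (uint64_t)high - low + 1;
    uint64_t scaled = (((uint64_t)(value - low) + 1) * m.total - 1) / range;
    int s = 0; uint64_t cl = 0;
    while (cl + m.freq[s] <= scaled) { cl += m.freq[s]; ++s; }
    uint64_t ch = cl + m.freq[s];
    high = low + (uint32_t)(range * ch / m.total) - 1;
    low  = low + (uint32_t)(range * cl / m.total);
    for (;;) {
      if (high < AC_HALF) { /* nothing */ }
      else if (low >= AC_HALF) { low -= AC_HALF; high -= AC_HALF; value -= AC_HALF; }
      else if (low >= AC_QTR && high < AC_3QTR) {
        low -= AC_QTR; high -= AC_QTR; value -= AC_QTR;
      } else break;
      low <<= 1; high = (high << 1) | 1u; value = (value << 1) | getbit();
    }
    m.update(s);
    return s;
  }
};

// ----------------------------------------------------------- prediction ---

// HEVC intra displacement table; index = mode id, valid for 2..34.
static const int ANGTAB[35] = {
  0, 0,
  32, 26, 21, 17, 13, 9, 5, 2, 0, -2, -5, -9, -13, -17, -21, -26,
  -32, -26, -21, -17, -13, -9, -5, -2, 0, 2, 5, 9, 13, 17, 21, 26, 32
};

static inline int rndDiv32(long num) {
  return num >= 0 ? (int)((num + 16) >> 5) : -(int)(((-num) + 16) >> 5);
}
static inline int rndHalfAway(double v) {
  return v >= 0 ? (int)std::floor(v + 0.5) : (int)std::ceil(v - 0.5);
}

// Reference vectors: L ("vertical vector", left + lower-left boundary,
// serves angular modes 2..17), A ("horizontal vector", above + upper-right,
// serves modes 18..34).  L[0] == A[0] == top-left corner sample; L[j]/A[j]
// is the j-th boundary sample moving away from the corner.  Length of each
// vector is 2*max(M,N) + 1.
struct RefVecs { std::vector<int> L, A; };

static RefVecs buildRefsC(const std::vector<int> &rec,
                          const std::vector<uint8_t> &msk,
                          int H, int W, int r0, int c0, int M, int N) {
  int mx = std::max(M, N), n = 2 * mx;
  std::vector<int> vals(2 * n + 1, 0);
  std::vector<uint8_t> av(2 * n + 1, 0);
  auto grab = [&](int r, int c, int k) {
    if (r >= 0 && r < H && c >= 0 && c < W && msk[(size_t)r * W + c]) {
      vals[k] = rec[(size_t)r * W + c]; av[k] = 1;
    }
  };
  // gather bottom-left upward, corner, then above rightward (HEVC order)
  for (int j = 1; j <= n; ++j) grab(r0 + j - 1, c0 - 1, n - j);
  grab(r0 - 1, c0 - 1, n);
  for (int j = 1; j <= n; ++j) grab(r0 - 1, c0 + j - 1, n + j);
  int first = -1;
  for (int k = 0; k < 2 * n + 1; ++k) if (av[k]) { first = k; break; }
  if (first >= 0) {
    for (int k = 0; k < first; ++k) vals[k] = vals[first];
    for (int k = first + 1; k < 2 * n + 1; ++k) if (!av[k]) vals[k] = vals[k - 1];
  } // else: nothing coded yet, all references default to 0 (zero-centered data)
  RefVecs R;
  R.L.assign(n + 1, 0); R.A.assign(n + 1, 0);
  R.L[0] = vals[n]; R.A[0] = vals[n];
  for (int j = 1; j <= n; ++j) { R.L[j] = vals[n - j]; R.A[j] = vals[n + j]; }
  return R;
}

// Predict an M x N block (row-major output) from reference vectors.
static std::vector<int> predictFromRefs(const RefVecs &rf, int mode, int M, int N) {
  std::vector<int> out((size_t)M * N, 0);
  int mx = std::max(M, N), n = 2 * mx;
  if (mode == 35) return out; // no prediction

  if (mode == 1) { // MFV: modal value of the concatenated reference vectors
    std::map<int, int> cnt;
    for (int j = 0; j <= n; ++j) { ++cnt[rf.L[j]]; ++cnt[rf.A[j]]; }
    int bv = 0, bc = -1;
    for (auto &kv : cnt) if (kv.second > bc) { bc = kv.second; bv = kv.first; }
    std::fill(out.begin(), out.end(), bv);
    return out;
  }
  if (mode == 0) { // planar: average of horizontal and vertical interpolation
    double tr = rf.A[N + 1], bl = rf.L[M + 1];
    for (int y = 0; y < M; ++y)
      for (int x = 0; x < N; ++x) {
        double ph = ((N - 1 - x) * (double)rf.L[y + 1] + (x + 1) * tr) / N;
        double pv = ((M - 1 - y) * (double)rf.A[x + 1] + (y + 1) * bl) / M;
        out[(size_t)y * N + x] = rndHalfAway((ph + pv) / 2.0);
      }
    return out;
  }
  // angular: modes 2..17 extrapolate the left ("vertical") vector,
  // 18..34 the above ("horizontal") vector, with 1/32-sample interpolation.
  int Aang = ANGTAB[mode];
  bool vert = (mode >= 18);
  const std::vector<int> &main = vert ? rf.A : rf.L;
  const std::vector<int> &side = vert ? rf.L : rf.A;
  int D  = vert ? M : N;  // projected depth
  int Wd = vert ? N : M;  // extent along the main reference
  int minK = (D * Aang) >> 5; if (minK > 0) minK = 0;
  int maxK = Wd + D + 1;
  std::vector<int> rm((size_t)(maxK - minK + 2), 0);
  int off = -minK;
  int hi = std::min(maxK, n);
  for (int k = 0; k <= hi; ++k) rm[off + k] = main[k];
  for (int k = hi + 1; k <= maxK; ++k) rm[off + k] = main[hi];
  if (Aang < 0 && minK < 0) {
    long ia = -std::lround(-8192.0 / Aang); // HEVC inverse angle (negative)
    for (int k = -1; k >= minK; --k) {
      long si = ((long)k * ia + 128) >> 8;
      if (si < 0) si = 0; if (si > n) si = n;
      rm[off + k] = side[si];
    }
  }
  for (int t = 0; t < D; ++t) {
    long pos = (long)(t + 1) * Aang;
    long i = pos >> 5;
    int f = (int)(pos & 31);
    for (int u = 0; u < Wd; ++u) {
      long k = u + i + 1;
      int r1 = rm[off + k], r2 = rm[off + k + 1];
      int v = rndDiv32((long)(32 - f) * r1 + (long)f * r2);
      if (vert) out[(size_t)t * N + u] = v;
      else      out[(size_t)u * N + t] = v;
    }
  }
  return out;
}

// ------------------------------------------------------- scale transform ---

// Separable 1-D resampling: contraction by box averaging, expansion by
// sample repetition with linear weighting; rounding half-away-from-zero
// applied once at the end.
static std::vector<double> resample1(const std::vector<double> &in, int b) {
  int a = (int)in.size();
  std::vector<double> out((size_t)b);
  if (b == a) { out = in; }
  else if (b < a) {
    int f = a / b;
    for (int j = 0; j < b; ++j) {
      double s = 0;
      for (int t = 0; t < f; ++t) s += in[(size_t)j * f + t];
      out[j] = s / f;
    }
  } else {
    for (int j = 0; j < b; ++j) {
      double p = (j + 0.5) * a / (double)b - 0.5;
      if (p < 0) p = 0; if (p > a - 1) p = a - 1;
      int i0 = (int)std::floor(p);
      int i1 = std::min(i0 + 1, a - 1);
      double fr = p - i0;
      out[j] = in[i0] * (1 - fr) + in[i1] * fr;
    }
  }
  return out;
}

static std::vector<int> transformPat(const std::vector<int> &pat,
                                     int sm, int sn, int dm, int dn) {
  std::vector<double> tmp((size_t)sm * dn);
  std::vector<double> row((size_t)sn);
  for (int r = 0; r < sm; ++r) {
    for (int c = 0; c < sn; ++c) row[c] = pat[(size_t)r * sn + c];
    auto o = resample1(row, dn);
    for (int c = 0; c < dn; ++c) tmp[(size_t)r * dn + c] = o[c];
  }
  std::vector<int> out((size_t)dm * dn);
  std::vector<double> col((size_t)sm);
  for (int c = 0; c < dn; ++c) {
    for (int r = 0; r < sm; ++r) col[r] = tmp[(size_t)r * dn + c];
    auto o = resample1(col, dm);
    for (int r = 0; r < dm; ++r) out[(size_t)r * dn + c] = rndHalfAway(o[r]);
  }
  return out;
}

// ------------------------------------------------ initial dictionary -------

// Nonuniform homogeneous levels: start at -X, advance by the magnitude-
// banded step p (1 / 4 / 8 / 13), stop past +X.
static std::vector<int> dictLevelsC(int X) {
  std::vector<int> v;
  long cur = -(long)X;
  while (cur <= X) {
    v.push_back((int)cur);
    long a = std::llabs(cur);
    int p = (a <= 10) ? 1 : (a <= 22) ? 4 : (a <= 86) ? 8 : 13;
    cur += p;
  }
  return v;
}

static double redundancyThresholdC(double lambda) {
  if (lambda <= 4)  return 20;
  if (lambda <= 22) return 40;
  if (lambda <= 50) return 60;
  return 80;
}

// ------------------------------------------------------------- the codec ---

static const int MODE_NONE = 35;

struct ONode {
  int flag;   // 0..4
  int mode;   // -1 absent; 0..35 at region roots
  int scale;
  int part;   // leaf: origin-scale partition of the chosen entry
  int pidx;   // leaf: 0-based index within partition
  int entry;  // leaf: flat entry id at the scale
  int c0, c1; // children (arena ids) for flags 1..4
};

struct SymRec { std::vector<int> type, value, part; };

struct UpdateRec { std::vector<int> pat; int M, N, origin; };

struct OptRes { double cost; int node; };

struct Codec {
  int H = 0, W = 0, Xmax = 1, cap = 50000, nfull = 2;
  double lambda = 0, dthr = 20;
  bool addsym = false, thorough = false;

  std::vector<int> img, rec;
  std::vector<uint8_t> msk;

  // dictionary, per scale
  std::vector<std::vector<int>> pats[26];
  std::vector<int> org[26], pip[26];
  std::vector<std::vector<int>> part[26]; // 26 origin partitions per scale
  uint64_t dhash = 1469598103934665603ULL;

  // probability models
  AdaptiveModel flagU[26], flagR[26], modeM[26], partM[26], idxM[26][26];
  std::vector<int> fUs[26], fRs[26], mS[26];

  // per-block frozen rate caches (optimizer only)
  std::vector<int> scan[26];
  std::vector<double> erate[26];
  std::vector<double> fUbits[26], fRbits[26], mbits[26];

  std::vector<ONode> arena;
  std::vector<UpdateRec> updates;

  void init(int H_, int W_, int Xmax_, double lambda_, List opts) {
    initDims();
    H = H_; W = W_; Xmax = std::max(1, Xmax_); lambda = lambda_;
    dthr = redundancyThresholdC(lambda);
    cap = as<int>(opts["cap"]);
    addsym = as<bool>(opts["additive_symmetric"]);
    thorough = as<bool>(opts["thorough"]);
    nfull = as<int>(opts["n_full_modes"]);
    img.assign((size_t)H * W, 0);
    rec.assign((size_t)H * W, 0);
    msk.assign((size_t)H * W, 0);

    for (int s = 1; s <= 25; ++s) {
      int M = DIMM[s], N = DIMN[s];
      part[s].assign(26, std::vector<int>());
      // symbol alphabets
      fRs[s].clear(); fRs[s].push_back(0);
      if (N >= 2) fRs[s].push_back(1);
      if (M >= 2) fRs[s].push_back(2);
      fUs[s] = fRs[s];
      if (s >= 9 && N >= 2) fUs[s].push_back(3);
      if (s >= 9 && M >= 2) fUs[s].push_back(4);
      mS[s].clear();
      if (s >= 4) {
        mS[s].push_back(MODE_NONE);
        for (int m : allowedModesC(s)) mS[s].push_back(m);
      }
      flagU[s].init(fUs[s].size());
      flagR[s].init(fRs[s].size());
      if (!mS[s].empty()) modeM[s].init(mS[s].size());
      partM[s].init(26);
      // initial entries (origin partition 0; built before the redundancy
      // threshold applies)
      if (s == 1) {
        for (int v = -Xmax; v <= Xmax; ++v) appendEntry(1, std::vector<int>{v}, 0);
      } else {
        for (int v : dictLevelsC(Xmax))
          appendEntry(s, std::vector<int>((size_t)M * N, v), 0);
      }
    }
  }

  void appendEntry(int s, const std::vector<int> &p, int origin) {
    int id = (int)pats[s].size();
    pats[s].push_back(p);
    org[s].push_back(origin);
    pip[s].push_back((int)part[s][origin].size());
    part[s][origin].push_back(id);
    idxM[s][origin].addSymbol();
    uint64_t h = dhash;
    h ^= (uint64_t)(s * 131 + origin) + 0x9e3779b97f4a7c15ULL + (h << 6) + (h >> 2);
    for (int v : p) h ^= (uint64_t)(int64_t)v + 0x9e3779b97f4a7c15ULL + (h << 6) + (h >> 2);
    dhash = h;
  }

  // --- per-block frozen caches ---------------------------------------
  int posOf(const std::vector<int> &syms, int v) const {
    for (size_t i = 0; i < syms.size(); ++i) if (syms[i] == v) return (int)i;
    return -1;
  }
  void prepBlock() {
    for (int s = 1; s <= 25; ++s) {
      scan[s].clear();
      for (int p = 0; p < 26; ++p)
        for (int id : part[s][p]) scan[s].push_back(id);
      erate[s].assign(pats[s].size(), 0.0);
      for (int p = 0; p < 26; ++p) {
        if (part[s][p].empty()) continue;
        double pb = partM[s].bits(p);
        for (int id : part[s][p]) erate[s][id] = pb + idxM[s][p].bits(pip[s][id]);
      }
      fUbits[s].resize(fUs[s].size());
      for (size_t k = 0; k < fUs[s].size(); ++k) fUbits[s][k] = flagU[s].bits((int)k);
      fRbits[s].resize(fRs[s].size());
      for (size_t k = 0; k < fRs[s].size(); ++k) fRbits[s][k] = flagR[s].bits((int)k);
      mbits[s].resize(mS[s].size());
      for (size_t k = 0; k < mS[s].size(); ++k) mbits[s][k] = modeM[s].bits((int)k);
    }
  }
  double fUb(int s, int f) const { return fUbits[s][posOf(fUs[s], f)]; }
  double fRb(int s, int f) const { return fRbits[s][posOf(fRs[s], f)]; }
  double mBits(int s, int m) const { return mbits[s][posOf(mS[s], m)]; }

  // --- dictionary search ----------------------------------------------
  // res: row-major buffer with given stride; block at (r, c), dims M x N.
  double bestMatch(const int *res, int stride, int r, int c,
                   int M, int N, int s, int &entryOut) const {
    double best = 1e300; int be = -1;
    if (s == 1) {
      // scale 1 holds every integer in [-Xmax, Xmax] in partition 0
      // (entry id = value + Xmax); search outward from the nearest level
      // and stop once the squared distance alone exceeds the best cost.
      int v = res[(size_t)r * stride + c];
      int ctr = v; if (ctr > Xmax) ctr = Xmax; if (ctr < -Xmax) ctr = -Xmax;
      int ic = ctr + Xmax;
      auto tryE = [&](int e) {
        double d0 = (double)v - pats[1][e][0];
        double cost = d0 * d0 + lambda * erate[1][e];
        if (cost < best) { best = cost; be = e; }
      };
      tryE(ic);
      for (int t = 1;; ++t) {
        bool any = false;
        double dd = (double)t * t; // |v - (ctr +- t)| >= t for in-range v
        if (dd >= best) break;
        if (ic - t >= 0) { tryE(ic - t); any = true; }
        if (ic + t <= 2 * Xmax) { tryE(ic + t); any = true; }
        if (!any) break;
      }
      for (int p = 1; p < 26; ++p)
        for (int id : part[1][p]) tryE(id);
      entryOut = be;
      return best;
    }
    for (int e : scan[s]) {
      double rb = lambda * erate[s][e];
      if (rb >= best) continue;
      const int *q = pats[s][e].data();
      int64_t ssd = 0;
      bool pruned = false;
      for (int i = 0; i < M; ++i) {
        const int *rp = res + (size_t)(r + i) * stride + c;
        const int *qp = q + (size_t)i * N;
        for (int j = 0; j < N; ++j) {
          int64_t d0 = (int64_t)rp[j] - qp[j];
          ssd += d0 * d0;
        }
        if ((double)ssd + rb >= best) { pruned = true; break; }
      }
      if (pruned) continue;
      double cost = (double)ssd + rb;
      if (cost < best) { best = cost; be = e; }
    }
    entryOut = be;
    return best;
  }

  // --- residue-tree optimization (plain MMP over one residue block) ----
  struct DPSolver {
    const Codec *C;
    const int *res; int stride;
    std::vector<double> cost, leafC;
    std::vector<int8_t> chc;
    std::vector<int> ent;
    std::vector<int> *ownBuf = nullptr;
    DPSolver(const Codec *c, const int *r, int stride_)
      : C(c), res(r), stride(stride_),
        cost(6400, -1.0), leafC(6400, -1.0), chc(6400, 0), ent(6400, -1) {}
    ~DPSolver() { delete ownBuf; }
    static int key(int r, int c, int M, int N) {
      int lm = ilog2p2(M), ln = ilog2p2(N);
      return (((lm * 5 + ln) * 16 + r / M) * 16 + c / N);
    }
    // D + lambda * R(index) for the best single-entry approximation
    double leaf(int r, int c, int M, int N) {
      int k = key(r, c, M, N);
      if (leafC[k] >= 0) return leafC[k];
      int e;
      double d = C->bestMatch(res, stride, r, c, M, N, scaleIndexC(M, N), e);
      ent[k] = e; leafC[k] = d;
      return d;
    }
    double solve(int r, int c, int M, int N) {
      int k = key(r, c, M, N);
      if (cost[k] >= 0) return cost[k];
      int s = scaleIndexC(M, N);
      double best = leaf(r, c, M, N) + C->lambda * C->fRb(s, 0);
      int8_t ch = 0;
      if (N >= 2) {
        double cv = C->lambda * C->fRb(s, 1)
          + solve(r, c, M, N / 2) + solve(r, c + N / 2, M, N / 2);
        if (cv < best) { best = cv; ch = 1; }
      }
      if (M >= 2) {
        double chh = C->lambda * C->fRb(s, 2)
          + solve(r, c, M / 2, N) + solve(r + M / 2, c, M / 2, N);
        if (chh < best) { best = chh; ch = 2; }
      }
      cost[k] = best; chc[k] = ch;
      return best;
    }
    // root of a predicted region: the first flag is coded in the
    // prediction-layer (unpredicted) context, deeper flags as residue.
    double rootOpt(int r, int c, int M, int N, int &flagOut) {
      int s = scaleIndexC(M, N);
      double best = leaf(r, c, M, N) + C->lambda * C->fUb(s, 0);
      flagOut = 0;
      if (N >= 2) {
        double cv = C->lambda * C->fUb(s, 1)
          + solve(r, c, M, N / 2) + solve(r, c + N / 2, M, N / 2);
        if (cv < best) { best = cv; flagOut = 1; }
      }
      if (M >= 2) {
        double chh = C->lambda * C->fUb(s, 2)
          + solve(r, c, M / 2, N) + solve(r + M / 2, c, M / 2, N);
        if (chh < best) { best = chh; flagOut = 2; }
      }
      return best;
    }
  };

  int dpToNodes(const DPSolver &dp, int r, int c, int M, int N) {
    int k = DPSolver::key(r, c, M, N);
    ONode nd; nd.scale = scaleIndexC(M, N); nd.mode = -1;
    nd.part = -1; nd.pidx = -1; nd.entry = -1; nd.c0 = nd.c1 = -1;
    nd.flag = dp.chc[k];
    if (nd.flag == 0) {
      nd.entry = dp.ent[k];
      nd.part = org[nd.scale][nd.entry];
      nd.pidx = pip[nd.scale][nd.entry];
      arena.push_back(nd);
      return (int)arena.size() - 1;
    }
    int a, b;
    if (nd.flag == 1) {
      a = dpToNodes(dp, r, c, M, N / 2);
      b = dpToNodes(dp, r, c + N / 2, M, N / 2);
    } else {
      a = dpToNodes(dp, r, c, M / 2, N);
      b = dpToNodes(dp, r + M / 2, c, M / 2, N);
    }
    nd.c0 = a; nd.c1 = b;
    arena.push_back(nd);
    return (int)arena.size() - 1;
  }

  void rebuildResidue(const DPSolver &dp, int r, int c, int M, int N,
                      std::vector<int> &out, int ostride, int orr, int occ) const {
    int k = DPSolver::key(r, c, M, N);
    int ch = dp.chc[k];
    if (ch == 0) {
      int s = scaleIndexC(M, N);
      const std::vector<int> &p = pats[s][dp.ent[k]];
      for (int i = 0; i < M; ++i)
        for (int j = 0; j < N; ++j)
          out[(size_t)(orr + i) * ostride + occ + j] = p[(size_t)i * N + j];
    } else if (ch == 1) {
      rebuildResidue(dp, r, c, M, N / 2, out, ostride, orr, occ);
      rebuildResidue(dp, r, c + N / 2, M, N / 2, out, ostride, orr, occ + N / 2);
    } else {
      rebuildResidue(dp, r, c, M / 2, N, out, ostride, orr, occ);
      rebuildResidue(dp, r + M / 2, c, M / 2, N, out, ostride, orr + M / 2, occ);
    }
  }

  // --- patch helpers ----------------------------------------------------
  struct Patch { std::vector<int> r; std::vector<uint8_t> m; };
  Patch savePatch(int r0, int c0, int M, int N) const {
    Patch p; p.r.resize((size_t)M * N); p.m.resize((size_t)M * N);
    for (int i = 0; i < M; ++i)
      for (int j = 0; j < N; ++j) {
        size_t g = (size_t)(r0 + i) * W + c0 + j, l = (size_t)i * N + j;
        p.r[l] = rec[g]; p.m[l] = msk[g];
      }
    return p;
  }
  void restorePatch(const Patch &p, int r0, int c0, int M, int N) {
    for (int i = 0; i < M; ++i)
      for (int j = 0; j < N; ++j) {
        size_t g = (size_t)(r0 + i) * W + c0 + j, l = (size_t)i * N + j;
        rec[g] = p.r[l]; msk[g] = p.m[l];
      }
  }
  void clearPatch(int r0, int c0, int M, int N) {
    for (int i = 0; i < M; ++i)
      for (int j = 0; j < N; ++j) {
        size_t g = (size_t)(r0 + i) * W + c0 + j;
        rec[g] = 0; msk[g] = 0;
      }
  }

  // --- hierarchical optimization ---------------------------------------
  // Optimizes the block at (r0, c0) and commits the chosen reconstruction.
  // noneDP is shared across all nodes of the current 16x16 block: the
  // "no prediction" residue is the original content, so its segmentation
  // costs are position-indexed and common to every node.
  OptRes optimizeUnpred(int r0, int c0, int M, int N,
                        DPSolver &noneDP, int bR, int bC) {
    int s = scaleIndexC(M, N);
    int relR = r0 - bR, relC = c0 - bC;
    RefVecs rf = buildRefsC(rec, msk, H, W, r0, c0, M, N);

    // candidate prediction modes: "no prediction" always; others either all
    // (thorough) or the nfull best by SAD of prediction vs block.
    std::vector<int> cand; cand.push_back(MODE_NONE);
    std::vector<std::vector<int>> candPred; candPred.push_back(std::vector<int>());
    {
      std::vector<int> am = allowedModesC(s);
      if (thorough) {
        for (int m : am) {
          candPred.push_back(predictFromRefs(rf, m, M, N));
          cand.push_back(m);
        }
      } else if (nfull > 0 && !am.empty()) {
        std::vector<std::pair<long, int>> sc;
        std::vector<std::vector<int>> preds(am.size());
        for (size_t i = 0; i < am.size(); ++i) {
          preds[i] = predictFromRefs(rf, am[i], M, N);
          long sad = 0;
          for (int r = 0; r < M; ++r)
            for (int c = 0; c < N; ++c)
              sad += std::labs((long)img[(size_t)(r0 + r) * W + c0 + c]
                               - preds[i][(size_t)r * N + c]);
          sc.push_back(std::make_pair(sad, (int)i));
        }
        std::stable_sort(sc.begin(), sc.end());
        int k = std::min((int)sc.size(), nfull);
        for (int i = 0; i < k; ++i) {
          cand.push_back(am[sc[i].second]);
          candPred.push_back(preds[sc[i].second]);
        }
      }
    }

    double bestCost = 1e300;
    int bestKind = -1;       // 0 = region, 3/4 = prediction split
    int bestMode = -1, bestRootFlag = -1;
    bool bestShared = false;
    DPSolver *bestDP = nullptr;
    std::vector<int> bestPred;
    Patch bestSplitPatch;
    int bestChild0 = -1, bestChild1 = -1;

    for (size_t ci = 0; ci < cand.size(); ++ci) {
      int m = cand[ci];
      double c0c; int rflag;
      DPSolver *dp = nullptr;
      if (m == MODE_NONE) {
        c0c = noneDP.rootOpt(relR, relC, M, N, rflag);
      } else {
        const std::vector<int> &pr = candPred[ci];
        std::vector<int> *buf = new std::vector<int>((size_t)M * N);
        for (int r = 0; r < M; ++r)
          for (int c = 0; c < N; ++c) {
            size_t l = (size_t)r * N + c;
            (*buf)[l] = img[(size_t)(r0 + r) * W + c0 + c] - pr[l];
          }
        dp = new DPSolver(this, buf->data(), N);
        dp->ownBuf = buf;
        c0c = dp->rootOpt(0, 0, M, N, rflag);
      }
      double total = c0c + (mS[s].empty() ? 0.0 : lambda * mBits(s, m));
      if (total < bestCost) {
        bestCost = total; bestKind = 0; bestMode = m;
        bestRootFlag = rflag;
        bestShared = (m == MODE_NONE);
        delete bestDP; bestDP = dp;
        bestPred = candPred[ci];
      } else delete dp;
    }

    if (s >= 9 && N >= 2) { // vertical prediction split (flag 3)
      Patch sv = savePatch(r0, c0, M, N);
      OptRes a = optimizeUnpred(r0, c0, M, N / 2, noneDP, bR, bC);
      OptRes b = optimizeUnpred(r0, c0 + N / 2, M, N / 2, noneDP, bR, bC);
      double ct = lambda * fUb(s, 3) + a.cost + b.cost;
      Patch got = savePatch(r0, c0, M, N);
      restorePatch(sv, r0, c0, M, N);
      if (ct < bestCost) {
        bestCost = ct; bestKind = 3;
        bestChild0 = a.node; bestChild1 = b.node;
        bestSplitPatch = got;
        delete bestDP; bestDP = nullptr;
      }
    }
    if (s >= 9 && M >= 2) { // horizontal prediction split (flag 4)
      Patch sv = savePatch(r0, c0, M, N);
      OptRes a = optimizeUnpred(r0, c0, M / 2, N, noneDP, bR, bC);
      OptRes b = optimizeUnpred(r0 + M / 2, c0, M / 2, N, noneDP, bR, bC);
      double ct = lambda * fUb(s, 4) + a.cost + b.cost;
      Patch got = savePatch(r0, c0, M, N);
      restorePatch(sv, r0, c0, M, N);
      if (ct < bestCost) {
        bestCost = ct; bestKind = 4;
        bestChild0 = a.node; bestChild1 = b.node;
        bestSplitPatch = got;
        delete bestDP; bestDP = nullptr;
      }
    }

    OptRes out; out.cost = bestCost;
    if (bestKind == 0) {
      DPSolver &dp = bestShared ? noneDP : *bestDP;
      int rr = bestShared ? relR : 0, cc = bestShared ? relC : 0;
      // rebuild residue, commit pred + residue reconstruction
      std::vector<int> rres((size_t)M * N, 0);
      int nodeId;
      ONode nd; nd.scale = s; nd.mode = bestMode;
      nd.part = -1; nd.pidx = -1; nd.entry = -1; nd.c0 = nd.c1 = -1;
      if (bestRootFlag == 0) {
        int be = dp.ent[DPSolver::key(rr, cc, M, N)];
        const std::vector<int> &p = pats[s][be];
        for (size_t l = 0; l < p.size(); ++l) rres[l] = p[l];
        nd.flag = 0; nd.entry = be;
        nd.part = org[s][be]; nd.pidx = pip[s][be];
        arena.push_back(nd);
        nodeId = (int)arena.size() - 1;
      } else if (bestRootFlag == 1) {
        rebuildResidue(dp, rr, cc, M, N / 2, rres, N, 0, 0);
        rebuildResidue(dp, rr, cc + N / 2, M, N / 2, rres, N, 0, N / 2);
        nd.flag = 1;
        nd.c0 = dpToNodes(dp, rr, cc, M, N / 2);
        nd.c1 = dpToNodes(dp, rr, cc + N / 2, M, N / 2);
        arena.push_back(nd);
        nodeId = (int)arena.size() - 1;
      } else {
        rebuildResidue(dp, rr, cc, M / 2, N, rres, N, 0, 0);
        rebuildResidue(dp, rr + M / 2, cc, M / 2, N, rres, N, M / 2, 0);
        nd.flag = 2;
        nd.c0 = dpToNodes(dp, rr, cc, M / 2, N);
        nd.c1 = dpToNodes(dp, rr + M / 2, cc, M / 2, N);
        arena.push_back(nd);
        nodeId = (int)arena.size() - 1;
      }
      for (int r = 0; r < M; ++r)
        for (int c = 0; c < N; ++c) {
          size_t g = (size_t)(r0 + r) * W + c0 + c, l = (size_t)r * N + c;
          rec[g] = rres[l] + (bestMode == MODE_NONE ? 0 : bestPred[l]);
          msk[g] = 1;
        }
      out.node = nodeId;
    } else {
      restorePatch(bestSplitPatch, r0, c0, M, N);
      ONode nd; nd.flag = bestKind; nd.mode = -1; nd.scale = s;
      nd.part = -1; nd.pidx = -1; nd.entry = -1;
      nd.c0 = bestChild0; nd.c1 = bestChild1;
      arena.push_back(nd);
      out.node = (int)arena.size() - 1;
    }
    delete bestDP;
    return out;
  }

  // --- symbol emission / parsing with reconstruction -------------------
  void recSym(SymRec &S, int type, int value, int prt) {
    S.type.push_back(type); S.value.push_back(value); S.part.push_back(prt);
  }

  void collectResidueUpdate(const std::vector<int> &rres, int stride,
                            int r, int c, int M, int N, int origin) {
    UpdateRec u; u.M = M; u.N = N; u.origin = origin;
    u.pat.resize((size_t)M * N);
    for (int i = 0; i < M; ++i)
      for (int j = 0; j < N; ++j)
        u.pat[(size_t)i * N + j] = rres[(size_t)(r + i) * stride + c + j];
    updates.push_back(u);
  }
  void collectSignalUpdate(int r0, int c0, int M, int N, int origin) {
    UpdateRec u; u.M = M; u.N = N; u.origin = origin;
    u.pat.resize((size_t)M * N);
    for (int i = 0; i < M; ++i)
      for (int j = 0; j < N; ++j) {
        int v = rec[(size_t)(r0 + i) * W + c0 + j];
        if (v > Xmax) v = Xmax; if (v < -Xmax) v = -Xmax;
        u.pat[(size_t)i * N + j] = v;
      }
    updates.push_back(u);
  }

  // residue subtree (flags and leaves below a region root)
  void emitResidue(ArithEncoder *enc, int node, std::vector<int> &rres,
                   int stride, int r, int c, int M, int N, SymRec &S) {
    ONode &nd = arena[node];
    int s = nd.scale;
    if (enc) enc->encode(flagR[s], posOf(fRs[s], nd.flag));
    recSym(S, 0, nd.flag, -1);
    emitResidueRest(enc, node, rres, stride, r, c, M, N, S);
  }
  void emitResidueRest(ArithEncoder *enc, int node, std::vector<int> &rres,
                       int stride, int r, int c, int M, int N, SymRec &S) {
    ONode &nd = arena[node];
    int s = nd.scale;
    if (nd.flag == 0) {
      if (enc) {
        enc->encode(partM[s], nd.part);
        enc->encode(idxM[s][nd.part], nd.pidx);
      }
      recSym(S, 2, nd.pidx + 1, nd.part);
      const std::vector<int> &p = pats[s][nd.entry];
      for (int i = 0; i < M; ++i)
        for (int j = 0; j < N; ++j)
          rres[(size_t)(r + i) * stride + c + j] = p[(size_t)i * N + j];
    } else if (nd.flag == 1) {
      emitResidue(enc, nd.c0, rres, stride, r, c, M, N / 2, S);
      emitResidue(enc, nd.c1, rres, stride, r, c + N / 2, M, N / 2, S);
      collectResidueUpdate(rres, stride, r, c, M, N, s);
    } else {
      emitResidue(enc, nd.c0, rres, stride, r, c, M / 2, N, S);
      emitResidue(enc, nd.c1, rres, stride, r + M / 2, c, M / 2, N, S);
      collectResidueUpdate(rres, stride, r, c, M, N, s);
    }
  }

  void emitUnpred(ArithEncoder *enc, int node, int r0, int c0,
                  int M, int N, SymRec &S) {
    ONode &nd = arena[node];
    int s = nd.scale;
    if (enc) enc->encode(flagU[s], posOf(fUs[s], nd.flag));
    recSym(S, 0, nd.flag, -1);
    if (nd.flag == 3) {
      emitUnpred(enc, nd.c0, r0, c0, M, N / 2, S);
      emitUnpred(enc, nd.c1, r0, c0 + N / 2, M, N / 2, S);
      collectSignalUpdate(r0, c0, M, N, s);
    } else if (nd.flag == 4) {
      emitUnpred(enc, nd.c0, r0, c0, M / 2, N, S);
      emitUnpred(enc, nd.c1, r0 + M / 2, c0, M / 2, N, S);
      collectSignalUpdate(r0, c0, M, N, s);
    } else {
      if (enc && !mS[s].empty()) enc->encode(modeM[s], posOf(mS[s], nd.mode));
      recSym(S, 1, nd.mode, -1);
      RefVecs rf = buildRefsC(rec, msk, H, W, r0, c0, M, N);
      std::vector<int> pred = predictFromRefs(rf, nd.mode, M, N);
      std::vector<int> rres((size_t)M * N, 0);
      emitResidueRest(enc, node, rres, N, 0, 0, M, N, S);
      for (int i = 0; i < M; ++i)
        for (int j = 0; j < N; ++j) {
          size_t g = (size_t)(r0 + i) * W + c0 + j, l = (size_t)i * N + j;
          rec[g] = rres[l] + pred[l];
          msk[g] = 1;
        }
    }
  }

  // --- decoder-side parse ----------------------------------------------
  int parseResidue(ArithDecoder &dec, int s, std::vector<int> &rres,
                   int stride, int r, int c, int M, int N, SymRec &S) {
    int f = fRs[s][dec.decode(flagR[s])];
    recSym(S, 0, f, -1);
    return parseResidueRest(dec, s, f, rres, stride, r, c, M, N, S);
  }
  int parseResidueRest(ArithDecoder &dec, int s, int f, std::vector<int> &rres,
                       int stride, int r, int c, int M, int N, SymRec &S) {
    ONode nd; nd.flag = f; nd.mode = -1; nd.scale = s;
    nd.part = -1; nd.pidx = -1; nd.entry = -1; nd.c0 = nd.c1 = -1;
    if (f == 0) {
      int p = dec.decode(partM[s]);
      if (part[s][p].empty()) stop("corrupt stream: empty dictionary partition");
      int pi = dec.decode(idxM[s][p]);
      int e = part[s][p][pi];
      recSym(S, 2, pi + 1, p);
      nd.part = p; nd.pidx = pi; nd.entry = e;
      const std::vector<int> &q = pats[s][e];
      for (int i = 0; i < M; ++i)
        for (int j = 0; j < N; ++j)
          rres[(size_t)(r + i) * stride + c + j] = q[(size_t)i * N + j];
      arena.push_back(nd);
      return (int)arena.size() - 1;
    }
    if (f == 1) {
      int sc = scaleIndexC(M, N / 2);
      nd.c0 = parseResidue(dec, sc, rres, stride, r, c, M, N / 2, S);
      nd.c1 = parseResidue(dec, sc, rres, stride, r, c + N / 2, M, N / 2, S);
      collectResidueUpdate(rres, stride, r, c, M, N, s);
    } else {
      int sc = scaleIndexC(M / 2, N);
      nd.c0 = parseResidue(dec, sc, rres, stride, r, c, M / 2, N, S);
      nd.c1 = parseResidue(dec, sc, rres, stride, r + M / 2, c, M / 2, N, S);
      collectResidueUpdate(rres, stride, r, c, M, N, s);
    }
    arena.push_back(nd);
    return (int)arena.size() - 1;
  }

  int parseUnpred(ArithDecoder &dec, int r0, int c0, int M, int N, SymRec &S) {
    int s = scaleIndexC(M, N);
    int f = fUs[s][dec.decode(flagU[s])];
    recSym(S, 0, f, -1);
    ONode nd; nd.flag = f; nd.mode = -1; nd.scale = s;
    nd.part = -1; nd.pidx = -1; nd.entry = -1; nd.c0 = nd.c1 = -1;
    if (f == 3) {
      nd.c0 = parseUnpred(dec, r0, c0, M, N / 2, S);
      nd.c1 = parseUnpred(dec, r0, c0 + N / 2, M, N / 2, S);
      collectSignalUpdate(r0, c0, M, N, s);
      arena.push_back(nd);
      return (int)arena.size() - 1;
    }
    if (f == 4) {
      nd.c0 = parseUnpred(dec, r0, c0, M / 2, N, S);
      nd.c1 = parseUnpred(dec, r0 + M / 2, c0, M / 2, N, S);
      collectSignalUpdate(r0, c0, M, N, s);
      arena.push_back(nd);
      return (int)arena.size() - 1;
    }
    int m = MODE_NONE;
    if (!mS[s].empty()) m = mS[s][dec.decode(modeM[s])];
    recSym(S, 1, m, -1);
    RefVecs rf = buildRefsC(rec, msk, H, W, r0, c0, M, N);
    std::vector<int> pred = predictFromRefs(rf, m, M, N);
    std::vector<int> rres((size_t)M * N, 0);
    int sub = parseResidueRest(dec, s, f, rres, N, 0, 0, M, N, S);
    arena[sub].mode = m;
    for (int i = 0; i < M; ++i)
      for (int j = 0; j < N; ++j) {
        size_t g = (size_t)(r0 + i) * W + c0 + j, l = (size_t)i * N + j;
        rec[g] = rres[l] + pred[l];
        msk[g] = 1;
      }
    return sub;
  }

  // --- dictionary update ------------------------------------------------
  bool tooClose(int s, const std::vector<int> &p) const {
    double thr = dthr * (double)p.size();
    for (const auto &q : pats[s]) {
      double ssd = 0; bool far_ = false;
      for (size_t i = 0; i < p.size(); ++i) {
        double d0 = (double)p[i] - q[i];
        ssd += d0 * d0;
        if (ssd > thr) { far_ = true; break; }
      }
      if (!far_) return true;
    }
    return false;
  }
  void insertPattern(int s, const std::vector<int> &p, int origin) {
    if ((int)pats[s].size() >= cap) return;
    if (tooClose(s, p)) return;
    appendEntry(s, p, origin);
  }
  void applyUpdates() {
    for (const UpdateRec &u : updates) {
      for (int t = 1; t <= 25; ++t) {
        std::vector<int> pt = transformPat(u.pat, u.M, u.N, DIMM[t], DIMN[t]);
        insertPattern(t, pt, u.origin);
        if (addsym) {
          std::vector<int> np(pt.size());
          for (size_t i = 0; i < pt.size(); ++i) np[i] = -pt[i];
          insertPattern(t, np, u.origin);
        }
      }
    }
    updates.clear();
  }

  double stateHash() const {
    uint64_t h = dhash;
    auto mix = [&h](uint64_t v) {
      h ^= v + 0x9e3779b97f4a7c15ULL + (h << 6) + (h >> 2);
    };
    for (int s = 1; s <= 25; ++s) {
      mix(pats[s].size());
      for (uint32_t f : flagU[s].freq) mix(f);
      for (uint32_t f : flagR[s].freq) mix(f);
      for (uint32_t f : modeM[s].freq) mix(f);
      mix(partM[s].total);
      for (int p = 0; p < 26; ++p) mix(idxM[s][p].total);
    }
    return (double)(h & ((1ULL << 53) - 1));
  }

  // --- tree export -------------------------------------------------------
  List nodeToR(int id) const {
    const ONode &nd = arena[id];
    const char *kinds[] = {"leaf", "vsplit", "hsplit", "pred_vsplit", "pred_hsplit"};
    if (nd.flag == 0) {
      return List::create(
        _["kind"] = kinds[0], _["scale"] = nd.scale,
        _["mode"] = nd.mode < 0 ? R_NilValue : wrap(nd.mode),
        _["partition"] = nd.part, _["index"] = nd.pidx + 1);
    }
    return List::create(
      _["kind"] = kinds[nd.flag], _["scale"] = nd.scale,
      _["mode"] = nd.mode < 0 ? R_NilValue : wrap(nd.mode),
      _["children"] = List::create(nodeToR(nd.c0), nodeToR(nd.c1)));
  }
};

static IntegerMatrix symToR(const SymRec &S) {
  int n = (int)S.type.size();
  IntegerMatrix m(n, 3);
  for (int i = 0; i < n; ++i) {
    m(i, 0) = S.type[i]; m(i, 1) = S.value[i]; m(i, 2) = S.part[i];
  }
  colnames(m) = CharacterVector::create("type", "value", "partition");
  return m;
}

// ------------------------------------------------------------- exports ----

// [[Rcpp::export]]
int cpp_scale_index(int M, int N) {
  if (!validDim(M) || !validDim(N))
    stop("block dimensions must be powers of two in {1,...,16}");
  return scaleIndexC(M, N);
}

// [[Rcpp::export]]
IntegerVector cpp_dict_levels(int Xmax) {
  if (Xmax < 1) stop("X_max must be >= 1");
  return wrap(dictLevelsC(Xmax));
}

// [[Rcpp::export]]
List cpp_build_refs(IntegerMatrix recon, LogicalMatrix mask,
                    int r0, int c0, int M, int N) {
  int H = recon.nrow(), W = recon.ncol();
  std::vector<int> rc((size_t)H * W);
  std::vector<uint8_t> mk((size_t)H * W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      rc[(size_t)i * W + j] = recon(i, j);
      mk[(size_t)i * W + j] = mask(i, j) ? 1 : 0;
    }
  RefVecs rf = buildRefsC(rc, mk, H, W, r0 - 1, c0 - 1, M, N);
  return List::create(_["vertical"] = wrap(rf.L), _["horizontal"] = wrap(rf.A));
}

// [[Rcpp::export]]
IntegerMatrix cpp_predict_block(IntegerVector vertical, IntegerVector horizontal,
                                int mode, int M, int N) {
  int need = 2 * std::max(M, N) + 1;
  if (vertical.size() < need || horizontal.size() < need)
    stop("reference vectors must have at least 2*max(M,N)+1 samples");
  RefVecs rf;
  rf.L.assign(vertical.begin(), vertical.begin() + need);
  rf.A.assign(horizontal.begin(), horizontal.begin() + need);
  std::vector<int> out = predictFromRefs(rf, mode, M, N);
  IntegerMatrix o(M, N);
  for (int i = 0; i < M; ++i)
    for (int j = 0; j < N; ++j) o(i, j) = out[(size_t)i * N + j];
  return o;
}

// [[Rcpp::export]]
IntegerMatrix cpp_scale_transform(IntegerMatrix pat, int M, int N) {
  if (!validDim(M) || !validDim(N) ||
      !validDim(pat.nrow()) || !validDim(pat.ncol()))
    stop("dimensions must be powers of two in {1,...,16}");
  int sm = pat.nrow(), sn = pat.ncol();
  std::vector<int> p((size_t)sm * sn);
  for (int i = 0; i < sm; ++i)
    for (int j = 0; j < sn; ++j) p[(size_t)i * sn + j] = pat(i, j);
  std::vector<int> out = transformPat(p, sm, sn, M, N);
  IntegerMatrix o(M, N);
  for (int i = 0; i < M; ++i)
    for (int j = 0; j < N; ++j) o(i, j) = out[(size_t)i * N + j];
  return o;
}

// [[Rcpp::export]]
List cpp_best_match(IntegerMatrix block, List entries, double lambda,
                    NumericVector rates) {
  int M = block.nrow(), N = block.ncol();
  int n = entries.size();
  if (n == 0) stop("empty dictionary scale");
  double best = R_PosInf; int bi = -1;
  for (int e = 0; e < n; ++e) {
    IntegerMatrix q = entries[e];
    if (q.nrow() != M || q.ncol() != N) stop("entry dimension mismatch");
    double ssd = 0;
    for (int i = 0; i < M; ++i)
      for (int j = 0; j < N; ++j) {
        double d0 = (double)block(i, j) - q(i, j);
        ssd += d0 * d0;
      }
    double cost = ssd + lambda * (rates.size() ? rates[e] : 0.0);
    if (cost < best) { best = cost; bi = e; }
  }
  return List::create(_["index"] = bi + 1, _["cost"] = best);
}

// [[Rcpp::export]]
RawVector cpp_arith_encode(IntegerVector syms, int nalpha) {
  if (nalpha < 1) stop("alphabet size must be >= 1");
  AdaptiveModel m; m.init(nalpha);
  ArithEncoder enc;
  for (int i = 0; i < syms.size(); ++i) {
    int s = syms[i];
    if (s < 0 || s >= nalpha) stop("symbol outside alphabet");
    enc.encode(m, s);
  }
  std::vector<uint8_t> b = enc.finish();
  RawVector out(b.size());
  std::copy(b.begin(), b.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_arith_decode(RawVector bytes, int n, int nalpha) {
  if (nalpha < 1) stop("alphabet size must be >= 1");
  AdaptiveModel m; m.init(nalpha);
  std::vector<uint8_t> b(bytes.begin(), bytes.end());
  if (n > 0 && b.empty()) stop("bitstream exhausted");
  ArithDecoder dec(b.data(), b.size());
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = dec.decode(m);
  return out;
}

static Codec *makeCodec(int H, int W, int Xmax, double lambda, List opts) {
  if (H % 16 || W % 16) stop("matrix must be padded to multiples of 16");
  Codec *cd = new Codec();
  cd->init(H, W, Xmax, lambda, opts);
  return cd;
}

// [[Rcpp::export]]
List cpp_mmp_encode(IntegerMatrix mat, double lambda, List opts) {
  int H = mat.nrow(), W = mat.ncol();
  int Xmax = 1;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) Xmax = std::max(Xmax, std::abs(mat(i, j)));
  Codec *cd = makeCodec(H, W, Xmax, lambda, opts);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) cd->img[(size_t)i * W + j] = mat(i, j);

  int nb = (H / 16) * (W / 16);
  ArithEncoder enc;
  List trees(nb), symbols(nb);
  NumericVector hashes(nb);
  IntegerMatrix dsizes(nb, 25);
  int bi = 0;
  for (int br = 0; br < H; br += 16) {
    for (int bc = 0; bc < W; bc += 16) {
      cd->prepBlock();
      cd->arena.clear();
      Codec::DPSolver noneDP(cd, cd->img.data() + (size_t)br * W + bc, W);
      OptRes r = cd->optimizeUnpred(br, bc, 16, 16, noneDP, br, bc);
      cd->clearPatch(br, bc, 16, 16);
      cd->updates.clear();
      SymRec S;
      cd->emitUnpred(&enc, r.node, br, bc, 16, 16, S);
      cd->applyUpdates();
      trees[bi] = cd->nodeToR(r.node);
      symbols[bi] = symToR(S);
      hashes[bi] = cd->stateHash();
      for (int s = 1; s <= 25; ++s) dsizes(bi, s - 1) = (int)cd->pats[s].size();
      ++bi;
      Rcpp::checkUserInterrupt();
    }
  }
  std::vector<uint8_t> payload = enc.finish();
  RawVector pv(payload.size());
  std::copy(payload.begin(), payload.end(), pv.begin());
  IntegerMatrix recon(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) recon(i, j) = cd->rec[(size_t)i * W + j];
  delete cd;
  return List::create(
    _["payload"] = pv, _["recon"] = recon, _["x_max"] = Xmax,
    _["trees"] = trees, _["symbols"] = symbols,
    _["dict_sizes"] = dsizes, _["state_hash"] = hashes,
    _["bits"] = (int)(payload.size() * 8));
}

// [[Rcpp::export]]
List cpp_mmp_decode(RawVector payload, int H, int W, int Xmax,
                    double lambda, List opts) {
  Codec *cd = makeCodec(H, W, Xmax, lambda, opts);
  std::vector<uint8_t> b(payload.begin(), payload.end());
  ArithDecoder dec(b.data(), b.size());
  int nb = (H / 16) * (W / 16);
  List trees(nb), symbols(nb);
  NumericVector hashes(nb);
  IntegerMatrix dsizes(nb, 25);
  int bi = 0;
  for (int br = 0; br < H; br += 16) {
    for (int bc = 0; bc < W; bc += 16) {
      cd->arena.clear();
      cd->updates.clear();
      SymRec S;
      int node = cd->parseUnpred(dec, br, bc, 16, 16, S);
      cd->applyUpdates();
      trees[bi] = cd->nodeToR(node);
      symbols[bi] = symToR(S);
      hashes[bi] = cd->stateHash();
      for (int s = 1; s <= 25; ++s) dsizes(bi, s - 1) = (int)cd->pats[s].size();
      ++bi;
      Rcpp::checkUserInterrupt();
    }
  }
  IntegerMatrix recon(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) recon(i, j) = cd->rec[(size_t)i * W + j];
  delete cd;
  return List::create(
    _["recon"] = recon, _["trees"] = trees, _["symbols"] = symbols,
    _["dict_sizes"] = dsizes, _["state_hash"] = hashes);
}
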