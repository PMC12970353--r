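// Minimal BFV implementation (RNS variant) sufficient for the blind-extraction
// kernel: batch encode/encrypt, slot rotation via Galois automorphisms with
// special-prime (hybrid) key switching, plaintext masking, exact decryption and
// invariant-noise-budget measurement.  No ciphertext-ciphertext multiplication,
// no relinearization, no bootstrapping.
//
// Conventions: ring R_q = Z_q[x]/(x^N+1), N a power of two.  q = prod(data
// primes); one extra "special" prime is reserved for key switching, as in the
// usual BFVDefault parameter sets (data modulus = all but the last prime).
// Plaintext modulus t is a batching prime, t = 1 (mod 2N).

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <numeric>
#include <cstring>
#include <vector>
#include <random>
#include <string>
#include <map>
#include <fstream>
#include <sstream>

using u64 = uint64_t;
using i64 = int64_t;
using u128 = unsigned __int128;

// ---------------------------------------------------------------- mod arith

static inline u64 addmod(u64 a, u64 b, u64 p) { u64 r = a + b; return r >= p ? r - p : r; }
static inline u64 submod(u64 a, u64 b, u64 p) { return a >= b ? a - b : a + p - b; }
static inline u64 mulmod(u64 a, u64 b, u64 p) { return (u64)(((u128)a * b) % p); }

static u64 powmod(u64 a, u64 e, u64 p) {
  u64 r = 1; a %= p;
  while (e) { if (e & 1) r = mulmod(r, a, p); a = mulmod(a, a, p); e >>= 1; }
  return r;
}

// Shoup precomputation: w' = floor(w * 2^64 / p); requires p < 2^63.
static inline u64 shoup(u64 w, u64 p) { return (u64)((((u128)w) << 64) / p); }
static inline u64 mulmod_shoup(u64 a, u64 w, u64 wsh, u64 p) {
  u64 q = (u64)(((u128)a * wsh) >> 64);
  u64 r = a * w - q * p;            // wraps mod 2^64, result < 2p
  return r >= p ? r - p : r;
}

// deterministic Miller-Rabin for 64-bit
static bool is_prime_u64(u64 n) {
  if (n < 2) return false;
  for (u64 p : {2ull, 3ull, 5ull, 7ull, 11ull, 13ull, 17ull, 19ull, 23ull, 29ull, 31ull, 37ull}) {
    if (n % p == 0) return n == p;
  }
  u64 d = n - 1; int s = 0;
  while (!(d & 1)) { d >>= 1; ++s; }
  for (u64 a : {2ull, 3ull, 5ull, 7ull, 11ull, 13ull, 17ull, 19ull, 23ull, 29ull, 31ull, 37ull}) {
    u64 x = powmod(a, d, n);
    if (x == 1 || x == n - 1) continue;
    bool comp = true;
    for (int i = 1; i < s; ++i) {
      x = mulmod(x, x, n);
      if (x == n - 1) { comp = false; break; }
    }
    if (comp) return false;
  }
  return true;
}

static inline u64 bitrev(u64 x, int bits) {
  u64 r = 0;
  for (int i = 0; i < bits; ++i) { r = (r << 1) | (x & 1); x >>= 1; }
  return r;
}

// ---------------------------------------------------------------- small bignum

// fixed-capacity little-endian bignum, enough for ~500-bit intermediates
struct Big {
  u64 d[10];
  int n; // number of used limbs (may have leading zero limbs trimmed)
  Big() : n(0) { std::memset(d, 0, sizeof(d)); }
  static Big from_u64(u64 v) { Big b; b.d[0] = v; b.n = v ? 1 : 0; return b; }
  void trim() { while (n > 0 && d[n - 1] == 0) --n; }
};

static int big_cmp(const Big& a, const Big& b) {
  if (a.n != b.n) return a.n < b.n ? -1 : 1;
  for (int i = a.n - 1; i >= 0; --i)
    if (a.d[i] != b.d[i]) return a.d[i] < b.d[i] ? -1 : 1;
  return 0;
}

static void big_add(Big& a, const Big& b) { // a += b
  u128 carry = 0; int m = std::max(a.n, b.n);
  for (int i = 0; i < m; ++i) {
    u128 s = (u128)a.d[i] + (i < b.n ? b.d[i] : 0) + carry;
    a.d[i] = (u64)s; carry = s >> 64;
  }
  a.n = m;
  if (carry) { a.d[a.n++] = (u64)carry; }
}

static void big_sub(Big& a, const Big& b) { // a -= b, requires a >= b
  u128 borrow = 0;
  for (int i = 0; i < a.n; ++i) {
    u128 s = (u128)a.d[i] - (i < b.n ? b.d[i] : 0) - borrow;
    a.d[i] = (u64)s; borrow = (s >> 64) ? 1 : 0;
  }
  a.trim();
}

static Big big_mul_u64(const Big& a, u64 m) {
  Big r; u128 carry = 0;
  for (int i = 0; i < a.n; ++i) {
    u128 s = (u128)a.d[i] * m + carry;
    r.d[i] = (u64)s; carry = s >> 64;
  }
  r.n = a.n;
  if (carry) r.d[r.n++] = (u64)carry;
  r.trim();
  return r;
}

// divide by 64-bit scalar; returns quotient, sets rem
static Big big_div_u64(const Big& a, u64 m, u64* rem) {
  Big q; q.n = a.n;
  u128 r = 0;
  for (int i = a.n - 1; i >= 0; --i) {
    u128 cur = (r << 64) | a.d[i];
    q.d[i] = (u64)(cur / m);
    r = cur % m;
  }
  q.trim();
  if (rem) *rem = (u64)r;
  return q;
}

static u64 big_mod_u64(const Big& a, u64 m) {
  u128 r = 0;
  for (int i = a.n - 1; i >= 0; --i) r = ((r << 64) | a.d[i]) % m;
  return (u64)r;
}

static Big big_shl(const Big& a, int bits) {
  Big r;
  int limb = bits / 64, off = bits % 64;
  r.n = a.n + limb + 1;
  if (r.n > 10) r.n = 10;
  for (int i = a.n - 1; i >= 0; --i) {
    u128 v = ((u128)a.d[i]) << off;
    int lo = i + limb;
    if (lo + 1 < 10) r.d[lo + 1] |= (u64)(v >> 64);
    if (lo < 10) r.d[lo] |= (u64)v;
  }
  r.trim();
  return r;
}

static int big_bits(const Big& a) {
  if (a.n == 0) return 0;
  u64 top = a.d[a.n - 1];
  int b = 0; while (top) { ++b; top >>= 1; }
  return 64 * (a.n - 1) + b;
}

static long double big_to_ld(const Big& a) {
  long double v = 0, scale = 1;
  for (int i = 0; i < a.n; ++i) { v += (long double)a.d[i] * scale; scale *= 18446744073709551616.0L; }
  return v;
}

// floor(a / b) by binary long division; the quotient must fit in 64 bits
static u64 big_div_u64_quotient(const Big& a, const Big& b) {
  if (big_cmp(a, b) < 0) return 0;
  int shift = big_bits(a) - big_bits(b);
  Big r = a;
  u64 q = 0;
  for (int i = shift; i >= 0; --i) {
    Big bs = big_shl(b, i);
    if (big_cmp(r, bs) >= 0) { big_sub(r, bs); q |= (1ull << i); }
  }
  return q;
}

// ---------------------------------------------------------------- NTT tables

struct NTTTables {
  u64 p;
  int N, logN;
  std::vector<u64> psi_rev, psi_rev_sh;       // psi^{brv(i)} and Shoup companions
  std::vector<u64> psi_inv_rev, psi_inv_rev_sh;
  u64 n_inv, n_inv_sh;

  void init(u64 prime, int degree) {
    p = prime; N = degree;
    logN = 0; while ((1 << logN) < N) ++logN;
    // find primitive 2N-th root of unity: since 2N is a power of two it
    // suffices that psi^N = -1
    u64 psi = 0;
    std::mt19937_64 g(0x5eedULL ^ prime);
    while (true) {
      u64 a = g() % (p - 2) + 2;
      u64 c = powmod(a, (p - 1) / (2 * (u64)N), p);
      if (powmod(c, N, p) == p - 1) { psi = c; break; }
    }
    u64 psi_inv = powmod(psi, p - 2, p);
    psi_rev.assign(N, 0); psi_inv_rev.assign(N, 0);
    u64 pw = 1, pwi = 1;
    std::vector<u64> pows(N), powsi(N);
    for (int i = 0; i < N; ++i) { pows[i] = pw; powsi[i] = pwi; pw = mulmod(pw, psi, p); pwi = mulmod(pwi, psi_inv, p); }
    for (int i = 0; i < N; ++i) {
      psi_rev[i] = pows[bitrev(i, logN)];
      psi_inv_rev[i] = powsi[bitrev(i, logN)];
    }
    psi_rev_sh.resize(N); psi_inv_rev_sh.resize(N);
    for (int i = 0; i < N; ++i) { psi_rev_sh[i] = shoup(psi_rev[i], p); psi_inv_rev_sh[i] = shoup(psi_inv_rev[i], p); }
    n_inv = powmod(N, p - 2, p); n_inv_sh = shoup(n_inv, p);
  }

  // in-place forward negacyclic NTT, natural coeff order in, bit-reversed out.
  // Harvey-style lazy reduction: coefficients stay < 4p inside the loop
  // (p < 2^60 so no overflow), fully reduced on exit.
  void fwd(u64* a) const {
    const u64 twop = 2 * p;
    int t = N;
    for (int m = 1; m < N; m <<= 1) {
      t >>= 1;
      for (int i = 0; i < m; ++i) {
        int j1 = 2 * i * t, j2 = j1 + t;
        u64 S = psi_rev[m + i], Ssh = psi_rev_sh[m + i];
        for (int j = j1; j < j2; ++j) {
          u64 U = a[j];
          if (U >= twop) U -= twop;                       // < 2p
          u64 T = a[j + t];
          u64 q = (u64)(((u128)T * Ssh) >> 64);
          u64 V = T * S - q * p;                          // < 2p
          a[j] = U + V;                                   // < 4p
          a[j + t] = U - V + twop;                        // < 4p
        }
      }
    }
    for (int j = 0; j < N; ++j) {
      u64 v = a[j];
      if (v >= twop) v -= twop;
      if (v >= p) v -= p;
      a[j] = v;
    }
  }

  // in-place inverse negacyclic NTT, bit-reversed in, natural coeff order out
  void inv(u64* a) const {
    const u64 twop = 2 * p;
    int t = 1;
    for (int m = N; m > 1; m >>= 1) {
      int j1 = 0, h = m >> 1;
      for (int i = 0; i < h; ++i) {
        int j2 = j1 + t;
        u64 S = psi_inv_rev[h + i], Ssh = psi_inv_rev_sh[h + i];
        for (int j = j1; j < j2; ++j) {
          u64 U = a[j], V = a[j + t];                     // both < 2p
          u64 T0 = U + V;
          if (T0 >= twop) T0 -= twop;
          a[j] = T0;                                      // < 2p
          u64 T1 = U - V + twop;                          // < 4p
          u64 q = (u64)(((u128)T1 * Ssh) >> 64);
          a[j + t] = T1 * S - q * p;                      // < 2p
        }
        j1 += 2 * t;
      }
      t <<= 1;
    }
    for (int j = 0; j < N; ++j) {
      u64 q = (u64)(((u128)a[j] * n_inv_sh) >> 64);
      u64 v = a[j] * n_inv - q * p;
      if (v >= p) v -= p;
      a[j] = v;
    }
  }
};

// ---------------------------------------------------------------- parameters

struct GaloisPrecomp {
  std::vector<uint32_t> tgt;
  std::vector<uint8_t> flip;
};

struct BFVContext {
  int N, logN;
  int sec_bits;
  u64 t;
  int t_bits_req;
  std::vector<int> coeff_bits;          // includes special prime (last)
  std::vector<u64> primes;              // data primes + special prime (last)
  int L;                                // number of data primes
  std::vector<NTTTables> tab;           // per prime
  NTTTables ttab;                       // mod t (for batching)

  // CRT / scaling precomputation over the data modulus Q
  Big Q;
  int Q_bits;
  std::vector<Big> Q_over_qj;           // Q / q_j
  std::vector<u64> crt_inv;             // (Q/q_j)^{-1} mod q_j
  std::vector<u64> delta_mod_qj;        // floor(Q/t) mod q_j
  u64 QmodT;                            // Q mod t
  u64 P;                                // special prime
  std::vector<u64> P_mod_qj, Pinv_mod_qj;

  std::vector<uint32_t> slot_pos;       // slot index -> position in NTT output
  std::map<u64, GaloisPrecomp> gal;     // galois element -> index map
  std::vector<u64> pow3;                // 3^r mod 2N for r = 0..N/2-1
  int bs_base;                          // baby-step/giant-step base ~ sqrt(N/2)
  std::vector<u64> key_elts;            // galois elements holding switch keys
  u64 gal_swap;                         // 2N - 1

  // keys
  bool has_secret = false;
  std::vector<int8_t> s_ternary;                       // secret key coeffs
  std::vector<std::vector<u64>> s_ntt;                 // per prime (all), NTT
  std::vector<std::vector<u64>> pk0, pk1;              // per data prime, NTT
  // galois keys: element -> digit i -> {k0, k1} over all primes, NTT domain
  std::map<u64, std::vector<std::vector<std::vector<u64>>>> gkeys;

  std::vector<std::vector<u64>> mask_ntt;              // encode(e0) per data prime

  std::mt19937_64 rng;
  long op_rot = 0, op_mask = 0;
  std::string fingerprint;
  uint32_t fp_hash = 0;
};

static uint32_t fnv32(const std::string& s) {
  uint32_t h = 2166136261u;
  for (char c : s) { h ^= (uint8_t)c; h *= 16777619u; }
  return h;
}

static std::vector<int> default_coeff_bits_for(int N) {
  // standard BFVDefault chains at 128-bit security
  if (N == 4096) return {36, 36, 37};
  if (N == 8192) return {43, 43, 44, 44, 44};
  if (N == 16384) return {48, 48, 48, 49, 49, 49, 49, 49, 49};
  Rcpp::stop("no default coefficient modulus for poly_degree %d (supported: 4096, 8192, 16384)", N);
}

static int max_coeff_bits_128(int N) {
  if (N == 4096) return 109;
  if (N == 8192) return 218;
  if (N == 16384) return 438;
  return 0;
}

// largest prime below 2^bits with p = 1 (mod m), distinct from `used`
static u64 find_coeff_prime(int bits, u64 m, const std::vector<u64>& used) {
  u64 cand = (bits == 64) ? ~0ull : ((1ull << bits) - 1);
  cand -= (cand % m); cand += 1;               // = 1 mod m
  while (cand > (1ull << (bits - 1))) {
    if (is_prime_u64(cand)) {
      bool dup = false;
      for (u64 u : used) if (u == cand) dup = true;
      if (!dup) return cand;
    }
    cand -= m;
  }
  Rcpp::stop("no suitable %d-bit NTT prime found", bits);
}

// smallest prime of the requested bit length with p = 1 (mod m)
static u64 find_plain_prime(int bits, u64 m) {
  u64 lo = 1ull << (bits - 1);
  u64 cand = lo + ((m + 1 - lo % m) % m);      // smallest >= lo with cand = 1 mod m
  while (cand < (1ull << bits)) {
    if (is_prime_u64(cand)) return cand;
    cand += m;
  }
  Rcpp::stop("no %d-bit batching prime = 1 mod %llu exists", bits, (unsigned long long)m);
}

static void build_galois_precomp(BFVContext& C, u64 g) {
  GaloisPrecomp P;
  P.tgt.resize(C.N); P.flip.resize(C.N);
  u64 M = 2ull * C.N;
  for (int j = 0; j < C.N; ++j) {
    u64 k = ((u64)j * g) % M;
    if (k < (u64)C.N) { P.tgt[j] = (uint32_t)k; P.flip[j] = 0; }
    else { P.tgt[j] = (uint32_t)(k - C.N); P.flip[j] = 1; }
  }
  C.gal[g] = std::move(P);
}

// apply automorphism x -> x^g to a coefficient-domain poly
static void apply_galois(const BFVContext& C, u64 g, const u64* a, u64* out, u64 p) {
  const GaloisPrecomp& G = C.gal.at(g);
  for (int j = 0; j < C.N; ++j) {
    u64 v = a[j];
    out[G.tgt[j]] = (G.flip[j] && v != 0) ? p - v : v;
  }
}

// ---------------------------------------------------------------- sampling

static inline int cbd21(std::mt19937_64& rng) {
  u64 r = rng();
  int x = __builtin_popcountll(r & ((1ull << 21) - 1));
  int y = __builtin_popcountll((r >> 21) & ((1ull << 21) - 1));
  return x - y;                                // sigma ~ 3.24
}

static inline int ternary(std::mt19937_64& rng) { return (int)(rng() % 3) - 1; }

// ---------------------------------------------------------------- context setup

static void keygen_internal(BFVContext& C) {
  int N = C.N;
  // secret key
  C.s_ternary.resize(N);
  for (int i = 0; i < N; ++i) C.s_ternary[i] = (int8_t)ternary(C.rng);
  int K = (int)C.primes.size();
  C.s_ntt.assign(K, std::vector<u64>(N));
  for (int jp = 0; jp < K; ++jp) {
    u64 p = C.primes[jp];
    for (int i = 0; i < N; ++i) {
      int8_t v = C.s_ternary[i];
      C.s_ntt[jp][i] = v < 0 ? p - 1 : (u64)v;
    }
    C.tab[jp].fwd(C.s_ntt[jp].data());
  }
  // public key over data primes
  C.pk0.assign(C.L, std::vector<u64>(N));
  C.pk1.assign(C.L, std::vector<u64>(N));
  std::vector<int> e(N);
  for (int i = 0; i < N; ++i) e[i] = cbd21(C.rng);
  for (int jp = 0; jp < C.L; ++jp) {
    u64 p = C.primes[jp];
    std::vector<u64> en(N);
    for (int i = 0; i < N; ++i) en[i] = e[i] < 0 ? p - (u64)(-e[i]) : (u64)e[i];
    C.tab[jp].fwd(en.data());
    for (int i = 0; i < N; ++i) {
      u64 a = C.rng() % p;                     // uniform a, NTT domain
      C.pk1[jp][i] = a;
      C.pk0[jp][i] = submod(0, addmod(mulmod(a, C.s_ntt[jp][i], p), en[i], p), p);
    }
  }
  // galois keys for the baby-step/giant-step rotation set and the row swap
  for (u64 g : C.key_elts) {
    std::vector<u64> sg(N);                    // sigma_g(s) coefficients, signed
    std::vector<i64> sgs(N, 0);
    {
      u64 M = 2ull * N;
      for (int j = 0; j < N; ++j) {
        u64 k = ((u64)j * g) % M;
        i64 v = C.s_ternary[j];
        if (k < (u64)N) sgs[k] += v; else sgs[k - N] -= v;
      }
    }
    auto& key = C.gkeys[g];
    key.assign(C.L, std::vector<std::vector<u64>>(2, std::vector<u64>(K * N)));
    for (int i = 0; i < C.L; ++i) {
      std::vector<int> ei(N);
      for (int x = 0; x < N; ++x) ei[x] = cbd21(C.rng);
      for (int jp = 0; jp < K; ++jp) {
        u64 p = C.primes[jp];
        std::vector<u64> en(N), sgp(N);
        for (int x = 0; x < N; ++x) {
          en[x] = ei[x] < 0 ? p - (u64)(-ei[x]) : (u64)ei[x];
          i64 v = sgs[x];
          sgp[x] = v < 0 ? p - (u64)(-v) : (u64)v;
        }
        C.tab[jp].fwd(en.data());
        C.tab[jp].fwd(sgp.data());
        u64* k0 = key[i][0].data() + (size_t)jp * N;
        u64* k1 = key[i][1].data() + (size_t)jp * N;
        for (int x = 0; x < N; ++x) {
          u64 a = C.rng() % p;
          k1[x] = a;
          u64 v = submod(0, addmod(mulmod(a, C.s_ntt[jp][x], p), en[x], p), p);
          if (jp == i) {
            // + P * sigma_g(s) on the matching data prime
            u64 term = mulmod(C.P % p, sgp[x], p);
            v = addmod(v, term, p);
          }
          k0[x] = v;
        }
      }
    }
  }
  C.has_secret = true;
}

static void setup_context(BFVContext& C, int N, int t_bits, int sec_bits,
                          std::vector<int> coeff_bits, u64 seed) {
  if (N < 4096 || (N & (N - 1)) != 0)
    Rcpp::stop("poly_degree must be a power of two >= 4096 (got %d)", N);
  if (sec_bits != 128)
    Rcpp::stop("unsupported security level %d (only 128-bit supported)", sec_bits);
  if (t_bits < 16 || t_bits > 40)
    Rcpp::stop("plain_modulus_bits out of supported range [16, 40]");
  C.N = N;
  C.logN = 0; while ((1 << C.logN) < N) ++C.logN;
  C.sec_bits = sec_bits;
  C.t_bits_req = t_bits;
  if (coeff_bits.empty()) coeff_bits = default_coeff_bits_for(N);
  if ((int)coeff_bits.size() < 2)
    Rcpp::stop("coefficient modulus needs at least 2 primes (data + special)");
  int tot = 0; for (int b : coeff_bits) {
    if (b < 20 || b > 60) Rcpp::stop("coefficient prime bit-length %d out of range [20, 60]", b);
    tot += b;
  }
  int mx = max_coeff_bits_128(N);
  if (mx > 0 && tot > mx)
    Rcpp::stop("coefficient modulus of %d bits exceeds the %d-bit cap for 128-bit security at N=%d", tot, mx, N);
  C.coeff_bits = coeff_bits;
  u64 m = 2ull * N;
  C.t = find_plain_prime(t_bits, m);
  C.primes.clear();
  for (int b : coeff_bits) {
    if ((1ull << b) <= C.t && b <= t_bits)
      Rcpp::stop("coefficient primes must exceed the plaintext modulus");
    C.primes.push_back(find_coeff_prime(b, m, C.primes));
  }
  C.L = (int)C.primes.size() - 1;
  C.P = C.primes.back();
  C.tab.resize(C.primes.size());
  for (size_t i = 0; i < C.primes.size(); ++i) C.tab[i].init(C.primes[i], N);
  C.ttab.init(C.t, N);

  // CRT precomputation over Q (data primes)
  C.Q = Big::from_u64(1);
  for (int j = 0; j < C.L; ++j) C.Q = big_mul_u64(C.Q, C.primes[j]);
  C.Q_bits = big_bits(C.Q);
  C.Q_over_qj.clear(); C.crt_inv.clear();
  for (int j = 0; j < C.L; ++j) {
    Big qj = big_div_u64(C.Q, C.primes[j], nullptr);
    C.Q_over_qj.push_back(qj);
    u64 r = big_mod_u64(qj, C.primes[j]);
    C.crt_inv.push_back(powmod(r, C.primes[j] - 2, C.primes[j]));
  }
  u64 rem = 0;
  Big delta = big_div_u64(C.Q, C.t, &rem);
  C.QmodT = rem;
  C.delta_mod_qj.clear();
  for (int j = 0; j < C.L; ++j) C.delta_mod_qj.push_back(big_mod_u64(delta, C.primes[j]));
  C.P_mod_qj.clear(); C.Pinv_mod_qj.clear();
  for (int j = 0; j < C.L; ++j) {
    u64 pm = C.P % C.primes[j];
    C.P_mod_qj.push_back(pm);
    C.Pinv_mod_qj.push_back(powmod(pm, C.primes[j] - 2, C.primes[j]));
  }

  // slot index map: slot k of row 0 evaluates at psi^(3^k), row 1 at psi^(-3^k).
  // forward NTT output position i holds the evaluation at psi^(2*brv(i)+1).
  C.slot_pos.resize(N);
  {
    u64 M = 2ull * N, pos = 1;
    int half = N / 2;
    for (int k = 0; k < half; ++k) {
      u64 e1 = pos, e2 = M - pos;
      C.slot_pos[k] = (uint32_t)bitrev((e1 - 1) / 2, C.logN);
      C.slot_pos[half + k] = (uint32_t)bitrev((e2 - 1) / 2, C.logN);
      pos = (pos * 3) % M;
    }
  }

  // galois elements: any row rotation r in [1, N/2) decomposes as
  // r = base*j + b, covered by one giant-step and one baby-step key
  {
    u64 M = 2ull * N;
    int half = N / 2;
    C.pow3.resize(half);
    C.pow3[0] = 1;
    for (int r = 1; r < half; ++r) C.pow3[r] = (C.pow3[r - 1] * 3) % M;
    int base = 1; while (base * base < half) base <<= 1;   // power of two ~ sqrt(N/2)
    C.bs_base = base;
    C.key_elts.clear();
    for (int b = 1; b < base; ++b) C.key_elts.push_back(C.pow3[b]);
    for (int j = 1; (u64)base * j < (u64)half; ++j) C.key_elts.push_back(C.pow3[base * j]);
    C.gal_swap = M - 1;
    C.key_elts.push_back(C.gal_swap);
    for (u64 g : C.key_elts) build_galois_precomp(C, g);
  }

  std::ostringstream fp;
  fp << "bfv|N=" << N << "|t=" << C.t << "|q=";
  for (size_t i = 0; i < coeff_bits.size(); ++i) fp << (i ? "," : "") << coeff_bits[i];
  fp << "|sec=" << sec_bits;
  C.fingerprint = fp.str();
  C.fp_hash = fnv32(C.fingerprint);

  C.rng.seed(seed);
}

static void build_mask(BFVContext& C) {
  // encode the unit vector e0 and lift it (centered) to each data prime, NTT
  int N = C.N;
  std::vector<u64> ev(N, 0);
  ev[C.slot_pos[0]] = 1;
  C.ttab.inv(ev.data());                        // wrong domain order? see note
  // NOTE: encode path is evals (bit-reversed positions) -> inverse NTT ->
  // coefficients; slot_pos already indexes the bit-reversed layout.
  C.mask_ntt.assign(C.L, std::vector<u64>(N));
  u64 t = C.t;
  for (int jp = 0; jp < C.L; ++jp) {
    u64 p = C.primes[jp];
    for (int i = 0; i < N; ++i) {
      u64 v = ev[i];
      // centered lift from [0,t) to signed, then mod p
      if (v > t / 2) C.mask_ntt[jp][i] = p - ((t - v) % p);
      else C.mask_ntt[jp][i] = v % p;
      if (C.mask_ntt[jp][i] == p) C.mask_ntt[jp][i] = 0;
    }
    C.tab[jp].fwd(C.mask_ntt[jp].data());
  }
}

// ---------------------------------------------------------------- ciphertexts

// ciphertext: 2 polys over data primes, coefficient domain
struct Ct {
  std::vector<std::vector<u64>> c0, c1;        // [L][N]
};

static const uint32_t CT_MAGIC = 0x43424631;   // "CBF1"

static Rcpp::RawVector ct_serialize(const BFVContext& C, const Ct& ct) {
  size_t polybytes = (size_t)C.L * C.N * 8;
  Rcpp::RawVector out(16 + 2 * polybytes);
  uint8_t* p = (uint8_t*)RAW(out);
  uint32_t hdr[4] = {CT_MAGIC, C.fp_hash, (uint32_t)C.L, (uint32_t)C.N};
  std::memcpy(p, hdr, 16); p += 16;
  for (int j = 0; j < C.L; ++j) { std::memcpy(p, ct.c0[j].data(), (size_t)C.N * 8); p += (size_t)C.N * 8; }
  for (int j = 0; j < C.L; ++j) { std::memcpy(p, ct.c1[j].data(), (size_t)C.N * 8); p += (size_t)C.N * 8; }
  return out;
}

static Ct ct_deserialize(const BFVContext& C, const Rcpp::RawVector& raw) {
  if ((size_t)raw.size() < 16) Rcpp::stop("corrupt ciphertext blob (too short)");
  const uint8_t* p = (const uint8_t*)RAW(raw);
  uint32_t hdr[4];
  std::memcpy(hdr, p, 16); p += 16;
  if (hdr[0] != CT_MAGIC) Rcpp::stop("corrupt ciphertext blob (bad magic)");
  if (hdr[1] != C.fp_hash) Rcpp::stop("ciphertext was produced under different parameters (fingerprint mismatch)");
  if (hdr[2] != (uint32_t)C.L || hdr[3] != (uint32_t)C.N) Rcpp::stop("ciphertext shape mismatch");
  size_t need = 16 + 2 * (size_t)C.L * C.N * 8;
  if ((size_t)raw.size() != need) Rcpp::stop("corrupt ciphertext blob (wrong length)");
  Ct ct;
  ct.c0.assign(C.L, std::vector<u64>(C.N));
  ct.c1.assign(C.L, std::vector<u64>(C.N));
  for (int j = 0; j < C.L; ++j) { std::memcpy(ct.c0[j].data(), p, (size_t)C.N * 8); p += (size_t)C.N * 8; }
  for (int j = 0; j < C.L; ++j) { std::memcpy(ct.c1[j].data(), p, (size_t)C.N * 8); p += (size_t)C.N * 8; }
  return ct;
}

// encode slot values (mod t) into a plaintext polynomial (coeff domain mod t)
static std::vector<u64> encode_slots(const BFVContext& C, const std::vector<u64>& slots) {
  std::vector<u64> ev(C.N);
  for (int i = 0; i < C.N; ++i) ev[C.slot_pos[i]] = slots[i] % C.t;
  C.ttab.inv(ev.data());
  return ev;
}

static std::vector<u64> decode_slots(const BFVContext& C, std::vector<u64> poly) {
  C.ttab.fwd(poly.data());
  std::vector<u64> slots(C.N);
  for (int i = 0; i < C.N; ++i) slots[i] = poly[C.slot_pos[i]];
  return slots;
}

static Ct encrypt_internal(BFVContext& C, const std::vector<u64>& slots) {
  int N = C.N;
  std::vector<u64> pm = encode_slots(C, slots);
  std::vector<int> u(N), e1(N), e2(N);
  for (int i = 0; i < N; ++i) { u[i] = ternary(C.rng); e1[i] = cbd21(C.rng); e2[i] = cbd21(C.rng); }
  Ct ct;
  ct.c0.assign(C.L, std::vector<u64>(N));
  ct.c1.assign(C.L, std::vector<u64>(N));
  for (int jp = 0; jp < C.L; ++jp) {
    u64 p = C.primes[jp];
    std::vector<u64> un(N);
    for (int i = 0; i < N; ++i) un[i] = u[i] < 0 ? p - 1 : (u64)u[i];
    C.tab[jp].fwd(un.data());
    std::vector<u64>& c0 = ct.c0[jp];
    std::vector<u64>& c1 = ct.c1[jp];
    for (int i = 0; i < N; ++i) {
      c0[i] = mulmod(un[i], C.pk0[jp][i], p);
      c1[i] = mulmod(un[i], C.pk1[jp][i], p);
    }
    C.tab[jp].inv(c0.data());
    C.tab[jp].inv(c1.data());
    for (int i = 0; i < N; ++i) {
      u64 ee1 = e1[i] < 0 ? p - (u64)(-e1[i]) : (u64)e1[i];
      u64 ee2 = e2[i] < 0 ? p - (u64)(-e2[i]) : (u64)e2[i];
      // scaled message: round(Q*m/t) = m*floor(Q/t) + round(m*(Q mod t)/t)
      u64 mcoef = pm[i];
      u64 rq = (u64)(((u128)mcoef * C.QmodT + C.t / 2) / C.t);
      u64 sm = (u64)(((u128)(mcoef % p) * C.delta_mod_qj[jp] + rq) % p);
      c0[i] = addmod(addmod(c0[i], ee1, p), sm, p);
      c1[i] = addmod(c1[i], ee2, p);
    }
  }
  return ct;
}

// w = c0 + c1*s over data primes, coefficient domain
static std::vector<std::vector<u64>> dot_with_secret(const BFVContext& C, const Ct& ct) {
  int N = C.N;
  std::vector<std::vector<u64>> w(C.L, std::vector<u64>(N));
  for (int jp = 0; jp < C.L; ++jp) {
    u64 p = C.primes[jp];
    std::vector<u64> c1n = ct.c1[jp];
    C.tab[jp].fwd(c1n.data());
    for (int i = 0; i < N; ++i) c1n[i] = mulmod(c1n[i], C.s_ntt[jp][i], p);
    C.tab[jp].inv(c1n.data());
    for (int i = 0; i < N; ++i) w[jp][i] = addmod(ct.c0[jp][i], c1n[i], p);
  }
  return w;
}

// CRT-compose residues (one per data prime) into W in [0, Q)
static Big crt_compose(const BFVContext& C, const u64* res_per_prime, int stride, int coeff) {
  Big W;
  for (int j = 0; j < C.L; ++j) {
    u64 wj = res_per_prime[(size_t)j * stride + coeff];
    u64 y = mulmod(wj, C.crt_inv[j], C.primes[j]);
    Big term = big_mul_u64(C.Q_over_qj[j], y);
    big_add(W, term);
  }
  while (big_cmp(W, C.Q) >= 0) big_sub(W, C.Q);
  return W;
}

// decrypt; if budget_out != nullptr also report the invariant-noise budget
// (the rounding residual t*W - round(t*W/Q)*Q IS the centered noise poly)
static std::vector<u64> decrypt_internal(const BFVContext& C, const Ct& ct, int* budget_out) {
  int N = C.N;
  std::vector<std::vector<u64>> w = dot_with_secret(C, ct);
  // flatten for crt_compose
  std::vector<u64> flat((size_t)C.L * N);
  for (int j = 0; j < C.L; ++j) std::memcpy(flat.data() + (size_t)j * N, w[j].data(), (size_t)N * 8);
  std::vector<u64> poly(N);
  Big norm;
  Big twoQ = big_mul_u64(C.Q, 2);
  for (int i = 0; i < N; ++i) {
    Big W = crt_compose(C, flat.data(), N, i);
    // m = round(t*W/Q) mod t, exactly: qh = floor((2*t*W + Q) / (2*Q))
    Big tW = big_mul_u64(W, C.t);
    Big num = big_mul_u64(tW, 2);
    big_add(num, C.Q);
    u64 qh = big_div_u64_quotient(num, twoQ);
    if (budget_out) {
      Big qQ = big_mul_u64(C.Q, qh);
      Big resid;
      if (big_cmp(qQ, tW) > 0) { resid = qQ; big_sub(resid, tW); }
      else { resid = tW; big_sub(resid, qQ); }
      if (big_cmp(resid, norm) > 0) norm = resid;
    }
    poly[i] = qh % C.t;
  }
  if (budget_out) {
    int budget = C.Q_bits - big_bits(norm) - 1;
    *budget_out = budget < 0 ? 0 : budget;
  }
  return decode_slots(C, poly);
}

static int noise_budget_internal(const BFVContext& C, const Ct& ct) {
  int N = C.N;
  std::vector<std::vector<u64>> w = dot_with_secret(C, ct);
  // residues of t*w mod each prime
  std::vector<u64> flat((size_t)C.L * N);
  for (int j = 0; j < C.L; ++j) {
    u64 p = C.primes[j];
    u64 tm = C.t % p;
    for (int i = 0; i < N; ++i) flat[(size_t)j * N + i] = mulmod(w[j][i], tm, p);
  }
  Big half = big_div_u64(C.Q, 2, nullptr);
  Big norm;
  for (int i = 0; i < N; ++i) {
    Big W = crt_compose(C, flat.data(), N, i);
    if (big_cmp(W, half) > 0) { Big tmp = C.Q; big_sub(tmp, W); W = tmp; }
    if (big_cmp(W, norm) > 0) norm = W;
  }
  int budget = C.Q_bits - big_bits(norm) - 1;
  return budget < 0 ? 0 : budget;
}

// hybrid key switch: given poly d (coeff domain, data primes) that multiplies
// sigma_g(s), produce (u0, u1) mod Q such that u0 + u1*s ~ d*sigma_g(s)
static void keyswitch(BFVContext& C, u64 g, const std::vector<std::vector<u64>>& d,
                      std::vector<std::vector<u64>>& u0, std::vector<std::vector<u64>>& u1) {
  int N = C.N, K = (int)C.primes.size();
  const auto& key = C.gkeys.at(g);
  // lazy 128-bit accumulation: at most L products of < 2^120 each, no overflow
  std::vector<std::vector<u128>> wide0(K, std::vector<u128>(N, 0)), wide1(K, std::vector<u128>(N, 0));
  std::vector<u64> tmp(N);
  for (int i = 0; i < C.L; ++i) {
    for (int jp = 0; jp < K; ++jp) {
      u64 p = C.primes[jp];
      const std::vector<u64>& di = d[i];
      if (C.primes[i] == p) std::memcpy(tmp.data(), di.data(), (size_t)N * 8);
      else for (int x = 0; x < N; ++x) tmp[x] = di[x] % p;
      C.tab[jp].fwd(tmp.data());
      const u64* k0 = key[i][0].data() + (size_t)jp * N;
      const u64* k1 = key[i][1].data() + (size_t)jp * N;
      u128* a0 = wide0[jp].data();
      u128* a1 = wide1[jp].data();
      for (int x = 0; x < N; ++x) {
        a0[x] += (u128)tmp[x] * k0[x];
        a1[x] += (u128)tmp[x] * k1[x];
      }
    }
  }
  std::vector<std::vector<u64>> acc0(K, std::vector<u64>(N)), acc1(K, std::vector<u64>(N));
  for (int jp = 0; jp < K; ++jp) {
    u64 p = C.primes[jp];
    for (int x = 0; x < N; ++x) {
      acc0[jp][x] = (u64)(wide0[jp][x] % p);
      acc1[jp][x] = (u64)(wide1[jp][x] % p);
    }
    C.tab[jp].inv(acc0[jp].data());
    C.tab[jp].inv(acc1[jp].data());
  }
  // mod-down by the special prime with rounding
  u0.assign(C.L, std::vector<u64>(N));
  u1.assign(C.L, std::vector<u64>(N));
  u64 P = C.P, halfP = P >> 1;
  for (int jp = 0; jp < C.L; ++jp) {
    u64 p = C.primes[jp];
    u64 Pmod = C.P_mod_qj[jp], Pinv = C.Pinv_mod_qj[jp];
    const u64* rp0 = acc0[C.L].data();
    const u64* rp1 = acc1[C.L].data();
    for (int x = 0; x < N; ++x) {
      u64 r0 = rp0[x], r1 = rp1[x];
      u64 r0m = r0 % p, r1m = r1 % p;
      if (r0 >= halfP) r0m = addmod(r0m, p - (Pmod % p), p);   // centered lift
      if (r1 >= halfP) r1m = addmod(r1m, p - (Pmod % p), p);
      u0[jp][x] = mulmod(submod(acc0[jp][x], r0m, p), Pinv, p);
      u1[jp][x] = mulmod(submod(acc1[jp][x], r1m, p), Pinv, p);
    }
  }
}

// apply one Galois rotation (automorphism + key switch) in place
static void rotate_galois(BFVContext& C, Ct& ct, u64 g) {
  int N = C.N;
  std::vector<std::vector<u64>> a0(C.L, std::vector<u64>(N)), a1(C.L, std::vector<u64>(N));
  for (int jp = 0; jp < C.L; ++jp) {
    apply_galois(C, g, ct.c0[jp].data(), a0[jp].data(), C.primes[jp]);
    apply_galois(C, g, ct.c1[jp].data(), a1[jp].data(), C.primes[jp]);
  }
  std::vector<std::vector<u64>> u0, u1;
  keyswitch(C, g, a1, u0, u1);
  for (int jp = 0; jp < C.L; ++jp) {
    u64 p = C.primes[jp];
    for (int x = 0; x < N; ++x) {
      ct.c0[jp][x] = addmod(a0[jp][x], u0[jp][x], p);
      ct.c1[jp][x] = u1[jp][x];
    }
  }
  C.op_rot += 1;
}

static void rotate_rows_by(BFVContext& C, Ct& ct, int steps) {
  int half = C.N / 2;
  steps %= half; if (steps < 0) steps += half;
  if (!steps) return;
  int j = steps / C.bs_base, b = steps % C.bs_base;
  if (j) rotate_galois(C, ct, C.pow3[C.bs_base * j]);
  if (b) rotate_galois(C, ct, C.pow3[b]);
}

static void mask_front_internal(BFVContext& C, Ct& ct) {
  int N = C.N;
  for (int jp = 0; jp < C.L; ++jp) {
    u64 p = C.primes[jp];
    C.tab[jp].fwd(ct.c0[jp].data());
    C.tab[jp].fwd(ct.c1[jp].data());
    for (int x = 0; x < N; ++x) {
      ct.c0[jp][x] = mulmod(ct.c0[jp][x], C.mask_ntt[jp][x], p);
      ct.c1[jp][x] = mulmod(ct.c1[jp][x], C.mask_ntt[jp][x], p);
    }
    C.tab[jp].inv(ct.c0[jp].data());
    C.tab[jp].inv(ct.c1[jp].data());
  }
  C.op_mask += 1;
}

// ---------------------------------------------------------------- R interface

using Rcpp::XPtr;

static BFVContext* get_ctx(SEXP xp) {
  XPtr<BFVContext> p(xp);
  if (!p) Rcpp::stop("invalid backend context pointer");
  return p.get();
}

// [[Rcpp::export(name = ".bfv_context_new")]]
SEXP bfv_context_new(int poly_degree, int plain_bits, int security_bits,
                     Rcpp::IntegerVector coeff_bits, double seed) {
  BFVContext* C = new BFVContext();
  std::vector<int> cb(coeff_bits.begin(), coeff_bits.end());
  setup_context(*C, poly_degree, plain_bits, security_bits, cb, (u64)seed);
  keygen_internal(*C);
  build_mask(*C);
  XPtr<BFVContext> xp(C, true);
  return xp;
}

// [[Rcpp::export(name = ".bfv_params")]]
Rcpp::List bfv_params(SEXP xp) {
  BFVContext* C = get_ctx(xp);
  Rcpp::IntegerVector cb(C->coeff_bits.begin(), C->coeff_bits.end());
  return Rcpp::List::create(
    Rcpp::Named("poly_degree") = C->N,
    Rcpp::Named("slot_count") = C->N,
    Rcpp::Named("plain_modulus") = (double)C->t,
    Rcpp::Named("plain_modulus_bits") = C->t_bits_req,
    Rcpp::Named("coeff_modulus_bits") = cb,
    Rcpp::Named("coeff_modulus_total_bits") = (int)std::accumulate(C->coeff_bits.begin(), C->coeff_bits.end(), 0),
    Rcpp::Named("data_modulus_bits") = C->Q_bits,
    Rcpp::Named("security_bits") = C->sec_bits,
    Rcpp::Named("fingerprint") = C->fingerprint,
    Rcpp::Named("has_secret") = C->has_secret);
}

// [[Rcpp::export(name = ".bfv_default_coeff_bits")]]
Rcpp::IntegerVector bfv_default_coeff_bits(int poly_degree) {
  std::vector<int> v = default_coeff_bits_for(poly_degree);
  return Rcpp::IntegerVector(v.begin(), v.end());
}

// [[Rcpp::export(name = ".bfv_batch_prime")]]
double bfv_batch_prime(int poly_degree, int bits) {
  return (double)find_plain_prime(bits, 2ull * poly_degree);
}

// [[Rcpp::export(name = ".bfv_encrypt")]]
Rcpp::RawVector bfv_encrypt(SEXP xp, Rcpp::NumericVector values) {
  BFVContext* C = get_ctx(xp);
  if ((int)values.size() != C->N)
    Rcpp::stop("expected %d slot values, got %d", C->N, (int)values.size());
  std::vector<u64> slots(C->N);
  for (int i = 0; i < C->N; ++i) {
    double v = values[i];
    if (v < 0 || v != std::floor(v))
      Rcpp::stop("slot values must be non-negative integers");
    if (v >= (double)C->t)
      Rcpp::stop("slot value %.0f exceeds the plaintext modulus %llu", v, (unsigned long long)C->t);
    slots[i] = (u64)v;
  }
  Ct ct = encrypt_internal(*C, slots);
  return ct_serialize(*C, ct);
}

// [[Rcpp::export(name = ".bfv_decrypt")]]
Rcpp::NumericVector bfv_decrypt(SEXP xp, Rcpp::RawVector blob) {
  BFVContext* C = get_ctx(xp);
  if (!C->has_secret) Rcpp::stop("decryption requires the secret key");
  Ct ct = ct_deserialize(*C, blob);
  std::vector<u64> slots = decrypt_internal(*C, ct, nullptr);
  Rcpp::NumericVector out(C->N);
  for (int i = 0; i < C->N; ++i) out[i] = (double)slots[i];
  return out;
}

// [[Rcpp::export(name = ".bfv_decrypt_checked")]]
Rcpp::List bfv_decrypt_checked(SEXP xp, Rcpp::RawVector blob) {
  BFVContext* C = get_ctx(xp);
  if (!C->has_secret) Rcpp::stop("decryption requires the secret key");
  Ct ct = ct_deserialize(*C, blob);
  int budget = 0;
  std::vector<u64> slots = decrypt_internal(*C, ct, &budget);
  Rcpp::NumericVector out(C->N);
  for (int i = 0; i < C->N; ++i) out[i] = (double)slots[i];
  return Rcpp::List::create(Rcpp::Named("values") = out,
                            Rcpp::Named("budget") = budget);
}

// [[Rcpp::export(name = ".bfv_blob_matches")]]
bool bfv_blob_matches(SEXP xp, Rcpp::RawVector blob) {
  BFVContext* C = get_ctx(xp);
  if ((size_t)blob.size() < 16) return false;
  uint32_t hdr[4];
  std::memcpy(hdr, RAW(blob), 16);
  return hdr[0] == CT_MAGIC && hdr[1] == C->fp_hash &&
         hdr[2] == (uint32_t)C->L && hdr[3] == (uint32_t)C->N;
}

// [[Rcpp::export(name = ".bfv_public_clone")]]
SEXP bfv_public_clone(SEXP xp) {
  BFVContext* C = get_ctx(xp);
  BFVContext* D = new BFVContext(*C);
  D->has_secret = false;
  D->s_ternary.clear();
  D->s_ntt.clear();
  D->op_rot = 0; D->op_mask = 0;
  return XPtr<BFVContext>(D, true);
}

// [[Rcpp::export(name = ".bfv_noise_budget")]]
int bfv_noise_budget(SEXP xp, Rcpp::RawVector blob) {
  BFVContext* C = get_ctx(xp);
  if (!C->has_secret) Rcpp::stop("noise budget measurement requires the secret key");
  Ct ct = ct_deserialize(*C, blob);
  return noise_budget_internal(*C, ct);
}

// [[Rcpp::export(name = ".bfv_rotate_rows")]]
Rcpp::RawVector bfv_rotate_rows(SEXP xp, Rcpp::RawVector blob, int steps) {
  BFVContext* C = get_ctx(xp);
  if (steps <= 0 || steps >= C->N / 2) Rcpp::stop("rotation steps out of range [1, N/2)");
  Ct ct = ct_deserialize(*C, blob);
  rotate_rows_by(*C, ct, steps);
  return ct_serialize(*C, ct);
}

// [[Rcpp::export(name = ".bfv_swap_rows")]]
Rcpp::RawVector bfv_swap_rows(SEXP xp, Rcpp::RawVector blob) {
  BFVContext* C = get_ctx(xp);
  Ct ct = ct_deserialize(*C, blob);
  rotate_galois(*C, ct, C->gal_swap);
  return ct_serialize(*C, ct);
}

// [[Rcpp::export(name = ".bfv_bring_to_front")]]
Rcpp::RawVector bfv_bring_to_front(SEXP xp, Rcpp::RawVector blob, int offset) {
  BFVContext* C = get_ctx(xp);
  if (offset < 0 || offset >= C->N) Rcpp::stop("slot offset %d out of range [0, %d)", offset, C->N);
  Ct ct = ct_deserialize(*C, blob);
  int half = C->N / 2;
  if (offset >= half) { rotate_galois(*C, ct, C->gal_swap); offset -= half; }
  rotate_rows_by(*C, ct, offset);
  return ct_serialize(*C, ct);
}

// [[Rcpp::export(name = ".bfv_mask_front")]]
Rcpp::RawVector bfv_mask_front(SEXP xp, Rcpp::RawVector blob) {
  BFVContext* C = get_ctx(xp);
  Ct ct = ct_deserialize(*C, blob);
  mask_front_internal(*C, ct);
  return ct_serialize(*C, ct);
}

// [[Rcpp::export(name = ".bfv_op_counts")]]
Rcpp::IntegerVector bfv_op_counts(SEXP xp) {
  BFVContext* C = get_ctx(xp);
  return Rcpp::IntegerVector::create(
    Rcpp::Named("rotations") = (int)C->op_rot,
    Rcpp::Named("plain_mults") = (int)C->op_mask);
}

// [[Rcpp::export(name = ".bfv_reset_op_counts")]]
void bfv_reset_op_counts(SEXP xp) {
  BFVContext* C = get_ctx(xp);
  C->op_rot = 0; C->op_mask = 0;
}

// ---------------------------------------------------------------- key files

static const uint32_t PK_MAGIC = 0x43425042;   // public bundle
static const uint32_t SK_MAGIC = 0x43425345;   // secret key

template <typename T>
static void wr(std::ofstream& f, const T& v) { f.write((const char*)&v, sizeof(T)); }
template <typename T>
static void rd(std::ifstream& f, T& v) { f.read((char*)&v, sizeof(T)); }

static void write_polyset(std::ofstream& f, const std::vector<std::vector<u64>>& ps) {
  uint32_t n = (uint32_t)ps.size(); wr(f, n);
  for (const auto& p : ps) {
    uint32_t m = (uint32_t)p.size(); wr(f, m);
    f.write((const char*)p.data(), (std::streamsize)p.size() * 8);
  }
}

static void read_polyset(std::ifstream& f, std::vector<std::vector<u64>>& ps) {
  uint32_t n = 0; rd(f, n);
  ps.assign(n, {});
  for (auto& p : ps) {
    uint32_t m = 0; rd(f, m);
    p.resize(m);
    f.read((char*)p.data(), (std::streamsize)m * 8);
  }
}

// [[Rcpp::export(name = ".bfv_save_public")]]
void bfv_save_public(SEXP xp, std::string path) {
  BFVContext* C = get_ctx(xp);
  std::ofstream f(path, std::ios::binary);
  if (!f) Rcpp::stop("cannot write public key bundle to '%s'", path.c_str());
  wr(f, PK_MAGIC);
  uint32_t N = C->N, tb = C->t_bits_req, sec = C->sec_bits, ncb = (uint32_t)C->coeff_bits.size();
  wr(f, N); wr(f, tb); wr(f, sec); wr(f, ncb);
  for (int b : C->coeff_bits) { uint32_t bb = b; wr(f, bb); }
  write_polyset(f, C->pk0);
  write_polyset(f, C->pk1);
  uint32_t ng = (uint32_t)C->gkeys.size(); wr(f, ng);
  for (const auto& kv : C->gkeys) {
    u64 g = kv.first; wr(f, g);
    uint32_t nd = (uint32_t)kv.second.size(); wr(f, nd);
    for (const auto& digit : kv.second) {
      write_polyset(f, digit);
    }
  }
}

// [[Rcpp::export(name = ".bfv_save_secret")]]
void bfv_save_secret(SEXP xp, std::string path) {
  BFVContext* C = get_ctx(xp);
  if (!C->has_secret) Rcpp::stop("context holds no secret key");
  std::ofstream f(path, std::ios::binary);
  if (!f) Rcpp::stop("cannot write secret key to '%s'", path.c_str());
  wr(f, SK_MAGIC);
  uint32_t N = C->N; wr(f, N);
  f.write((const char*)C->s_ternary.data(), C->N);
}

// [[Rcpp::export(name = ".bfv_load")]]
SEXP bfv_load(std::string public_path, std::string secret_path) {
  std::ifstream f(public_path, std::ios::binary);
  if (!f) Rcpp::stop("cannot read public key bundle '%s'", public_path.c_str());
  uint32_t magic = 0; rd(f, magic);
  if (magic != PK_MAGIC) Rcpp::stop("'%s' is not a public key bundle", public_path.c_str());
  uint32_t N, tb, sec, ncb;
  rd(f, N); rd(f, tb); rd(f, sec); rd(f, ncb);
  std::vector<int> cb(ncb);
  for (uint32_t i = 0; i < ncb; ++i) { uint32_t b; rd(f, b); cb[i] = (int)b; }
  BFVContext* C = new BFVContext();
  setup_context(*C, (int)N, (int)tb, (int)sec, cb, 0);
  read_polyset(f, C->pk0);
  read_polyset(f, C->pk1);
  uint32_t ng = 0; rd(f, ng);
  for (uint32_t i = 0; i < ng; ++i) {
    u64 g; rd(f, g);
    uint32_t nd; rd(f, nd);
    auto& key = C->gkeys[g];
    key.resize(nd);
    for (uint32_t d = 0; d < nd; ++d) read_polyset(f, key[d]);
  }
  C->has_secret = false;
  if (!secret_path.empty()) {
    std::ifstream fs(secret_path, std::ios::binary);
    if (!fs) Rcpp::stop("cannot read secret key '%s'", secret_path.c_str());
    uint32_t sm = 0; rd(fs, sm);
    if (sm != SK_MAGIC) Rcpp::stop("'%s' is not a secret key file", secret_path.c_str());
    uint32_t sn = 0; rd(fs, sn);
    if (sn != N) Rcpp::stop("secret key degree mismatch");
    C->s_ternary.resize(N);
    fs.read((char*)C->s_ternary.data(), N);
    int K = (int)C->primes.size();
    C->s_ntt.assign(K, std::vector<u64>(N));
    for (int jp = 0; jp < K; ++jp) {
      u64 p = C->primes[jp];
      for (uint32_t x = 0; x < N; ++x) {
        int8_t v = C->s_ternary[x];
        C->s_ntt[jp][x] = v < 0 ? p - 1 : (u64)v;
      }
      C->tab[jp].fwd(C->s_ntt[jp].data());
    }
    C->has_secret = true;
  }
  build_mask(*C);
  XPtr<BFVContext> xp(C, true);
  return xp;
}
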