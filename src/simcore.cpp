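#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Agent-based core for linked cultural trait transmission.
//
// State layout (shared with R):
//   variants: integer matrix N x h, entries in 1..k (column-major: r + i*N)
//   links:    logical/uint8 array dim c(h, h, N); individual r's adjacency is
//             the contiguous block [r*h*h, (r+1)*h*h), entry (x,y) = x + y*h.
//
// Randomness: every exported entry point seeds one internal xoshiro256++
// generator from R's RNG stream, so set.seed() makes any run bitwise
// reproducible while the hot loops avoid per-draw calls into R. Draw order
// within a timestep is fixed:
//   (1) partners for r = 1..N;
//   (2) per focal r = 1..N: trait choice, then variant-copy draws over package
//       traits in ascending order, then link-acquisition draws over in-package
//       pairs (x < y) in ascending (x, y) order;
//   (3) link formation, individuals then pair index, by geometric skipping;
//   (4) innovation over (individual, trait) cells, by geometric skipping.
// Geometric skipping draws the gap to the next Bernoulli(p) success directly;
// it is exact per-trial and deterministic given the seed.

struct Xoshiro {
  uint64_t s[4];
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // strictly inside (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  void seed_from_R() {
    uint64_t seed = (uint64_t)(unif_rand() * 4294967296.0);
    seed = (seed << 32) ^ (uint64_t)(unif_rand() * 4294967296.0);
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {  // splitmix64 expansion of the seed
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
};

struct ModelPars {
  int N, h, k;
  std::vector<double> s;   // length h
  double a, b, cc, mu, s_kappa;
  bool b_shared;           // breakage also applies to links both hold
  int mode;                // 0 unbiased, 1 payoff, 2 conformist
  int n_fixed;             // -1: link-based packages; >= 0: fixed package size
};

static inline R_xlen_t geom_skip(double p, Xoshiro &rng) {
  // failures before the next success of a Bernoulli(p) trial stream
  return (R_xlen_t) std::floor(std::log(rng.unif()) / std::log1p(-p));
}

// connected component of `trait` (0-based) in one individual's adjacency;
// `queue` is caller-provided scratch of length >= h (avoids per-call
// allocation in the hot loop)
static void build_package_scratch(const uint8_t *adj, int h, int trait,
                                  std::vector<uint8_t> &inpkg, int *queue) {
  std::fill(inpkg.begin(), inpkg.end(), 0);
  int head = 0, tail = 0;
  queue[tail++] = trait;
  inpkg[trait] = 1;
  while (head < tail) {
    int x = queue[head++];
    const uint8_t *col = adj + x;  // column x, stride h
    for (int y = 0; y < h; ++y) {
      if (!inpkg[y] && col[y * h]) {
        inpkg[y] = 1;
        queue[tail++] = y;
      }
    }
  }
}

static void build_package(const uint8_t *adj, int h, int trait,
                          std::vector<uint8_t> &inpkg) {
  std::vector<int> queue(h);
  build_package_scratch(adj, h, trait, inpkg, queue.data());
}

// focal adopts partner's variant at each in-package trait w.p. cc
// (strides allow use on both N x h matrices and plain length-h vectors)
static void copy_variants_core(int *focal, int fstride, const int *partner,
                               int pstride, const std::vector<uint8_t> &inpkg,
                               int h, double cc, Xoshiro &rng) {
  for (int i = 0; i < h; ++i) {
    if (inpkg[i] && rng.unif() < cc) focal[i * fstride] = partner[i * pstride];
  }
}

// link update table: within the package a link shared by both is kept
// (or, under the b_shared sensitivity variant, kept w.p. 1-b), a link only
// the partner has is acquired w.p. 1-b, a link only the focal has is
// broken; links crossing the package boundary are lost; links fully outside
// are untouched.
static void transmit_links_core(uint8_t *fl, const uint8_t *fl_snap,
                                const uint8_t *pl,
                                const std::vector<uint8_t> &inpkg, int h,
                                double b, bool b_shared, Xoshiro &rng) {
  int psize = 0, pt = 0;
  for (int i = 0; i < h; ++i)
    if (inpkg[i]) {
      ++psize;
      pt = i;
    }
  if (psize == 1) {
    // singleton package: no in-package pairs; every link at the chosen
    // trait crosses the boundary and is lost (no draws either way)
    for (int y = 0; y < h; ++y) {
      if (y != pt) fl[pt + y * h] = fl[y + pt * h] = 0;
    }
    return;
  }
  for (int x = 0; x < h - 1; ++x) {
    for (int y = x + 1; y < h; ++y) {
      bool inX = inpkg[x], inY = inpkg[y];
      if (inX && inY) {
        bool pHas = pl[x + y * h] != 0, fHas = fl_snap[x + y * h] != 0;
        uint8_t val;
        if (pHas && fHas) {
          val = (!b_shared || rng.unif() < 1.0 - b) ? 1 : 0;
        } else if (pHas && !fHas) {
          val = (rng.unif() < 1.0 - b) ? 1 : 0;
        } else {
          val = 0;  // focal-only link broken; neither -> none
        }
        fl[x + y * h] = fl[y + x * h] = val;
      } else if (inX != inY) {
        fl[x + y * h] = fl[y + x * h] = 0;  // boundary-crossing link lost
      }
      // both endpoints outside: unchanged
    }
  }
}

static void compute_weights(const std::vector<int> &V, const ModelPars &P,
                            std::vector<double> &w) {
  if (P.mode == 1) {  // pay-off: f_r = prod_i (1 - (j-1)/(k-1) * s_i)
    for (int r = 0; r < P.N; ++r) {
      double f = 1.0;
      for (int i = 0; i < P.h; ++i) {
        if (P.s[i] != 0.0) {
          int j = V[r + i * P.N];
          f *= 1.0 - ((double)(j - 1) / (double)(P.k - 1)) * P.s[i];
        }
      }
      w[r] = f;
    }
  } else {  // conformist (h == 1): w_r = 1 - s_kappa * (1 - q_r)
    std::vector<double> cnt(P.k, 0.0), wv(P.k);
    for (int r = 0; r < P.N; ++r) cnt[V[r] - 1] += 1.0;
    for (int j = 0; j < P.k; ++j) {
      wv[j] = 1.0 - P.s_kappa * (1.0 - cnt[j] / (double)P.N);
    }
    for (int r = 0; r < P.N; ++r) w[r] = wv[V[r] - 1];
  }
}

static inline void sample_partners_unbiased(int N, std::vector<int> &partner,
                                            Xoshiro &rng) {
  for (int r = 0; r < N; ++r) {
    int idx = (int)(rng.unif() * (N - 1));
    if (idx >= N - 1) idx = N - 2;
    if (idx >= r) ++idx;
    partner[r] = idx;
  }
}

// partner for each focal, proportional to w over non-self candidates
// (rejection sampling from the full distribution is exactly the
// self-excluded renormalized distribution). Degenerate all-zero weights fall
// back to unbiased choice. Weights are constant within classes of identical
// variant profiles, so candidates are drawn class-first (class probability
// proportional to class weight times class size, member uniform within the
// class), which is exactly proportional to the per-individual weights.
static bool sample_partners(const std::vector<int> &V, const ModelPars &P,
                            std::vector<int> &partner, Xoshiro &rng) {
  const int N = P.N;
  if (P.mode == 0) {
    sample_partners_unbiased(N, partner, rng);
    return false;
  }
  // functional traits define the weight classes
  std::vector<int> func;
  if (P.mode == 1) {
    for (int i = 0; i < P.h; ++i)
      if (P.s[i] != 0.0) func.push_back(i);
  } else {
    func.push_back(0);  // conformist: h == 1, class = variant
  }
  long ncl_l = 1;
  for (size_t i = 0; i < func.size(); ++i) ncl_l *= P.k;
  if (ncl_l > 4096) {  // very many classes: direct per-individual sampling
    std::vector<double> w(N);
    compute_weights(V, P, w);
    std::vector<double> cum(N);
    double tot = 0.0;
    for (int r = 0; r < N; ++r) {
      tot += w[r];
      cum[r] = tot;
    }
    if (!(tot > 0.0) || !std::isfinite(tot)) {
      sample_partners_unbiased(N, partner, rng);
      return true;
    }
    for (int r = 0; r < N; ++r) {
      int idx;
      do {
        double u = rng.unif() * tot;
        idx = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
        if (idx >= N) idx = N - 1;
      } while (idx == r);
      partner[r] = idx;
    }
    return false;
  }
  const int ncl = (int)ncl_l;
  std::vector<int> cls(N, 0);
  for (size_t d = 0; d < func.size(); ++d) {
    int i = func[d];
    for (int r = 0; r < N; ++r) cls[r] = cls[r] * P.k + (V[r + i * N] - 1);
  }
  std::vector<int> cnt(ncl, 0);
  for (int r = 0; r < N; ++r) ++cnt[cls[r]];
  std::vector<double> wc(ncl, 1.0);
  if (P.mode == 1) {
    for (int c = 0; c < ncl; ++c) {
      int code = c;
      double f = 1.0;
      for (int d = (int)func.size() - 1; d >= 0; --d) {
        int j = code % P.k;
        code /= P.k;
        f *= 1.0 - ((double)j / (double)(P.k - 1)) * P.s[func[d]];
      }
      wc[c] = f;
    }
  } else {
    for (int c = 0; c < ncl; ++c) {
      wc[c] = 1.0 - P.s_kappa * (1.0 - (double)cnt[c] / (double)N);
    }
  }
  std::vector<double> cumc(ncl);
  double tot = 0.0;
  for (int c = 0; c < ncl; ++c) {
    tot += wc[c] * cnt[c];
    cumc[c] = tot;
  }
  if (!(tot > 0.0) || !std::isfinite(tot)) {
    sample_partners_unbiased(N, partner, rng);
    return true;
  }
  // member lists per class
  std::vector<int> offset(ncl + 1, 0);
  for (int c = 0; c < ncl; ++c) offset[c + 1] = offset[c] + cnt[c];
  std::vector<int> members(N), fill(offset.begin(), offset.end() - 1);
  for (int r = 0; r < N; ++r) members[fill[cls[r]]++] = r;
  for (int r = 0; r < N; ++r) {
    int idx;
    do {
      double u = rng.unif() * tot;
      int c = (int)(std::upper_bound(cumc.begin(), cumc.end(), u) -
                    cumc.begin());
      if (c >= ncl) c = ncl - 1;
      int m = (int)(rng.unif() * cnt[c]);
      if (m >= cnt[c]) m = cnt[c] - 1;
      idx = members[offset[c] + m];
    } while (idx == r);
    partner[r] = idx;
  }
  return false;
}

// each currently unlinked pair gains a link w.p. a (a Bernoulli(a) stream
// over all pairs with no-op hits on linked pairs gives unlinked pairs exactly
// probability a)
static void form_links_core(std::vector<uint8_t> &L, int N, int h, double a,
                            Xoshiro &rng) {
  const R_xlen_t Pn = (R_xlen_t)h * (h - 1) / 2;
  const R_xlen_t total = (R_xlen_t)N * Pn;
  if (a <= 0.0 || Pn == 0) return;
  std::vector<int> px(Pn), py(Pn);
  {
    R_xlen_t q = 0;
    for (int x = 0; x < h - 1; ++x)
      for (int y = x + 1; y < h; ++y) {
        px[q] = x;
        py[q] = y;
        ++q;
      }
  }
  if (a >= 1.0) {
    for (R_xlen_t idx = 0; idx < total; ++idx) {
      R_xlen_t r = idx / Pn, q = idx % Pn;
      uint8_t *fl = &L[(size_t)r * h * h];
      fl[px[q] + py[q] * h] = fl[py[q] + px[q] * h] = 1;
    }
  } else {
    R_xlen_t idx = geom_skip(a, rng);
    while (idx < total) {
      R_xlen_t r = idx / Pn, q = idx % Pn;
      uint8_t *fl = &L[(size_t)r * h * h];
      if (!fl[px[q] + py[q] * h])
        fl[px[q] + py[q] * h] = fl[py[q] + px[q] * h] = 1;
      idx += 1 + geom_skip(a, rng);
    }
  }
}

// w.p. mu a trait switches to one of the other k-1 variants, uniformly
static void innovate_core(std::vector<int> &V, int N, int h, int k, double mu,
                          Xoshiro &rng) {
  if (mu <= 0.0) return;
  const R_xlen_t total = (R_xlen_t)N * h;
  R_xlen_t idx = (mu >= 1.0) ? 0 : geom_skip(mu, rng);
  while (idx < total) {
    int r = (int)(idx / h), i = (int)(idx % h);
    int cur = V[r + i * N];
    int m = (int)(rng.unif() * (k - 1));
    if (m >= k - 1) m = k - 2;
    V[r + i * N] = (m + 1 < cur) ? m + 1 : m + 2;
    idx += (mu >= 1.0) ? 1 : 1 + geom_skip(mu, rng);
  }
}

// one synchronous timestep; V and L are updated in place (all reads from
// start-of-step snapshots)
static bool do_step(std::vector<int> &V, std::vector<uint8_t> &L,
                    const ModelPars &P, Xoshiro &rng) {
  const int N = P.N, h = P.h;
  std::vector<int> snapV(V);
  std::vector<uint8_t> snapL(L);
  std::vector<int> partner(N);
  bool degenerate = sample_partners(snapV, P, partner, rng);

  std::vector<uint8_t> inpkg(h);
  if (P.n_fixed >= 0) {
    // fixed-package control: copy n_fixed random distinct traits, no links
    std::vector<int> pool(h);
    for (int r = 0; r < N; ++r) {
      int p = partner[r];
      for (int i = 0; i < h; ++i) pool[i] = i;
      std::fill(inpkg.begin(), inpkg.end(), 0);
      for (int d = 0; d < P.n_fixed; ++d) {
        int j = d + (int)(rng.unif() * (h - d));
        if (j >= h) j = h - 1;
        std::swap(pool[d], pool[j]);
        inpkg[pool[d]] = 1;
      }
      copy_variants_core(&V[r], N, &snapV[p], N, inpkg, h, P.cc, rng);
    }
  } else {
    std::vector<int> queue(h);
    for (int r = 0; r < N; ++r) {
      int p = partner[r];
      int t = (int)(rng.unif() * h);
      if (t >= h) t = h - 1;
      build_package_scratch(&snapL[(size_t)p * h * h], h, t, inpkg,
                            queue.data());
      copy_variants_core(&V[r], N, &snapV[p], N, inpkg, h, P.cc, rng);
      transmit_links_core(&L[(size_t)r * h * h], &snapL[(size_t)r * h * h],
                          &snapL[(size_t)p * h * h], inpkg, h, P.b, P.b_shared, rng);
    }
    form_links_core(L, N, h, P.a, rng);
  }
  innovate_core(V, P.N, P.h, P.k, P.mu, rng);
  return degenerate;
}

static ModelPars make_pars(int N, int h, int k, NumericVector s, double a,
                           double b, double cc, double mu, double s_kappa,
                           int mode, int n_fixed, bool b_shared = false) {
  ModelPars P;
  P.N = N;
  P.h = h;
  P.k = k;
  P.s = as<std::vector<double>>(s);
  P.a = a;
  P.b = b;
  P.cc = cc;
  P.mu = mu;
  P.s_kappa = s_kappa;
  P.b_shared = b_shared;
  P.mode = mode;
  P.n_fixed = n_fixed;
  return P;
}

// [[Rcpp::export]]
IntegerVector cpp_package_of(int trait, LogicalMatrix links) {
  int h = links.nrow();
  std::vector<uint8_t> adj((size_t)h * h);
  for (int i = 0; i < h * h; ++i) adj[i] = links[i] ? 1 : 0;
  std::vector<uint8_t> inpkg(h);
  build_package(adj.data(), h, trait - 1, inpkg);
  std::vector<int> out;
  for (int i = 0; i < h; ++i)
    if (inpkg[i]) out.push_back(i + 1);
  return wrap(out);
}

// [[Rcpp::export]]
IntegerVector cpp_transmit_variants(IntegerVector focal, IntegerVector partner,
                                    IntegerVector package, double cc) {
  Xoshiro rng;
  rng.seed_from_R();
  int h = focal.size();
  std::vector<uint8_t> inpkg(h, 0);
  for (int i = 0; i < package.size(); ++i) inpkg[package[i] - 1] = 1;
  IntegerVector out = clone(focal);
  std::vector<int> f = as<std::vector<int>>(out);
  std::vector<int> p = as<std::vector<int>>(partner);
  copy_variants_core(f.data(), 1, p.data(), 1, inpkg, h, cc, rng);
  for (int i = 0; i < h; ++i) out[i] = f[i];
  return out;
}

// [[Rcpp::export]]
LogicalMatrix cpp_transmit_links(LogicalMatrix focal_links,
                                 LogicalMatrix partner_links,
                                 IntegerVector package, double b,
                                 bool b_shared = false) {
  Xoshiro rng;
  rng.seed_from_R();
  int h = focal_links.nrow();
  std::vector<uint8_t> inpkg(h, 0);
  for (int i = 0; i < package.size(); ++i) inpkg[package[i] - 1] = 1;
  std::vector<uint8_t> fl((size_t)h * h), pl((size_t)h * h);
  for (int i = 0; i < h * h; ++i) {
    fl[i] = focal_links[i] ? 1 : 0;
    pl[i] = partner_links[i] ? 1 : 0;
  }
  std::vector<uint8_t> snap(fl);
  transmit_links_core(fl.data(), snap.data(), pl.data(), inpkg, h, b,
                      b_shared, rng);
  LogicalMatrix out(h, h);
  for (int i = 0; i < h * h; ++i) out[i] = fl[i] != 0;
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_form_links(LogicalVector links, int N, int h, double a) {
  Xoshiro rng;
  rng.seed_from_R();
  std::vector<uint8_t> L((size_t)N * h * h);
  for (R_xlen_t i = 0; i < links.size(); ++i) L[i] = links[i] ? 1 : 0;
  form_links_core(L, N, h, a, rng);
  LogicalVector out(links.size());
  for (R_xlen_t i = 0; i < links.size(); ++i) out[i] = L[i] != 0;
  out.attr("dim") = IntegerVector::create(h, h, N);
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_innovate(IntegerMatrix variants, int k, double mu) {
  Xoshiro rng;
  rng.seed_from_R();
  int N = variants.nrow(), h = variants.ncol();
  std::vector<int> V = as<std::vector<int>>(IntegerVector(variants));
  innovate_core(V, N, h, k, mu, rng);
  IntegerMatrix out(N, h);
  for (R_xlen_t i = 0; i < (R_xlen_t)N * h; ++i) out[i] = V[i];
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_choose_partners(IntegerMatrix variants, int k,
                                  NumericVector s, double s_kappa, int mode) {
  Xoshiro rng;
  rng.seed_from_R();
  int N = variants.nrow(), h = variants.ncol();
  ModelPars P = make_pars(N, h, k, s, 0, 0, 0, 0, s_kappa, mode, -1);
  std::vector<int> V = as<std::vector<int>>(IntegerVector(variants));
  std::vector<int> partner(N);
  bool degenerate = sample_partners(V, P, partner, rng);
  IntegerVector out(N);
  for (int r = 0; r < N; ++r) out[r] = partner[r] + 1;
  if (degenerate) out.attr("degenerate") = true;
  return out;
}

// [[Rcpp::export]]
List cpp_step(IntegerMatrix variants, LogicalVector links, int k,
              NumericVector s, double a, double b, double cc, double mu,
              double s_kappa, int mode, int n_fixed,
              bool b_shared = false) {
  Xoshiro rng;
  rng.seed_from_R();
  int N = variants.nrow(), h = variants.ncol();
  ModelPars P = make_pars(N, h, k, s, a, b, cc, mu, s_kappa, mode, n_fixed,
                          b_shared);
  std::vector<int> V = as<std::vector<int>>(IntegerVector(variants));
  std::vector<uint8_t> L((size_t)N * h * h);
  for (R_xlen_t i = 0; i < links.size(); ++i) L[i] = links[i] ? 1 : 0;
  bool degenerate = do_step(V, L, P, rng);
  IntegerMatrix Vout(N, h);
  for (R_xlen_t i = 0; i < (R_xlen_t)N * h; ++i) Vout[i] = V[i];
  LogicalVector Lout(links.size());
  for (R_xlen_t i = 0; i < links.size(); ++i) Lout[i] = L[i] != 0;
  Lout.attr("dim") = IntegerVector::create(h, h, N);
  return List::create(_["variants"] = Vout, _["links"] = Lout,
                      _["degenerate"] = degenerate);
}

// [[Rcpp::export]]
List cpp_run(IntegerMatrix variants, LogicalVector links, int steps, int k,
             NumericVector s, double a, double b, double cc, double mu,
             double s_kappa, int mode, int n_fixed, bool record_links,
             bool record_pkg_var, bool b_shared = false) {
  Xoshiro rng;
  rng.seed_from_R();
  int N = variants.nrow(), h = variants.ncol();
  ModelPars P = make_pars(N, h, k, s, a, b, cc, mu, s_kappa, mode, n_fixed,
                          b_shared);
  std::vector<int> V = as<std::vector<int>>(IntegerVector(variants));
  std::vector<uint8_t> L((size_t)N * h * h);
  for (R_xlen_t i = 0; i < links.size(); ++i) L[i] = links[i] ? 1 : 0;

  IntegerVector counts((R_xlen_t)steps * h * k);
  NumericVector linkfreq(record_links ? steps : 0);
  NumericVector pkgvar(record_pkg_var ? steps : 0);
  const double npairs = (double)h * (h - 1) / 2.0;
  std::vector<uint8_t> inpkg(h);
  std::vector<int> sizes;
  if (record_pkg_var) sizes.resize((size_t)N * h);
  bool any_degen = false;

  for (int t = 0; t < steps; ++t) {
    any_degen = do_step(V, L, P, rng) || any_degen;
    int *ct = &counts[(R_xlen_t)t * h * k];
    for (int i = 0; i < h; ++i)
      for (int r = 0; r < N; ++r) ++ct[i + (V[r + i * N] - 1) * h];
    if (record_links) {
      long tot = 0;
      for (R_xlen_t i = 0; i < (R_xlen_t)N * h * h; ++i) tot += L[i];
      linkfreq[t] = (npairs > 0) ? (double)tot / 2.0 / (npairs * N) : 0.0;
    }
    if (record_pkg_var) {
      for (int r = 0; r < N; ++r) {
        const uint8_t *adj = &L[(size_t)r * h * h];
        std::vector<int> comp(h, -1);
        int nc = 0;
        for (int i = 0; i < h; ++i) {
          if (comp[i] < 0) {
            build_package(adj, h, i, inpkg);
            int sz = 0;
            for (int x = 0; x < h; ++x) sz += inpkg[x];
            for (int x = 0; x < h; ++x)
              if (inpkg[x]) comp[x] = nc;
            for (int x = 0; x < h; ++x)
              if (comp[x] == nc) sizes[(size_t)r * h + x] = sz;
            ++nc;
          }
        }
      }
      double m = 0.0;
      for (size_t i = 0; i < sizes.size(); ++i) m += sizes[i];
      m /= (double)sizes.size();
      double ss = 0.0;
      for (size_t i = 0; i < sizes.size(); ++i) {
        double d = sizes[i] - m;
        ss += d * d;
      }
      pkgvar[t] = ((R_xlen_t)N * h > 1) ? ss / ((double)N * h - 1.0) : 0.0;
    }
    if ((t & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  counts.attr("dim") = IntegerVector::create(h, k, steps);
  IntegerMatrix Vout(N, h);
  for (R_xlen_t i = 0; i < (R_xlen_t)N * h; ++i) Vout[i] = V[i];
  LogicalVector Lout(links.size());
  for (R_xlen_t i = 0; i < links.size(); ++i) Lout[i] = L[i] != 0;
  Lout.attr("dim") = IntegerVector::create(h, h, N);
  return List::create(_["counts"] = counts, _["link_freq"] = linkfreq,
                      _["pkg_var"] = pkgvar, _["variants"] = Vout,
                      _["links"] = Lout, _["degenerate"] = any_degen);
}

// per-individual, per-trait connected-component (package) sizes
// [[Rcpp::export]]
IntegerMatrix cpp_component_sizes(LogicalVector links, int N, int h) {
  std::vector<uint8_t> L((size_t)N * h * h);
  for (R_xlen_t i = 0; i < links.size(); ++i) L[i] = links[i] ? 1 : 0;
  IntegerMatrix out(N, h);
  std::vector<uint8_t> inpkg(h);
  for (int r = 0; r < N; ++r) {
    const uint8_t *adj = &L[(size_t)r * h * h];
    std::vector<int> comp(h, -1);
    for (int i = 0; i < h; ++i) {
      if (comp[i] < 0) {
        build_package(adj, h, i, inpkg);
        int sz = 0;
        for (int x = 0; x < h; ++x) sz += inpkg[x];
        for (int x = 0; x < h; ++x)
          if (inpkg[x]) {
            comp[x] = i;
            out(r, x) = sz;
          }
      }
    }
  }
  return out;
}
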