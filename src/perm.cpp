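#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// Null distribution of the Pearson correlation of two independently
// permuted count rows, sampled without materialising permutations of the
// full bin axis. A random bijection between bins contributes to the dot
// product only where both values are nonzero, so per replicate:
//   (a) the number H of y-nonzeros landing on x-nonzero slots is
//       hypergeometric;
//   (b) the H matched (x, y) value pairs are a uniform without-replacement
//       sample of the two nonzero multisets, paired at random.
// When the rows take few distinct values (binned spike counts at fast
// timescales are nearly binary) step (b) collapses to a small random
// contingency table drawn by sequential hypergeometric sampling; otherwise
// the value arrays are partially shuffled with a fast internal generator
// seeded from R's RNG. Both routes are exact in distribution.

// ---- xoshiro256++, seeded from the R RNG so results follow set.seed ----
struct FastRng {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9e3779b97f4a7c15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit FastRng(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix(seed);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  // uniform integer in [0, n)
  uint32_t below(uint32_t n) { return (uint32_t)((next() >> 11) % n); }
};

static FastRng rng_from_R() {
  uint64_t a = (uint64_t)(unif_rand() * 4294967296.0);
  uint64_t b = (uint64_t)(unif_rand() * 4294967296.0);
  return FastRng((a << 32) ^ b ^ 0x5bd1e995u);
}

static const int MAX_CATS = 12;

struct RowInfo {
  std::vector<double> nz;       // nonzero values
  std::vector<double> vals;     // distinct nonzero values (category path)
  std::vector<int> cnt;         // their multiplicities
  bool categorical = false;
  double sum = 0.0, ss = 0.0;
  bool valid = false;
};

static RowInfo row_info(const double *x, int B, int stride) {
  RowInfo r;
  r.nz.reserve(64);
  for (int b = 0; b < B; ++b) {
    double v = x[(size_t)b * stride];
    r.sum += v;
    r.ss += v * v;
    if (v != 0.0) r.nz.push_back(v);
  }
  double var = r.ss - r.sum * r.sum / B;
  r.valid = var > 1e-12 * std::max(1.0, r.ss);
  // distinct-value histogram, abandoned beyond MAX_CATS categories
  std::vector<double> sorted = r.nz;
  std::sort(sorted.begin(), sorted.end());
  for (size_t i = 0; i < sorted.size();) {
    size_t j = i;
    while (j < sorted.size() && sorted[j] == sorted[i]) ++j;
    if ((int)r.vals.size() == MAX_CATS) { r.vals.clear(); r.cnt.clear(); break; }
    r.vals.push_back(sorted[i]);
    r.cnt.push_back((int)(j - i));
    i = j;
  }
  r.categorical = !r.vals.empty();
  return r;
}

static inline void partial_shuffle(std::vector<double> &v, int H, FastRng &g) {
  int n = (int)v.size();
  for (int t = 0; t < H; ++t) {
    int a = t + (int)g.below((uint32_t)(n - t));
    std::swap(v[t], v[a]);
  }
}

// one null dot product of H matched nonzero pairs
static double null_dot(const RowInfo &xi, const RowInfo &yj, int H,
                       std::vector<double> &vx, std::vector<double> &vy,
                       std::vector<int> &cx, std::vector<int> &cy,
                       FastRng &g) {
  if (H == 0) return 0.0;
  if (xi.categorical && yj.categorical) {
    int Kx = (int)xi.vals.size(), Ky = (int)yj.vals.size();
    // composition of the H matched x-values
    int rem = (int)xi.nz.size(), remH = H;
    for (int k = 0; k < Kx; ++k) {
      int m;
      if (k == Kx - 1) m = remH;
      else m = (int)::Rf_rhyper((double)xi.cnt[k], (double)(rem - xi.cnt[k]),
                                (double)remH);
      cx[k] = m;
      rem -= xi.cnt[k];
      remH -= m;
    }
    // deplete y's histogram category-by-category of x
    for (int k = 0; k < Ky; ++k) cy[k] = yj.cnt[k];
    int remY = (int)yj.nz.size();
    double dot = 0.0;
    for (int a = 0; a < Kx; ++a) {
      int need = cx[a];
      if (need == 0) continue;
      int left = remY;
      for (int b = 0; b < Ky; ++b) {
        int m;
        if (b == Ky - 1) m = need;
        else m = (int)::Rf_rhyper((double)cy[b], (double)(left - cy[b]),
                                  (double)need);
        dot += (double)m * xi.vals[a] * yj.vals[b];
        cy[b] -= m;
        left -= cy[b] + m;   // left tracks remaining candidates past b
        need -= m;
        if (need == 0) { remY -= cx[a]; break; }
      }
    }
    return dot;
  }
  partial_shuffle(vx, H, g);
  partial_shuffle(vy, H, g);
  double dot = 0.0;
  for (int t = 0; t < H; ++t) dot += vx[t] * vy[t];
  return dot;
}

static double pair_pvalue(const RowInfo &xi, const RowInfo &yj,
                          double dot_emp, int B, int n_perm, FastRng &g) {
  double cx_ = xi.ss - xi.sum * xi.sum / B;
  double cy_ = yj.ss - yj.sum * yj.sum / B;
  double denom = std::sqrt(cx_ * cy_);
  double cross = xi.sum * yj.sum / B;
  double demp = dot_emp - cross;          // compare on the dot scale
  int nx = (int)xi.nz.size(), ny = (int)yj.nz.size();
  std::vector<double> vx, vy;
  if (!(xi.categorical && yj.categorical)) { vx = xi.nz; vy = yj.nz; }
  std::vector<int> cxv(MAX_CATS), cyv(MAX_CATS);
  int cnt = 0;
  double eps = 1e-9 * denom + 1e-300;
  for (int rep = 0; rep < n_perm; ++rep) {
    int H = (int)::Rf_rhyper((double)ny, (double)(B - ny), (double)nx);
    double d = null_dot(xi, yj, H, vx, vy, cxv, cyv, g);
    if (d - cross <= demp + eps) ++cnt;
  }
  return (double)cnt / n_perm;
}

// [[Rcpp::export]]
NumericMatrix cpp_perm_pvalues(NumericMatrix counts, int n_perm) {
  int n = counts.nrow(), B = counts.ncol();
  NumericMatrix P(n, n);
  std::fill(P.begin(), P.end(), NA_REAL);
  std::vector<RowInfo> info(n);
  for (int i = 0; i < n; ++i) info[i] = row_info(&counts(i, 0), B, n);
  // all pairwise empirical dot products, accumulated sparsely per bin
  std::vector<double> dots((size_t)n * n, 0.0);
  {
    std::vector<int> act(n);
    std::vector<double> val(n);
    for (int b = 0; b < B; ++b) {
      int k = 0;
      for (int i = 0; i < n; ++i) {
        double v = counts(i, b);
        if (v != 0.0) { act[k] = i; val[k] = v; ++k; }
      }
      for (int a = 0; a < k; ++a)
        for (int c = a + 1; c < k; ++c)
          dots[(size_t)act[a] * n + act[c]] += val[a] * val[c];
    }
  }
  FastRng g = rng_from_R();
  for (int i = 0; i < n - 1; ++i) {
    Rcpp::checkUserInterrupt();
    for (int j = i + 1; j < n; ++j) {
      if (!info[i].valid || !info[j].valid) continue;
      double p = pair_pvalue(info[i], info[j], dots[(size_t)i * n + j],
                             B, n_perm, g);
      P(i, j) = p;
      P(j, i) = p;
    }
  }
  return P;
}

// Null correlation sample for a single pair (testing hook: lets the R
// suite compare this sampler against brute-force permutation of full
// vectors).
// [[Rcpp::export]]
NumericVector cpp_perm_null_sample(NumericVector x, NumericVector y,
                                   int n_perm) {
  int B = x.size();
  if (y.size() != B) stop("length mismatch");
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  RowInfo xi = row_info(xv.data(), B, 1), yj = row_info(yv.data(), B, 1);
  if (!xi.valid || !yj.valid) stop("zero-variance input");
  double cx_ = xi.ss - xi.sum * xi.sum / B;
  double cy_ = yj.ss - yj.sum * yj.sum / B;
  double denom = std::sqrt(cx_ * cy_);
  double cross = xi.sum * yj.sum / B;
  int nx = (int)xi.nz.size(), ny = (int)yj.nz.size();
  std::vector<double> vx, vy;
  if (!(xi.categorical && yj.categorical)) { vx = xi.nz; vy = yj.nz; }
  std::vector<int> cxv(MAX_CATS), cyv(MAX_CATS);
  FastRng g = rng_from_R();
  NumericVector out(n_perm);
  for (int rep = 0; rep < n_perm; ++rep) {
    int H = (int)::Rf_rhyper((double)ny, (double)(B - ny), (double)nx);
    double d = null_dot(xi, yj, H, vx, vy, cxv, cyv, g);
    out[rep] = (d - cross) / denom;
  }
  return out;
}
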