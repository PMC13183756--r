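#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "dpo.h"

using namespace Rcpp;

// Efron's double-Poisson density term (unnormalized), with 0^0 := 1 at y = 0.
// f(y) = tau^(1/2) exp(-tau m) (exp(-y) y^y / y!) (e m / y)^(tau y)
static inline double lgamma1p_int(int y) {
  // lgamma(y + 1) with a lookup table for the small counts that dominate
  static std::vector<double> tab;
  if (tab.empty()) {
    tab.resize(4097);
    for (int i = 0; i <= 4096; i++) tab[i] = R::lgammafn(i + 1.0);
  }
  return (y <= 4096) ? tab[y] : R::lgammafn(y + 1.0);
}

double dpo_logterm(int y, double m, double tau) {
  if (m <= 0.0) return (y == 0) ? 0.5 * std::log(tau) : R_NegInf;
  if (y == 0) return 0.5 * std::log(tau) - tau * m;
  double ly = std::log((double) y);
  return 0.5 * std::log(tau) - tau * m
    - y + y * ly - lgamma1p_int(y)
    + tau * y * (1.0 + std::log(m) - ly);
}

// Truncated-summation normalizer.  The tail decays faster than geometrically
// once y is well past the mean, so we sum until terms are negligible.  The
// summation is anchored at the mode (y near m) so that plain exponentials
// stay in range without a log-sum-exp pass.
static double dpo_logz_exact(double m, double tau) {
  if (m <= 0.0) return 0.5 * std::log(tau);
  double lmode = dpo_logterm((int) (m + 0.5), m, tau);
  double sd = std::sqrt(m / tau);
  int L = (int) std::ceil(m + 15.0 * sd) + 30;
  double s = 0.0, last = 0.0;
  int y = 0;
  for (; y <= L; y++) {
    last = std::exp(dpo_logterm(y, m, tau) - lmode);
    s += last;
    if (y > m && last < 1e-20 * s) break;     // tail no longer contributes
  }
  // extend while the last term still carries mass
  while (last > 1e-20 * s && y < 1000000) {
    y++;
    last = std::exp(dpo_logterm(y, m, tau) - lmode);
    s += last;
  }
  return lmode + std::log(s);
}

// Efron's analytic approximation to the normalizer, accurate for large m*tau;
// used only where the exact sum would be long (large means).
static double dpo_logz_approx(double m, double tau) {
  double mt = m * tau;
  double c = (1.0 - tau) / (12.0 * mt) * (1.0 + 1.0 / mt);
  return std::log1p(c);
}

// Direct-mapped memo for the exact normalizer: the samplers evaluate the
// same (mean, tau) pairs many times within a sweep (small integer true
// counts times a fixed rate).
struct LogzCache {
  static const int N = 4096;
  double key_m[N], key_t[N], val[N];
  LogzCache() { for (int i = 0; i < N; i++) { key_m[i] = -1.0; key_t[i] = -1.0; } }
};
static LogzCache zcache;

double dpo_logz(double m, double tau) {
  if (m > 40.0 && m * tau > 15.0) return dpo_logz_approx(m, tau);
  union { double d; unsigned long long u; } a, b;
  a.d = m; b.d = tau;
  unsigned long long h = a.u * 2654435761ULL ^ (b.u * 40503ULL);
  int slot = (int) (h % LogzCache::N);
  if (zcache.key_m[slot] == m && zcache.key_t[slot] == tau) return zcache.val[slot];
  double z = dpo_logz_exact(m, tau);
  zcache.key_m[slot] = m;
  zcache.key_t[slot] = tau;
  zcache.val[slot] = z;
  return z;
}

double dpo_logpmf(int y, double m, double tau) {
  if (y < 0) return R_NegInf;
  return dpo_logterm(y, m, tau) - dpo_logz(m, tau);
}

std::vector<double> dpo_pmf_vec(int ymax, double m, double tau) {
  std::vector<double> out(ymax + 1);
  double lz = dpo_logz(m, tau);
  for (int y = 0; y <= ymax; y++) out[y] = std::exp(dpo_logterm(y, m, tau) - lz);
  return out;
}

// Per-window counts are capped (<= 64 here, 40 at the user level), so the
// convolution runs on stack buffers.
#define VOCALIB_NMAX 64

// Direct-mapped cache of normalized pmf prefixes: the samplers revisit the
// same (mean, tau) pairs constantly (integer true counts times a shared
// rate), so the leading pmf values are stored once per pair.
struct PmfCache {
  static const int N = 2048;
  static const int LEN = 25;
  std::vector<double> key_m, key_t, val;
  PmfCache() : key_m(N, -1.0), key_t(N, -1.0), val((size_t) N * LEN) {}
};
static PmfCache pcache;

static void dpo_pmf_into(double *p, int nj, double m, double tau) {
  if (nj + 1 > PmfCache::LEN) {            // rare long windows: no caching
    double lz = dpo_logz(m, tau);
    for (int y = 0; y <= nj; y++) p[y] = std::exp(dpo_logterm(y, m, tau) - lz);
    return;
  }
  union { double d; unsigned long long u; } a, b;
  a.d = m; b.d = tau;
  unsigned long long h = a.u * 2654435761ULL ^ (b.u * 40503ULL);
  int slot = (int) (h % PmfCache::N);
  double *cached = &pcache.val[(size_t) slot * PmfCache::LEN];
  if (pcache.key_m[slot] == m && pcache.key_t[slot] == tau) {
    std::copy(cached, cached + nj + 1, p);
    return;
  }
  double lz = dpo_logz(m, tau);
  for (int y = 0; y < PmfCache::LEN; y++) cached[y] = std::exp(dpo_logterm(y, m, tau) - lz);
  pcache.key_m[slot] = m;
  pcache.key_t[slot] = tau;
  std::copy(cached, cached + nj + 1, p);
}

// safe path: rescales between convolutions so extreme tails cannot
// underflow to an exact zero
static double clip_class_loglik_safe(int nj, const int *v, const double *lambda,
                                     int j, double tau) {
  double acc[VOCALIB_NMAX + 1], nxt[VOCALIB_NMAX + 1], p[VOCALIB_NMAX + 1];
  for (int t = 0; t <= nj; t++) acc[t] = 0.0;
  acc[0] = 1.0;
  double logscale = 0.0;
  for (int i = 0; i < 4; i++) {
    double mij = lambda[i * 4 + j] * v[i];
    if (mij <= 0.0) continue;
    dpo_pmf_into(p, nj, mij, tau);
    double mx = 0.0;
    for (int t = 0; t <= nj; t++) {
      double s = 0.0;
      for (int u = 0; u <= t; u++) s += acc[u] * p[t - u];
      nxt[t] = s;
      if (s > mx) mx = s;
    }
    for (int t = 0; t <= nj; t++) acc[t] = nxt[t];
    if (mx > 0.0 && mx < 1e-200) {
      for (int t = 0; t <= nj; t++) acc[t] /= mx;
      logscale += std::log(mx);
    }
  }
  double pj = acc[nj];
  if (pj <= 0.0) return R_NegInf;
  return std::log(pj) + logscale;
}

double clip_class_loglik(int nj, const int *v, const double *lambda, int j, double tau) {
  if (nj > VOCALIB_NMAX) return R_NegInf;
  // fast path: in-place convolution of the four source pmfs at nj
  double acc[VOCALIB_NMAX + 1], p[VOCALIB_NMAX + 1];
  for (int t = 1; t <= nj; t++) acc[t] = 0.0;
  acc[0] = 1.0;
  for (int i = 0; i < 4; i++) {
    double mij = lambda[i * 4 + j] * v[i];
    if (mij <= 0.0) continue;                 // point mass at 0: identity
    dpo_pmf_into(p, nj, mij, tau);
    for (int t = nj; t >= 0; t--) {           // descending: in place
      double s = 0.0;
      for (int u = 0; u <= t; u++) s += acc[u] * p[t - u];
      acc[t] = s;
    }
  }
  double pj = acc[nj];
  if (pj > 0.0 && R_FINITE(pj)) return std::log(pj);
  return clip_class_loglik_safe(nj, v, lambda, j, tau);
}

double clip_loglik(const int *n, const int *v, const double *lambda, double tau) {
  double total = 0.0;
  for (int j = 0; j < 4; j++) {
    double t = clip_class_loglik(n[j], v, lambda, j, tau);
    if (!R_FINITE(t)) return R_NegInf;
    total += t;
  }
  return total;
}

double rec_loglik(const int *n, const double *v, const double *lambda, double tau) {
  double total = 0.0;
  for (int j = 0; j < 4; j++) {
    double mj = 0.0;
    for (int i = 0; i < 4; i++) mj += lambda[i * 4 + j] * v[i];
    if (mj <= 0.0) {
      if (n[j] != 0) return R_NegInf;
      continue;
    }
    total += dpo_logpmf(n[j], mj, tau);
  }
  return total;
}

// ---------------------------------------------------------------------------
// Exported interface

// [[Rcpp::export]]
NumericVector ddpo_cpp(IntegerVector y, double m, double tau, bool log_p) {
  if (m < 0.0 || tau <= 0.0) stop("require m >= 0 and tau > 0");
  int n = y.size();
  NumericVector out(n);
  double lz = dpo_logz(m, tau);
  for (int i = 0; i < n; i++) {
    double lp = (y[i] < 0) ? R_NegInf : dpo_logterm(y[i], m, tau) - lz;
    out[i] = log_p ? lp : std::exp(lp);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector rdpo_cpp(int n, double m, double tau) {
  if (m < 0.0 || tau <= 0.0) stop("require m >= 0 and tau > 0");
  IntegerVector out(n);
  if (m == 0.0) return out;                    // all zeros
  double sd = std::sqrt(m / tau);
  int L = (int) std::ceil(m + 15.0 * sd) + 30;
  std::vector<double> pmf = dpo_pmf_vec(L, m, tau);
  std::vector<double> cdf(pmf.size());
  double s = 0.0;
  for (size_t i = 0; i < pmf.size(); i++) { s += pmf[i]; cdf[i] = s; }
  for (auto &c : cdf) c /= s;                  // absorb tiny truncated tail
  for (int k = 0; k < n; k++) {
    double u = unif_rand();
    int lo = 0, hi = (int) cdf.size() - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cdf[mid] < u) lo = mid + 1; else hi = mid;
    }
    out[k] = lo;
  }
  return out;
}

// [[Rcpp::export]]
double clip_loglik_cpp(IntegerVector n, IntegerVector v, NumericMatrix lambda, double tau) {
  if (n.size() != 4 || v.size() != 4) stop("n and v must have length 4");
  double lam[16];
  for (int i = 0; i < 4; i++)
    for (int j = 0; j < 4; j++) lam[i * 4 + j] = lambda(i, j);
  return clip_loglik(&n[0], &v[0], lam, tau);
}

// [[Rcpp::export]]
double rec_loglik_cpp(IntegerVector n, NumericVector v, NumericMatrix lambda, double tau) {
  if (n.size() != 4 || v.size() != 4) stop("n and v must have length 4");
  double lam[16];
  for (int i = 0; i < 4; i++)
    for (int j = 0; j < 4; j++) lam[i * 4 + j] = lambda(i, j);
  return rec_loglik(&n[0], &v[0], lam, tau);
}

// Simulate classifier counts for one unit: n_ij ~ DPO(lambda_ij v_i, tau),
// n_j = sum_i n_ij.  Uses R's RNG.
// [[Rcpp::export]]
IntegerVector simulate_counts_cpp(IntegerVector v, NumericMatrix lambda, double tau) {
  if (v.size() != 4) stop("v must have length 4");
  IntegerVector out(4);
  for (int i = 0; i < 4; i++) {
    if (v[i] <= 0) continue;
    for (int j = 0; j < 4; j++) {
      double mij = lambda(i, j) * v[i];
      if (mij <= 0.0) continue;
      IntegerVector d = rdpo_cpp(1, mij, tau);
      out[j] += d[0];
    }
  }
  return out;
}

// Monte-Carlo frequency of one exact outcome: simulates the confusion model
// n_reps times and counts replicates whose class totals equal `target`.
// Used to validate the marginalized window likelihood against simulation.
// [[Rcpp::export]]
int sim_counts_freq_cpp(IntegerVector v, NumericMatrix lambda, double tau,
                        int n_reps, IntegerVector target) {
  if (v.size() != 4 || target.size() != 4) stop("v and target must have length 4");
  int hits = 0;
  for (int rep = 0; rep < n_reps; rep++) {
    int out[4] = {0, 0, 0, 0};
    for (int i = 0; i < 4; i++) {
      if (v[i] <= 0) continue;
      for (int j = 0; j < 4; j++) {
        double mij = lambda(i, j) * v[i];
        if (mij <= 0.0) continue;
        IntegerVector d = rdpo_cpp(1, mij, tau);
        out[j] += d[0];
      }
    }
    bool same = true;
    for (int j = 0; j < 4; j++) if (out[j] != target[j]) { same = false; break; }
    if (same) hits++;
  }
  return hits;
}
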