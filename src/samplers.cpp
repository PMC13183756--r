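#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <functional>
#include <array>
#include "dpo.h"

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Shared helpers for the adaptive Metropolis-within-Gibbs samplers.
//
// Every scalar is updated with a random-walk proposal (Gaussian on the
// unconstrained scale; multiplicative log-normal for positive parameters)
// whose step size is tuned during warmup toward a 0.44 acceptance rate with
// diminishing adaptation, then frozen for the sampling phase.

struct Adapt {
  std::vector<double> ls;
  bool on;
  Adapt(int n, double init_step) : ls(n, std::log(init_step)), on(true) {}
  double step(int i) const { return std::exp(ls[i]); }
  void tune(int i, double acc, int sweep) {
    if (!on) return;
    ls[i] += (acc - 0.44) / std::pow((double) sweep + 1.0, 0.6);
    if (ls[i] < -12.0) ls[i] = -12.0;
    if (ls[i] > 4.0) ls[i] = 4.0;
  }
};

static inline double lp_gamma_mean(double x, double shape, double mean) {
  // Gamma density parameterized by shape and mean (rate = shape / mean)
  if (mean <= 0.0) return R_NegInf;
  return R::dgamma(x, shape, mean / shape, 1);
}

static inline double lp_exp(double x, double rate) { return -rate * x; }
static inline double lp_halfnormal(double x, double sd) { return -0.5 * x * x / (sd * sd); }
static inline double lp_pareto_shape(double a) {
  // Pareto(scale 1, shape 1.5), support a >= 1
  if (a < 1.0) return R_NegInf;
  return std::log(1.5) - 2.5 * std::log(a);
}
static inline double acc_prob(double logr) {
  if (!R_FINITE(logr)) return logr > 0 ? 1.0 : 0.0;
  return logr >= 0.0 ? 1.0 : std::exp(logr);
}
static inline bool mh_accept(double logr) { return std::log(unif_rand()) < logr; }

// ---------------------------------------------------------------------------
// Confusion-model sampler: posterior over (mu_ij, alpha_ij, tau, lambda_kij)
// given calibration windows with true counts v and classifier counts n.
//
// vmat, nmat: W x 4 integer matrices; rec: 0-based recording index per window.

// [[Rcpp::export]]
List mcmc_confusion_cpp(IntegerMatrix vmat, IntegerMatrix nmat, IntegerVector rec,
                        int K, double mu_prior_rate, int warmup, int iter,
                        List init, bool store_lam) {
  const int W = vmat.nrow();

  // copy data into flat arrays
  std::vector<int> v(W * 4), n(W * 4);
  for (int w = 0; w < W; w++)
    for (int s = 0; s < 4; s++) { v[w * 4 + s] = vmat(w, s); n[w * 4 + s] = nmat(w, s); }
  std::vector<std::vector<int>> wins(K);
  for (int w = 0; w < W; w++) wins[rec[w]].push_back(w);

  // state
  std::vector<double> mu = as<std::vector<double>>(init["mu"]);
  std::vector<double> al = as<std::vector<double>>(init["alpha"]);
  double tau = as<double>(init["tau"]);
  std::vector<double> lam = as<std::vector<double>>(init["lambda"]); // K*16, row-major per rec

  // cached class-wise window log likelihoods
  std::vector<double> clw(W * 4, 0.0);
  for (int w = 0; w < W; w++)
    for (int j = 0; j < 4; j++)
      clw[w * 4 + j] = clip_class_loglik(n[w * 4 + j], &v[w * 4], &lam[rec[w] * 16], j, tau);

  const int n_par = K * 16 + 16 + 16 + 1;
  Adapt ad(n_par, 0.5);
  // parameter index layout for the adapter:
  //   [0, K*16)           lambda
  //   [K*16, K*16+16)     mu
  //   [K*16+16, K*16+32)  alpha
  //   K*16+32             tau
  const int off_mu = K * 16, off_al = K * 16 + 16, idx_tau = K * 16 + 32;

  const int n_keep = iter;
  const int n_col = 33 + (store_lam ? K * 16 : 0);
  NumericMatrix draws(n_keep, n_col);

  for (int sweep = 0; sweep < warmup + iter; sweep++) {
    ad.on = sweep < warmup;

    // lambda_kij (random-scan: each cell updated with probability 1/2)
    for (int k = 0; k < K; k++) {
      for (int ij = 0; ij < 16; ij++) {
        if (unif_rand() < 0.5) continue;
        const int i = ij / 4, j = ij % 4;
        const int p = k * 16 + ij;
        double cur = lam[p];
        double prop = cur * std::exp(ad.step(p) * norm_rand());
        double logr = lp_gamma_mean(prop, al[ij], mu[ij]) - lp_gamma_mean(cur, al[ij], mu[ij])
                    + std::log(prop / cur);
        double lamtmp[16];
        std::copy(&lam[k * 16], &lam[k * 16] + 16, lamtmp);
        lamtmp[ij] = prop;
        std::vector<double> newll(wins[k].size());
        for (size_t t = 0; t < wins[k].size(); t++) {
          int w = wins[k][t];
          newll[t] = clip_class_loglik(n[w * 4 + j], &v[w * 4], lamtmp, j, tau);
          logr += newll[t] - clw[w * 4 + j];
        }
        (void) i;
        ad.tune(p, acc_prob(logr), sweep);
        if (mh_accept(logr)) {
          lam[p] = prop;
          for (size_t t = 0; t < wins[k].size(); t++) clw[wins[k][t] * 4 + j] = newll[t];
        }
      }
    }

    // mu_ij (population mean confusion rates)
    for (int ij = 0; ij < 16; ij++) {
      double cur = mu[ij];
      double prop = cur * std::exp(ad.step(off_mu + ij) * norm_rand());
      double logr = lp_exp(prop, mu_prior_rate) - lp_exp(cur, mu_prior_rate)
                  + std::log(prop / cur);
      for (int k = 0; k < K; k++)
        logr += lp_gamma_mean(lam[k * 16 + ij], al[ij], prop)
              - lp_gamma_mean(lam[k * 16 + ij], al[ij], cur);
      ad.tune(off_mu + ij, acc_prob(logr), sweep);
      if (mh_accept(logr)) mu[ij] = prop;
    }

    // alpha_ij (Gamma shapes), sampled as 1 + exp(z)
    for (int ij = 0; ij < 16; ij++) {
      double cur = al[ij];
      double prop = 1.0 + (cur - 1.0) * std::exp(ad.step(off_al + ij) * norm_rand());
      double logr = lp_pareto_shape(prop) - lp_pareto_shape(cur)
                  + std::log((prop - 1.0) / (cur - 1.0));
      for (int k = 0; k < K; k++)
        logr += lp_gamma_mean(lam[k * 16 + ij], prop, mu[ij])
              - lp_gamma_mean(lam[k * 16 + ij], cur, mu[ij]);
      ad.tune(off_al + ij, acc_prob(logr), sweep);
      if (mh_accept(logr)) al[ij] = prop;
    }

    // tau (shared dispersion)
    {
      double cur = tau;
      double prop = cur * std::exp(ad.step(idx_tau) * norm_rand());
      double logr = lp_halfnormal(prop, 1.0) - lp_halfnormal(cur, 1.0)
                  + std::log(prop / cur);
      std::vector<double> newll(W * 4);
      for (int w = 0; w < W; w++)
        for (int j = 0; j < 4; j++) {
          newll[w * 4 + j] = clip_class_loglik(n[w * 4 + j], &v[w * 4], &lam[rec[w] * 16], j, prop);
          logr += newll[w * 4 + j] - clw[w * 4 + j];
        }
      ad.tune(idx_tau, acc_prob(logr), sweep);
      if (mh_accept(logr)) { tau = prop; clw.swap(newll); }
    }

    if (sweep >= warmup) {
      int row = sweep - warmup;
      for (int ij = 0; ij < 16; ij++) draws(row, ij) = mu[ij];
      for (int ij = 0; ij < 16; ij++) draws(row, 16 + ij) = al[ij];
      draws(row, 32) = tau;
      if (store_lam)
        for (int p = 0; p < K * 16; p++) draws(row, 33 + p) = lam[p];
    }
  }

  return List::create(_["draws"] = draws);
}

// ---------------------------------------------------------------------------
// Joint sampler: behavior model + latent true counts + confusion model.
// With naive = true the classifier counts are treated as true counts and only
// the behavior block is sampled (negative-binomial observation model).
//
// Behavior parameter layout in the stored draws:
//   0..3  mu_pop[CHI,OCH,FEM,MAL]   4 sigma_corpus   5 sigma_child
//   6 beta_sib_och   7 beta_sib_adu  8 alpha_dev  9 sigma_dev
//   10 beta_dev      11 phi
// followed (joint fit only) by mu[16], alpha[16], tau, then latent v (R*4)
// when store_v is set.

struct JointState {
  // data
  int R, C, G, Kc, Wc;
  std::vector<int> nobs;            // R*4
  std::vector<int> child, corpus;   // per recording
  std::vector<double> age;          // per recording
  std::vector<double> sibc;         // per child (0/1)
  std::vector<int> gc;              // corpus per child
  std::vector<int> cv, cn, crec;    // calibration windows
  std::vector<std::vector<int>> cwins;  // windows per calibration recording
  std::vector<std::vector<int>> crecs;  // recordings per child
  double plateau;
  bool naive;

  // behavior parameters
  double mupop[4];
  std::vector<double> devC;   // G*4
  std::vector<double> devK;   // C*4
  double sigC, sigK, bsoch, bsadu, adev, sigdev, bdev, phi;
  std::vector<double> slope;  // C

  // confusion parameters and latents
  std::vector<double> mu, al; // 16
  double tau;
  std::vector<double> lamC;   // Kc*16
  std::vector<double> lamR;   // R*16
  std::vector<double> vlat;   // R*4 (continuous latent true counts)

  // caches
  std::vector<double> la;     // child-level log adult rate (C)
  std::vector<double> A;      // standardized adult input level (C)
  std::vector<double> m;      // R*4 expected rates
  std::vector<double> lpv;    // R*4 behavior data terms
  std::vector<double> obs;    // R*4 observation terms (joint only)
  std::vector<double> clw;    // Wc*4 calibration window terms (joint only)

  double ageb(double a) const { return std::min(a, plateau) / plateau; }

  void compute_la(std::vector<double> &out) const {
    for (int c = 0; c < C; c++) {
      double eF = mupop[2] + devC[gc[c] * 4 + 2] + devK[c * 4 + 2] + bsadu * sibc[c];
      double eM = mupop[3] + devC[gc[c] * 4 + 3] + devK[c * 4 + 3] + bsadu * sibc[c];
      double mx = std::max(eF, eM);
      out[c] = mx + std::log(std::exp(eF - mx) + std::exp(eM - mx));
    }
  }

  static void standardize(const std::vector<double> &la_, std::vector<double> &A_) {
    int C = la_.size();
    double mn = 0.0;
    for (double x : la_) mn += x;
    mn /= C;
    double s2 = 0.0;
    for (double x : la_) s2 += (x - mn) * (x - mn);
    double sd = (C > 1) ? std::sqrt(s2 / (C - 1)) : 0.0;
    for (int c = 0; c < C; c++) A_[c] = (sd > 1e-12) ? (la_[c] - mn) / sd : 0.0;
  }

  double mean_rs(int r, int s, const std::vector<double> &A_) const {
    int c = child[r], g = corpus[r];
    double eta = mupop[s] + devC[g * 4 + s] + devK[c * 4 + s];
    if (s == 1) eta += bsoch * sibc[c];
    if (s >= 2) eta += bsadu * sibc[c];
    if (s == 0) eta += (slope[c] + bdev * A_[c]) * ageb(age[r]);
    return std::exp(eta);
  }

  // Continuous latent prior: Gamma moment-matched to the gamma-Poisson
  // count law (variance m + m^2/phi), so the Poisson layer's variance is
  // not lost at moderate means.
  double latent_lp(double v, double mrs) const {
    if (mrs <= 0.0) return R_NegInf;
    double shape = phi * mrs / (phi + mrs);
    return lp_gamma_mean(v, shape, mrs);
  }

  // behavior data term: latent prior (joint) or negative binomial on the
  // observed count (naive)
  double data_lp(int r, int s, double mrs) const {
    if (naive) return R::dnbinom_mu((double) nobs[r * 4 + s], phi, mrs, 1);
    return latent_lp(vlat[r * 4 + s], mrs);
  }

  double obs_class(int r, int j) const {
    double mj = 0.0;
    for (int i = 0; i < 4; i++) mj += lamR[r * 16 + i * 4 + j] * vlat[r * 4 + i];
    if (mj <= 0.0) return (nobs[r * 4 + j] == 0) ? 0.0 : R_NegInf;
    return dpo_logpmf(nobs[r * 4 + j], mj, tau);
  }

  void refresh_all() {
    compute_la(la);
    standardize(la, A);
    for (int r = 0; r < R; r++)
      for (int s = 0; s < 4; s++) {
        m[r * 4 + s] = mean_rs(r, s, A);
        lpv[r * 4 + s] = data_lp(r, s, m[r * 4 + s]);
      }
    if (!naive) {
      for (int r = 0; r < R; r++)
        for (int j = 0; j < 4; j++) obs[r * 4 + j] = obs_class(r, j);
      for (int w = 0; w < Wc; w++)
        for (int j = 0; j < 4; j++)
          clw[w * 4 + j] = clip_class_loglik(cn[w * 4 + j], &cv[w * 4], &lamC[crec[w] * 16], j, tau);
    }
  }
};

// [[Rcpp::export]]
List mcmc_joint_cpp(IntegerMatrix cvmat, IntegerMatrix cnmat, IntegerVector crec, int Kc,
                    IntegerMatrix nobs, IntegerVector child, IntegerVector corpus,
                    NumericVector age, NumericVector sib_child, IntegerVector child_corpus,
                    bool naive, double plateau, List prior,
                    int warmup, int iter, List init, bool store_v) {
  JointState st;
  st.R = nobs.nrow();
  st.C = sib_child.size();
  st.G = 0;
  for (int i = 0; i < child_corpus.size(); i++) st.G = std::max(st.G, child_corpus[i] + 1);
  st.Kc = Kc;
  st.Wc = cvmat.nrow();
  st.naive = naive;
  st.plateau = plateau;

  st.nobs.resize(st.R * 4);
  st.child.assign(child.begin(), child.end());
  st.corpus.assign(corpus.begin(), corpus.end());
  st.age.assign(age.begin(), age.end());
  st.sibc.assign(sib_child.begin(), sib_child.end());
  st.gc.assign(child_corpus.begin(), child_corpus.end());
  for (int r = 0; r < st.R; r++)
    for (int s = 0; s < 4; s++) st.nobs[r * 4 + s] = nobs(r, s);
  st.crecs.assign(st.C, {});
  for (int r = 0; r < st.R; r++) st.crecs[st.child[r]].push_back(r);

  st.cv.resize(st.Wc * 4);
  st.cn.resize(st.Wc * 4);
  st.crec.assign(crec.begin(), crec.end());
  for (int w = 0; w < st.Wc; w++)
    for (int s = 0; s < 4; s++) { st.cv[w * 4 + s] = cvmat(w, s); st.cn[w * 4 + s] = cnmat(w, s); }
  st.cwins.assign(std::max(Kc, 1), {});
  for (int w = 0; w < st.Wc; w++) st.cwins[st.crec[w]].push_back(w);

  // priors
  const double mu_rate = as<double>(prior["mu_rate"]);
  NumericVector mpm = prior["mupop_mean"];          // length 1 or 4
  double mp_mean_[4];
  for (int s = 0; s < 4; s++) mp_mean_[s] = mpm[mpm.size() == 4 ? s : 0];
  const double mp_sd = as<double>(prior["mupop_sd"]);
  const double phi_rate = as<double>(prior["phi_rate"]);
  const double sd_eff = as<double>(prior["effect_sd"]);  // unconstrained effects
  const double sd_sig = as<double>(prior["sigma_sd"]);   // half-normal on SDs
  const double tau_shift = as<double>(prior["tau_shift"]);
  const double tau_sd = as<double>(prior["tau_sd"]);

  // init
  {
    NumericVector x;
    x = init["mu_pop"];   for (int s = 0; s < 4; s++) st.mupop[s] = x[s];
    st.devC = as<std::vector<double>>(init["dev_corpus"]);
    st.devK = as<std::vector<double>>(init["dev_child"]);
    st.sigC = as<double>(init["sigma_corpus"]);
    st.sigK = as<double>(init["sigma_child"]);
    st.bsoch = as<double>(init["beta_sib_och"]);
    st.bsadu = as<double>(init["beta_sib_adu"]);
    st.adev = as<double>(init["alpha_dev"]);
    st.sigdev = as<double>(init["sigma_dev"]);
    st.bdev = as<double>(init["beta_dev"]);
    st.phi = as<double>(init["phi"]);
    st.slope = as<std::vector<double>>(init["slope"]);
    st.mu = as<std::vector<double>>(init["mu"]);
    st.al = as<std::vector<double>>(init["alpha"]);
    st.tau = as<double>(init["tau"]);
    st.lamC = as<std::vector<double>>(init["lambda_calib"]);
    st.lamR = as<std::vector<double>>(init["lambda_rec"]);
    st.vlat = as<std::vector<double>>(init["v"]);
  }

  st.la.resize(st.C);
  st.A.resize(st.C);
  st.m.resize(st.R * 4);
  st.lpv.resize(st.R * 4);
  st.obs.resize(st.R * 4);
  st.clw.resize(std::max(st.Wc, 1) * 4);
  st.refresh_all();

  // adapter layout
  // extra adapter slots: intercept/slope, per-child dev/slope, OCH and adult
  // intercept/sibling-effect ridge moves
  const int nb = 12 + st.G * 4 + st.C * 4 + st.C + st.C + 3 + 4;
  const int nc = naive ? 0 : (33 + st.Kc * 16 + st.R * 16 + st.R * 4 + st.R * 4);
  Adapt ad(nb + nc, 0.3);
  const int off_devC = 12, off_devK = 12 + st.G * 4, off_slope = off_devK + st.C * 4;
  const int idx_m1 = off_slope + st.C, off_m2 = idx_m1 + 1;
  const int idx_m3 = off_m2 + st.C, idx_m4 = idx_m3 + 1;
  const int off_gscale = idx_m4 + 1;   // per-source global scaling moves
  const int off_cmu = nb, off_cal = nb + 16, idx_ctau = nb + 32;
  const int off_lamC = nb + 33, off_lamR = off_lamC + st.Kc * 16, off_v = off_lamR + st.R * 16;
  const int off_ridge = off_v + st.R * 4;

  // mean age bases, used to aim the intercept/slope ridge moves
  double abbar = 0.0;
  std::vector<double> abc(st.C, 0.0);
  for (int r = 0; r < st.R; r++) {
    double ab = st.ageb(st.age[r]);
    abbar += ab / st.R;
    abc[st.child[r]] += ab / st.crecs[st.child[r]].size();
  }
  if (abbar < 0.05) abbar = 0.05;
  for (int c = 0; c < st.C; c++) if (abc[c] < 0.05) abc[c] = 0.05;

  const int n_theta = 12;
  const int n_col = n_theta + (naive ? 0 : 33) + ((!naive && store_v) ? st.R * 4 : 0);
  NumericMatrix draws(iter, n_col);

  // helper: propose a global behavior parameter; only the speaker classes
  // in `mask` have changed means and need recomputation
  std::vector<double> la2(st.C), A2(st.C), m2(st.R * 4), lpv2(st.R * 4);
  auto try_global = [&](double lp_delta_prior, int adapt_idx, int sweep,
                        const std::array<bool, 4> &mask,
                        std::function<void()> apply, std::function<void()> revert) {
    apply();
    st.compute_la(la2);
    JointState::standardize(la2, A2);
    m2 = st.m;
    lpv2 = st.lpv;
    double dll = lp_delta_prior;
    for (int r = 0; r < st.R; r++)
      for (int s = 0; s < 4; s++) {
        if (!mask[s]) continue;
        m2[r * 4 + s] = st.mean_rs(r, s, A2);
        lpv2[r * 4 + s] = st.data_lp(r, s, m2[r * 4 + s]);
        dll += lpv2[r * 4 + s] - st.lpv[r * 4 + s];
      }
    ad.tune(adapt_idx, acc_prob(dll), sweep);
    if (mh_accept(dll)) {
      st.la.swap(la2); st.A.swap(A2); st.m.swap(m2); st.lpv.swap(lpv2);
    } else revert();
  };
  const std::array<bool, 4> mask_chi = {true, false, false, false};
  const std::array<bool, 4> mask_och = {false, true, false, false};
  const std::array<bool, 4> mask_adu = {true, false, true, true};
  const std::array<bool, 4> mask_fem = {true, false, true, false};
  const std::array<bool, 4> mask_mal = {true, false, false, true};

  for (int sweep = 0; sweep < warmup + iter; sweep++) {
    ad.on = sweep < warmup;

    // --- global behavior parameters -------------------------------------
    for (int s = 0; s < 4; s++) {
      double cur = st.mupop[s], prop = cur + ad.step(s) * norm_rand();
      double dpri = R::dnorm(prop, mp_mean_[s], mp_sd, 1) - R::dnorm(cur, mp_mean_[s], mp_sd, 1);
      const std::array<bool, 4> &mk = (s == 0) ? mask_chi : (s == 1) ? mask_och
                                    : (s == 2) ? mask_fem : mask_mal;
      try_global(dpri, s, sweep, mk,
                 [&] { st.mupop[s] = prop; }, [&] { st.mupop[s] = cur; });
    }
    for (int g = 0; g < st.G; g++)
      for (int s = 0; s < 4; s++) {
        int p = off_devC + g * 4 + s;
        double cur = st.devC[g * 4 + s], prop = cur + ad.step(p) * norm_rand();
        double dpri = R::dnorm(prop, 0.0, st.sigC, 1) - R::dnorm(cur, 0.0, st.sigC, 1);
        const std::array<bool, 4> &mk = (s == 0) ? mask_chi : (s == 1) ? mask_och
                                      : (s == 2) ? mask_fem : mask_mal;
        try_global(dpri, p, sweep, mk,
                   [&] { st.devC[g * 4 + s] = prop; }, [&] { st.devC[g * 4 + s] = cur; });
      }
    {
      int p = 6;  // beta_sib_och
      double cur = st.bsoch, prop = cur + ad.step(p) * norm_rand();
      double dpri = R::dnorm(prop, 0.0, sd_eff, 1) - R::dnorm(cur, 0.0, sd_eff, 1);
      try_global(dpri, p, sweep, mask_och,
                 [&] { st.bsoch = prop; }, [&] { st.bsoch = cur; });
    }
    {
      int p = 7;  // beta_sib_adu
      double cur = st.bsadu, prop = cur + ad.step(p) * norm_rand();
      double dpri = R::dnorm(prop, 0.0, sd_eff, 1) - R::dnorm(cur, 0.0, sd_eff, 1);
      try_global(dpri, p, sweep, mask_adu,
                 [&] { st.bsadu = prop; }, [&] { st.bsadu = cur; });
    }
    {
      int p = 10; // beta_dev
      double cur = st.bdev, prop = cur + ad.step(p) * norm_rand();
      double dpri = R::dnorm(prop, 0.0, sd_eff, 1) - R::dnorm(cur, 0.0, sd_eff, 1);
      try_global(dpri, p, sweep, mask_chi,
                 [&] { st.bdev = prop; }, [&] { st.bdev = cur; });
    }
    {
      int p = 11; // phi: means unchanged, all data terms recomputed
      // prior: exponential on (phi - 1), support phi >= 1
      double cur = st.phi;
      double prop = 1.0 + (cur - 1.0) * std::exp(ad.step(p) * norm_rand());
      double dll = lp_exp(prop - 1.0, phi_rate) - lp_exp(cur - 1.0, phi_rate)
                 + std::log((prop - 1.0) / (cur - 1.0));
      st.phi = prop;
      for (int r = 0; r < st.R; r++)
        for (int s = 0; s < 4; s++) {
          lpv2[r * 4 + s] = st.data_lp(r, s, st.m[r * 4 + s]);
          dll += lpv2[r * 4 + s] - st.lpv[r * 4 + s];
        }
      ad.tune(p, acc_prob(dll), sweep);
      if (mh_accept(dll)) st.lpv.swap(lpv2); else st.phi = cur;
    }

    // --- ridge moves along known posterior trade-offs --------------------
    {
      // key-child intercept against the developmental slopes: shifting the
      // population log rate up while shifting the slope hierarchy down by
      // delta / mean(age basis) leaves the fitted CHI rates nearly unchanged
      double delta = ad.step(idx_m1) * norm_rand();
      double cur_mu = st.mupop[0], cur_adev = st.adev;
      std::vector<double> cur_slope = st.slope;
      double shift = delta / abbar;
      double dpri = R::dnorm(cur_mu + delta, mp_mean_[0], mp_sd, 1)
                  - R::dnorm(cur_mu, mp_mean_[0], mp_sd, 1)
                  + R::dnorm(cur_adev - shift, 0.0, sd_eff, 1)
                  - R::dnorm(cur_adev, 0.0, sd_eff, 1);
      try_global(dpri, idx_m1, sweep, mask_chi,
                 [&] {
                   st.mupop[0] = cur_mu + delta;
                   st.adev = cur_adev - shift;
                   for (int c = 0; c < st.C; c++) st.slope[c] = cur_slope[c] - shift;
                 },
                 [&] {
                   st.mupop[0] = cur_mu;
                   st.adev = cur_adev;
                   st.slope = cur_slope;
                 });
    }
    {
      // OCH intercept against the sibling effect on other children
      double delta = ad.step(idx_m3) * norm_rand();
      double cur_mu = st.mupop[1], cur_b = st.bsoch;
      double dpri = R::dnorm(cur_mu + delta, mp_mean_[1], mp_sd, 1)
                  - R::dnorm(cur_mu, mp_mean_[1], mp_sd, 1)
                  + R::dnorm(cur_b - delta, 0.0, sd_eff, 1)
                  - R::dnorm(cur_b, 0.0, sd_eff, 1);
      try_global(dpri, idx_m3, sweep, mask_och,
                 [&] { st.mupop[1] = cur_mu + delta; st.bsoch = cur_b - delta; },
                 [&] { st.mupop[1] = cur_mu; st.bsoch = cur_b; });
    }
    {
      // adult intercepts against the sibling effect on adults
      double delta = ad.step(idx_m4) * norm_rand();
      double cur_f = st.mupop[2], cur_m = st.mupop[3], cur_b = st.bsadu;
      double dpri = R::dnorm(cur_f + delta, mp_mean_[2], mp_sd, 1)
                  - R::dnorm(cur_f, mp_mean_[2], mp_sd, 1)
                  + R::dnorm(cur_m + delta, mp_mean_[3], mp_sd, 1)
                  - R::dnorm(cur_m, mp_mean_[3], mp_sd, 1)
                  + R::dnorm(cur_b - delta, 0.0, sd_eff, 1)
                  - R::dnorm(cur_b, 0.0, sd_eff, 1);
      try_global(dpri, idx_m4, sweep, mask_adu,
                 [&] { st.mupop[2] = cur_f + delta; st.mupop[3] = cur_m + delta;
                       st.bsadu = cur_b - delta; },
                 [&] { st.mupop[2] = cur_f; st.mupop[3] = cur_m; st.bsadu = cur_b; });
    }
    // per-child trade-off between the CHI deviation and the child's slope
    for (int c = 0; c < st.C; c++) {
      int p = off_m2 + c;
      double delta = ad.step(p) * norm_rand();
      double shift = delta / abc[c];
      double cur_dev = st.devK[c * 4 + 0], cur_slope = st.slope[c];
      double dll = R::dnorm(cur_dev + delta, 0.0, st.sigK, 1)
                 - R::dnorm(cur_dev, 0.0, st.sigK, 1)
                 + R::dnorm(cur_slope - shift, st.adev, st.sigdev, 1)
                 - R::dnorm(cur_slope, st.adev, st.sigdev, 1);
      st.devK[c * 4 + 0] = cur_dev + delta;
      st.slope[c] = cur_slope - shift;
      std::vector<std::pair<int, double>> upd_m, upd_lp;
      for (int r : st.crecs[c]) {
        double mm = st.mean_rs(r, 0, st.A);
        double ll = st.data_lp(r, 0, mm);
        upd_m.push_back({r * 4 + 0, mm});
        upd_lp.push_back({r * 4 + 0, ll});
        dll += ll - st.lpv[r * 4 + 0];
      }
      ad.tune(p, acc_prob(dll), sweep);
      if (mh_accept(dll)) {
        for (auto &u : upd_m) st.m[u.first] = u.second;
        for (auto &u : upd_lp) st.lpv[u.first] = u.second;
      } else { st.devK[c * 4 + 0] = cur_dev; st.slope[c] = cur_slope; }
    }

    // --- child-level deviations -----------------------------------------
    for (int c = 0; c < st.C; c++)
      for (int s = 0; s < 4; s++) {
        if (unif_rand() < 0.5) continue;      // random scan
        int p = off_devK + c * 4 + s;
        double cur = st.devK[c * 4 + s], prop = cur + ad.step(p) * norm_rand();
        double dll = R::dnorm(prop, 0.0, st.sigK, 1) - R::dnorm(cur, 0.0, st.sigK, 1);
        if (s >= 2) {
          // adult rate changes -> adult-input standardization shifts for all
          st.devK[c * 4 + s] = prop;
          st.compute_la(la2);
          JointState::standardize(la2, A2);
          // affected: CHI terms everywhere + speaker-s terms of this child
          std::vector<std::pair<int, double>> upd_m, upd_lp;
          for (int r = 0; r < st.R; r++) {
            double mm = st.mean_rs(r, 0, A2);
            double ll = st.data_lp(r, 0, mm);
            upd_m.push_back({r * 4 + 0, mm});
            upd_lp.push_back({r * 4 + 0, ll});
            dll += ll - st.lpv[r * 4 + 0];
          }
          for (int r : st.crecs[c]) {
            double mm = st.mean_rs(r, s, A2);
            double ll = st.data_lp(r, s, mm);
            upd_m.push_back({r * 4 + s, mm});
            upd_lp.push_back({r * 4 + s, ll});
            dll += ll - st.lpv[r * 4 + s];
          }
          ad.tune(p, acc_prob(dll), sweep);
          if (mh_accept(dll)) {
            st.la.swap(la2); st.A.swap(A2);
            for (auto &u : upd_m) st.m[u.first] = u.second;
            for (auto &u : upd_lp) st.lpv[u.first] = u.second;
          } else st.devK[c * 4 + s] = cur;
        } else {
          st.devK[c * 4 + s] = prop;
          std::vector<std::pair<int, double>> upd_m, upd_lp;
          for (int r : st.crecs[c]) {
            double mm = st.mean_rs(r, s, st.A);
            double ll = st.data_lp(r, s, mm);
            upd_m.push_back({r * 4 + s, mm});
            upd_lp.push_back({r * 4 + s, ll});
            dll += ll - st.lpv[r * 4 + s];
          }
          ad.tune(p, acc_prob(dll), sweep);
          if (mh_accept(dll)) {
            for (auto &u : upd_m) st.m[u.first] = u.second;
            for (auto &u : upd_lp) st.lpv[u.first] = u.second;
          } else st.devK[c * 4 + s] = cur;
        }
      }

    // --- child age slopes -------------------------------------------------
    for (int c = 0; c < st.C; c++) {
      int p = off_slope + c;
      double cur = st.slope[c], prop = cur + ad.step(p) * norm_rand();
      double dll = R::dnorm(prop, st.adev, st.sigdev, 1) - R::dnorm(cur, st.adev, st.sigdev, 1);
      st.slope[c] = prop;
      std::vector<std::pair<int, double>> upd_m, upd_lp;
      for (int r : st.crecs[c]) {
        double mm = st.mean_rs(r, 0, st.A);
        double ll = st.data_lp(r, 0, mm);
        upd_m.push_back({r * 4 + 0, mm});
        upd_lp.push_back({r * 4 + 0, ll});
        dll += ll - st.lpv[r * 4 + 0];
      }
      ad.tune(p, acc_prob(dll), sweep);
      if (mh_accept(dll)) {
        for (auto &u : upd_m) st.m[u.first] = u.second;
        for (auto &u : upd_lp) st.lpv[u.first] = u.second;
      } else st.slope[c] = cur;
    }

    // --- hierarchy scales and slope mean ---------------------------------
    {
      int p = 8;  // alpha_dev
      double cur = st.adev, prop = cur + ad.step(p) * norm_rand();
      double dll = R::dnorm(prop, 0.0, sd_eff, 1) - R::dnorm(cur, 0.0, sd_eff, 1);
      for (int c = 0; c < st.C; c++)
        dll += R::dnorm(st.slope[c], prop, st.sigdev, 1) - R::dnorm(st.slope[c], cur, st.sigdev, 1);
      ad.tune(p, acc_prob(dll), sweep);
      if (mh_accept(dll)) st.adev = prop;
    }
    {
      int p = 9;  // sigma_dev
      double cur = st.sigdev, prop = cur * std::exp(ad.step(p) * norm_rand());
      double dll = lp_halfnormal(prop, sd_sig) - lp_halfnormal(cur, sd_sig) + std::log(prop / cur);
      for (int c = 0; c < st.C; c++)
        dll += R::dnorm(st.slope[c], st.adev, prop, 1) - R::dnorm(st.slope[c], st.adev, cur, 1);
      ad.tune(p, acc_prob(dll), sweep);
      if (mh_accept(dll)) st.sigdev = prop;
    }
    {
      int p = 4;  // sigma_corpus
      double cur = st.sigC, prop = cur * std::exp(ad.step(p) * norm_rand());
      double dll = lp_halfnormal(prop, sd_sig) - lp_halfnormal(cur, sd_sig) + std::log(prop / cur);
      for (int g = 0; g < st.G; g++)
        for (int s = 0; s < 4; s++)
          dll += R::dnorm(st.devC[g * 4 + s], 0.0, prop, 1) - R::dnorm(st.devC[g * 4 + s], 0.0, cur, 1);
      ad.tune(p, acc_prob(dll), sweep);
      if (mh_accept(dll)) st.sigC = prop;
    }
    {
      int p = 5;  // sigma_child
      double cur = st.sigK, prop = cur * std::exp(ad.step(p) * norm_rand());
      double dll = lp_halfnormal(prop, sd_sig) - lp_halfnormal(cur, sd_sig) + std::log(prop / cur);
      for (int c = 0; c < st.C; c++)
        for (int s = 0; s < 4; s++)
          dll += R::dnorm(st.devK[c * 4 + s], 0.0, prop, 1) - R::dnorm(st.devK[c * 4 + s], 0.0, cur, 1);
      ad.tune(p, acc_prob(dll), sweep);
      if (mh_accept(dll)) st.sigK = prop;
    }

    if (!naive) {
      // --- latent true counts --------------------------------------------
      for (int r = 0; r < st.R; r++)
        for (int i = 0; i < 4; i++) {
          int p = off_v + r * 4 + i;
          double cur = st.vlat[r * 4 + i];
          double prop = cur * std::exp(ad.step(p) * norm_rand());
          double dll = st.latent_lp(prop, st.m[r * 4 + i])
                     - st.lpv[r * 4 + i] + std::log(prop / cur);
          st.vlat[r * 4 + i] = prop;
          double newobs[4];
          for (int j = 0; j < 4; j++) {
            newobs[j] = st.obs_class(r, j);
            dll += newobs[j] - st.obs[r * 4 + j];
          }
          ad.tune(p, acc_prob(dll), sweep);
          if (mh_accept(dll)) {
            st.lpv[r * 4 + i] = st.latent_lp(prop, st.m[r * 4 + i]);
            for (int j = 0; j < 4; j++) st.obs[r * 4 + j] = newobs[j];
          } else st.vlat[r * 4 + i] = cur;
        }

      // --- ridge move: rescale v_ri against its lambda row ----------------
      // The observation means sum_i lambda_ij v_i are invariant under
      // v_ri -> c v_ri, lambda_i. -> lambda_i. / c, so this move travels
      // along the direction the scalar updates mix worst; only the priors
      // and the log-scale Jacobian enter the acceptance ratio.
      for (int r = 0; r < st.R; r++)
        for (int i = 0; i < 4; i++) {
          int p = off_ridge + r * 4 + i;
          double delta = ad.step(p) * norm_rand();
          double c = std::exp(delta);
          double vcur = st.vlat[r * 4 + i], vprop = vcur * c;
          double dll = st.latent_lp(vprop, st.m[r * 4 + i])
                     - st.lpv[r * 4 + i] - 3.0 * delta;
          double lamprop[4];
          for (int j = 0; j < 4; j++) {
            double lcur = st.lamR[r * 16 + i * 4 + j];
            lamprop[j] = lcur / c;
            dll += lp_gamma_mean(lamprop[j], st.al[i * 4 + j], st.mu[i * 4 + j])
                 - lp_gamma_mean(lcur, st.al[i * 4 + j], st.mu[i * 4 + j]);
          }
          ad.tune(p, acc_prob(dll), sweep);
          if (mh_accept(dll)) {
            st.vlat[r * 4 + i] = vprop;
            st.lpv[r * 4 + i] = st.latent_lp(vprop, st.m[r * 4 + i]);
            for (int j = 0; j < 4; j++) st.lamR[r * 16 + i * 4 + j] = lamprop[j];
          }
        }

      // --- global source-scaling move --------------------------------------
      // For one source class i, scale every latent v_ri up by c while
      // scaling the whole lambda row i (recordings and calibration) and
      // mu_i. down by c.  All observation means are invariant; the
      // calibration-clip likelihood (which anchors the absolute scale) and
      // the priors arbitrate the move.
      for (int i = 0; i < 4; i++) {
        if (unif_rand() < 0.5) continue;
        int p = off_gscale + i;
        double delta = ad.step(p) * norm_rand();
        double c = std::exp(delta);
        double dll = 0.0;
        // latent priors and their Jacobian
        std::vector<double> lpv2i(st.R);
        for (int r = 0; r < st.R; r++) {
          lpv2i[r] = st.latent_lp(st.vlat[r * 4 + i] * c, st.m[r * 4 + i]);
          dll += lpv2i[r] - st.lpv[r * 4 + i];
        }
        dll += st.R * delta;
        // lambda priors: scaling lambda and mu together contributes +delta
        // per draw; Jacobians contribute -delta per draw and per mu cell
        dll += 4.0 * (st.Kc + st.R) * delta;     // prior terms
        dll -= 4.0 * (st.Kc + st.R) * delta;     // lambda Jacobians
        dll -= 4.0 * delta;                      // mu Jacobians
        for (int j = 0; j < 4; j++) {
          double mu_old = st.mu[i * 4 + j];
          dll += lp_exp(mu_old / c, mu_rate) - lp_exp(mu_old, mu_rate);
        }
        // calibration-clip likelihood under the scaled lambda row
        std::vector<double> newclw;
        if (st.Wc > 0) {
          newclw.resize(st.Wc * 4);
          for (int w = 0; w < st.Wc; w++) {
            double lamtmp[16];
            std::copy(&st.lamC[st.crec[w] * 16], &st.lamC[st.crec[w] * 16] + 16, lamtmp);
            for (int j = 0; j < 4; j++) lamtmp[i * 4 + j] /= c;
            for (int j = 0; j < 4; j++) {
              newclw[w * 4 + j] = clip_class_loglik(st.cn[w * 4 + j], &st.cv[w * 4],
                                                    lamtmp, j, st.tau);
              dll += newclw[w * 4 + j] - st.clw[w * 4 + j];
            }
          }
        }
        ad.tune(p, acc_prob(dll), sweep);
        if (mh_accept(dll)) {
          for (int r = 0; r < st.R; r++) {
            st.vlat[r * 4 + i] *= c;
            st.lpv[r * 4 + i] = lpv2i[r];
            for (int j = 0; j < 4; j++) st.lamR[r * 16 + i * 4 + j] /= c;
          }
          for (int k = 0; k < st.Kc; k++)
            for (int j = 0; j < 4; j++) st.lamC[k * 16 + i * 4 + j] /= c;
          for (int j = 0; j < 4; j++) st.mu[i * 4 + j] /= c;
          if (st.Wc > 0) st.clw.swap(newclw);
        }
      }

      // --- per-recording confusion rates (unlabeled recordings) ----------
      for (int r = 0; r < st.R; r++)
        for (int ij = 0; ij < 16; ij++) {
          if (unif_rand() < 0.5) continue;
          int j = ij % 4;
          int p = off_lamR + r * 16 + ij;
          double cur = st.lamR[r * 16 + ij];
          double prop = cur * std::exp(ad.step(p) * norm_rand());
          double dll = lp_gamma_mean(prop, st.al[ij], st.mu[ij])
                     - lp_gamma_mean(cur, st.al[ij], st.mu[ij]) + std::log(prop / cur);
          st.lamR[r * 16 + ij] = prop;
          double no = st.obs_class(r, j);
          dll += no - st.obs[r * 4 + j];
          ad.tune(p, acc_prob(dll), sweep);
          if (mh_accept(dll)) st.obs[r * 4 + j] = no;
          else st.lamR[r * 16 + ij] = cur;
        }

      // --- calibration-recording confusion rates --------------------------
      for (int k = 0; k < st.Kc; k++)
        for (int ij = 0; ij < 16; ij++) {
          if (unif_rand() < 0.5) continue;
          int j = ij % 4;
          int p = off_lamC + k * 16 + ij;
          double cur = st.lamC[k * 16 + ij];
          double prop = cur * std::exp(ad.step(p) * norm_rand());
          double dll = lp_gamma_mean(prop, st.al[ij], st.mu[ij])
                     - lp_gamma_mean(cur, st.al[ij], st.mu[ij]) + std::log(prop / cur);
          double lamtmp[16];
          std::copy(&st.lamC[k * 16], &st.lamC[k * 16] + 16, lamtmp);
          lamtmp[ij] = prop;
          std::vector<double> newll(st.cwins[k].size());
          for (size_t t = 0; t < st.cwins[k].size(); t++) {
            int w = st.cwins[k][t];
            newll[t] = clip_class_loglik(st.cn[w * 4 + j], &st.cv[w * 4], lamtmp, j, st.tau);
            dll += newll[t] - st.clw[w * 4 + j];
          }
          ad.tune(p, acc_prob(dll), sweep);
          if (mh_accept(dll)) {
            st.lamC[k * 16 + ij] = prop;
            for (size_t t = 0; t < st.cwins[k].size(); t++)
              st.clw[st.cwins[k][t] * 4 + j] = newll[t];
          }
        }

      // --- confusion hyperparameters --------------------------------------
      for (int ij = 0; ij < 16; ij++) {
        int p = off_cmu + ij;
        double cur = st.mu[ij], prop = cur * std::exp(ad.step(p) * norm_rand());
        double dll = lp_exp(prop, mu_rate) - lp_exp(cur, mu_rate) + std::log(prop / cur);
        for (int k = 0; k < st.Kc; k++)
          dll += lp_gamma_mean(st.lamC[k * 16 + ij], st.al[ij], prop)
               - lp_gamma_mean(st.lamC[k * 16 + ij], st.al[ij], cur);
        for (int r = 0; r < st.R; r++)
          dll += lp_gamma_mean(st.lamR[r * 16 + ij], st.al[ij], prop)
               - lp_gamma_mean(st.lamR[r * 16 + ij], st.al[ij], cur);
        ad.tune(p, acc_prob(dll), sweep);
        if (mh_accept(dll)) st.mu[ij] = prop;
      }
      for (int ij = 0; ij < 16; ij++) {
        int p = off_cal + ij;
        double cur = st.al[ij];
        double prop = 1.0 + (cur - 1.0) * std::exp(ad.step(p) * norm_rand());
        double dll = lp_pareto_shape(prop) - lp_pareto_shape(cur)
                   + std::log((prop - 1.0) / (cur - 1.0));
        for (int k = 0; k < st.Kc; k++)
          dll += lp_gamma_mean(st.lamC[k * 16 + ij], prop, st.mu[ij])
               - lp_gamma_mean(st.lamC[k * 16 + ij], cur, st.mu[ij]);
        for (int r = 0; r < st.R; r++)
          dll += lp_gamma_mean(st.lamR[r * 16 + ij], prop, st.mu[ij])
               - lp_gamma_mean(st.lamR[r * 16 + ij], cur, st.mu[ij]);
        ad.tune(p, acc_prob(dll), sweep);
        if (mh_accept(dll)) st.al[ij] = prop;
      }
      {
        // tau prior: half-normal on (tau - tau_shift), support tau >= shift
        double cur = st.tau;
        double prop = tau_shift + (cur - tau_shift) * std::exp(ad.step(idx_ctau) * norm_rand());
        double dll = lp_halfnormal(prop - tau_shift, tau_sd)
                   - lp_halfnormal(cur - tau_shift, tau_sd)
                   + std::log((prop - tau_shift) / (cur - tau_shift));
        st.tau = prop;
        std::vector<double> newobs(st.R * 4), newclw(st.Wc * 4);
        for (int r = 0; r < st.R; r++)
          for (int j = 0; j < 4; j++) {
            newobs[r * 4 + j] = st.obs_class(r, j);
            dll += newobs[r * 4 + j] - st.obs[r * 4 + j];
          }
        for (int w = 0; w < st.Wc; w++)
          for (int j = 0; j < 4; j++) {
            newclw[w * 4 + j] = clip_class_loglik(st.cn[w * 4 + j], &st.cv[w * 4],
                                                  &st.lamC[st.crec[w] * 16], j, st.tau);
            dll += newclw[w * 4 + j] - st.clw[w * 4 + j];
          }
        ad.tune(idx_ctau, acc_prob(dll), sweep);
        if (mh_accept(dll)) { st.obs.swap(newobs); st.clw.swap(newclw); }
        else st.tau = cur;
      }
    }

    // --- record draws -----------------------------------------------------
    if (sweep >= warmup) {
      int row = sweep - warmup;
      for (int s = 0; s < 4; s++) draws(row, s) = st.mupop[s];
      draws(row, 4) = st.sigC;
      draws(row, 5) = st.sigK;
      draws(row, 6) = st.bsoch;
      draws(row, 7) = st.bsadu;
      draws(row, 8) = st.adev;
      draws(row, 9) = st.sigdev;
      draws(row, 10) = st.bdev;
      draws(row, 11) = st.phi;
      if (!naive) {
        for (int ij = 0; ij < 16; ij++) draws(row, 12 + ij) = st.mu[ij];
        for (int ij = 0; ij < 16; ij++) draws(row, 28 + ij) = st.al[ij];
        draws(row, 44) = st.tau;
        if (store_v)
          for (int q = 0; q < st.R * 4; q++) draws(row, 45 + q) = st.vlat[q];
      }
    }
  }

  return List::create(_["draws"] = draws);
}
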