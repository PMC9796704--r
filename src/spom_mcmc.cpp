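// Metropolis-within-Gibbs sampler for dynamic-connectivity stochastic
// patch occupancy models with imperfect detection.
//
// Latent occupancy states z[i][t] are updated by single-site Gibbs from
// their full conditionals; under demographic weighting a flip of z[i][t]
// changes the colonization pressure on every other patch in year t+1, so
// the full conditional carries a cross-patch product term handled here by
// O(n) delta updates of cached connectivity sums. Continuous parameters
// use adaptive random-walk Metropolis on transformed scales; model
// indicators (I_z, I_D) are sampled by Gibbs variable selection with
// Normal pseudo-priors for the deactivated random-effect block.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double safe_log(double x) {
  return std::log(x > 1e-300 ? x : 1e-300);
}

// log(1 - exp(-s)) for s >= 0, floored for s == 0
static inline double log_gamma_of(double s) {
  if (s <= 0.0) return -690.0; // log(1e-300)
  if (s < 1e-8) return std::log(s) - 0.5 * s;
  return std::log(-std::expm1(-s));
}

static inline double dnorm_log(double x, double m, double s) {
  double r = (x - m) / s;
  return -0.918938533204672742 - std::log(s) - 0.5 * r * r;
}

struct SpomState {
  int n, T;
  bool weighted, time_varying, gvs;

  // data
  std::vector<int> ysum, J, forced; // n*T, col-major [i + n*t]
  std::vector<double> A;
  const NumericMatrix *D;

  // parameters
  double psi1, delta0, delta1, la, lb;       // la = log alpha, lb = log beta
  std::vector<double> eps_a, eps_b;          // log-scale deviates, length T-1
  double lsa, lsb;                           // log sigma_alpha, log sigma_beta
  double mu_p, lsp;                          // detection hyper-parameters
  std::vector<double> lp;                    // logit p_t, length T
  int Iz, ID;

  // derived caches
  std::vector<double> alpha_t, beta_t;       // length T-1 (transition into t+1)
  std::vector<double> eps_i;                 // extinction prob per patch
  std::vector<double> p_t;                   // detection prob per year
  std::vector<std::vector<double> > K;       // T-1 kernel matrices n*n
  std::vector<double> Bw, Bu;                // n*(T-1) connectivity sums
  std::vector<int> z;                        // n*T

  bool idEff() const { return time_varying && (!gvs || ID == 1); }
  bool izEff() const { return gvs ? (Iz == 1) : weighted; }
  bool trackW() const { return weighted || gvs; }

  void refreshDispersal() {
    double a0 = std::exp(la), b0 = std::exp(lb);
    bool tv = idEff();
    for (int t = 0; t < T - 1; ++t) {
      alpha_t[t] = tv ? std::exp(la + eps_a[t]) : a0;
      beta_t[t]  = tv ? std::exp(lb + eps_b[t]) : b0;
    }
  }

  void refreshEps() {
    for (int i = 0; i < n; ++i)
      eps_i[i] = 1.0 / (1.0 + std::exp(-(delta0 + delta1 * A[i])));
  }

  void refreshP() {
    for (int t = 0; t < T; ++t)
      p_t[t] = 1.0 / (1.0 + std::exp(-lp[t]));
  }

  void kernelYear(int t, std::vector<double> &Kt) const {
    const NumericMatrix &d = *D;
    double a = alpha_t[t];
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i)
        Kt[i + (size_t)n * j] = (i == j) ? 0.0 : std::exp(-a * d(i, j));
  }

  void refreshK() {
    bool shared = true;
    for (int t = 1; t < T - 1; ++t)
      if (alpha_t[t] != alpha_t[0]) { shared = false; break; }
    kernelYear(0, K[0]);
    for (int t = 1; t < T - 1; ++t) {
      if (shared) K[t] = K[0];
      else kernelYear(t, K[t]);
    }
  }

  void refreshB() {
    for (int t = 0; t < T - 1; ++t) {
      const std::vector<double> &Kt = K[t];
      for (int i = 0; i < n; ++i) {
        double sw = 0.0, su = 0.0;
        for (int j = 0; j < n; ++j) {
          double w = A[j] * Kt[i + (size_t)n * j];
          su += w;
          if (z[j + (size_t)n * t]) sw += w;
        }
        Bu[i + (size_t)n * t] = su;
        Bw[i + (size_t)n * t] = sw;
      }
    }
  }

  void refreshAll() {
    refreshDispersal();
    refreshEps();
    refreshP();
    refreshK();
    refreshB();
  }

  // colonization part of the transition log-likelihood (cells with
  // z[i][t] == 0 transitioning into year t+1)
  double llCol(const std::vector<double> &B,
               const std::vector<double> &bt) const {
    double ll = 0.0;
    for (int t = 0; t < T - 1; ++t) {
      double b = bt[t];
      for (int i = 0; i < n; ++i) {
        if (z[i + (size_t)n * t]) continue;
        double s = b * B[i + (size_t)n * t];
        ll += z[i + (size_t)n * (t + 1)] ? log_gamma_of(s) : -s;
      }
    }
    return ll;
  }

  double llColYear(int t, const std::vector<double> &B, double b) const {
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      if (z[i + (size_t)n * t]) continue;
      double s = b * B[i + (size_t)n * t];
      ll += z[i + (size_t)n * (t + 1)] ? log_gamma_of(s) : -s;
    }
    return ll;
  }

  // persistence/extinction part (cells with z[i][t] == 1)
  double llExt(const std::vector<double> &ei) const {
    double ll = 0.0;
    for (int t = 0; t < T - 1; ++t)
      for (int i = 0; i < n; ++i) {
        if (!z[i + (size_t)n * t]) continue;
        ll += z[i + (size_t)n * (t + 1)] ? safe_log(1.0 - ei[i])
                                         : safe_log(ei[i]);
      }
    return ll;
  }

  double llDet() const {
    double ll = 0.0;
    for (int t = 0; t < T; ++t) {
      double logp = safe_log(p_t[t]), logq = safe_log(1.0 - p_t[t]);
      for (int i = 0; i < n; ++i) {
        size_t c = i + (size_t)n * t;
        if (J[c] > 0 && z[c])
          ll += ysum[c] * logp + (J[c] - ysum[c]) * logq;
      }
    }
    return ll;
  }

  double llDetYear(int t, double p) const {
    double ll = 0.0, logp = safe_log(p), logq = safe_log(1.0 - p);
    for (int i = 0; i < n; ++i) {
      size_t c = i + (size_t)n * t;
      if (J[c] > 0 && z[c])
        ll += ysum[c] * logp + (J[c] - ysum[c]) * logq;
    }
    return ll;
  }

  double llPsi1() const {
    double ll = 0.0;
    for (int i = 0; i < n; ++i)
      ll += z[i] ? safe_log(psi1) : safe_log(1.0 - psi1);
    return ll;
  }

  // one full sequential Gibbs sweep over the latent states
  void sweepZ() {
    const std::vector<double> &B = izEff() ? Bw : Bu;
    bool cross = izEff();
    for (int t = 0; t < T; ++t) {
      for (int i = 0; i < n; ++i) {
        size_t c = i + (size_t)n * t;
        if (forced[c]) continue; // detection forces occupancy
        double lr = 0.0;
        // detection: z=1 must explain J all-zero visits; z=0 contributes 0
        if (J[c] > 0)
          lr += J[c] * safe_log(1.0 - p_t[t]);
        // backward (prior) term
        if (t == 0) {
          lr += safe_log(psi1) - safe_log(1.0 - psi1);
        } else if (z[i + (size_t)n * (t - 1)]) {
          lr += safe_log(1.0 - eps_i[i]) - safe_log(eps_i[i]);
        } else {
          double s = beta_t[t - 1] * B[i + (size_t)n * (t - 1)];
          lr += log_gamma_of(s) + s; // log gamma - log(1-gamma)
        }
        if (t < T - 1) {
          // own forward term: self excluded from connectivity, so the
          // colonization branch is identical under both states of z[i][t]
          int znext = z[i + (size_t)n * (t + 1)];
          double sOwn = beta_t[t] * B[i + (size_t)n * t];
          double l1 = znext ? safe_log(1.0 - eps_i[i]) : safe_log(eps_i[i]);
          double l0 = znext ? log_gamma_of(sOwn) : -sOwn;
          lr += l1 - l0;
          // cross-patch coupling under demographic weighting: flipping
          // z[i][t] shifts the colonization pressure on every empty patch
          if (cross) {
            const std::vector<double> &Kt = K[t];
            double b = beta_t[t];
            int zcur = z[c];
            for (int k = 0; k < n; ++k) {
              if (k == i || z[k + (size_t)n * t]) continue;
              double dlt = A[i] * Kt[k + (size_t)n * i];
              if (dlt == 0.0) continue;
              double base = Bw[k + (size_t)n * t] - (zcur ? dlt : 0.0);
              if (z[k + (size_t)n * (t + 1)])
                lr += log_gamma_of(b * (base + dlt)) -
                      log_gamma_of(b * base);
              else
                lr += -b * dlt;
            }
          }
        }
        double p1 = 1.0 / (1.0 + std::exp(-lr));
        int znew = (unif_rand() < p1) ? 1 : 0;
        if (znew != z[c]) {
          z[c] = znew;
          if (trackW() && t < T - 1) {
            const std::vector<double> &Kt = K[t];
            double sgn = znew ? 1.0 : -1.0;
            for (int k = 0; k < n; ++k)
              if (k != i)
                Bw[k + (size_t)n * t] += sgn * A[i] * Kt[k + (size_t)n * i];
          }
        }
      }
    }
  }
};

// adaptive random-walk proposal bookkeeping
struct Tuner {
  double sd;
  int tries, acc;
  Tuner(double s = 0.2) : sd(s), tries(0), acc(0) {}
  void update() {
    if (tries >= 50) {
      double rate = (double)acc / tries;
      sd *= std::exp(rate - 0.44);
      if (sd < 1e-3) sd = 1e-3;
      if (sd > 10.0) sd = 10.0;
      tries = 0; acc = 0;
    }
  }
};

// [[Rcpp::export(name = ".spom_mcmc_cpp")]]
List spom_mcmc_cpp(IntegerMatrix ysum_, IntegerMatrix J_, NumericMatrix D_,
                   NumericVector A_, bool weighted, bool time_varying,
                   bool gvs, List init, List prior, List pseudo, List tune,
                   int n_iter, int n_burnin, int thin, bool sample_params,
                   bool save_z) {
  RNGScope scope;
  SpomState st;
  st.n = ysum_.nrow();
  st.T = ysum_.ncol();
  st.weighted = weighted;
  st.time_varying = time_varying;
  st.gvs = gvs;
  const int n = st.n, T = st.T;
  st.D = &D_;
  st.A.assign(A_.begin(), A_.end());
  st.ysum.resize((size_t)n * T);
  st.J.resize((size_t)n * T);
  st.forced.resize((size_t)n * T);
  for (int t = 0; t < T; ++t)
    for (int i = 0; i < n; ++i) {
      size_t c = i + (size_t)n * t;
      st.ysum[c] = ysum_(i, t);
      st.J[c] = J_(i, t);
      st.forced[c] = ysum_(i, t) > 0 ? 1 : 0;
    }

  // initial values
  st.psi1 = as<double>(init["psi1"]);
  st.delta0 = as<double>(init["delta0"]);
  st.delta1 = as<double>(init["delta1"]);
  st.la = std::log(as<double>(init["alpha"]));
  st.lb = std::log(as<double>(init["beta"]));
  NumericVector ea = init["eps_a"], eb = init["eps_b"], lp0 = init["lp"];
  st.eps_a.assign(ea.begin(), ea.end());
  st.eps_b.assign(eb.begin(), eb.end());
  st.lp.assign(lp0.begin(), lp0.end());
  st.lsa = std::log(as<double>(init["sigma_a"]));
  st.lsb = std::log(as<double>(init["sigma_b"]));
  st.mu_p = as<double>(init["mu_p"]);
  st.lsp = std::log(as<double>(init["sigma_p"]));
  st.Iz = as<int>(init["Iz"]);
  st.ID = as<int>(init["ID"]);

  st.z.assign((size_t)n * T, 0);
  IntegerMatrix z0 = init["z"];
  for (int t = 0; t < T; ++t)
    for (int i = 0; i < n; ++i)
      st.z[i + (size_t)n * t] = st.forced[i + (size_t)n * t] ? 1 : z0(i, t);

  st.alpha_t.resize(T - 1);
  st.beta_t.resize(T - 1);
  st.eps_i.resize(n);
  st.p_t.resize(T);
  st.K.assign(T - 1, std::vector<double>((size_t)n * n));
  st.Bw.resize((size_t)n * (T - 1));
  st.Bu.resize((size_t)n * (T - 1));
  st.refreshAll();

  // priors
  const double delta_sd = as<double>(prior["delta_sd"]);
  const double alpha_max = as<double>(prior["alpha_max"]);
  const double beta_max = as<double>(prior["beta_max"]);
  const double sigma_max = as<double>(prior["sigma_max"]);
  const double mup_sd = as<double>(prior["mup_sd"]);

  // pseudo-priors for the GVS-deactivated block (Normal on sampling scale)
  std::vector<double> ps_ea_m, ps_ea_s, ps_eb_m, ps_eb_s;
  double ps_lsa_m = 0, ps_lsa_s = 1, ps_lsb_m = 0, ps_lsb_s = 1;
  if (gvs) {
    NumericVector m1 = pseudo["ea_mean"], s1 = pseudo["ea_sd"];
    NumericVector m2 = pseudo["eb_mean"], s2 = pseudo["eb_sd"];
    ps_ea_m.assign(m1.begin(), m1.end());
    ps_ea_s.assign(s1.begin(), s1.end());
    ps_eb_m.assign(m2.begin(), m2.end());
    ps_eb_s.assign(s2.begin(), s2.end());
    ps_lsa_m = as<double>(pseudo["lsa_mean"]);
    ps_lsa_s = as<double>(pseudo["lsa_sd"]);
    ps_lsb_m = as<double>(pseudo["lsb_mean"]);
    ps_lsb_s = as<double>(pseudo["lsb_sd"]);
  }

  Tuner tDelta0(as<double>(tune["delta"])), tDelta1(as<double>(tune["delta"]));
  Tuner tAlpha(as<double>(tune["alpha"])), tBeta(as<double>(tune["beta"]));
  Tuner tSigA(as<double>(tune["sigma"])), tSigB(as<double>(tune["sigma"]));
  Tuner tSigP(as<double>(tune["sigma"]));
  std::vector<Tuner> tEa(T - 1, Tuner(as<double>(tune["eps"])));
  std::vector<Tuner> tEb(T - 1, Tuner(as<double>(tune["eps"])));
  std::vector<Tuner> tLp(T, Tuner(as<double>(tune["lp"])));

  const bool tvBlock = time_varying || gvs;
  int n_keep = (n_iter - n_burnin) / thin;
  int n_par = 5 + 2 + T +                     // psi1..beta, mu_p/sigma_p, p_t
              (tvBlock ? (2 + 2 * (T - 1)) : 0) +
              (gvs ? 2 : 0) + 1;              // indicators + loglik
  NumericMatrix out(n_keep, n_par);
  IntegerVector zout(save_z ? (R_xlen_t)n_keep * n * T : 0);

  // cached likelihood pieces for Metropolis ratios
  double llColCur = st.llCol(st.izEff() ? st.Bw : st.Bu, st.beta_t);
  double llExtCur = st.llExt(st.eps_i);

  std::vector<double> alpha_p(T - 1), beta_p(T - 1);
  std::vector<std::vector<double> > Kp(T - 1,
      std::vector<double>((size_t)n * n));
  std::vector<double> Bwp((size_t)n * (T - 1)), Bup((size_t)n * (T - 1));

  int keep = 0;
  for (int iter = 0; iter < n_iter; ++iter) {
    // --- latent states ---
    st.sweepZ();
    llColCur = st.llCol(st.izEff() ? st.Bw : st.Bu, st.beta_t);
    llExtCur = st.llExt(st.eps_i);

    if (sample_params) {
      bool adapting = iter < n_burnin;

      // psi1: conjugate Beta under the Uniform(0,1) prior
      int s1 = 0;
      for (int i = 0; i < n; ++i) s1 += st.z[i];
      st.psi1 = R::rbeta(1.0 + s1, 1.0 + n - s1);

      // extinction regression delta0, delta1
      for (int which = 0; which < 2; ++which) {
        Tuner &tn = which ? tDelta1 : tDelta0;
        double cur = which ? st.delta1 : st.delta0;
        double propv = cur + tn.sd * norm_rand();
        double d0 = which ? st.delta0 : propv;
        double d1 = which ? propv : st.delta1;
        std::vector<double> ep(n);
        for (int i = 0; i < n; ++i)
          ep[i] = 1.0 / (1.0 + std::exp(-(d0 + d1 * st.A[i])));
        double llp = st.llExt(ep);
        double lr = llp - llExtCur +
          dnorm_log(propv, 0.0, delta_sd) - dnorm_log(cur, 0.0, delta_sd);
        ++tn.tries;
        if (std::log(unif_rand()) < lr) {
          if (which) st.delta1 = propv; else st.delta0 = propv;
          st.eps_i = ep;
          llExtCur = llp;
          ++tn.acc;
        }
        if (adapting) tn.update();
      }

      // base dispersal scale alpha (log scale; Uniform(0, alpha_max) prior)
      {
        double lap = st.la + tAlpha.sd * norm_rand();
        ++tAlpha.tries;
        if (std::exp(lap) < alpha_max) {
          bool tv = st.idEff();
          bool ok = true;
          for (int t = 0; t < T - 1; ++t) {
            alpha_p[t] = tv ? std::exp(lap + st.eps_a[t]) : std::exp(lap);
            if (!std::isfinite(alpha_p[t])) ok = false;
          }
          if (ok) {
            std::swap(st.alpha_t, alpha_p);
            st.refreshK(); // into st.K using proposed alpha_t
            // proposed B
            std::swap(st.Bw, Bwp); std::swap(st.Bu, Bup);
            st.refreshB();
            double llp = st.llCol(st.izEff() ? st.Bw : st.Bu, st.beta_t);
            double lr = llp - llColCur + (lap - st.la); // log-scale Jacobian
            if (std::log(unif_rand()) < lr) {
              st.la = lap;
              llColCur = llp;
              ++tAlpha.acc;
            } else { // roll back
              std::swap(st.alpha_t, alpha_p);
              std::swap(st.Bw, Bwp); std::swap(st.Bu, Bup);
              st.refreshK();
            }
          }
        }
        if (adapting) tAlpha.update();
      }

      // base dispersal rate beta (log scale; Uniform(0, beta_max) prior)
      {
        double lbp = st.lb + tBeta.sd * norm_rand();
        ++tBeta.tries;
        if (std::exp(lbp) < beta_max) {
          bool tv = st.idEff();
          for (int t = 0; t < T - 1; ++t)
            beta_p[t] = tv ? std::exp(lbp + st.eps_b[t]) : std::exp(lbp);
          double llp = st.llCol(st.izEff() ? st.Bw : st.Bu, beta_p);
          double lr = llp - llColCur + (lbp - st.lb);
          if (std::log(unif_rand()) < lr) {
            st.lb = lbp;
            std::swap(st.beta_t, beta_p);
            llColCur = llp;
            ++tBeta.acc;
          }
        }
        if (adapting) tBeta.update();
      }

      // year-specific dispersal deviates
      if (tvBlock) {
        double sa = std::exp(st.lsa), sb = std::exp(st.lsb);
        if (st.idEff()) {
          const std::vector<double> &Bact = st.izEff() ? st.Bw : st.Bu;
          for (int t = 0; t < T - 1; ++t) {
            // eps_alpha[t]: kernel scale deviate for transitions into t+1
            double cur = st.eps_a[t];
            double prop = cur + tEa[t].sd * norm_rand();
            ++tEa[t].tries;
            double at_p = std::exp(st.la + prop);
            if (std::isfinite(at_p)) {
              double ll0 = st.llColYear(t, Bact, st.beta_t[t]);
              double keepA = st.alpha_t[t];
              st.alpha_t[t] = at_p;
              st.kernelYear(t, Kp[0]);
              std::swap(st.K[t], Kp[0]);
              // recompute year-t columns of both B caches
              for (int i = 0; i < n; ++i) {
                double sw = 0.0, su = 0.0;
                const std::vector<double> &Kt = st.K[t];
                for (int j = 0; j < n; ++j) {
                  double w = st.A[j] * Kt[i + (size_t)n * j];
                  su += w;
                  if (st.z[j + (size_t)n * t]) sw += w;
                }
                Bup[i] = st.Bu[i + (size_t)n * t];
                Bwp[i] = st.Bw[i + (size_t)n * t];
                st.Bu[i + (size_t)n * t] = su;
                st.Bw[i + (size_t)n * t] = sw;
              }
              double ll1 = st.llColYear(t, Bact, st.beta_t[t]);
              double lr = ll1 - ll0 +
                dnorm_log(prop, 0.0, sa) - dnorm_log(cur, 0.0, sa);
              if (std::log(unif_rand()) < lr) {
                st.eps_a[t] = prop;
                llColCur += ll1 - ll0;
                ++tEa[t].acc;
              } else {
                st.alpha_t[t] = keepA;
                std::swap(st.K[t], Kp[0]);
                for (int i = 0; i < n; ++i) {
                  st.Bu[i + (size_t)n * t] = Bup[i];
                  st.Bw[i + (size_t)n * t] = Bwp[i];
                }
              }
            }
            if (adapting) tEa[t].update();

            // eps_beta[t]: dispersal-rate deviate
            cur = st.eps_b[t];
            prop = cur + tEb[t].sd * norm_rand();
            ++tEb[t].tries;
            double bt_p = std::exp(st.lb + prop);
            if (std::isfinite(bt_p)) {
              double ll0 = st.llColYear(t, Bact, st.beta_t[t]);
              double ll1 = st.llColYear(t, Bact, bt_p);
              double lr = ll1 - ll0 +
                dnorm_log(prop, 0.0, sb) - dnorm_log(cur, 0.0, sb);
              if (std::log(unif_rand()) < lr) {
                st.eps_b[t] = prop;
                st.beta_t[t] = bt_p;
                llColCur += ll1 - ll0;
                ++tEb[t].acc;
              }
            }
            if (adapting) tEb[t].update();
          }

          // random-effect SDs (log scale; Uniform(0, sigma_max) priors)
          for (int which = 0; which < 2; ++which) {
            Tuner &tn = which ? tSigB : tSigA;
            double cur = which ? st.lsb : st.lsa;
            const std::vector<double> &e = which ? st.eps_b : st.eps_a;
            double prop = cur + tn.sd * norm_rand();
            ++tn.tries;
            if (std::exp(prop) < sigma_max) {
              double lr = prop - cur; // Jacobian of log transform
              double s0 = std::exp(cur), s1v = std::exp(prop);
              for (int t = 0; t < T - 1; ++t)
                lr += dnorm_log(e[t], 0.0, s1v) - dnorm_log(e[t], 0.0, s0);
              if (std::log(unif_rand()) < lr) {
                if (which) st.lsb = prop; else st.lsa = prop;
                ++tn.acc;
              }
            }
            if (adapting) tn.update();
          }
        } else {
          // GVS with I_D = 0: the deactivated block does not enter the
          // likelihood and is refreshed from its pseudo-prior
          for (int t = 0; t < T - 1; ++t) {
            st.eps_a[t] = ps_ea_m[t] + ps_ea_s[t] * norm_rand();
            st.eps_b[t] = ps_eb_m[t] + ps_eb_s[t] * norm_rand();
          }
          st.lsa = ps_lsa_m + ps_lsa_s * norm_rand();
          st.lsb = ps_lsb_m + ps_lsb_s * norm_rand();
        }
      }

      // detection: year effects, hyper-mean (conjugate), hyper-SD
      {
        double sp = std::exp(st.lsp);
        for (int t = 0; t < T; ++t) {
          double cur = st.lp[t];
          double prop = cur + tLp[t].sd * norm_rand();
          ++tLp[t].tries;
          double pprop = 1.0 / (1.0 + std::exp(-prop));
          double ll0 = st.llDetYear(t, st.p_t[t]);
          double ll1 = st.llDetYear(t, pprop);
          double lr = ll1 - ll0 +
            dnorm_log(prop, st.mu_p, sp) - dnorm_log(cur, st.mu_p, sp);
          if (std::log(unif_rand()) < lr) {
            st.lp[t] = prop;
            st.p_t[t] = pprop;
            ++tLp[t].acc;
          }
          if (adapting) tLp[t].update();
        }
        double prec = T / (sp * sp) + 1.0 / (mup_sd * mup_sd);
        double mean = 0.0;
        for (int t = 0; t < T; ++t) mean += st.lp[t];
        mean = (mean / (sp * sp)) / prec;
        st.mu_p = mean + norm_rand() / std::sqrt(prec);

        double prop = st.lsp + tSigP.sd * norm_rand();
        ++tSigP.tries;
        if (std::exp(prop) < sigma_max) {
          double lr = prop - st.lsp;
          double s0 = sp, s1v = std::exp(prop);
          for (int t = 0; t < T; ++t)
            lr += dnorm_log(st.lp[t], st.mu_p, s1v) -
                  dnorm_log(st.lp[t], st.mu_p, s0);
          if (std::log(unif_rand()) < lr) {
            st.lsp = prop;
            ++tSigP.acc;
          }
        }
        if (adapting) tSigP.update();
      }

      // --- Gibbs variable selection over (I_z, I_D) ---
      if (gvs) {
        // I_z: occupancy weighting on/off (Bernoulli(0.5) prior)
        {
          double llw = st.llCol(st.Bw, st.beta_t);
          double llu = st.llCol(st.Bu, st.beta_t);
          double p1 = 1.0 / (1.0 + std::exp(-(llw - llu)));
          st.Iz = (unif_rand() < p1) ? 1 : 0;
          llColCur = st.Iz ? llw : llu;
        }
        // I_D: time-varying dispersal on/off with pseudo-priors for the
        // deactivated deviates and their SDs
        {
          double sa = std::exp(st.lsa), sb = std::exp(st.lsb);
          // structure under I_D = 1
          for (int t = 0; t < T - 1; ++t) {
            alpha_p[t] = std::exp(st.la + st.eps_a[t]);
            beta_p[t] = std::exp(st.lb + st.eps_b[t]);
          }
          double ll1, ll0;
          if (st.ID == 1) {
            ll1 = llColCur;
            // evaluate static structure in temporaries
            std::vector<double> aTmp(T - 1, std::exp(st.la));
            std::vector<double> bTmp(T - 1, std::exp(st.lb));
            std::swap(st.alpha_t, aTmp);
            st.refreshK();
            std::swap(st.Bw, Bwp); std::swap(st.Bu, Bup);
            st.refreshB();
            ll0 = st.llCol(st.izEff() ? st.Bw : st.Bu, bTmp);
            // restore the time-varying structure for now
            std::swap(st.alpha_t, aTmp);
            std::swap(st.Bw, Bwp); std::swap(st.Bu, Bup);
            st.refreshK();
          } else {
            ll0 = llColCur;
            std::swap(st.alpha_t, alpha_p);
            st.refreshK();
            std::swap(st.Bw, Bwp); std::swap(st.Bu, Bup);
            st.refreshB();
            ll1 = st.llCol(st.izEff() ? st.Bw : st.Bu, beta_p);
            std::swap(st.alpha_t, alpha_p);
            std::swap(st.Bw, Bwp); std::swap(st.Bu, Bup);
            st.refreshK();
          }
          // prior vs pseudo-prior mass of the random-effect block
          double lpr = 0.0;
          for (int t = 0; t < T - 1; ++t) {
            lpr += dnorm_log(st.eps_a[t], 0.0, sa) -
                   dnorm_log(st.eps_a[t], ps_ea_m[t], ps_ea_s[t]);
            lpr += dnorm_log(st.eps_b[t], 0.0, sb) -
                   dnorm_log(st.eps_b[t], ps_eb_m[t], ps_eb_s[t]);
          }
          // SDs: Uniform(0, sigma_max) prior on sigma => density
          // exp(ls)/sigma_max on the log scale; pseudo-prior Normal(ls)
          lpr += (st.lsa - std::log(sigma_max)) -
                 dnorm_log(st.lsa, ps_lsa_m, ps_lsa_s);
          lpr += (st.lsb - std::log(sigma_max)) -
                 dnorm_log(st.lsb, ps_lsb_m, ps_lsb_s);
          double p1 = 1.0 / (1.0 + std::exp(-((ll1 + lpr) - ll0)));
          int newID = (unif_rand() < p1) ? 1 : 0;
          if (newID != st.ID) {
            st.ID = newID;
            st.refreshDispersal();
            st.refreshK();
            st.refreshB();
            llColCur = st.llCol(st.izEff() ? st.Bw : st.Bu, st.beta_t);
          }
        }
      }
    }

    // --- record ---
    if (iter >= n_burnin && (iter - n_burnin) % thin == 0) {
      int c = 0;
      out(keep, c++) = st.psi1;
      out(keep, c++) = st.delta0;
      out(keep, c++) = st.delta1;
      out(keep, c++) = std::exp(st.la);
      out(keep, c++) = std::exp(st.lb);
      if (tvBlock) {
        out(keep, c++) = std::exp(st.lsa);
        out(keep, c++) = std::exp(st.lsb);
        for (int t = 0; t < T - 1; ++t) out(keep, c++) = st.alpha_t[t];
        for (int t = 0; t < T - 1; ++t) out(keep, c++) = st.beta_t[t];
      }
      out(keep, c++) = st.mu_p;
      out(keep, c++) = std::exp(st.lsp);
      for (int t = 0; t < T; ++t) out(keep, c++) = st.p_t[t];
      if (gvs) {
        out(keep, c++) = st.Iz;
        out(keep, c++) = st.ID;
      }
      out(keep, c++) = st.llDet() + llExtCur + llColCur + st.llPsi1();
      if (save_z) {
        R_xlen_t off = (R_xlen_t)keep * n * T;
        for (size_t q = 0; q < (size_t)n * T; ++q)
          zout[off + (R_xlen_t)q] = st.z[q];
      }
      ++keep;
    }
  }

  NumericVector acc = NumericVector::create(
    _["delta0"] = tDelta0.tries ? (double)tDelta0.acc / tDelta0.tries : NA_REAL,
    _["delta1"] = tDelta1.tries ? (double)tDelta1.acc / tDelta1.tries : NA_REAL,
    _["alpha"] = tAlpha.tries ? (double)tAlpha.acc / tAlpha.tries : NA_REAL,
    _["beta"] = tBeta.tries ? (double)tBeta.acc / tBeta.tries : NA_REAL);

  return List::create(_["draws"] = out, _["z"] = zout, _["accept"] = acc,
                      _["n_keep"] = keep);
}
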