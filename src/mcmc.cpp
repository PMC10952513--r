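// Adaptive component-wise random-walk Metropolis samplers for the two
// posteriors the design refits at every cohort: the reparameterized logistic
// dose-toxicity model and the EXNEX/MAC stagewise dose-efficacy hierarchy.
// Sampling is done on unconstrained scales (logits / logs) with Jacobian
// corrections; draws are returned on the natural scale. All randomness goes
// through R's RNG so set.seed() on the R side makes runs reproducible.
#include <Rcpp.h>
using namespace Rcpp;

static inline double logit(double p) { return std::log(p / (1.0 - p)); }
static inline double inv_logit(double u) {
  if (u >= 0) { double e = std::exp(-u); return 1.0 / (1.0 + e); }
  double e = std::exp(u); return e / (1.0 + e);
}
// log(sigmoid(u)), numerically stable
static inline double log_inv_logit(double u) {
  return (u >= 0) ? -std::log1p(std::exp(-u)) : u - std::log1p(std::exp(u));
}

// Bernoulli log-likelihood of a logistic-linear predictor eta given outcome w
static inline double bern_ll(int w, double eta) {
  return w ? log_inv_logit(eta) : log_inv_logit(-eta);
}

// ---------------------------------------------------------------------------
// Toxicity model.
// Unconstrained state v = (logit r, logit rho01, logit rho10, log alpha3),
// r = rho00 / min(rho01, rho10). Priors: r ~ Beta(ar, br),
// rho01 ~ Beta(a01, b01), rho10 ~ Beta(a10, b10), alpha3 ~ Gamma(sh, rate).
struct ToxData {
  const IntegerVector &z; const NumericVector &x, &y;
  NumericVector prior; // a01 b01 a10 b10 ar br sh rate
};

static double tox_logpost(const double *v, const ToxData &d) {
  double r   = inv_logit(v[0]);
  double p01 = inv_logit(v[1]);
  double p10 = inv_logit(v[2]);
  double a3  = std::exp(v[3]);
  double p00 = r * std::min(p01, p10);
  if (p00 <= 0 || p00 >= 1) return R_NegInf;
  double lp = 0.0;
  lp += R::dbeta(r,   d.prior[4], d.prior[5], 1) + std::log(r * (1 - r));
  lp += R::dbeta(p01, d.prior[0], d.prior[1], 1) + std::log(p01 * (1 - p01));
  lp += R::dbeta(p10, d.prior[2], d.prior[3], 1) + std::log(p10 * (1 - p10));
  lp += R::dgamma(a3, d.prior[6], 1.0 / d.prior[7], 1) + v[3];
  if (!R_finite(lp)) return R_NegInf;
  double a0 = logit(p00);
  double a1 = logit(p10) - a0;
  double a2 = logit(p01) - a0;
  int n = d.z.size();
  for (int i = 0; i < n; ++i) {
    double eta = a0 + a1 * d.x[i] + a2 * d.y[i] + a3 * d.x[i] * d.y[i];
    lp += bern_ll(d.z[i], eta);
  }
  return lp;
}

// lower-triangular Cholesky; returns false if not positive definite
static bool cholesky(const std::vector<double> &A, std::vector<double> &L,
                     int d) {
  L.assign(d * d, 0.0);
  for (int i = 0; i < d; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * d + j];
      for (int k = 0; k < j; ++k) s -= L[i * d + k] * L[j * d + k];
      if (i == j) {
        if (s <= 0) return false;
        L[i * d + i] = std::sqrt(s);
      } else L[i * d + j] = s / L[j * d + j];
    }
  }
  return true;
}

// Generic adaptive Metropolis chain: each iteration does one component-wise
// sweep (per-component step sizes tuned to 0.44 acceptance during warmup)
// followed by one joint random-walk update whose proposal covariance is the
// running empirical covariance of the warmup history (Haario-style), with a
// scalar factor tuned to 0.25 acceptance. All adaptation stops at the end of
// warmup, so kept draws target the exact posterior. logpost must return -Inf
// outside the support.
template <typename LP>
static void run_chain(LP logpost, std::vector<double> &v, int dim,
                      int warmup, int iter, NumericMatrix &out, int row0,
                      std::vector<double> &step) {
  double lp = logpost(v.data());
  std::vector<int> acc(dim, 0);
  int adapt_win = 25, win_count = 0;
  // running moments for the joint proposal covariance
  std::vector<double> mean(v.begin(), v.end());
  std::vector<double> cov(dim * dim, 0.0), chol_l(dim * dim, 0.0);
  bool have_chol = false;
  long nmom = 0;
  double log_s = std::log(2.38 / std::sqrt((double)dim));
  int joint_acc = 0, joint_tot = 0;
  std::vector<double> prop(dim), z(dim);
  for (int it = 0; it < warmup + iter; ++it) {
    for (int k = 0; k < dim; ++k) {
      double old = v[k];
      v[k] = old + step[k] * R::norm_rand();
      double lp_new = logpost(v.data());
      if (std::log(R::unif_rand()) < lp_new - lp) { lp = lp_new; acc[k]++; }
      else v[k] = old;
    }
    if (have_chol) {
      double s = std::exp(log_s);
      for (int k = 0; k < dim; ++k) z[k] = R::norm_rand();
      for (int i = 0; i < dim; ++i) {
        double dz = 0.0;
        for (int k = 0; k <= i; ++k) dz += chol_l[i * dim + k] * z[k];
        prop[i] = v[i] + s * dz;
      }
      double lp_new = logpost(prop.data());
      joint_tot++;
      if (std::log(R::unif_rand()) < lp_new - lp) {
        lp = lp_new; v = prop; joint_acc++;
      }
    }
    if (it < warmup) {
      // accumulate running mean/covariance of the warmup trajectory
      nmom++;
      for (int i = 0; i < dim; ++i) {
        double di = v[i] - mean[i];
        mean[i] += di / nmom;
        for (int j = 0; j <= i; ++j)
          cov[i * dim + j] += di * (v[j] - mean[j]);
      }
      if (++win_count == adapt_win) {
        for (int k = 0; k < dim; ++k) {
          double rate = acc[k] / (double)adapt_win;
          step[k] *= std::exp(rate - 0.44);
          step[k] = std::min(std::max(step[k], 1e-4), 10.0);
          acc[k] = 0;
        }
        if (joint_tot > 0) {
          log_s += (joint_acc / (double)joint_tot - 0.25);
          joint_acc = joint_tot = 0;
        }
        // refresh the joint proposal from the running covariance once enough
        // history has accumulated
        if (nmom >= 10 * dim) {
          std::vector<double> c(dim * dim);
          for (int i = 0; i < dim; ++i)
            for (int j = 0; j <= i; ++j) {
              double cij = cov[i * dim + j] / (nmom - 1);
              c[i * dim + j] = c[j * dim + i] = cij;
            }
          for (int i = 0; i < dim; ++i) c[i * dim + i] += 1e-8;
          have_chol = cholesky(c, chol_l, dim);
        }
        win_count = 0;
      }
    }
    if (it >= warmup)
      for (int k = 0; k < dim; ++k) out(row0 + it - warmup, k) = v[k];
  }
}

// [[Rcpp::export]]
NumericMatrix mcmc_tox_cpp(IntegerVector z, NumericVector x, NumericVector y,
                           NumericVector prior, int chains, int warmup,
                           int iter) {
  ToxData d{z, x, y, prior};
  NumericMatrix out(chains * iter, 5); // rho00 rho01 rho10 alpha3 chain
  for (int c = 0; c < chains; ++c) {
    // overdispersed prior-scale starting points
    std::vector<double> v(4);
    v[0] = logit(R::rbeta(prior[4], prior[5]));
    v[1] = logit(R::rbeta(prior[0], prior[1]));
    v[2] = logit(R::rbeta(prior[2], prior[3]));
    v[3] = std::log(R::rgamma(prior[6], 1.0 / prior[7]) + 1e-3);
    std::vector<double> step(4, 0.5);
    NumericMatrix raw(iter, 4);
    auto lp = [&](const double *vv) { return tox_logpost(vv, d); };
    run_chain(lp, v, 4, warmup, iter, raw, 0, step);
    for (int i = 0; i < iter; ++i) {
      double r = inv_logit(raw(i, 0)), p01 = inv_logit(raw(i, 1)),
             p10 = inv_logit(raw(i, 2));
      int row = c * iter + i;
      out(row, 0) = r * std::min(p01, p10);
      out(row, 1) = p01;
      out(row, 2) = p10;
      out(row, 3) = std::exp(raw(i, 3));
      out(row, 4) = c + 1;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// EXNEX efficacy model.
// Unconstrained state (14): b01 b11 b21 log(b31) b02 b12 b22 log(b32)
//                           mu1 mu2 log(tau1) log(tau2) u_xi u_zeta
// xi = xi_max * inv_logit(u_xi), same for zeta. Mixture over the stage-2
// exchangeability indicator is marginalized by log-sum-exp.
struct EffData {
  const NumericVector &x1, &y1, &x2, &y2;
  const IntegerVector &e1, &e2;
  // prior: b0m b0s b3sh b3rate eta1 s1 eta2 s2 z1 z2 ximax zetamax omega
  NumericVector prior;
};

static inline double bvn_logpdf(double a, double b, double m1, double m2,
                                double s11, double s12, double s22) {
  double det = s11 * s22 - s12 * s12;
  if (det <= 0) return R_NegInf;
  double d1 = a - m1, d2 = b - m2;
  double q = (s22 * d1 * d1 - 2 * s12 * d1 * d2 + s11 * d2 * d2) / det;
  return -std::log(2 * M_PI) - 0.5 * std::log(det) - 0.5 * q;
}

static double eff_mix_terms(const double *v, const EffData &d,
                            double *log_ex, double *log_nex) {
  // returns log prior (everything except the Psi2 mixture term), and fills
  // the two branch log-densities for Psi2
  const NumericVector &pr = d.prior;
  double b31 = std::exp(v[3]), b32 = std::exp(v[7]);
  double tau1 = std::exp(v[10]) + 1e-6, tau2 = std::exp(v[11]) + 1e-6;
  double xi = pr[10] * inv_logit(v[12]);
  double zeta = pr[11] * inv_logit(v[13]);
  double lp = 0.0;
  lp += R::dnorm(v[0], pr[0], pr[1], 1);          // beta0, stage 1
  lp += R::dnorm(v[4], pr[0], pr[1], 1);          // beta0, stage 2
  lp += R::dgamma(b31, pr[2], 1.0 / pr[3], 1) + v[3];
  lp += R::dgamma(b32, pr[2], 1.0 / pr[3], 1) + v[7];
  lp += R::dnorm(v[8], pr[4], pr[5], 1);          // mu1
  lp += R::dnorm(v[9], pr[6], pr[7], 1);          // mu2
  // half-normal on tau with log Jacobian
  lp += M_LN2 + R::dnorm(tau1, 0.0, pr[8], 1) + v[10];
  lp += M_LN2 + R::dnorm(tau2, 0.0, pr[9], 1) + v[11];
  // uniform(0, max) via logit transform: Jacobian only (density constant)
  double pxi = inv_logit(v[12]), pz = inv_logit(v[13]);
  lp += std::log(pxi * (1 - pxi)) + std::log(pz * (1 - pz));
  // Psi1 ~ BVN(mu, Phi)
  double s11 = tau1 * tau1, s22 = tau2 * tau2, s12 = xi * tau1 * tau2;
  lp += bvn_logpdf(v[1], v[2], v[8], v[9], s11, s12, s22);
  *log_ex  = bvn_logpdf(v[5], v[6], v[8], v[9], s11, s12, s22);
  *log_nex = bvn_logpdf(v[5], v[6], 0.0, 0.0, 100.0, 100.0 * zeta, 100.0);
  return lp;
}

static double eff_logpost(const double *v, const EffData &d) {
  double log_ex, log_nex;
  double lp = eff_mix_terms(v, d, &log_ex, &log_nex);
  if (!R_finite(lp)) return R_NegInf;
  double omega = d.prior[12];
  if (omega >= 1.0) lp += log_ex;
  else if (omega <= 0.0) lp += log_nex;
  else {
    double la = std::log(omega) + log_ex, lb = std::log1p(-omega) + log_nex;
    double m = std::max(la, lb);
    lp += m + std::log(std::exp(la - m) + std::exp(lb - m));
  }
  double e11 = std::exp(v[1]), e21 = std::exp(v[2]), b31 = std::exp(v[3]);
  for (int i = 0; i < d.e1.size(); ++i) {
    double eta = v[0] + e11 * d.x1[i] + e21 * d.y1[i] + b31 * d.x1[i] * d.y1[i];
    lp += bern_ll(d.e1[i], eta);
  }
  double e12 = std::exp(v[5]), e22 = std::exp(v[6]), b32 = std::exp(v[7]);
  for (int i = 0; i < d.e2.size(); ++i) {
    double eta = v[4] + e12 * d.x2[i] + e22 * d.y2[i] + b32 * d.x2[i] * d.y2[i];
    lp += bern_ll(d.e2[i], eta);
  }
  return lp;
}

// [[Rcpp::export]]
NumericMatrix mcmc_eff_cpp(NumericVector x1, NumericVector y1, IntegerVector e1,
                           NumericVector x2, NumericVector y2, IntegerVector e2,
                           NumericVector prior, int chains, int warmup,
                           int iter) {
  EffData d{x1, y1, x2, y2, e1, e2, prior};
  // cols: beta01 beta11 beta21 beta31 beta02 beta12 beta22 beta32
  //       mu1 mu2 tau1 tau2 xi zeta w_exch chain
  NumericMatrix out(chains * iter, 16);
  double omega = prior[12];
  for (int c = 0; c < chains; ++c) {
    std::vector<double> v(14);
    v[0] = R::rnorm(prior[0], 1.0);
    v[4] = R::rnorm(prior[0], 1.0);
    v[1] = R::rnorm(0.0, 1.0); v[2] = R::rnorm(0.0, 1.0);
    v[5] = R::rnorm(0.0, 1.0); v[6] = R::rnorm(0.0, 1.0);
    v[3] = R::rnorm(-2.0, 1.0); v[7] = R::rnorm(-2.0, 1.0);
    v[8] = R::rnorm(0.0, 1.0); v[9] = R::rnorm(0.0, 1.0);
    v[10] = R::rnorm(-1.5, 0.5); v[11] = R::rnorm(-1.5, 0.5);
    v[12] = R::rnorm(0.0, 1.0); v[13] = R::rnorm(0.0, 1.0);
    std::vector<double> step(14, 0.4);
    NumericMatrix raw(iter, 14);
    auto lp = [&](const double *vv) { return eff_logpost(vv, d); };
    run_chain(lp, v, 14, warmup, iter, raw, 0, step);
    for (int i = 0; i < iter; ++i) {
      int row = c * iter + i;
      double vv[14];
      for (int k = 0; k < 14; ++k) vv[k] = raw(i, k);
      out(row, 0) = vv[0]; out(row, 1) = vv[1]; out(row, 2) = vv[2];
      out(row, 3) = std::exp(vv[3]);
      out(row, 4) = vv[4]; out(row, 5) = vv[5]; out(row, 6) = vv[6];
      out(row, 7) = std::exp(vv[7]);
      out(row, 8) = vv[8]; out(row, 9) = vv[9];
      out(row, 10) = std::exp(vv[10]) + 1e-6;
      out(row, 11) = std::exp(vv[11]) + 1e-6;
      out(row, 12) = prior[10] * inv_logit(vv[12]);
      out(row, 13) = prior[11] * inv_logit(vv[13]);
      // posterior responsibility of the exchangeable branch at this draw
      double w;
      if (omega >= 1.0) w = 1.0;
      else if (omega <= 0.0) w = 0.0;
      else {
        double lex, lnex;
        eff_mix_terms(vv, d, &lex, &lnex);
        double la = std::log(omega) + lex, lb = std::log1p(-omega) + lnex;
        double m = std::max(la, lb);
        w = std::exp(la - m) / (std::exp(la - m) + std::exp(lb - m));
      }
      out(row, 14) = w;
      out(row, 15) = c + 1;
    }
  }
  return out;
}
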