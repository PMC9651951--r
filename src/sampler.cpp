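// Adaptive Metropolis-within-Gibbs sampler for hierarchical time-field models.
//
// Model levels (variant "main"):
//   spikes t_j on trial i of cell c:  t ~ a1 * N(mu_ci, sw_c^2) + (1 - a1) / L
//   trial:        mu_ci ~ N(M_c, st_c^2)            (untruncated)
//   population:   M_c   ~ tau^-alpha / C  on [pmin, pmax]
// Variants swap one level at a time:
//   lognormal_field : field is LogNormal with median mu_ci (seconds), shape sh_c
//   trial_vary_width: mu_ci == M_c fixed; per-trial width swi ~ N(sW_c, st_c^2), swi > 0
//   exponential_pop : M_c ~ Exp(beta) renormalised to [pmin, pmax]
//   weibull_pop     : M_c ~ Weibull(k, lambda) renormalised to [pmin, pmax]
//
// One call runs one chain; chains are looped (and seeded) from R.

#include <Rcpp.h>
#include <random>
#include <cmath>

using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

struct Rng {
  std::mt19937_64 eng;
  std::normal_distribution<double> norm;
  std::uniform_real_distribution<double> unif;
  Rng(uint64_t seed) : eng(seed), norm(0.0, 1.0), unif(0.0, 1.0) {}
  double rnorm() { return norm(eng); }
  double runif() { return unif(eng); }
};

// log of the bounded power-law normaliser C(alpha) on [lo, hi]
static inline double bpl_log_norm(double alpha, double lo, double hi) {
  double om = 1.0 - alpha;
  double r = std::log(hi / lo);
  if (std::fabs(om) < 1e-12) return std::log(r);
  // C = lo^(1-a) * expm1((1-a) * log(hi/lo)) / (1-a), stable as alpha -> 1
  return om * std::log(lo) + std::log(std::expm1(om * r) / om);
}

static inline double bpl_logpdf(double tau, double alpha, double lo, double hi,
                                double logC) {
  if (tau < lo || tau > hi) return R_NegInf;
  return -alpha * std::log(tau) - logC;
}

// truncated exponential on [lo, hi]
static inline double texp_logpdf(double tau, double beta, double lo, double hi) {
  if (tau < lo || tau > hi) return R_NegInf;
  double lognorm = -beta * lo + std::log1p(-std::exp(-beta * (hi - lo)));
  return std::log(beta) - beta * tau - lognorm;
}

// truncated Weibull on [lo, hi]
static inline double tweib_logpdf(double tau, double k, double lam, double lo,
                                  double hi) {
  if (tau < lo || tau > hi) return R_NegInf;
  double zlo = std::pow(lo / lam, k), zhi = std::pow(hi / lam, k);
  double lognorm = -zlo + std::log1p(-std::exp(-(zhi - zlo)));
  return std::log(k / lam) + (k - 1.0) * std::log(tau / lam) -
         std::pow(tau / lam, k) - lognorm;
}

enum Variant { MAIN = 0, LOGNORMAL = 1, TRIALWIDTH = 2, EXP_POP = 3, WEIB_POP = 4 };

class HbmChain {
public:
  // data
  NumericVector spk;        // all spike times
  IntegerVector toff;       // trial offsets into spk, length ntr + 1
  IntegerVector coff;       // cell offsets into trials, length nc + 1
  double L, pmin, pmax;
  int variant, nc, ntr;

  // state
  std::vector<double> mu;   // per trial: field location (MAIN/LOGNORMAL/EXP/WEIB)
                            // or per-trial width (TRIALWIDTH)
  std::vector<double> M, sw, st, a1;  // per cell (sw = sigma_w, or sigma_W / shape)
  double alpha, beta, kshp, lam;

  // priors
  double sw_scale, st_scale, a1_s1, a1_s2, alpha_max, beta_max;
  double k_min, k_max, lam_min, lam_max;
  bool alpha_fixed; double alpha_fix_val;

  // proposal scales (s_shift drives the joint cell-translation move)
  std::vector<double> s_mu, s_M, s_sw, s_st, s_a1, s_shift;
  std::vector<int> acc_mu, acc_M, acc_sw, acc_st, acc_a1, acc_shift;
  double s_alpha, s_beta, s_k, s_lam;
  int acc_alpha, acc_beta, acc_k, acc_lam;

  Rng rng;

  HbmChain(NumericVector spk_, IntegerVector toff_, IntegerVector coff_,
           double L_, double pmin_, double pmax_, int variant_, List priors,
           uint64_t seed)
      : spk(spk_), toff(toff_), coff(coff_), L(L_), pmin(pmin_), pmax(pmax_),
        variant(variant_), rng(seed) {
    nc = coff.size() - 1;
    ntr = toff.size() - 1;
    sw_scale = priors["sw_scale"];
    st_scale = priors["st_scale"];
    a1_s1 = priors["a1_shape1"];
    a1_s2 = priors["a1_shape2"];
    alpha_max = priors["alpha_max"];
    beta_max = priors["beta_max"];
    k_min = priors["k_min"]; k_max = priors["k_max"];
    lam_min = priors["lambda_min"]; lam_max = priors["lambda_max"];
    alpha_fixed = priors["alpha_fixed"];
    alpha_fix_val = priors["alpha_fix_value"];

    mu.resize(ntr); M.resize(nc); sw.resize(nc); st.resize(nc); a1.resize(nc);
    s_mu.assign(ntr, 0.25); s_M.assign(nc, 0.2); s_sw.assign(nc, 0.3);
    s_st.assign(nc, 0.3); s_a1.assign(nc, 0.5); s_shift.assign(nc, 0.15);
    s_alpha = 0.2; s_beta = 0.2; s_k = 0.2; s_lam = 0.2;
    reset_acc();
  }

  void reset_acc() {
    acc_mu.assign(ntr, 0); acc_M.assign(nc, 0); acc_sw.assign(nc, 0);
    acc_st.assign(nc, 0); acc_a1.assign(nc, 0); acc_shift.assign(nc, 0);
    acc_alpha = acc_beta = acc_k = acc_lam = 0;
  }

  // log-likelihood of one trial's spikes given current cell/trial state
  double trial_ll(int c, int ti, double mu_ti, double width) const {
    double u = (1.0 - a1[c]) / L;
    double w = a1[c];
    double ll = 0.0;
    if (variant == LOGNORMAL) {
      double lmu = std::log(mu_ti);
      double inv2s2 = 0.5 / (width * width);
      double lognormconst = std::log(width) + 0.5 * LOG2PI;
      for (int j = toff[ti]; j < toff[ti + 1]; ++j) {
        double t = spk[j];
        double lt = std::log(t);
        double z = lt - lmu;
        double g = std::exp(-z * z * inv2s2 - lt - lognormconst);
        ll += std::log(w * g + u);
      }
    } else {
      double inv2s2 = 0.5 / (width * width);
      double normconst = std::exp(-std::log(width) - 0.5 * LOG2PI);
      for (int j = toff[ti]; j < toff[ti + 1]; ++j) {
        double z = spk[j] - mu_ti;
        double g = normconst * std::exp(-z * z * inv2s2);
        ll += std::log(w * g + u);
      }
    }
    return ll;
  }

  double cell_ll(int c) const {
    double ll = 0.0;
    for (int ti = coff[c]; ti < coff[c + 1]; ++ti) {
      double loc = (variant == TRIALWIDTH) ? M[c] : mu[ti];
      double wid = (variant == TRIALWIDTH) ? mu[ti] : sw[c];
      ll += trial_ll(c, ti, loc, wid);
    }
    return ll;
  }

  double pop_logpdf(double tau) const {
    switch (variant) {
      case EXP_POP:  return texp_logpdf(tau, beta, pmin, pmax);
      case WEIB_POP: return tweib_logpdf(tau, kshp, lam, pmin, pmax);
      default: {
        double logC = bpl_log_norm(alpha, pmin, pmax);
        return bpl_logpdf(tau, alpha, pmin, pmax, logC);
      }
    }
  }

  static inline double halfnorm_lp(double x, double scale) {
    return -0.5 * (x * x) / (scale * scale);
  }

  bool mh(double logratio) {
    if (logratio >= 0) return true;
    return std::log(rng.runif()) < logratio;
  }

  void update_trial_params() {
    for (int c = 0; c < nc; ++c) {
      for (int ti = coff[c]; ti < coff[c + 1]; ++ti) {
        double cur = mu[ti];
        double prop = cur + s_mu[ti] * rng.rnorm();
        double lr;
        if (variant == TRIALWIDTH) {
          if (prop <= 0) continue;  // per-trial width must stay positive
          lr = trial_ll(c, ti, M[c], prop) - trial_ll(c, ti, M[c], cur);
          double z1 = (prop - sw[c]) / st[c], z0 = (cur - sw[c]) / st[c];
          lr += -0.5 * (z1 * z1 - z0 * z0);
        } else {
          if (variant == LOGNORMAL && prop <= 0) continue;
          lr = trial_ll(c, ti, prop, sw[c]) - trial_ll(c, ti, cur, sw[c]);
          double z1 = (prop - M[c]) / st[c], z0 = (cur - M[c]) / st[c];
          lr += -0.5 * (z1 * z1 - z0 * z0);
        }
        if (mh(lr)) { mu[ti] = prop; acc_mu[ti]++; }
      }
    }
  }

  void update_cell_params() {
    for (int c = 0; c < nc; ++c) {
      int t0 = coff[c], t1 = coff[c + 1];
      int ntrc = t1 - t0;

      // M_c
      {
        double cur = M[c], prop = cur + s_M[c] * rng.rnorm();
        if (prop >= pmin && prop <= pmax) {
          double lr = pop_logpdf(prop) - pop_logpdf(cur);
          if (variant == TRIALWIDTH) {
            for (int ti = t0; ti < t1; ++ti)
              lr += trial_ll(c, ti, prop, mu[ti]) - trial_ll(c, ti, cur, mu[ti]);
          } else {
            for (int ti = t0; ti < t1; ++ti) {
              double z1 = (mu[ti] - prop) / st[c], z0 = (mu[ti] - cur) / st[c];
              lr += -0.5 * (z1 * z1 - z0 * z0);
            }
          }
          if (mh(lr)) { M[c] = prop; acc_M[c]++; }
        }
      }

      // joint translation of M and all mu_i: breaks the tight coupling when
      // sigma_t is small (the conditional M move then barely travels)
      if (variant != TRIALWIDTH) {
        double eps = s_shift[c] * rng.rnorm();
        double Mp = M[c] + eps;
        if (Mp >= pmin && Mp <= pmax) {
          bool ok = true;
          if (variant == LOGNORMAL) {
            for (int ti = t0; ti < t1 && ok; ++ti)
              if (mu[ti] + eps <= 0) ok = false;
          }
          if (ok) {
            double lr = pop_logpdf(Mp) - pop_logpdf(M[c]);
            for (int ti = t0; ti < t1; ++ti)
              lr += trial_ll(c, ti, mu[ti] + eps, sw[c]) -
                    trial_ll(c, ti, mu[ti], sw[c]);
            if (mh(lr)) {
              M[c] = Mp;
              for (int ti = t0; ti < t1; ++ti) mu[ti] += eps;
              acc_shift[c]++;
            }
          }
        }
      }

      // sw_c (field width; sigma_W for TRIALWIDTH; log-scale RW)
      {
        double cur = sw[c], prop = cur * std::exp(s_sw[c] * rng.rnorm());
        double lr = halfnorm_lp(prop, sw_scale) - halfnorm_lp(cur, sw_scale) +
                    std::log(prop) - std::log(cur);  // Jacobian
        if (variant == TRIALWIDTH) {
          for (int ti = t0; ti < t1; ++ti) {
            double z1 = (mu[ti] - prop) / st[c], z0 = (mu[ti] - cur) / st[c];
            lr += -0.5 * (z1 * z1 - z0 * z0);
          }
        } else {
          for (int ti = t0; ti < t1; ++ti)
            lr += trial_ll(c, ti, mu[ti], prop) - trial_ll(c, ti, mu[ti], cur);
        }
        if (mh(lr)) { sw[c] = prop; acc_sw[c]++; }
      }

      // st_c (across-trial sd; log-scale RW)
      {
        double cur = st[c], prop = cur * std::exp(s_st[c] * rng.rnorm());
        double lr = halfnorm_lp(prop, st_scale) - halfnorm_lp(cur, st_scale) +
                    std::log(prop) - std::log(cur);
        double ctr = (variant == TRIALWIDTH) ? sw[c] : M[c];
        for (int ti = t0; ti < t1; ++ti) {
          double z1 = (mu[ti] - ctr) / prop, z0 = (mu[ti] - ctr) / cur;
          lr += -0.5 * (z1 * z1 - z0 * z0);
        }
        lr += -ntrc * (std::log(prop) - std::log(cur));
        if (mh(lr)) { st[c] = prop; acc_st[c]++; }
      }

      // a1_c (logit RW)
      {
        double cur = a1[c];
        double lcur = std::log(cur / (1.0 - cur));
        double lprop = lcur + s_a1[c] * rng.rnorm();
        double prop = 1.0 / (1.0 + std::exp(-lprop));
        double save = a1[c];
        double ll0 = 0.0, ll1 = 0.0;
        for (int ti = t0; ti < t1; ++ti) {
          double loc = (variant == TRIALWIDTH) ? M[c] : mu[ti];
          double wid = (variant == TRIALWIDTH) ? mu[ti] : sw[c];
          ll0 += trial_ll(c, ti, loc, wid);
          a1[c] = prop;
          ll1 += trial_ll(c, ti, loc, wid);
          a1[c] = save;
        }
        // Beta prior + logit Jacobian
        double lr = ll1 - ll0 +
                    a1_s1 * (std::log(prop) - std::log(cur)) +
                    a1_s2 * (std::log1p(-prop) - std::log1p(-cur));
        if (mh(lr)) { a1[c] = prop; acc_a1[c]++; }
      }
    }
  }

  void update_population() {
    switch (variant) {
      case EXP_POP: {
        double cur = beta, prop = cur * std::exp(s_beta * rng.rnorm());
        if (prop < beta_max) {
          double lr = std::log(prop) - std::log(cur);  // Jacobian, flat prior
          for (int c = 0; c < nc; ++c) {
            double save = beta;
            beta = prop; lr += pop_logpdf(M[c]);
            beta = save; lr -= pop_logpdf(M[c]);
          }
          if (mh(lr)) { beta = prop; acc_beta++; }
        }
        break;
      }
      case WEIB_POP: {
        {
          double cur = kshp, prop = cur * std::exp(s_k * rng.rnorm());
          if (prop > k_min && prop < k_max) {
            double lr = std::log(prop) - std::log(cur);
            for (int c = 0; c < nc; ++c) {
              lr += tweib_logpdf(M[c], prop, lam, pmin, pmax) -
                    tweib_logpdf(M[c], cur, lam, pmin, pmax);
            }
            if (mh(lr)) { kshp = prop; acc_k++; }
          }
        }
        {
          double cur = lam, prop = cur * std::exp(s_lam * rng.rnorm());
          if (prop > lam_min && prop < lam_max) {
            double lr = std::log(prop) - std::log(cur);
            for (int c = 0; c < nc; ++c) {
              lr += tweib_logpdf(M[c], kshp, prop, pmin, pmax) -
                    tweib_logpdf(M[c], kshp, cur, pmin, pmax);
            }
            if (mh(lr)) { lam = prop; acc_lam++; }
          }
        }
        break;
      }
      default: {
        if (alpha_fixed) break;
        double cur = alpha, prop = cur + s_alpha * rng.rnorm();
        if (prop >= 0 && prop <= alpha_max) {
          double logC0 = bpl_log_norm(cur, pmin, pmax);
          double logC1 = bpl_log_norm(prop, pmin, pmax);
          double slm = 0.0;
          for (int c = 0; c < nc; ++c) slm += std::log(M[c]);
          double lr = -(prop - cur) * slm - nc * (logC1 - logC0);
          if (mh(lr)) { alpha = prop; acc_alpha++; }
        }
      }
    }
  }

  void adapt(int batch_size, int batch_no) {
    double delta = std::min(0.1, 1.0 / std::sqrt((double)batch_no));
    auto tune = [&](double &s, int acc) {
      double rate = (double)acc / batch_size;
      s *= std::exp(rate > 0.44 ? delta : -delta);
      s = std::min(std::max(s, 1e-4), 10.0);
    };
    for (int ti = 0; ti < ntr; ++ti) tune(s_mu[ti], acc_mu[ti]);
    for (int c = 0; c < nc; ++c) {
      tune(s_M[c], acc_M[c]); tune(s_sw[c], acc_sw[c]);
      tune(s_st[c], acc_st[c]); tune(s_a1[c], acc_a1[c]);
      tune(s_shift[c], acc_shift[c]);
    }
    tune(s_alpha, acc_alpha); tune(s_beta, acc_beta);
    tune(s_k, acc_k); tune(s_lam, acc_lam);
    reset_acc();
  }

  void sweep() {
    update_trial_params();
    update_cell_params();
    update_population();
  }
};

// [[Rcpp::export]]
List hbm_chain_cpp(NumericVector spk, IntegerVector toff, IntegerVector coff,
                   double delay, double pmin, double pmax, int variant,
                   List priors, List init, int warmup, int n_keep,
                   double seed) {
  HbmChain ch(spk, toff, coff, delay, pmin, pmax, variant, priors,
              (uint64_t)seed);

  NumericVector iM = init["M"], isw = init["sw"], ist = init["st"],
                ia1 = init["a1"], imu = init["mu"];
  for (int c = 0; c < ch.nc; ++c) {
    ch.M[c] = iM[c]; ch.sw[c] = isw[c]; ch.st[c] = ist[c]; ch.a1[c] = ia1[c];
  }
  for (int ti = 0; ti < ch.ntr; ++ti) ch.mu[ti] = imu[ti];
  ch.alpha = init["alpha"]; ch.beta = init["beta"];
  ch.kshp = init["k"]; ch.lam = init["lambda"];
  if (ch.alpha_fixed) ch.alpha = ch.alpha_fix_val;

  const int batch = 50;
  int batch_no = 0;
  for (int it = 0; it < warmup; ++it) {
    ch.sweep();
    if ((it + 1) % batch == 0) ch.adapt(batch, ++batch_no);
    if ((it & 255) == 0) Rcpp::checkUserInterrupt();
  }

  int npop = (variant == WEIB_POP) ? 2 : 1;
  NumericMatrix pop_draws(n_keep, npop);
  NumericMatrix cell_draws(n_keep, 4 * ch.nc);
  NumericMatrix mu_draws(n_keep, ch.ntr);
  NumericMatrix ll_draws(n_keep, ch.ntr);

  for (int d = 0; d < n_keep; ++d) {
    ch.sweep();
    if (variant == EXP_POP) pop_draws(d, 0) = ch.beta;
    else if (variant == WEIB_POP) { pop_draws(d, 0) = ch.kshp; pop_draws(d, 1) = ch.lam; }
    else pop_draws(d, 0) = ch.alpha;
    for (int c = 0; c < ch.nc; ++c) {
      cell_draws(d, c) = ch.M[c];
      cell_draws(d, ch.nc + c) = ch.sw[c];
      cell_draws(d, 2 * ch.nc + c) = ch.st[c];
      cell_draws(d, 3 * ch.nc + c) = ch.a1[c];
      for (int ti = ch.coff[c]; ti < ch.coff[c + 1]; ++ti) {
        mu_draws(d, ti) = ch.mu[ti];
        double loc = (variant == TRIALWIDTH) ? ch.M[c] : ch.mu[ti];
        double wid = (variant == TRIALWIDTH) ? ch.mu[ti] : ch.sw[c];
        ll_draws(d, ti) = ch.trial_ll(c, ti, loc, wid);
      }
    }
    if ((d & 255) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["pop"] = pop_draws, _["cells"] = cell_draws,
                      _["mu"] = mu_draws, _["loglik"] = ll_draws);
}
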