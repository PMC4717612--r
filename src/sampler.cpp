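// Log-posterior kernels for the hierarchical measurement-error model and a
// componentwise adaptive random-walk Metropolis sampler.
//
// Parameterization is centered: series-level biases mu_i and log-SDs
// lambda_i (and, in the joint model, bias corrections delta_i and
// transformed SD-ratios z_i) are sampled directly, which suits the
// data-dominated regime of published aggregates (n_i of tens to hundreds:
// each series parameter is strongly informed by its own likelihood, so
// posterior correlation with the hyperparameters is weak).  Scale
// hyperparameters are sampled on the log scale, correlations on the atanh
// scale; all Jacobians are included so the target is the posterior stated
// on the natural scales with Cauchy / half-Cauchy / uniform priors.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct ModelData {
  int K;
  std::vector<double> m, s;
  std::vector<int> n;
  // per-series precomputed constants
  std::vector<double> t_const, t_c, t_df;   // mean kernel
  std::vector<double> c_const, c_a, c_k;    // SD kernel
  // calibrated blocks
  std::vector<int> cal;                     // indices with calibrated data
  std::vector<double> mc, sc;               // aligned with cal
  std::vector<int> nc;
  std::vector<double> tc_const, tc_c, tc_df, cc_const, cc_a, cc_k;
  double loc_scale, sd_scale;
  bool as_printed;
};

inline double t_kernel_const(double df, double c, double s) {
  return R::lgammafn(0.5 * (df + 1.0)) - R::lgammafn(0.5 * df)
       - 0.5 * std::log(df * M_PI) + std::log(c / s);
}

// log density in m of the observed mean given (mu, s, n)
inline double ll_mean(double m, double mu, double cst, double c,
                      double df, double s) {
  double t = c * (m - mu) / s;
  return cst - 0.5 * (df + 1.0) * std::log1p(t * t / df);
}

// log density in s of the observed SD given sigma (passed as log sigma):
// chi-square pivot plus Jacobian, collapsed to
// const - k log(sigma) - a / (2 sigma^2), with k = n-1, a = (n-1) s^2
inline double ll_sd(double logsigma, double cst, double a, double k) {
  return cst - k * logsigma - 0.5 * a * std::exp(-2.0 * logsigma);
}

inline double sd_kernel_const(double a, double k, double s) {
  return (0.5 * k - 1.0) * std::log(a) - 0.5 * k * M_LN2
       - R::lgammafn(0.5 * k) + std::log(2.0 * k * s);
}

inline double lp_cauchy(double x, double scale) {
  return -std::log(M_PI * scale * (1.0 + (x / scale) * (x / scale)));
}

// half-Cauchy prior on sigma = exp(xi), density in xi (Jacobian = sigma)
inline double lp_half_cauchy_log(double xi, double scale) {
  double sig = std::exp(xi);
  return std::log(2.0 / (M_PI * scale * (1.0 + (sig / scale) * (sig / scale))))
       + xi;
}

inline double lp_normal(double x, double mu, double sigma) {
  double z = (x - mu) / sigma;
  return -0.5 * z * z - std::log(sigma) - 0.5 * std::log(2.0 * M_PI);
}

// bivariate normal log density with sd1, sd2, correlation rho
inline double lp_binormal(double x1, double x2, double m1, double m2,
                          double sd1, double sd2, double rho) {
  double q = 1.0 - rho * rho;
  double a = (x1 - m1) / sd1, b = (x2 - m2) / sd2;
  return -std::log(2.0 * M_PI) - std::log(sd1 * sd2) - 0.5 * std::log(q)
       - 0.5 * (a * a - 2.0 * rho * a * b + b * b) / q;
}

ModelData build_data(const List& data) {
  ModelData d;
  NumericVector m = data["m"], s = data["s"];
  IntegerVector n = data["n"];
  d.K = m.size();
  d.loc_scale = as<double>(data["loc_scale"]);
  d.sd_scale = as<double>(data["sd_scale"]);
  d.as_printed = as<bool>(data["as_printed"]);
  for (int i = 0; i < d.K; ++i) {
    d.m.push_back(m[i]); d.s.push_back(s[i]); d.n.push_back(n[i]);
    double df = n[i] - 1.0;
    double c = d.as_printed ? std::sqrt(df) : std::sqrt((double)n[i]);
    d.t_df.push_back(df); d.t_c.push_back(c);
    d.t_const.push_back(t_kernel_const(df, c, s[i]));
    double k = df, a = k * s[i] * s[i];
    d.c_k.push_back(k); d.c_a.push_back(a);
    d.c_const.push_back(sd_kernel_const(a, k, s[i]));
  }
  IntegerVector cal = data["cal_idx"];     // 0-based
  NumericVector mc = data["mc"], sc = data["sc"];
  IntegerVector nc = data["nc"];
  for (int j = 0; j < cal.size(); ++j) {
    d.cal.push_back(cal[j]);
    d.mc.push_back(mc[j]); d.sc.push_back(sc[j]); d.nc.push_back(nc[j]);
    double df = nc[j] - 1.0;
    double c = d.as_printed ? std::sqrt(df) : std::sqrt((double)nc[j]);
    d.tc_df.push_back(df); d.tc_c.push_back(c);
    d.tc_const.push_back(t_kernel_const(df, c, sc[j]));
    double k = df, a = k * sc[j] * sc[j];
    d.cc_k.push_back(k); d.cc_a.push_back(a);
    d.cc_const.push_back(sd_kernel_const(a, k, sc[j]));
  }
  return d;
}

// raw model: p = [mu_m, log sigma_m, mu_ls, log sigma_ls,
//                 mu_i (K), lambda_i = log sigma_i (K)]
double lp_raw(const std::vector<double>& p, const ModelData& d) {
  const double mu_m = p[0], sm = std::exp(p[1]);
  const double mls = p[2], sls = std::exp(p[3]);
  double lp = lp_cauchy(mu_m, d.loc_scale) + lp_half_cauchy_log(p[1], d.sd_scale)
            + lp_cauchy(mls, d.loc_scale) + lp_half_cauchy_log(p[3], d.sd_scale);
  for (int i = 0; i < d.K; ++i) {
    double mu_i = p[4 + i], lam_i = p[4 + d.K + i];
    lp += lp_normal(mu_i, mu_m, sm) + lp_normal(lam_i, mls, sls);
    lp += ll_mean(d.m[i], mu_i, d.t_const[i], d.t_c[i], d.t_df[i], d.s[i]);
    lp += ll_sd(lam_i, d.c_const[i], d.c_a[i], d.c_k[i]);
  }
  return lp;
}

// joint model:
// p = [mu_m, log sigma_m, mu_ls, log sigma_ls, mu_d, log sigma_d,
//      atanh rho_p, mu_lt, log sigma_lt, atanh rho_s,
//      mu_i (K), lambda_i (K), delta_cal (C), z_cal (C)]
// delta_i and z_i of series WITHOUT calibrated data contribute no
// likelihood, so they are integrated out analytically: those series enter
// through the normal marginals of the bivariate laws (the model's own
// marginal-consistency property), and their delta_i / z_i are recovered
// afterwards by sampling the conditional prior.  This removes the
// funnel between the population scales and 30-odd data-free parameters.
double lp_joint(const std::vector<double>& p, const ModelData& d) {
  const int K = d.K;
  const double mu_m = p[0], sm = std::exp(p[1]);
  const double mls = p[2], sls = std::exp(p[3]);
  const double mu_d = p[4], sd_d = std::exp(p[5]);
  const double rho_p = std::tanh(p[6]);
  const double mlt = p[7], slt = std::exp(p[8]);
  const double rho_s = std::tanh(p[9]);
  double lp = lp_cauchy(mu_m, d.loc_scale) + lp_half_cauchy_log(p[1], d.sd_scale)
            + lp_cauchy(mls, d.loc_scale) + lp_half_cauchy_log(p[3], d.sd_scale)
            + lp_cauchy(mu_d, d.loc_scale) + lp_half_cauchy_log(p[5], d.sd_scale)
            + lp_cauchy(mlt, d.loc_scale) + lp_half_cauchy_log(p[8], d.sd_scale);
  // Uniform(-1,1) prior on rho, sampled as y = atanh(rho):
  // log |drho/dy| = log(1 - rho^2)
  lp += std::log1p(-rho_p * rho_p) + std::log1p(-rho_s * rho_s);
  std::vector<char> is_cal(K, 0);
  for (size_t j = 0; j < d.cal.size(); ++j) is_cal[d.cal[j]] = 1;
  for (int i = 0; i < K; ++i) {
    double mu_i = p[10 + i], lam_i = p[10 + K + i];
    if (!is_cal[i]) {  // marginals of Eqs (10)-(11)
      lp += lp_normal(mu_i, mu_m, sm) + lp_normal(lam_i, mls, sls);
    }
    lp += ll_mean(d.m[i], mu_i, d.t_const[i], d.t_c[i], d.t_df[i], d.s[i]);
    lp += ll_sd(lam_i, d.c_const[i], d.c_a[i], d.c_k[i]);
  }
  const int C0 = 10 + 2 * K;
  const int C = (int)d.cal.size();
  for (int j = 0; j < C; ++j) {
    int i = d.cal[j];
    double mu_i = p[10 + i], lam_i = p[10 + K + i];
    double del_i = p[C0 + j], z_i = p[C0 + C + j];
    lp += lp_binormal(mu_i, del_i, mu_m, mu_d, sm, sd_d, rho_p);
    lp += lp_binormal(lam_i, z_i, mls, mlt, sls, slt, rho_s);
    // theta = sqrt(2) / (1 + exp(-z)); log theta = 0.5 log 2 - log1p(exp(-z))
    double logtheta = 0.5 * M_LN2 - std::log1p(std::exp(-z_i));
    lp += ll_mean(d.mc[j], mu_i + del_i, d.tc_const[j], d.tc_c[j],
                  d.tc_df[j], d.sc[j]);
    lp += ll_sd(lam_i + logtheta, d.cc_const[j], d.cc_a[j], d.cc_k[j]);
  }
  return lp;
}

} // namespace

// [[Rcpp::export]]
double logpost_cpp(int model, NumericVector pars, List data) {
  ModelData d = build_data(data);
  std::vector<double> p(pars.begin(), pars.end());
  return model == 1 ? lp_raw(p, d) : lp_joint(p, d);
}

// One MCMC chain: componentwise Gaussian random-walk Metropolis with
// Robbins-Monro step adaptation during warmup (frozen afterwards).
// Uses R's RNG: seed with set.seed() before calling.
// [[Rcpp::export]]
List mwg_chain_cpp(int model, List data, NumericVector init,
                   int n_warmup, int n_save, double target_accept,
                   NumericVector step_init) {
  ModelData d = build_data(data);
  const int P = init.size();
  std::vector<double> p(init.begin(), init.end());
  std::vector<double> lstep(P);
  for (int j = 0; j < P; ++j) lstep[j] = std::log(step_init[j]);
  double (*lpfun)(const std::vector<double>&, const ModelData&) =
      (model == 1) ? lp_raw : lp_joint;
  double lp = lpfun(p, d);
  if (!std::isfinite(lp)) stop("non-finite log-posterior at initial values");
  NumericMatrix draws(n_save, P);
  NumericVector lps(n_save);
  std::vector<double> acc(P, 0.0);
  const int n_total = n_warmup + n_save;
  for (int it = 0; it < n_total; ++it) {
    for (int j = 0; j < P; ++j) {
      double old = p[j];
      p[j] = old + std::exp(lstep[j]) * R::norm_rand();
      double lp_new = lpfun(p, d);
      double a = std::isfinite(lp_new) ? std::min(1.0, std::exp(lp_new - lp))
                                       : 0.0;
      if (R::unif_rand() < a) {
        lp = lp_new;
      } else {
        p[j] = old;
      }
      if (it < n_warmup) {
        double gamma = std::pow((double)(it + 1), -0.6);
        lstep[j] += gamma * (a - target_accept);
      } else {
        acc[j] += a;
      }
    }
    if (it >= n_warmup) {
      int r = it - n_warmup;
      for (int j = 0; j < P; ++j) draws(r, j) = p[j];
      lps[r] = lp;
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector accv(P), stepv(P);
  for (int j = 0; j < P; ++j) {
    accv[j] = acc[j] / n_save;
    stepv[j] = std::exp(lstep[j]);
  }
  return List::create(_["draws"] = draws, _["lp"] = lps,
                      _["accept"] = accv, _["step"] = stepv);
}
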