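#include <Rcpp.h>
using namespace Rcpp;

// Mixed-treatment-comparison posterior: contrast-normal or arm-binomial
// likelihood, fixed or random effects, vague normal priors on basic
// parameters d and trial baselines mu, Uniform(0, tau_upper) on the
// between-trial sd.  Random effects delta are parameterized per
// non-baseline unit (contrast row / non-baseline arm) with the standard
// 0.5*tau^2 within-trial correlation handled by sequential
// conditionals: for the j-th unit of a trial,
//   delta_j | previous ~ N(dcon_j + mean(prev residuals), tau^2*(j+1)/(2j)).

struct Model {
  int likelihood;      // 0 = contrast normal, 1 = arm binomial
  int random;          // 0 = fixed, 1 = random effects
  // contrast data
  std::vector<int> c_t, c_b;           // treatment index, 0 = reference
  std::vector<double> c_y, c_se;
  // arm data (binomial)
  std::vector<int> a_trial, a_t, a_b, a_unit; // a_unit: -1 baseline, else unit id
  std::vector<double> a_r, a_n;
  // random-effect units grouped by trial: unit_trial, unit_pos (1-based)
  std::vector<int> u_trial, u_pos;
  // unit -> (t, b) for its consistency contrast
  std::vector<int> u_t, u_b;
  int n_d, n_trial, n_unit;
  double prior_sd_d, tau_upper;

  double dval(const std::vector<double> &d, int idx) const {
    return idx == 0 ? 0.0 : d[idx - 1];
  }
  double dcon(const std::vector<double> &d, int t, int b) const {
    return dval(d, t) - dval(d, b);
  }

  // minus twice the log-likelihood, with full normalizing constants
  double deviance(const std::vector<double> &d, double /*tau*/,
                  const std::vector<double> &delta,
                  const std::vector<double> &mu) const {
    double ll = 0.0;
    if (likelihood == 0) {
      for (size_t i = 0; i < c_y.size(); ++i) {
        double th = random ? delta[i] : dcon(d, c_t[i], c_b[i]);
        ll += R::dnorm(c_y[i], th, c_se[i], 1);
      }
    } else {
      for (size_t i = 0; i < a_r.size(); ++i) {
        double eta = mu[a_trial[i]];
        if (a_unit[i] >= 0)
          eta += random ? delta[a_unit[i]] : dcon(d, a_t[i], a_b[i]);
        double p = 1.0 / (1.0 + std::exp(-eta));
        ll += R::dbinom(a_r[i], a_n[i], p, 1);
      }
    }
    return -2.0 * ll;
  }

  double log_post(const std::vector<double> &d, double tau,
                  const std::vector<double> &delta,
                  const std::vector<double> &mu) const {
    if (random && (tau <= 0.0 || tau >= tau_upper))
      return R_NegInf;
    double lp = -0.5 * deviance(d, tau, delta, mu);
    for (int k = 0; k < n_d; ++k)
      lp += R::dnorm(d[k], 0.0, prior_sd_d, 1);
    if (likelihood == 1)
      for (int t = 0; t < n_trial; ++t)
        lp += R::dnorm(mu[t], 0.0, prior_sd_d, 1);
    if (random) {
      // sequential conditionals within trial
      int i = 0;
      while (i < n_unit) {
        int tr = u_trial[i];
        double resid = 0.0;
        int j = 0;
        while (i < n_unit && u_trial[i] == tr) {
          ++j;
          double dc = dcon(d, u_t[i], u_b[i]);
          double m = dc + (j > 1 ? resid / j : 0.0);
          double v = tau * tau * (j + 1.0) / (2.0 * j);
          lp += R::dnorm(delta[i], m, std::sqrt(v), 1);
          resid += delta[i] - dc;
          ++i;
        }
      }
    }
    return lp;
  }
};

static Model build_model(List dat) {
  Model m;
  m.likelihood = as<int>(dat["likelihood"]);
  m.random = as<int>(dat["random"]);
  m.c_t = as<std::vector<int> >(dat["c_t"]);
  m.c_b = as<std::vector<int> >(dat["c_b"]);
  m.c_y = as<std::vector<double> >(dat["c_y"]);
  m.c_se = as<std::vector<double> >(dat["c_se"]);
  m.a_trial = as<std::vector<int> >(dat["a_trial"]);
  m.a_t = as<std::vector<int> >(dat["a_t"]);
  m.a_b = as<std::vector<int> >(dat["a_b"]);
  m.a_unit = as<std::vector<int> >(dat["a_unit"]);
  m.a_r = as<std::vector<double> >(dat["a_r"]);
  m.a_n = as<std::vector<double> >(dat["a_n"]);
  m.u_trial = as<std::vector<int> >(dat["u_trial"]);
  m.u_pos = as<std::vector<int> >(dat["u_pos"]);
  m.u_t = as<std::vector<int> >(dat["u_t"]);
  m.u_b = as<std::vector<int> >(dat["u_b"]);
  m.n_d = as<int>(dat["n_d"]);
  m.n_trial = as<int>(dat["n_trial"]);
  m.n_unit = as<int>(dat["n_unit"]);
  m.prior_sd_d = as<double>(dat["prior_sd_d"]);
  m.tau_upper = as<double>(dat["tau_upper"]);
  return m;
}

// [[Rcpp::export]]
double mtc_log_post_cpp(List dat, NumericVector d, double tau,
                        NumericVector delta, NumericVector mu) {
  Model m = build_model(dat);
  return m.log_post(as<std::vector<double> >(d), tau,
                    as<std::vector<double> >(delta),
                    as<std::vector<double> >(mu));
}

// [[Rcpp::export]]
double mtc_deviance_cpp(List dat, NumericVector d, double tau,
                        NumericVector delta, NumericVector mu) {
  Model m = build_model(dat);
  return m.deviance(as<std::vector<double> >(d), tau,
                    as<std::vector<double> >(delta),
                    as<std::vector<double> >(mu));
}

// Adaptive scalar random-walk Metropolis within Gibbs.  Step sizes adapt
// toward ~44% acceptance during burn-in only (frozen afterwards, so the
// retained chain has a fixed kernel and detailed balance holds).
// [[Rcpp::export]]
List mtc_chain_cpp(List dat, NumericVector init_d, double init_tau,
                   NumericVector init_delta, NumericVector init_mu,
                   int burn, int keep, int thin, int adapt_interval) {
  Model m = build_model(dat);
  std::vector<double> d = as<std::vector<double> >(init_d);
  std::vector<double> delta = as<std::vector<double> >(init_delta);
  std::vector<double> mu = as<std::vector<double> >(init_mu);
  double tau = init_tau;

  int np = m.n_d + (m.random ? 1 + m.n_unit : 0) +
           (m.likelihood == 1 ? m.n_trial : 0);
  std::vector<double> step(np, 0.5);
  if (m.random) step[m.n_d] = 0.2; // tau
  std::vector<int> acc(np, 0), tries(np, 0);
  std::vector<long> acc_tot(np, 0), tries_tot(np, 0);

  double lp = m.log_post(d, tau, delta, mu);
  if (!R_finite(lp)) stop("non-finite log posterior at initial state");

  int total = burn + keep * thin;
  NumericMatrix out(keep, m.n_d + (m.random ? 1 : 0) +
                            (m.likelihood == 1 ? m.n_trial : 0) +
                            m.n_unit * (m.random ? 1 : 0) + 1);
  int row = 0;
  RNGScope scope;

  for (int it = 1; it <= total; ++it) {
    int p = 0;
    for (int k = 0; k < m.n_d; ++k, ++p) {
      double old = d[k];
      d[k] += R::norm_rand() * step[p];
      double lp2 = m.log_post(d, tau, delta, mu);
      ++tries[p];
      if (std::log(R::unif_rand()) < lp2 - lp) { lp = lp2; ++acc[p]; }
      else d[k] = old;
    }
    if (m.random) {
      double old = tau;
      tau += R::norm_rand() * step[p];
      double lp2 = m.log_post(d, tau, delta, mu);
      ++tries[p];
      if (std::log(R::unif_rand()) < lp2 - lp) { lp = lp2; ++acc[p]; }
      else tau = old;
      ++p;
      for (int u = 0; u < m.n_unit; ++u, ++p) {
        double o = delta[u];
        delta[u] += R::norm_rand() * step[p];
        double lp2u = m.log_post(d, tau, delta, mu);
        ++tries[p];
        if (std::log(R::unif_rand()) < lp2u - lp) { lp = lp2u; ++acc[p]; }
        else delta[u] = o;
      }
    }
    if (m.likelihood == 1) {
      for (int t = 0; t < m.n_trial; ++t, ++p) {
        double o = mu[t];
        mu[t] += R::norm_rand() * step[p];
        double lp2 = m.log_post(d, tau, delta, mu);
        ++tries[p];
        if (std::log(R::unif_rand()) < lp2 - lp) { lp = lp2; ++acc[p]; }
        else mu[t] = o;
      }
    }

    if (it <= burn && it % adapt_interval == 0) {
      for (int q = 0; q < np; ++q) {
        if (tries[q] > 0) {
          double rate = (double)acc[q] / tries[q];
          step[q] *= std::exp(rate > 0.44 ? 0.15 : -0.15);
          acc_tot[q] += acc[q]; tries_tot[q] += tries[q];
          acc[q] = 0; tries[q] = 0;
        }
      }
    }

    if (it > burn && (it - burn) % thin == 0) {
      int col = 0;
      for (int k = 0; k < m.n_d; ++k) out(row, col++) = d[k];
      if (m.random) out(row, col++) = tau;
      if (m.likelihood == 1)
        for (int t = 0; t < m.n_trial; ++t) out(row, col++) = mu[t];
      if (m.random)
        for (int u = 0; u < m.n_unit; ++u) out(row, col++) = delta[u];
      out(row, col++) = m.deviance(d, tau, delta, mu);
      ++row;
    }
  }
  for (int q = 0; q < np; ++q) { acc_tot[q] += acc[q]; tries_tot[q] += tries[q]; }
  NumericVector rates(np);
  for (int q = 0; q < np; ++q)
    rates[q] = tries_tot[q] ? (double)acc_tot[q] / tries_tot[q] : NA_REAL;
  return List::create(_["draws"] = out, _["accept"] = rates,
                      _["step"] = NumericVector(step.begin(), step.end()));
}
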