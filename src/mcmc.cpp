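#include <Rcpp.h>
using namespace Rcpp;

// Adaptive coordinate-wise random-walk Metropolis for Bayesian logistic
// regressions with Cauchy priors on the coefficients. Proposal scales are
// tuned toward ~30% acceptance during burn-in only, so the post-burn-in
// chain is a valid (non-adaptive) Metropolis sampler. All randomness uses
// R's RNG.

static inline double log1p_exp(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double dcauchy_log(double x, double scale) {
  return -std::log(M_PI * scale * (1.0 + (x / scale) * (x / scale)));
}

// Binomial logit log-likelihood for responses y in {0,1}
static double loglik_logit(const IntegerVector& y,
                           const std::vector<double>& eta) {
  double ll = 0.0;
  for (size_t i = 0; i < eta.size(); ++i)
    ll += (y[i] ? eta[i] : 0.0) - log1p_exp(eta[i]);
  return ll;
}

// [[Rcpp::export]]
List cpp_mh_logit(const IntegerVector& y, const NumericMatrix& X,
                  double prior_scale, int iterations, int burn_in,
                  int thinning) {
  const int n = y.size(), p = X.ncol();
  std::vector<double> beta(p, 0.0), eta(n, 0.0), scale(p, 0.5);
  std::vector<int> acc(p, 0), prop(p, 0);
  double ll = loglik_logit(y, eta);
  double lprior = 0.0;
  for (int j = 0; j < p; ++j) lprior += dcauchy_log(beta[j], prior_scale);

  const int n_keep = (iterations - burn_in) / thinning;
  NumericMatrix samples(n_keep, p);
  NumericVector deviance(n_keep);
  int kept = 0;
  std::vector<int> win_acc(p, 0), win_prop(p, 0);

  for (int it = 1; it <= iterations; ++it) {
    if (it % 4096 == 0) Rcpp::checkUserInterrupt();
    for (int j = 0; j < p; ++j) {
      const double d = R::norm_rand() * scale[j];
      const double cand = beta[j] + d;
      double ll_new = 0.0;
      for (int i = 0; i < n; ++i) {
        const double e = eta[i] + X(i, j) * d;
        ll_new += (y[i] ? e : 0.0) - log1p_exp(e);
      }
      const double lp_new = lprior - dcauchy_log(beta[j], prior_scale) +
                            dcauchy_log(cand, prior_scale);
      ++prop[j]; ++win_prop[j];
      if (std::log(R::unif_rand()) < (ll_new + lp_new) - (ll + lprior)) {
        for (int i = 0; i < n; ++i) eta[i] += X(i, j) * d;
        beta[j] = cand; ll = ll_new; lprior = lp_new;
        ++acc[j]; ++win_acc[j];
      }
    }
    if (it <= burn_in && it % 50 == 0) {
      for (int j = 0; j < p; ++j) {
        const double rate = win_prop[j] ? double(win_acc[j]) / win_prop[j] : 0.3;
        scale[j] *= std::exp(rate - 0.3);
        win_acc[j] = 0; win_prop[j] = 0;
      }
    }
    if (it > burn_in && (it - burn_in) % thinning == 0 && kept < n_keep) {
      for (int j = 0; j < p; ++j) samples(kept, j) = beta[j];
      deviance[kept] = -2.0 * ll;
      ++kept;
    }
  }
  NumericVector rates(p);
  for (int j = 0; j < p; ++j)
    rates[j] = prop[j] ? double(acc[j]) / prop[j] : NA_REAL;
  return List::create(_["samples"] = samples, _["deviance"] = deviance,
                      _["accept_rate"] = rates);
}

// Baseline-category (multinomial) logit with 3 categories; y in {0,1,2},
// 0 = baseline. Coefficients: p for category 1 then p for category 2.
// [[Rcpp::export]]
List cpp_mh_multilogit(const IntegerVector& y, const NumericMatrix& X,
                       double prior_scale, int iterations, int burn_in,
                       int thinning) {
  const int n = y.size(), p = X.ncol(), P = 2 * p;
  std::vector<double> beta(P, 0.0), eta1(n, 0.0), eta2(n, 0.0), scale(P, 0.5);
  std::vector<int> acc(P, 0), prop(P, 0), win_acc(P, 0), win_prop(P, 0);

  auto loglik = [&](const std::vector<double>& e1,
                    const std::vector<double>& e2) {
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      const double m = std::max(0.0, std::max(e1[i], e2[i]));
      const double lse = m + std::log(std::exp(-m) + std::exp(e1[i] - m) +
                                      std::exp(e2[i] - m));
      const double num = (y[i] == 1) ? e1[i] : (y[i] == 2) ? e2[i] : 0.0;
      ll += num - lse;
    }
    return ll;
  };
  double ll = loglik(eta1, eta2);
  double lprior = 0.0;
  for (int j = 0; j < P; ++j) lprior += dcauchy_log(beta[j], prior_scale);

  const int n_keep = (iterations - burn_in) / thinning;
  NumericMatrix samples(n_keep, P);
  NumericVector deviance(n_keep);
  int kept = 0;
  std::vector<double> e_new(n);

  for (int it = 1; it <= iterations; ++it) {
    if (it % 2048 == 0) Rcpp::checkUserInterrupt();
    for (int j = 0; j < P; ++j) {
      const bool cat1 = j < p;
      const int col = cat1 ? j : j - p;
      const double d = R::norm_rand() * scale[j];
      const double cand = beta[j] + d;
      std::vector<double>& e_cur = cat1 ? eta1 : eta2;
      for (int i = 0; i < n; ++i) e_new[i] = e_cur[i] + X(i, col) * d;
      const double ll_new = cat1 ? loglik(e_new, eta2) : loglik(eta1, e_new);
      const double lp_new = lprior - dcauchy_log(beta[j], prior_scale) +
                            dcauchy_log(cand, prior_scale);
      ++prop[j]; ++win_prop[j];
      if (std::log(R::unif_rand()) < (ll_new + lp_new) - (ll + lprior)) {
        e_cur = e_new;
        beta[j] = cand; ll = ll_new; lprior = lp_new;
        ++acc[j]; ++win_acc[j];
      }
    }
    if (it <= burn_in && it % 50 == 0) {
      for (int j = 0; j < P; ++j) {
        const double rate = win_prop[j] ? double(win_acc[j]) / win_prop[j] : 0.3;
        scale[j] *= std::exp(rate - 0.3);
        win_acc[j] = 0; win_prop[j] = 0;
      }
    }
    if (it > burn_in && (it - burn_in) % thinning == 0 && kept < n_keep) {
      for (int j = 0; j < P; ++j) samples(kept, j) = beta[j];
      deviance[kept] = -2.0 * ll;
      ++kept;
    }
  }
  NumericVector rates(P);
  for (int j = 0; j < P; ++j)
    rates[j] = prop[j] ? double(acc[j]) / prop[j] : NA_REAL;
  return List::create(_["samples"] = samples, _["deviance"] = deviance,
                      _["accept_rate"] = rates);
}

// Binomial logit GLMM with a random intercept per group: Cauchy priors on
// fixed effects, u_g ~ N(0, sigma^2), sigma ~ half-Cauchy(sigma_scale),
// sigma updated on the log scale (Jacobian included). Deviance is the
// conditional binomial deviance given (beta, u). estimate_sigma = false
// pins sigma and all u_g at zero (reduction to the fixed-effects model).
// [[Rcpp::export]]
List cpp_mh_logit_mm(const IntegerVector& y, const NumericMatrix& X,
                     const IntegerVector& group, int n_groups,
                     double prior_scale, double sigma_scale, int iterations,
                     int burn_in, int thinning, bool estimate_sigma) {
  const int n = y.size(), p = X.ncol(), G = n_groups;
  std::vector<double> beta(p, 0.0), u(G, 0.0), eta(n, 0.0);
  double sigma = estimate_sigma ? 0.5 : 0.0;
  std::vector<std::vector<int> > rows(G);
  for (int i = 0; i < n; ++i) rows[group[i]].push_back(i);

  const int P = p + G + 1;  // proposal scales: beta, u, log-sigma
  std::vector<double> scale(P, 0.5);
  std::vector<int> win_acc(P, 0), win_prop(P, 0);
  std::vector<long> acc(P, 0), prop(P, 0);

  double ll = loglik_logit(y, eta);

  auto lprior_beta = [&](void) {
    double lp = 0.0;
    for (int j = 0; j < p; ++j) lp += dcauchy_log(beta[j], prior_scale);
    return lp;
  };
  double lpb = lprior_beta();

  const int n_keep = (iterations - burn_in) / thinning;
  NumericMatrix samples(n_keep, p + G + 1);
  NumericVector deviance(n_keep);
  int kept = 0;

  for (int it = 1; it <= iterations; ++it) {
    if (it % 1024 == 0) Rcpp::checkUserInterrupt();
    // fixed effects
    for (int j = 0; j < p; ++j) {
      const double d = R::norm_rand() * scale[j];
      const double cand = beta[j] + d;
      double ll_new = 0.0;
      for (int i = 0; i < n; ++i) {
        const double e = eta[i] + X(i, j) * d;
        ll_new += (y[i] ? e : 0.0) - log1p_exp(e);
      }
      const double dlp = dcauchy_log(cand, prior_scale) -
                         dcauchy_log(beta[j], prior_scale);
      ++prop[j]; ++win_prop[j];
      if (std::log(R::unif_rand()) < (ll_new - ll) + dlp) {
        for (int i = 0; i < n; ++i) eta[i] += X(i, j) * d;
        beta[j] = cand; ll = ll_new; lpb += dlp;
        ++acc[j]; ++win_acc[j];
      }
    }
    if (estimate_sigma) {
      // random intercepts: only the group's rows enter the likelihood delta
      for (int g = 0; g < G; ++g) {
        const int jj = p + g;
        const double d = R::norm_rand() * scale[jj];
        const double cand = u[g] + d;
        double dll = 0.0;
        for (int idx : rows[g]) {
          const double e_old = eta[idx], e_new = e_old + d;
          dll += ((y[idx] ? e_new : 0.0) - log1p_exp(e_new)) -
                 ((y[idx] ? e_old : 0.0) - log1p_exp(e_old));
        }
        const double dlp = R::dnorm4(cand, 0.0, sigma, 1) -
                           R::dnorm4(u[g], 0.0, sigma, 1);
        ++prop[jj]; ++win_prop[jj];
        if (std::log(R::unif_rand()) < dll + dlp) {
          for (int idx : rows[g]) eta[idx] += d;
          u[g] = cand; ll += dll;
          ++acc[jj]; ++win_acc[jj];
        }
      }
      // sigma on the log scale; likelihood is unchanged (conditional)
      {
        const int jj = p + G;
        const double lam = std::log(sigma);
        const double cand_lam = lam + R::norm_rand() * scale[jj];
        const double cand = std::exp(cand_lam);
        double dlp = 0.0;
        for (int g = 0; g < G; ++g)
          dlp += R::dnorm4(u[g], 0.0, cand, 1) - R::dnorm4(u[g], 0.0, sigma, 1);
        // half-Cauchy prior and log-scale Jacobian
        dlp += dcauchy_log(cand, sigma_scale) - dcauchy_log(sigma, sigma_scale);
        dlp += cand_lam - lam;
        ++prop[jj]; ++win_prop[jj];
        if (std::log(R::unif_rand()) < dlp) {
          sigma = cand;
          ++acc[jj]; ++win_acc[jj];
        }
      }
    }
    if (it <= burn_in && it % 50 == 0) {
      for (int j = 0; j < P; ++j) {
        const double rate = win_prop[j] ? double(win_acc[j]) / win_prop[j] : 0.3;
        scale[j] *= std::exp(rate - 0.3);
        win_acc[j] = 0; win_prop[j] = 0;
      }
    }
    if (it > burn_in && (it - burn_in) % thinning == 0 && kept < n_keep) {
      for (int j = 0; j < p; ++j) samples(kept, j) = beta[j];
      for (int g = 0; g < G; ++g) samples(kept, p + g) = u[g];
      samples(kept, p + G) = sigma;
      deviance[kept] = -2.0 * ll;
      ++kept;
    }
  }
  NumericVector rates(P);
  for (int j = 0; j < P; ++j)
    rates[j] = prop[j] ? double(acc[j]) / prop[j] : NA_REAL;
  return List::create(_["samples"] = samples, _["deviance"] = deviance,
                      _["accept_rate"] = rates);
}
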