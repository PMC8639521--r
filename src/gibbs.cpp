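#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for whole-genome marker regressions ("Bayesian alphabet").
//
// Model: y = mu + X beta + e, e ~ N(0, sigma_e^2 I).
// family: 0 = BRR (pooled normal), 1 = BayesA (per-marker scaled-inv-chisq),
//         2 = BayesB (spike + per-marker t slab), 3 = BayesC (spike + pooled
//         normal slab).
// Scaled-inverse-chi-square convention: sigma^2 ~ S / chisq_nu (prior mode
// S / (nu + 2)); conjugate update sigma^2 | SS, m ~ (S + SS) / chisq_{nu+m}.
// Uses R's RNG so seeding from R makes chains reproducible.
//
// [[Rcpp::export]]
List gibbs_bayes_cpp(NumericVector y, NumericMatrix X, int family,
                     double nu, double S, double pi_zero,
                     double nu_e, double S_e,
                     int iters, int burnin, int thin,
                     bool fix_var, double sigma_beta2_init,
                     double sigma_e2_init, bool keep_samples) {
  const int n = y.size();
  const int p = X.ncol();

  std::vector<double> xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }

  std::vector<double> beta(p, 0.0);
  std::vector<double> sb2(p, sigma_beta2_init); // per-marker (A/B); [0] pooled (BRR/C)
  std::vector<int> delta(p, 1);
  double sigma_e2 = sigma_e2_init;
  double sigma_b2 = sigma_beta2_init; // pooled slab variance (BRR, BayesC)
  double mu = mean(y);

  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  const bool spike = (family == 2 || family == 3);
  const bool per_marker = (family == 1 || family == 2);

  // accumulators
  double mu_sum = 0.0, se2_sum = 0.0;
  std::vector<double> beta_sum(p, 0.0), beta_sumsq(p, 0.0), incl_sum(p, 0.0);
  int kept = 0;
  const int n_keep = (iters - burnin + thin - 1) / thin;
  NumericMatrix beta_draws = keep_samples ? NumericMatrix(n_keep, p)
                                          : NumericMatrix(0, 0);
  NumericVector mu_draws = keep_samples ? NumericVector(n_keep)
                                        : NumericVector(0);

  for (int it = 0; it < iters; ++it) {
    // intercept: full conditional N(mu + mean(e), sigma_e2 / n)
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar /= n;
    double mu_new = mu + ebar + norm_rand() * std::sqrt(sigma_e2 / n);
    double shift = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= shift;
    mu = mu_new;

    // marker effects
    for (int j = 0; j < p; ++j) {
      if (xtx[j] <= 0.0) { beta[j] = 0.0; continue; }
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += X(i, j) * e[i];
      rhs += xtx[j] * beta[j];

      double sbj = per_marker ? sb2[j] : sigma_b2;
      double b_new = 0.0;
      int d_new = 1;
      if (spike) {
        if (pi_zero >= 1.0) {
          d_new = 0;
        } else if (pi_zero <= 0.0) {
          d_new = 1;
        } else {
          // marginal of rhs: N(0, xtx*se2) under exclusion,
          // N(0, xtx^2*sbj + xtx*se2) under inclusion
          double v0 = xtx[j] * sigma_e2;
          double v1 = xtx[j] * xtx[j] * sbj + v0;
          double log_odds = std::log(1.0 - pi_zero) - std::log(pi_zero)
            + 0.5 * (std::log(v0) - std::log(v1))
            + 0.5 * rhs * rhs * (1.0 / v0 - 1.0 / v1);
          double p1 = 1.0 / (1.0 + std::exp(-log_odds));
          d_new = (unif_rand() < p1) ? 1 : 0;
        }
      }
      if (!spike || d_new == 1) {
        double C = xtx[j] + sigma_e2 / sbj;
        b_new = rhs / C + norm_rand() * std::sqrt(sigma_e2 / C);
      }
      double diff = b_new - beta[j];
      if (diff != 0.0) {
        for (int i = 0; i < n; ++i) e[i] -= X(i, j) * diff;
      }
      beta[j] = b_new;
      delta[j] = spike ? d_new : 1;
    }

    // variance updates
    if (!fix_var) {
      if (family == 0) { // BRR pooled
        double ss = 0.0;
        for (int j = 0; j < p; ++j) ss += beta[j] * beta[j];
        sigma_b2 = (S + ss) / R::rchisq(nu + p);
      } else if (family == 1) { // BayesA per marker
        for (int j = 0; j < p; ++j) {
          sb2[j] = (S + beta[j] * beta[j]) / R::rchisq(nu + 1.0);
        }
      } else if (family == 2) { // BayesB: slab variance per included marker
        for (int j = 0; j < p; ++j) {
          if (delta[j] == 1) {
            sb2[j] = (S + beta[j] * beta[j]) / R::rchisq(nu + 1.0);
          } else {
            sb2[j] = S / R::rchisq(nu); // fresh prior draw for next inclusion step
          }
        }
      } else { // BayesC pooled slab over included markers
        double ss = 0.0; int m = 0;
        for (int j = 0; j < p; ++j) {
          if (delta[j] == 1) { ss += beta[j] * beta[j]; ++m; }
        }
        sigma_b2 = (S + ss) / R::rchisq(nu + m);
      }
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      sigma_e2 = (S_e + sse) / R::rchisq(nu_e + n);
    }

    // accumulate
    if (it >= burnin && ((it - burnin) % thin == 0)) {
      mu_sum += mu;
      se2_sum += sigma_e2;
      for (int j = 0; j < p; ++j) {
        beta_sum[j] += beta[j];
        beta_sumsq[j] += beta[j] * beta[j];
        incl_sum[j] += delta[j];
      }
      if (keep_samples) {
        for (int j = 0; j < p; ++j) beta_draws(kept, j) = beta[j];
        mu_draws[kept] = mu;
      }
      ++kept;
    }
  }

  NumericVector beta_hat(p), beta_sd(p), incl(p);
  for (int j = 0; j < p; ++j) {
    beta_hat[j] = beta_sum[j] / kept;
    double v = beta_sumsq[j] / kept - beta_hat[j] * beta_hat[j];
    beta_sd[j] = v > 0 ? std::sqrt(v) : 0.0;
    incl[j] = incl_sum[j] / kept;
  }

  List out = List::create(
    _["mu_hat"] = mu_sum / kept,
    _["beta_hat"] = beta_hat,
    _["beta_sd"] = beta_sd,
    _["inclusion_prob"] = incl,
    _["residual_var_hat"] = se2_sum / kept,
    _["n_kept"] = kept);
  if (keep_samples) {
    out["beta_draws"] = beta_draws;
    out["mu_draws"] = mu_draws;
  }
  return out;
}
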