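#include <Rcpp.h>
using namespace Rcpp;

// Bayes B Gibbs sampler for y = 1*mu + sum_j Z_j beta_j delta_j + e.
//
// Per locus j: delta_j ~ Bernoulli(1 - pi) a priori, beta_j | sigma2_j ~
// N(0, sigma2_j), sigma2_j ~ nu * S2 / chisq(nu) (scaled inverse
// chi-square). delta_j is sampled from its full conditional with beta_j
// integrated out given sigma2_j; beta_j is then drawn from its normal full
// conditional when delta_j = 1. sigma2_j is refreshed from its conditional
// (posterior when the locus is in the model, prior otherwise). The residual
// variance has a scaled-inverse-chi-square prior (nu_e, S2e). Uses R's RNG,
// so results are reproducible under set.seed().
//
// Z must be column-centered. Saved samples are the post-burn-in states at
// every `thin`-th iteration; the effect samples are delta_j * beta_j.
// [[Rcpp::export]]
List bayesb_mcmc(const NumericMatrix& Z, const NumericVector& y,
                 double pi_excl, int chain_length, int burn_in, int thin,
                 double nu, double S2, double nu_e, double S2e,
                 bool keep_samples) {
  const int n = Z.nrow(), m = Z.ncol();
  if (burn_in >= chain_length) stop("burn_in must be < chain_length");
  if (S2 <= 0 || S2e <= 0) stop("prior scale must be positive");

  std::vector<double> zz(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    const double* zj = &Z(0, j);
    for (int i = 0; i < n; ++i) s += zj[i] * zj[i];
    zz[j] = s;
  }

  std::vector<double> beta(m, 0.0), sigma2(m);
  std::vector<int> delta(m, 0);
  for (int j = 0; j < m; ++j) sigma2[j] = nu * S2 / R::rchisq(nu);
  double mu = Rcpp::mean(y), sigma2e = S2e;
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  const int n_save = (chain_length - burn_in) / thin;
  NumericMatrix eff;  // m x n_save
  if (keep_samples) eff = NumericMatrix(m, n_save);
  NumericVector phat(m), post_mean(m), mu_save(n_save), s2e_save(n_save);
  const double log_prior_odds = std::log((1.0 - pi_excl) / pi_excl);
  int isave = 0;

  for (int it = 0; it < chain_length; ++it) {
    // intercept
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar /= n;
    double mu_new = ebar + mu + R::norm_rand() * std::sqrt(sigma2e / n);
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    mu = mu_new;

    for (int j = 0; j < m; ++j) {
      if (zz[j] <= 0.0) continue;  // monomorphic after centering
      const double* zj = &Z(0, j);
      double zr = 0.0;
      for (int i = 0; i < n; ++i) zr += zj[i] * e[i];
      const double b_old = (delta[j] == 1) ? beta[j] : 0.0;
      zr += zz[j] * b_old;  // z_j' (e + Z_j beta_j): residual excluding locus j
      const double C = zz[j] / sigma2e + 1.0 / sigma2[j];
      const double rhs = zr / sigma2e;
      const double log_odds = log_prior_odds -
        0.5 * std::log(sigma2[j] * C) + 0.5 * rhs * rhs / C;
      const double p1 = 1.0 / (1.0 + std::exp(-log_odds));
      const int d_new = (unif_rand() < p1) ? 1 : 0;
      double b_new = 0.0;
      if (d_new == 1) b_new = rhs / C + R::norm_rand() / std::sqrt(C);
      const double db = b_new - b_old;
      if (db != 0.0) for (int i = 0; i < n; ++i) e[i] -= zj[i] * db;
      delta[j] = d_new;
      beta[j] = b_new;
      // locus variance: posterior when in the model, prior draw otherwise
      if (d_new == 1) {
        sigma2[j] = (b_new * b_new + nu * S2) / R::rchisq(nu + 1.0);
      } else {
        sigma2[j] = nu * S2 / R::rchisq(nu);
      }
    }

    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma2e = (sse + nu_e * S2e) / R::rchisq(nu_e + n);
    if (!R_finite(sigma2e) || sigma2e <= 0)
      stop("residual variance diverged at iteration %d", it + 1);

    if (it >= burn_in && (it - burn_in) % thin == 0 && isave < n_save) {
      for (int j = 0; j < m; ++j) {
        const double bj = (delta[j] == 1) ? beta[j] : 0.0;
        if (keep_samples) eff(j, isave) = bj;
        phat[j] += delta[j];
        post_mean[j] += bj;
      }
      mu_save[isave] = mu;
      s2e_save[isave] = sigma2e;
      ++isave;
    }
  }
  for (int j = 0; j < m; ++j) { phat[j] /= isave; post_mean[j] /= isave; }
  return List::create(_["p_hat"] = phat, _["post_mean_effect"] = post_mean,
                      _["effect_samples"] = eff, _["mu"] = mu_save,
                      _["sigma2e"] = s2e_save, _["n_saved"] = isave);
}
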