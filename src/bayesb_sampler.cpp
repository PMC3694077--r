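// Single-site Gibbs sampler for the BayesB mixture whole-genome
// regression:
//   y = X b + sum_j z_j a_j delta_j + e
// with P(delta_j = 0) = pi, a_j | sigma2_j ~ N(0, sigma2_j),
// sigma2_j ~ nu_a S_a / chi2_nu_a, e ~ N(0, I sigma2_e),
// sigma2_e ~ nu_e S_e / chi2_nu_e, flat priors on b.
//
// delta_j is sampled from the likelihood with a_j integrated out given
// the current locus variance (drawn from its prior when the locus is
// excluded, from its full conditional when included), which avoids the
// reducibility of updating a_j at a point mass.  Residuals are updated
// in place so each locus costs O(n); the bookkeeping is audited against
// a fresh reconstruction every `audit_every` iterations.
//
// Uses R's RNG so results are reproducible from set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static inline double rinvchisq(double nu, double scale) {
  // scaled inverse chi-square draw: nu * scale / chi2_nu
  return nu * scale / R::rchisq(nu);
}

// [[Rcpp::export(name = ".bayesb_mcmc")]]
List bayesb_mcmc(NumericVector y, NumericMatrix X, NumericMatrix Z,
                 double pi_null, int n_iter, int burn_in, int thin,
                 double nu_a, double S_a, double nu_e, double S_e,
                 int audit_every = 1000) {
  const int n = y.size(), p = X.ncol(), k = Z.ncol();
  const double *Xp = X.begin(), *Zp = Z.begin();
  std::vector<double> xtx(p), ztz(k);
  for (int l = 0; l < p; ++l) {
    const double *xl = Xp + (size_t)l * n;
    double s = 0; for (int i = 0; i < n; ++i) s += xl[i] * xl[i];
    xtx[l] = s;
  }
  for (int j = 0; j < k; ++j) {
    const double *zj = Zp + (size_t)j * n;
    double s = 0; for (int i = 0; i < n; ++i) s += zj[i] * zj[i];
    ztz[j] = s;
  }

  std::vector<double> b(p, 0.0), a(k, 0.0), e(y.begin(), y.end());
  std::vector<int> delta(k, 0);
  double sigma2e = S_e > 0 ? S_e : 1.0;
  const double log_prior_odds = std::log1p(-pi_null) - std::log(pi_null);

  int n_states = (n_iter - burn_in) / thin;
  if (n_states < 0) n_states = 0;
  List saved_idx(n_states), saved_eff(n_states);
  NumericVector out_s2e(n_states), out_varg(n_states);
  IntegerVector out_nincl(n_states);
  NumericMatrix out_b(p, n_states);
  std::vector<double> incl_freq(k, 0.0), eff_sum(k, 0.0);
  double audit_max = 0.0;
  std::vector<double> g(n);

  int state = 0;
  for (int iter = 1; iter <= n_iter; ++iter) {
    // fixed effects, flat prior full conditionals
    for (int l = 0; l < p; ++l) {
      if (xtx[l] <= 0) continue;
      const double *xl = Xp + (size_t)l * n;
      double rhs = 0;
      for (int i = 0; i < n; ++i) rhs += xl[i] * e[i];
      rhs += xtx[l] * b[l];
      double mean = rhs / xtx[l];
      double bnew = mean + std::sqrt(sigma2e / xtx[l]) * R::norm_rand();
      double dlt = bnew - b[l];
      for (int i = 0; i < n; ++i) e[i] -= xl[i] * dlt;
      b[l] = bnew;
    }

    // marker effects: mixture update per locus
    for (int j = 0; j < k; ++j) {
      if (ztz[j] <= 0) { delta[j] = 0; a[j] = 0; continue; }
      const double *zj = Zp + (size_t)j * n;
      double old = delta[j] ? a[j] : 0.0;
      double r = 0;
      for (int i = 0; i < n; ++i) r += zj[i] * e[i];
      r += ztz[j] * old;  // right-hand side with locus j removed

      double s2j = delta[j]
        ? rinvchisq(nu_a + 1.0, (nu_a * S_a + a[j] * a[j]) / (nu_a + 1.0))
        : rinvchisq(nu_a, S_a);

      double v1 = ztz[j] * s2j + sigma2e;
      double logL1 = 0.5 * (r * r * s2j / (sigma2e * v1))
                   - 0.5 * std::log(v1 / sigma2e);
      double lo = log_prior_odds + logL1;
      double p1 = 1.0 / (1.0 + std::exp(-lo));
      int dnew = (R::unif_rand() < p1) ? 1 : 0;

      double anew = 0.0;
      if (dnew) {
        double c = ztz[j] + sigma2e / s2j;
        anew = r / c + std::sqrt(sigma2e / c) * R::norm_rand();
      }
      double dlt = anew - old;
      if (dlt != 0.0)
        for (int i = 0; i < n; ++i) e[i] -= zj[i] * dlt;
      delta[j] = dnew;
      a[j] = anew;
    }

    // residual variance
    double sse = 0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma2e = (sse + nu_e * S_e) / R::rchisq(nu_e + n);

    // audit residual bookkeeping against a fresh reconstruction
    if (audit_every > 0 && iter % audit_every == 0) {
      std::vector<double> et(y.begin(), y.end());
      for (int l = 0; l < p; ++l)
        if (b[l] != 0) {
          const double *xl = Xp + (size_t)l * n;
          for (int i = 0; i < n; ++i) et[i] -= xl[i] * b[l];
        }
      for (int j = 0; j < k; ++j)
        if (delta[j] && a[j] != 0) {
          const double *zj = Zp + (size_t)j * n;
          for (int i = 0; i < n; ++i) et[i] -= zj[i] * a[j];
        }
      double mx = 0;
      for (int i = 0; i < n; ++i)
        mx = std::max(mx, std::fabs(et[i] - e[i]));
      if (mx > audit_max) audit_max = mx;
      e.assign(et.begin(), et.end());
    }

    // save thinned post-burn-in states
    if (iter > burn_in && (iter - burn_in) % thin == 0 && state < n_states) {
      std::vector<int> idx;
      std::vector<double> eff;
      for (int j = 0; j < k; ++j)
        if (delta[j]) { idx.push_back(j + 1); eff.push_back(a[j]); }
      std::fill(g.begin(), g.end(), 0.0);
      for (size_t m = 0; m < idx.size(); ++m) {
        const double *zj = Zp + (size_t)(idx[m] - 1) * n;
        for (int i = 0; i < n; ++i) g[i] += zj[i] * eff[m];
      }
      double gm = 0; for (int i = 0; i < n; ++i) gm += g[i];
      gm /= n;
      double vg = 0; for (int i = 0; i < n; ++i) vg += (g[i] - gm) * (g[i] - gm);
      vg = (n > 1) ? vg / (n - 1) : 0.0;
      saved_idx[state] = wrap(idx);
      saved_eff[state] = wrap(eff);
      out_s2e[state] = sigma2e;
      out_varg[state] = vg;
      out_nincl[state] = (int)idx.size();
      for (int l = 0; l < p; ++l) out_b(l, state) = b[l];
      for (size_t m = 0; m < idx.size(); ++m) {
        incl_freq[idx[m] - 1] += 1.0;
        eff_sum[idx[m] - 1] += eff[m];
      }
      ++state;
    }
  }

  NumericVector pincl(k), pmean(k);
  for (int j = 0; j < k; ++j) {
    pincl[j] = n_states > 0 ? incl_freq[j] / n_states : 0.0;
    pmean[j] = n_states > 0 ? eff_sum[j] / n_states : 0.0;
  }
  return List::create(
    _["effect_idx"] = saved_idx, _["effect_val"] = saved_eff,
    _["sigma2_e"] = out_s2e, _["var_g"] = out_varg,
    _["n_included"] = out_nincl, _["b"] = out_b,
    _["post_inclusion"] = pincl, _["post_mean_effect"] = pmean,
    _["audit_max"] = audit_max);
}
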