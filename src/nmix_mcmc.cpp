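#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the stratified multispecies N-mixture
// model, partially collapsed over the latent abundances. Sweep order:
// detection parameters and random effects are updated conditional on N;
// abundance-side species parameters use random-walk proposals accepted
// against the likelihood with N summed out over its truncated support
// (breaking the slow lambda-N coupling of plain data augmentation); the
// community means with normal hyperpriors are drawn from their conjugate
// normal full conditionals, detection-intercept means (standard-logistic
// prior on the logit scale) and all standard deviations (uniform(0,10)) use
// random walks; finally N is re-imputed exactly from its truncated full
// conditional. Proposal scales adapt during burn-in only (target acceptance
// 0.2-0.5) and are frozen afterwards so the post-burn-in chain is a valid
// fixed-kernel Markov chain.

static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return 0.0;
  return std::log1p(std::exp(x));
}

struct Adapt {
  double scale;
  int n_prop, n_acc;
  long tot_prop, tot_acc;
  Adapt() : scale(0.5), n_prop(0), n_acc(0), tot_prop(0), tot_acc(0) {}
  void tally(bool acc) {
    n_prop++; tot_prop++;
    if (acc) { n_acc++; tot_acc++; }
  }
  void window_adapt() {
    if (n_prop >= 50) {
      double r = (double)n_acc / n_prop;
      if (r < 0.2) scale *= 0.8;
      else if (r > 0.5) scale *= 1.25;
      n_prop = 0; n_acc = 0;
    }
  }
  double rate() const { return tot_prop ? (double)tot_acc / tot_prop : NA_REAL; }
};

// family order: 0 beta_can, 1 beta_und, 2 beta1, 3 alpha_can, 4 alpha_und,
// 5 alpha1, 6 alpha2
// [[Rcpp::export]]
List nmix_mcmc_cpp(IntegerVector y, LogicalMatrix mask,
                   IntegerVector strata, NumericVector temp_site,
                   IntegerVector su, IntegerVector sm,
                   int n_su, int n_sm,
                   NumericMatrix date_obs, NumericMatrix temp_obs,
                   IntegerMatrix lo, IntegerMatrix hi,
                   NumericMatrix sp_init, NumericVector s_init,
                   NumericVector m_init, double sigma_s_init,
                   double sigma_m_init, NumericVector mu_init,
                   NumericVector sd_init, IntegerMatrix N_init,
                   int n_iter, int n_burn, int thin,
                   LogicalVector fix_species, LogicalVector fix_mu,
                   LogicalVector fix_sd, bool fix_re, bool fix_sigma,
                   bool fix_N) {
  IntegerVector dims = y.attr("dim");
  const int I = dims[0], J = dims[1], K = dims[2];
  auto Y = [&](int i, int j, int k) { return y[i + I * (j + (long)J * k)]; };

  // current state
  NumericMatrix sp = clone(sp_init);           // K x 7
  std::vector<double> s(s_init.begin(), s_init.end());
  std::vector<double> m(m_init.begin(), m_init.end());
  double sigma_s = sigma_s_init, sigma_m = sigma_m_init;
  std::vector<double> mu(mu_init.begin(), mu_init.end());
  std::vector<double> sdv(sd_init.begin(), sd_init.end());
  IntegerMatrix N = clone(N_init);             // I x K

  // caches
  NumericMatrix log_lam(I, K), lam(I, K);
  std::vector<double> lp(I * J * (long)K), lq(I * J * (long)K);
  auto pidx = [&](int i, int j, int k) { return i + I * (j + (long)J * k); };

  auto eta_abund = [&](int i, int k) {
    return sp(k, 0) * (1 - strata[i]) + sp(k, 1) * strata[i] +
           sp(k, 2) * temp_site[i] + s[su[i]] + m[sm[i]];
  };
  auto eta_det = [&](int i, int j, int k) {
    return sp(k, 3) * (1 - strata[i]) + sp(k, 4) * strata[i] +
           sp(k, 5) * date_obs(i, j) + sp(k, 6) * temp_obs(i, j);
  };
  auto refresh_lambda_col = [&](int k) {
    for (int i = 0; i < I; ++i) {
      log_lam(i, k) = eta_abund(i, k);
      lam(i, k) = std::exp(log_lam(i, k));
    }
  };
  auto refresh_p_col = [&](int k) {
    for (int i = 0; i < I; ++i)
      for (int j = 0; j < J; ++j) {
        double e = eta_det(i, j, k);
        lp[pidx(i, j, k)] = -softplus(-e);
        lq[pidx(i, j, k)] = -softplus(e);
      }
  };
  for (int k = 0; k < K; ++k) { refresh_lambda_col(k); refresh_p_col(k); }

  // snapshot buffers for global moves (restored on rejection)
  NumericMatrix lam_bak(I, K), log_lam_bak(I, K);
  std::vector<double> lp_bak(lp.size()), lq_bak(lq.size());
  auto save_lam = [&]() { lam_bak = clone(lam); log_lam_bak = clone(log_lam); };
  auto restore_lam = [&]() { lam = clone(lam_bak); log_lam = clone(log_lam_bak); };
  auto save_p = [&]() { lp_bak = lp; lq_bak = lq; };
  auto restore_p = [&]() { lp = lp_bak; lq = lq_bak; };

  // surveyed occasions per site
  std::vector<std::vector<int>> occ(I);
  for (int i = 0; i < I; ++i)
    for (int j = 0; j < J; ++j)
      if (mask(i, j)) occ[i].push_back(j);

  // sites whose likelihood a family's parameters can touch: canopy
  // intercepts only act on strata-0 sites, understory on strata-1,
  // slopes on all
  std::vector<std::vector<int>> fam_sites(7);
  for (int i = 0; i < I; ++i) {
    if (strata[i] == 0) { fam_sites[0].push_back(i); fam_sites[3].push_back(i); }
    else { fam_sites[1].push_back(i); fam_sites[4].push_back(i); }
    fam_sites[2].push_back(i); fam_sites[5].push_back(i); fam_sites[6].push_back(i);
  }

  // log of sum_{N=lo..hi} w(N) with w(lo) = 1 and the binomial/Poisson
  // weight recursion; lam_q = lambda * prod_j (1 - p_j)
  auto log_weight_sum = [&](int i, int k, int nlo, int nhi, double lam_q) {
    double cur = 1.0, total = 1.0, log_scale = 0.0;
    for (int n = nlo; n < nhi; ++n) {
      double r = lam_q / (n + 1.0);
      for (int j : occ[i]) {
        int yv = Y(i, j, k);
        r *= (n + 1.0) / (n + 1.0 - yv);
      }
      cur *= r;
      if (cur > 1e250) { cur *= 1e-250; total *= 1e-250; log_scale += 250.0 * M_LN10; }
      total += cur;
      if (r < 1.0 && cur < 1e-14 * total) break;  // tail is negligible
    }
    return std::log(total) + log_scale;
  };

  // log marginal likelihood contribution of (i, k) up to N-free constants:
  // log sum_N Pois(N; lam) prod_j Bin(y_j; N, p_j); the sum is anchored at
  // N = lo, whose Poisson and binomial terms (minus fixed combinatorial
  // constants) are written out so the value is usable in ratios across both
  // abundance and detection parameters
  auto log_marg = [&](int i, int k) {
    double qsum = 0.0, anchor = 0.0;
    const int l = lo(i, k);
    for (int j : occ[i]) {
      int yv = Y(i, j, k);
      anchor += yv * lp[pidx(i, j, k)] + (l - yv) * lq[pidx(i, j, k)];
      qsum += lq[pidx(i, j, k)];
    }
    double lam_q = lam(i, k) * std::exp(qsum);
    return l * log_lam(i, k) - lam(i, k) + anchor +
           log_weight_sum(i, k, l, hi(i, k), lam_q);
  };

  // adaptation blocks
  std::vector<std::vector<Adapt>> ad_sp(7, std::vector<Adapt>(K));
  std::vector<Adapt> ad_sd(7), ad_tr(7), ad_ridge(2), ad_sc(7);
  Adapt ad_s, ad_m, ad_sig, ad_mu;
  for (int f = 0; f < 7; ++f) {
    for (int k = 0; k < K; ++k) ad_sp[f][k].scale = 0.3;
    ad_sd[f].scale = 0.3; ad_tr[f].scale = 0.2;
    ad_sc[f].scale = 0.2;
  }
  ad_ridge[0].scale = 0.2; ad_ridge[1].scale = 0.2;
  Adapt ad_re_tr[2]; ad_re_tr[0].scale = 0.3; ad_re_tr[1].scale = 0.3;
  Adapt ad_re_sc[2]; ad_re_sc[0].scale = 0.3; ad_re_sc[1].scale = 0.3;
  ad_s.scale = 0.3; ad_m.scale = 0.3; ad_sig.scale = 0.3; ad_mu.scale = 0.5;

  const int n_keep = (n_iter - n_burn) / thin;
  NumericMatrix hyper_draws(std::max(n_keep, 0), 16);
  NumericVector species_draws((long)std::max(n_keep, 0) * K * 7);
  NumericMatrix re_draws(std::max(n_keep, 0), n_su + n_sm);
  IntegerVector N_draws((long)std::max(n_keep, 0) * I * K);
  int kept = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    bool adapting = iter <= n_burn;

    // --- species-specific parameters --------------------------------------
    auto update_family = [&](int f) {
      if (fix_species[f]) return;
      const std::vector<int> &sites = fam_sites[f];
      for (int k = 0; k < K; ++k) {
        double cur = sp(k, f);
        double prop = cur + ad_sp[f][k].scale * R::rnorm(0.0, 1.0);
        double lr = R::dnorm(prop, mu[f], sdv[f], 1) -
                    R::dnorm(cur, mu[f], sdv[f], 1);
        bool ok = true;
        if (f < 3) {
          // abundance side: N integrated out over its truncated support
          for (int i : sites) lr -= log_marg(i, k);
          sp(k, f) = prop;
          for (int i : sites) {
            double e_new = eta_abund(i, k);
            if (!R_finite(std::exp(e_new))) { ok = false; break; }
          }
          if (ok) {
            refresh_lambda_col(k);
            for (int i : sites) lr += log_marg(i, k);
          }
          sp(k, f) = cur;
          if (!ok || !(std::log(R::runif(0.0, 1.0)) < lr)) {
            refresh_lambda_col(k);  // restore cache
            ad_sp[f][k].tally(false);
          } else {
            sp(k, f) = prop;
            refresh_lambda_col(k);
            ad_sp[f][k].tally(true);
          }
        } else {
          // detection side: N integrated out as well, so the chain can move
          // along the abundance-detection ridge without dragging N
          for (int i : sites) lr -= log_marg(i, k);
          sp(k, f) = prop;
          refresh_p_col(k);
          for (int i : sites) lr += log_marg(i, k);
          if (!(std::log(R::runif(0.0, 1.0)) < lr)) {
            sp(k, f) = cur;
            refresh_p_col(k);
            ad_sp[f][k].tally(false);
          } else {
            ad_sp[f][k].tally(true);
          }
        }
        if (adapting) ad_sp[f][k].window_adapt();
      }
    };

    // --- random effects (marginal over N, like the species parameters) -----
    auto update_group_effect = [&](std::vector<double> &eff, double sigma,
                                   IntegerVector &grp, int g, Adapt &ad) {
      double d = ad.scale * R::rnorm(0.0, 1.0);
      double lr = R::dnorm(eff[g] + d, 0.0, sigma, 1) -
                  R::dnorm(eff[g], 0.0, sigma, 1);
      double ed = std::exp(d);
      for (int i = 0; i < I; ++i) {
        if (grp[i] != g) continue;
        for (int k = 0; k < K; ++k) lr -= log_marg(i, k);
      }
      for (int i = 0; i < I; ++i) {
        if (grp[i] != g) continue;
        for (int k = 0; k < K; ++k) { log_lam(i, k) += d; lam(i, k) *= ed; }
      }
      for (int i = 0; i < I; ++i) {
        if (grp[i] != g) continue;
        for (int k = 0; k < K; ++k) lr += log_marg(i, k);
      }
      bool acc = std::log(R::runif(0.0, 1.0)) < lr;
      if (acc) {
        eff[g] += d;
      } else {
        for (int i = 0; i < I; ++i) {
          if (grp[i] != g) continue;
          for (int k = 0; k < K; ++k) { log_lam(i, k) -= d; lam(i, k) /= ed; }
        }
      }
      ad.tally(acc);
    };
    if (!fix_re) {
      for (int u = 0; u < n_su; ++u) update_group_effect(s, sigma_s, su, u, ad_s);
      for (int g = 0; g < n_sm; ++g) update_group_effect(m, sigma_m, sm, g, ad_m);
      if (adapting) { ad_s.window_adapt(); ad_m.window_adapt(); }
    }

    // --- random-effect sds (uniform(0,10) prior) ---------------------------
    if (!fix_sigma) {
      {
        double prop = sigma_s + ad_sig.scale * R::rnorm(0.0, 1.0);
        bool acc = false;
        if (prop > 0.0 && prop <= 10.0) {
          double ss = 0.0;
          for (int u = 0; u < n_su; ++u) ss += s[u] * s[u];
          double lr = -n_su * std::log(prop / sigma_s) -
                      0.5 * ss * (1.0 / (prop * prop) - 1.0 / (sigma_s * sigma_s));
          acc = std::log(R::runif(0.0, 1.0)) < lr;
          if (acc) sigma_s = prop;
        }
        ad_sig.tally(acc);
      }
      {
        double prop = sigma_m + ad_sig.scale * R::rnorm(0.0, 1.0);
        bool acc = false;
        if (prop > 0.0 && prop <= 10.0) {
          double ss = 0.0;
          for (int g = 0; g < n_sm; ++g) ss += m[g] * m[g];
          double lr = -n_sm * std::log(prop / sigma_m) -
                      0.5 * ss * (1.0 / (prop * prop) - 1.0 / (sigma_m * sigma_m));
          acc = std::log(R::runif(0.0, 1.0)) < lr;
          if (acc) sigma_m = prop;
        }
        ad_sig.tally(acc);
      }
      if (adapting) ad_sig.window_adapt();
    }

    // species parameters: N is integrated out in every family's update and
    // re-imputed below, so no later update in this sweep may condition on
    // the (stale) N
    for (int f = 0; f < 7; ++f) update_family(f);

    // joint translation per family: shift the community mean and all
    // species parameters together, leaving the species-level prior terms
    // unchanged; breaks the slow random-walk of a location through its
    // group (only the hyperprior on the mean and the likelihood react)
    auto translate_family = [&](int f) {
      if (fix_species[f] || fix_mu[f]) return;
      double d = ad_tr[f].scale * R::rnorm(0.0, 1.0);
      double mu_new = mu[f] + d;
      double lr;
      if (f == 3 || f == 4) {
        lr = (-mu_new - 2.0 * softplus(-mu_new)) - (-mu[f] - 2.0 * softplus(-mu[f]));
      } else {
        lr = R::dnorm(mu_new, 0.0, std::sqrt(1000.0), 1) -
             R::dnorm(mu[f], 0.0, std::sqrt(1000.0), 1);
      }
      for (int i : fam_sites[f])
        for (int k = 0; k < K; ++k) lr -= log_marg(i, k);
      if (f < 3) save_lam(); else save_p();
      for (int k = 0; k < K; ++k) sp(k, f) += d;
      if (f < 3) for (int k = 0; k < K; ++k) refresh_lambda_col(k);
      else for (int k = 0; k < K; ++k) refresh_p_col(k);
      bool ok = true;
      for (int i = 0; i < I && ok; ++i)
        for (int k = 0; k < K; ++k) if (!R_finite(lam(i, k))) { ok = false; break; }
      if (ok)
        for (int i : fam_sites[f])
          for (int k = 0; k < K; ++k) lr += log_marg(i, k);
      bool acc = ok && std::log(R::runif(0.0, 1.0)) < lr;
      if (acc) {
        mu[f] = mu_new;
      } else {
        for (int k = 0; k < K; ++k) sp(k, f) -= d;
        if (f < 3) restore_lam(); else restore_p();
      }
      ad_tr[f].tally(acc);
      if (adapting) ad_tr[f].window_adapt();
    };
    for (int f = 0; f < 7; ++f) translate_family(f);

    // anti-correlated pair translation along the abundance-detection ridge
    // of one stratum: more animals seen less often fits the counts nearly
    // as well, so (beta, alpha) intercept families are shifted oppositely
    auto ridge_move = [&](int bf, int af, Adapt &ad) {
      if (fix_species[bf] || fix_mu[bf] || fix_species[af] || fix_mu[af]) return;
      double d = ad.scale * R::rnorm(0.0, 1.0);
      double mu_b = mu[bf] + d, mu_a = mu[af] - d;
      double lr = R::dnorm(mu_b, 0.0, std::sqrt(1000.0), 1) -
                  R::dnorm(mu[bf], 0.0, std::sqrt(1000.0), 1) +
                  (-mu_a - 2.0 * softplus(-mu_a)) -
                  (-mu[af] - 2.0 * softplus(-mu[af]));
      for (int i : fam_sites[bf])
        for (int k = 0; k < K; ++k) lr -= log_marg(i, k);
      save_lam(); save_p();
      for (int k = 0; k < K; ++k) { sp(k, bf) += d; sp(k, af) -= d; }
      for (int k = 0; k < K; ++k) { refresh_lambda_col(k); refresh_p_col(k); }
      bool ok = true;
      for (int i = 0; i < I && ok; ++i)
        for (int k = 0; k < K; ++k) if (!R_finite(lam(i, k))) { ok = false; break; }
      if (ok)
        for (int i : fam_sites[bf])
          for (int k = 0; k < K; ++k) lr += log_marg(i, k);
      bool acc = ok && std::log(R::runif(0.0, 1.0)) < lr;
      if (acc) {
        mu[bf] = mu_b; mu[af] = mu_a;
      } else {
        for (int k = 0; k < K; ++k) { sp(k, bf) -= d; sp(k, af) += d; }
        restore_lam(); restore_p();
      }
      ad.tally(acc);
      if (adapting) ad.window_adapt();
    };
    ridge_move(0, 3, ad_ridge[0]);
    ridge_move(1, 4, ad_ridge[1]);

    // scale interweaving: rescale a family's deviations about its mean
    // together with its sd (multiplicative walk); the standardized
    // residuals are invariant, so only the uniform support, the Jacobian
    // and the likelihood react -- this decouples the sd from its slowly
    // moving species parameters
    auto rescale_family = [&](int f) {
      if (fix_species[f] || fix_sd[f]) return;
      double lc = ad_sc[f].scale * R::rnorm(0.0, 1.0);
      double c = std::exp(lc);
      double sd_new = sdv[f] * c;
      bool ok = sd_new > 0.0 && sd_new <= 10.0;
      double lr = lc;  // prior terms + Jacobian collapse to +log c
      if (ok) {
        for (int i : fam_sites[f])
          for (int k = 0; k < K; ++k) lr -= log_marg(i, k);
        std::vector<double> col_bak(K);
        for (int k = 0; k < K; ++k) col_bak[k] = sp(k, f);
        if (f < 3) save_lam(); else save_p();
        for (int k = 0; k < K; ++k) sp(k, f) = mu[f] + c * (sp(k, f) - mu[f]);
        if (f < 3) for (int k = 0; k < K; ++k) refresh_lambda_col(k);
        else for (int k = 0; k < K; ++k) refresh_p_col(k);
        for (int i = 0; i < I && ok; ++i)
          for (int k = 0; k < K; ++k) if (!R_finite(lam(i, k))) { ok = false; break; }
        if (ok)
          for (int i : fam_sites[f])
            for (int k = 0; k < K; ++k) lr += log_marg(i, k);
        bool acc = ok && std::log(R::runif(0.0, 1.0)) < lr;
        if (acc) {
          sdv[f] = sd_new;
        } else {
          for (int k = 0; k < K; ++k) sp(k, f) = col_bak[k];
          if (f < 3) restore_lam(); else restore_p();
        }
        ad_sc[f].tally(acc);
      } else {
        ad_sc[f].tally(false);
      }
      if (adapting) ad_sc[f].window_adapt();
    };
    for (int f = 0; f < 7; ++f) rescale_family(f);

    // exact flat direction: adding d to every group effect while removing
    // d from both stratum abundance-intercept families leaves every lambda
    // unchanged; only the zero-mean prior of the effects and the
    // hyperpriors on the two means react, so the move costs no likelihood
    auto re_mean_shift = [&](std::vector<double> &eff, int n_eff, double sigma,
                             Adapt &ad) {
      if (fix_re || fix_species[0] || fix_species[1] || fix_mu[0] || fix_mu[1]) return;
      double d = ad.scale * R::rnorm(0.0, 1.0);
      double lr = 0.0;
      for (int u = 0; u < n_eff; ++u)
        lr += R::dnorm(eff[u] + d, 0.0, sigma, 1) - R::dnorm(eff[u], 0.0, sigma, 1);
      lr += R::dnorm(mu[0] - d, 0.0, std::sqrt(1000.0), 1) -
            R::dnorm(mu[0], 0.0, std::sqrt(1000.0), 1) +
            R::dnorm(mu[1] - d, 0.0, std::sqrt(1000.0), 1) -
            R::dnorm(mu[1], 0.0, std::sqrt(1000.0), 1);
      bool acc = std::log(R::runif(0.0, 1.0)) < lr;
      if (acc) {
        for (int u = 0; u < n_eff; ++u) eff[u] += d;
        for (int k = 0; k < K; ++k) { sp(k, 0) -= d; sp(k, 1) -= d; }
        mu[0] -= d; mu[1] -= d;
        // lambda is unchanged by construction; caches stay valid
      }
      ad.tally(acc);
      if (adapting) ad.window_adapt();
    };
    re_mean_shift(s, n_su, sigma_s, ad_re_tr[0]);
    re_mean_shift(m, n_sm, sigma_m, ad_re_tr[1]);

    // scale interweaving for a random-effect block: multiply every group
    // effect and its sd by a common factor; standardized effects are
    // invariant, so priors + Jacobian collapse to +log c and only the
    // likelihood (through lambda) reacts
    auto re_rescale = [&](std::vector<double> &eff, int n_eff, double &sigma,
                          Adapt &ad) {
      if (fix_re || fix_sigma) return;
      double lc = ad.scale * R::rnorm(0.0, 1.0);
      double c = std::exp(lc);
      double sig_new = sigma * c;
      if (sig_new <= 0.0 || sig_new > 10.0) { ad.tally(false); if (adapting) ad.window_adapt(); return; }
      double lr = lc;
      for (int i = 0; i < I; ++i)
        for (int k = 0; k < K; ++k) lr -= log_marg(i, k);
      save_lam();
      for (int u = 0; u < n_eff; ++u) eff[u] *= c;
      for (int k = 0; k < K; ++k) refresh_lambda_col(k);
      bool ok = true;
      for (int i = 0; i < I && ok; ++i)
        for (int k = 0; k < K; ++k) if (!R_finite(lam(i, k))) { ok = false; break; }
      if (ok)
        for (int i = 0; i < I; ++i)
          for (int k = 0; k < K; ++k) lr += log_marg(i, k);
      bool acc = ok && std::log(R::runif(0.0, 1.0)) < lr;
      if (acc) {
        sigma = sig_new;
      } else {
        for (int u = 0; u < n_eff; ++u) eff[u] /= c;
        restore_lam();
      }
      ad.tally(acc);
      if (adapting) ad.window_adapt();
    };
    re_rescale(s, n_su, sigma_s, ad_re_sc[0]);
    re_rescale(m, n_sm, sigma_m, ad_re_sc[1]);

    // --- community means ---------------------------------------------------
    for (int f = 0; f < 7; ++f) {
      if (fix_mu[f]) continue;
      double sum = 0.0;
      for (int k = 0; k < K; ++k) sum += sp(k, f);
      if (f == 3 || f == 4) {
        // uniform(0,1) prior on the probability scale = standard logistic on mu
        double cur = mu[f];
        double prop = cur + ad_mu.scale * R::rnorm(0.0, 1.0);
        double v = sdv[f] * sdv[f];
        double lr = (sum * (prop - cur) - 0.5 * K * (prop * prop - cur * cur)) / v;
        lr += (-prop - 2.0 * softplus(-prop)) - (-cur - 2.0 * softplus(-cur));
        bool acc = std::log(R::runif(0.0, 1.0)) < lr;
        if (acc) mu[f] = prop;
        ad_mu.tally(acc);
      } else {
        // conjugate normal-normal draw; hyperprior N(0, variance 1000)
        double prec = K / (sdv[f] * sdv[f]) + 1.0 / 1000.0;
        double mean = (sum / (sdv[f] * sdv[f])) / prec;
        mu[f] = R::rnorm(mean, std::sqrt(1.0 / prec));
      }
    }
    if (adapting) ad_mu.window_adapt();

    // --- community sds (uniform(0,10) prior) -------------------------------
    for (int f = 0; f < 7; ++f) {
      if (fix_sd[f]) continue;
      double prop = sdv[f] + ad_sd[f].scale * R::rnorm(0.0, 1.0);
      bool acc = false;
      if (prop > 0.0 && prop <= 10.0) {
        double ss = 0.0;
        for (int k = 0; k < K; ++k) {
          double d = sp(k, f) - mu[f];
          ss += d * d;
        }
        double lr = -K * std::log(prop / sdv[f]) -
                    0.5 * ss * (1.0 / (prop * prop) - 1.0 / (sdv[f] * sdv[f]));
        acc = std::log(R::runif(0.0, 1.0)) < lr;
        if (acc) sdv[f] = prop;
      }
      ad_sd[f].tally(acc);
      if (adapting) ad_sd[f].window_adapt();
    }

    // --- latent abundances -------------------------------------------------
    // exact Gibbs draw from the truncated full conditional
    //   pi(N) ~ Poisson(N; lambda) * prod_j Binomial(y_j; N, p_j),
    // enumerated on [lo, hi] via the stable weight recursion
    //   w(N+1)/w(N) = lambda * prod_j (1 - p_j) / (N+1) * prod_j (N+1)/(N+1-y_j)
    if (!fix_N) {
      std::vector<double> w(0);
      for (int i = 0; i < I; ++i) {
        for (int k = 0; k < K; ++k) {
          const int nlo = lo(i, k), nhi = hi(i, k);
          const int len = nhi - nlo + 1;
          if ((int)w.size() < len) w.resize(len);
          double qprod = 0.0;
          for (int j : occ[i]) qprod += lq[pidx(i, j, k)];
          const double lam_q = lam(i, k) * std::exp(qprod);
          double cur = 1.0, total = 1.0;
          w[0] = 1.0;
          int last = 0;
          for (int n = nlo; n < nhi; ++n) {
            double r = lam_q / (n + 1.0);
            for (int j : occ[i]) {
              int yv = Y(i, j, k);
              r *= (n + 1.0) / (n + 1.0 - yv);
            }
            cur *= r;
            if (cur > 1e250) {  // rescale to keep weights finite
              double f = 1e-250;
              for (int t = 0; t <= n - nlo; ++t) w[t] *= f;
              cur *= f; total *= f;
            }
            w[n - nlo + 1] = cur;
            total += cur;
            last = n - nlo + 1;
            if (r < 1.0 && cur < 1e-14 * total) break;  // tail negligible
          }
          double u = R::runif(0.0, total);
          double acc = 0.0;
          int pick = nlo + last;
          for (int t = 0; t <= last; ++t) {
            acc += w[t];
            if (u <= acc) { pick = nlo + t; break; }
          }
          N(i, k) = pick;
        }
      }
    }


    // --- retain ------------------------------------------------------------
    if (iter > n_burn && (iter - n_burn) % thin == 0) {
      for (int f = 0; f < 7; ++f) {
        hyper_draws(kept, f) = mu[f];
        hyper_draws(kept, 7 + f) = sdv[f];
      }
      hyper_draws(kept, 14) = sigma_s;
      hyper_draws(kept, 15) = sigma_m;
      for (int f = 0; f < 7; ++f)
        for (int k = 0; k < K; ++k)
          species_draws[kept + (long)n_keep * (k + (long)K * f)] = sp(k, f);
      for (int u = 0; u < n_su; ++u) re_draws(kept, u) = s[u];
      for (int g = 0; g < n_sm; ++g) re_draws(kept, n_su + g) = m[g];
      for (int k = 0; k < K; ++k)
        for (int i = 0; i < I; ++i)
          N_draws[kept + (long)n_keep * (i + (long)I * k)] = N(i, k);
      kept++;
    }
  }

  NumericVector acc_sp(7), acc_sd(7);
  for (int f = 0; f < 7; ++f) {
    double a = 0.0;
    for (int k = 0; k < K; ++k) a += ad_sp[f][k].rate();
    acc_sp[f] = a / K;
    acc_sd[f] = ad_sd[f].rate();
  }
  species_draws.attr("dim") = IntegerVector::create(n_keep, K, 7);
  N_draws.attr("dim") = IntegerVector::create(n_keep, I, K);
  return List::create(
    _["hyper"] = hyper_draws, _["species"] = species_draws,
    _["re"] = re_draws, _["N"] = N_draws,
    _["accept"] = List::create(_["species"] = acc_sp, _["sd"] = acc_sd,
                               _["s"] = ad_s.rate(), _["m"] = ad_m.rate(),
                               _["sigma"] = ad_sig.rate(), _["mu_logit"] = ad_mu.rate())
  );
}
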