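# small in-code fixtures shared across test files

# two canopy sites, two occasions, one species; covariates all zero so the
# linear predictors collapse to the intercepts
toy_dh_1sp <- function(y = c(1L, 2L, 0L, 3L)) {
  design <- site_design(strata = c(0L, 0L), temp_site = c(0, 0),
                        su = c(1, 1), sm = c(1, 1),
                        date_obs = matrix(0, 2, 2), temp_obs = matrix(0, 2, 2))
  detection_history(array(y, c(2, 2, 1)), design)
}

toy_tree <- function() {
  ape::read.tree(text = "((spA:1,spB:1):1,(spC:1.5,spD:0.5):2):0.5;")
}

toy_traits <- function(n = 4, labels = paste0("sp", c("A", "B", "C", "D"))) {
  set.seed(99)
  tibble::tibble(species = labels[seq_len(n)],
                 cont1 = rnorm(n), cont2 = runif(n),
                 bin1 = rep_len(c(0, 1), n))
}

# brute-force marginal likelihood by dense enumeration over N (independent
# oracle: no shared code with marginal_loglik_truncated)
enum_marginal <- function(dh, params, re, Nmax = 100) {
  lam <- lambda_matrix(params, re, dh$design)
  p <- detection_prob_array(params, dh$design)
  total <- 0
  for (i in seq_len(dh$n_sites)) {
    js <- which(dh$mask[i, ])
    for (k in seq_len(dh$n_species)) {
      lo <- max(dh$y[i, js, k])
      terms <- vapply(lo:Nmax, function(N) {
        dpois(N, lam[i, k]) * prod(dbinom(dh$y[i, js, k], N, p[i, js, k]))
      }, 0)
      total <- total + log(sum(terms))
    }
  }
  total
}

# one small fitted model, computed once per test run
cached_small_fit <- local({
  env <- new.env()
  function() {
    if (is.null(env$fit)) {
      env$sim <- simulate_metacommunity(n_species = 6, n_sites = 8, seed = 31)
      env$fit <- fit_nmixture(env$sim$dh,
                              mcmc_config(2, 1200, 600, thin = 3, seed = 17))
    }
    list(sim = env$sim, fit = env$fit)
  }
})
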