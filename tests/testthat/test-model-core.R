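test_that("expected abundance follows the stratified log-linear predictor", {
  design <- site_design(strata = c(0L, 1L), temp_site = c(1, -1),
                        su = c(1, 2), sm = c(1, 1),
                        date_obs = matrix(0, 2, 3), temp_obs = matrix(0, 2, 3))
  re0 <- random_effects(c(0, 0), 0, 1, 1)

  # all coefficients and random effects zero -> lambda = 1
  p0 <- species_params(beta_can = 0, beta_und = 0)
  expect_equal(expected_abundance(p0, re0, design, 1, 1), 1)

  # canopy site: only the canopy intercept enters; the understory intercept
  # is inert there (and vice versa)
  pc <- species_params(beta_can = log(4), beta_und = 99)
  expect_equal(expected_abundance(pc, re0, design, 1, 1) /
                 exp(pc$beta1[1] * design$temp_site[1]), 4)
  pu <- species_params(beta_can = 99, beta_und = log(4))
  expect_equal(expected_abundance(pu, re0, design, 2, 1) /
                 exp(pu$beta1[1] * design$temp_site[2]), 4)

  # hand evaluation: exp(ln 2 + ln 1.5 * 1) = 3 at a canopy site with Temp 1
  ph <- species_params(beta_can = log(2), beta_und = 0, beta1 = log(1.5))
  expect_equal(expected_abundance(ph, re0, design, 1, 1), 3)

  # random effects enter additively on the log scale
  re <- random_effects(c(0.5, 0), c(-0.2), 1, 1)
  expect_equal(expected_abundance(p0, re, design, 1, 1), exp(0.5 - 0.2))

  expect_error(expected_abundance(p0, re0, design, 3, 1), "out of range")
})

test_that("detection probability follows the stratified logit-linear predictor", {
  design <- site_design(strata = c(0L, 1L), temp_site = c(0, 0),
                        su = c(1, 1), sm = c(1, 1),
                        date_obs = matrix(c(-1, 0, 0, 0), 2, 2),
                        temp_obs = matrix(0, 2, 2))
  p0 <- species_params(beta_can = 0, beta_und = 0)
  expect_equal(detection_prob(p0, design, 2, 2, 1), 0.5)

  p8 <- species_params(beta_can = 0, beta_und = 0, alpha_und = qlogis(0.8))
  expect_equal(detection_prob(p8, design, 2, 2, 1), 0.8)

  # alpha1 = 1, Date = -1 at a canopy site -> 1 / (1 + e)
  p1 <- species_params(beta_can = 0, beta_und = 0, alpha1 = 1)
  expect_equal(detection_prob(p1, design, 1, 1, 1), 1 / (1 + exp(1)))
  expect_error(detection_prob(p0, design, 1, 5, 1), "out of range")
})

test_that("abundance and detection are invariant to swapping strata with intercepts", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 6
    design <- site_design(strata = sample(0:1, n, TRUE), temp_site = rnorm(n),
                          su = rep(1:3, each = 2), sm = rep(1:2, 3),
                          date_obs = matrix(rnorm(n * 2), n, 2),
                          temp_obs = matrix(rnorm(n * 2), n, 2),)
    flipped <- design
    flipped$strata <- 1L - design$strata
    pars <- species_params(beta_can = rnorm(3), beta_und = rnorm(3),
                           beta1 = rnorm(3), alpha_can = rnorm(3),
                           alpha_und = rnorm(3), alpha1 = rnorm(3),
                           alpha2 = rnorm(3))
    swapped <- pars
    swapped$beta_can <- pars$beta_und; swapped$beta_und <- pars$beta_can
    swapped$alpha_can <- pars$alpha_und; swapped$alpha_und <- pars$alpha_can
    re <- random_effects(rnorm(3), rnorm(2), 1, 1)
    expect_equal(lambda_matrix(pars, re, design),
                 lambda_matrix(swapped, re, flipped))
    expect_equal(detection_prob_array(pars, design),
                 detection_prob_array(swapped, flipped))
  }
})

test_that("joint log-likelihood matches closed-form pmf products", {
  # single site/species/occasion with N = 0, y = 0: only the Poisson zero term
  design1 <- site_design(strata = 0L, temp_site = 0, su = 1, sm = 1,
                         date_obs = matrix(0, 1, 1), temp_obs = matrix(0, 1, 1))
  dh1 <- detection_history(array(0L, c(1, 1, 1)), design1)
  lam <- 1.7
  pars <- species_params(beta_can = log(lam), beta_und = 0)
  re <- random_effects(0, 0, 1, 1)
  expect_equal(joint_loglik(dh1, matrix(0L, 1, 1), pars, re), -lam)

  # y > N is outside the binomial support
  dh1b <- detection_history(array(2L, c(1, 1, 1)), design1)
  expect_equal(joint_loglik(dh1b, matrix(1L, 1, 1), pars, re), -Inf)

  # 1 site, 2 occasions, N = 3, y = (2, 1), lambda = 2, p = 0.5
  design2 <- site_design(strata = 0L, temp_site = 0, su = 1, sm = 1,
                         date_obs = matrix(0, 1, 2), temp_obs = matrix(0, 1, 2))
  dh2 <- detection_history(array(c(2L, 1L), c(1, 2, 1)), design2)
  pars2 <- species_params(beta_can = log(2), beta_und = 0)
  expect_equal(joint_loglik(dh2, matrix(3L, 1, 1), pars2, re),
               dpois(3, 2, log = TRUE) + dbinom(2, 3, 0.5, log = TRUE) +
                 dbinom(1, 3, 0.5, log = TRUE))

  # masked occasions are excluded from the sum
  dh3 <- detection_history(array(c(2L, 9L), c(1, 2, 1)), design2,
                           mask = matrix(c(TRUE, FALSE), 1, 2))
  expect_equal(joint_loglik(dh3, matrix(3L, 1, 1), pars2, re),
               dpois(3, 2, log = TRUE) + dbinom(2, 3, 0.5, log = TRUE))
})

test_that("truncated marginal likelihood agrees with dense enumeration", {
  dh <- toy_dh_1sp()
  pars <- species_params(beta_can = 0.7, beta_und = 0)
  re <- random_effects(0, 0, 1, 1)
  expect_equal(marginal_loglik_truncated(dh, pars, re, Nmax = 100),
               enum_marginal(dh, pars, re, Nmax = 100), tolerance = 1e-12)

  # perfect detection pins N at the maximum count: marginal = Poisson pmf
  pars1 <- species_params(beta_can = log(2), beta_und = 0,
                          alpha_can = 40)  # p numerically 1
  design1 <- site_design(strata = 0L, temp_site = 0, su = 1, sm = 1,
                         date_obs = matrix(0, 1, 2), temp_obs = matrix(0, 1, 2))
  dh1 <- detection_history(array(c(3L, 3L), c(1, 2, 1)), design1)
  expect_equal(marginal_loglik_truncated(dh1, pars1, re, 120),
               dpois(3, 2, log = TRUE), tolerance = 1e-9)

  # monotone, convergent in the truncation bound
  l1 <- marginal_loglik_truncated(dh, pars, re, 50)
  l2 <- marginal_loglik_truncated(dh, pars, re, 100)
  expect_gte(l2, l1)
  expect_equal(l1, l2, tolerance = 1e-10)
  expect_error(marginal_loglik_truncated(dh, pars, re, 2), "below the maximum")
})

test_that("log prior enforces the stated supports and hyperpriors", {
  fams <- nmix_families()
  mu <- setNames(rep(0, 7), fams)
  sdv <- setNames(rep(1, 7), fams)
  hyper <- community_hyperparams(mu, sdv)
  pars <- species_params(beta_can = c(0, 0.3), beta_und = c(0, 0))
  re <- random_effects(c(0.1), c(-0.1), 1, 1)
  expect_true(is.finite(log_prior(pars, re, hyper)))

  # any sd above 10 is outside the uniform support
  bad_sd <- hyper; bad_sd$sd["beta1"] <- 10.5
  expect_equal(log_prior(pars, re, bad_sd), -Inf)
  expect_error(community_hyperparams(mu, replace(sdv, 2, 11)), "0, 10")
  expect_equal(log_prior(pars, random_effects(0, 0, 12, 1), hyper), -Inf)

  # probability-scale detection-intercept mean outside (0,1) has no finite
  # logit: rejected
  bad_mu <- hyper; bad_mu$mu["alpha_can"] <- qlogis(1)  # Inf
  expect_equal(log_prior(pars, re, bad_mu), -Inf)

  # species parameters at their community means maximize the species-level
  # contribution for fixed sds
  at_mode <- species_params(beta_can = c(0, 0), beta_und = c(0, 0))
  expect_gt(log_prior(at_mode, re, hyper), log_prior(pars, re, hyper))

  # joint + prior finite on any state satisfying the type invariants
  set.seed(4)
  for (rep in 1:5) {
    sim <- simulate_metacommunity(n_species = 4, n_sites = 4, seed = rep)
    ll <- joint_loglik(sim$dh, sim$truth$N, sim$truth$params, sim$truth$re)
    lp <- log_prior(sim$truth$params, sim$truth$re,
                    community_hyperparams(
                      setNames(sim$truth$hyper[paste0("mu_", fams)], fams),
                      setNames(sim$truth$hyper[paste0("sd_", fams)], fams)))
    expect_true(is.finite(ll + lp))
  }
})
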