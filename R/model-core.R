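#' Parameter families of the stratified multispecies N-mixture model
#'
#' The seven species-level parameter families, in the fixed order used
#' throughout the package (columns of draw arrays, hyperparameter names):
#' canopy/understory abundance intercepts, abundance temperature slope,
#' canopy/understory detection intercepts, detection date and temperature
#' slopes.
#'
#' @return Character vector of length 7.
#' @export
nmix_families <- function() {
  c("beta_can", "beta_und", "beta1", "alpha_can", "alpha_und", "alpha1", "alpha2")
}

#' Species-specific parameters of the N-mixture model
#'
#' Log-scale abundance intercepts for canopy (`beta_can`) and understory
#' (`beta_und`), a temperature slope (`beta1`), and logit-scale detection
#' intercepts/slopes (`alpha_can`, `alpha_und`, `alpha1` for date, `alpha2`
#' for occasion temperature). All vectors have one entry per species.
#'
#' @param beta_can,beta_und,beta1,alpha_can,alpha_und,alpha1,alpha2 numeric
#'   vectors of equal length (one value per species).
#' @return An object of class `species_params`.
#' @export
species_params <- function(beta_can, beta_und, beta1 = 0 * beta_can,
                           alpha_can = 0 * beta_can, alpha_und = 0 * beta_can,
                           alpha1 = 0 * beta_can, alpha2 = 0 * beta_can) {
  out <- list(beta_can = beta_can, beta_und = beta_und, beta1 = beta1,
              alpha_can = alpha_can, alpha_und = alpha_und,
              alpha1 = alpha1, alpha2 = alpha2)
  n <- unique(lengths(out))
  if (length(n) != 1L) stop("all parameter vectors must have the same length")
  if (!all(vapply(out, function(x) all(is.finite(x)), logical(1)))) {
    stop("species parameters must be finite")
  }
  structure(c(out, list(n_species = n)), class = "species_params")
}

#' Random effects for sampling units and sampling months
#'
#' @param s numeric vector of sampling-unit effects.
#' @param m numeric vector of sampling-month effects.
#' @param sigma_s,sigma_m positive standard deviations of the two effects.
#' @return An object of class `random_effects`.
#' @export
random_effects <- function(s, m, sigma_s = 1, sigma_m = 1) {
  if (sigma_s <= 0 || sigma_m <= 0) stop("sigma_s and sigma_m must be > 0")
  structure(list(s = s, m = m, sigma_s = sigma_s, sigma_m = sigma_m),
            class = "random_effects")
}

#' Community-level hyperparameters
#'
#' Means and standard deviations of the normal hyperdistributions that the
#' species-specific parameters are drawn from, one pair per parameter family.
#' Detection-intercept means (`mu_alpha_can`, `mu_alpha_und`) are stored on
#' the logit scale; their prior is uniform on the probability scale, so their
#' inverse-logit always lies in (0, 1).
#'
#' @param mu named numeric vector over the seven families
#'   (`beta_can`, `beta_und`, `beta1`, `alpha_can`, `alpha_und`, `alpha1`,
#'   `alpha2`).
#' @param sd named numeric vector over the same families; the uniform prior
#'   restricts each to (0, 10].
#' @return An object of class `community_hyperparams`.
#' @export
community_hyperparams <- function(mu, sd) {
  fams <- nmix_families()
  mu <- mu[fams]; sd <- sd[fams]
  if (anyNA(mu) || anyNA(sd)) stop("`mu` and `sd` must name all seven families")
  if (any(sd <= 0 | sd > 10)) stop("hyper-sds must lie in (0, 10]")
  structure(list(mu = mu, sd = sd), class = "community_hyperparams")
}

#' Expected abundance lambda for every (site, species)
#'
#' Log-linear predictor: stratum-specific intercept (canopy intercept enters
#' when `strata == 0`, understory when `strata == 1`), site temperature
#' slope, and the sampling-unit and sampling-month random effects.
#'
#' @param params a [species_params()].
#' @param re a [random_effects()].
#' @param design a [site_design()].
#' @return Numeric matrix, sites x species, strictly positive.
#' @export
lambda_matrix <- function(params, re, design) {
  str <- design$strata
  intercept <- outer(1 - str, params$beta_can) + outer(str, params$beta_und)
  eta <- intercept + outer(design$temp_site, params$beta1) +
    re$s[design$su] + re$m[design$sm]
  out <- exp(eta)
  if (!all(is.finite(out))) stop("non-finite expected abundance: invalid parameter state")
  out
}

#' Expected abundance for one (site, species) pair
#'
#' @inheritParams lambda_matrix
#' @param i site index.
#' @param k species index.
#' @return Positive scalar.
#' @export
expected_abundance <- function(params, re, design, i, k) {
  if (i < 1 || i > length(design$strata)) stop("site index out of range")
  if (k < 1 || k > params$n_species) stop("species index out of range")
  str <- design$strata[i]
  eta <- params$beta_can[k] * (1 - str) + params$beta_und[k] * str +
    params$beta1[k] * design$temp_site[i] +
    re$s[design$su[i]] + re$m[design$sm[i]]
  out <- exp(eta)
  if (!is.finite(out)) stop("non-finite expected abundance: invalid parameter state")
  out
}

#' Detection probabilities for every (site, occasion, species)
#'
#' Logit-linear predictor with stratum-specific intercepts and slopes for
#' (standardized Julian) date and occasion temperature.
#'
#' @inheritParams lambda_matrix
#' @return Numeric array, sites x occasions x species, strictly inside (0, 1).
#' @export
detection_prob_array <- function(params, design) {
  n_sites <- length(design$strata); n_occ <- ncol(design$date_obs)
  K <- params$n_species
  str <- design$strata
  out <- array(NA_real_, c(n_sites, n_occ, K))
  for (k in seq_len(K)) {
    eta <- params$alpha_can[k] * (1 - str) + params$alpha_und[k] * str
    out[, , k] <- plogis(eta + params$alpha1[k] * design$date_obs +
                           params$alpha2[k] * design$temp_obs)
  }
  out
}

#' Detection probability for one (site, occasion, species)
#'
#' @inheritParams expected_abundance
#' @param j occasion index.
#' @return Probability strictly inside (0, 1).
#' @export
detection_prob <- function(params, design, i, j, k) {
  if (i < 1 || i > length(design$strata)) stop("site index out of range")
  if (j < 1 || j > ncol(design$date_obs)) stop("occasion index out of range")
  if (k < 1 || k > params$n_species) stop("species index out of range")
  str <- design$strata[i]
  plogis(params$alpha_can[k] * (1 - str) + params$alpha_und[k] * str +
           params$alpha1[k] * design$date_obs[i, j] +
           params$alpha2[k] * design$temp_obs[i, j])
}

#' Joint log-likelihood of counts and latent abundances
#'
#' Poisson log-density of the latent abundances `N[i, k]` at their expected
#' values plus the binomial log-density of every unmasked count `y[i, j, k]`
#' with size `N[i, k]`. Exactly `-Inf` whenever any count exceeds its latent
#' abundance (outside the binomial support).
#'
#' @param dh a [detection_history()].
#' @param N integer matrix, sites x species, of latent abundances.
#' @param params a [species_params()].
#' @param re a [random_effects()].
#' @return Scalar log-likelihood.
#' @export
joint_loglik <- function(dh, N, params, re) {
  design <- dh$design
  if (!all(dim(N) == c(dh$n_sites, dh$n_species))) stop("dimension mismatch for N")
  lam <- lambda_matrix(params, re, design)
  ll <- sum(dpois(N, lam, log = TRUE))
  p <- detection_prob_array(params, design)
  for (j in seq_len(dh$n_occasions)) {
    idx <- which(dh$mask[, j])
    if (!length(idx)) next
    yj <- dh$y[idx, j, , drop = FALSE]
    dim(yj) <- dim(N[idx, , drop = FALSE])
    pj <- p[idx, j, , drop = FALSE]
    dim(pj) <- dim(yj)
    ll <- ll + sum(dbinom(yj, N[idx, , drop = FALSE], pj, log = TRUE))
  }
  ll
}

#' Marginal log-likelihood with truncated summation over N
#'
#' Exact reference likelihood: for each (site, species) the latent abundance
#' is summed out from the largest observed count up to `Nmax`. Serves as the
#' brute-force oracle the MCMC sampler is checked against; it is not a
#' user-facing fitter.
#'
#' @inheritParams joint_loglik
#' @param Nmax truncation bound, either a scalar or a sites x species matrix;
#'   must be at least the per-(site, species) maximum observed count.
#' @return Scalar log-likelihood, monotonically non-decreasing in `Nmax`.
#' @export
marginal_loglik_truncated <- function(dh, params, re, Nmax) {
  design <- dh$design
  lam <- lambda_matrix(params, re, design)
  p <- detection_prob_array(params, design)
  maxy <- min_abundance_bound(dh)
  if (length(Nmax) == 1L) Nmax <- matrix(Nmax, dh$n_sites, dh$n_species)
  if (any(Nmax < maxy)) stop("Nmax is below the maximum observed count")
  total <- 0
  for (i in seq_len(dh$n_sites)) {
    js <- which(dh$mask[i, ])
    for (k in seq_len(dh$n_species)) {
      Ns <- maxy[i, k]:Nmax[i, k]
      lp <- dpois(Ns, lam[i, k], log = TRUE)
      for (j in js) {
        lp <- lp + dbinom(dh$y[i, j, k], Ns, p[i, j, k], log = TRUE)
      }
      total <- total + log_sum_exp(lp)
    }
  }
  total
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Log prior density of a full parameter state
#'
#' Species parameters are normal around their community means; random
#' effects are normal around zero with their own standard deviations. The
#' hyperpriors are vague: Normal(0, precision 0.001), i.e. variance 1000, on
#' the abundance means and detection slopes' means; uniform(0, 1) on the
#' probability-scale detection-intercept means (standard-logistic density on
#' the stored logit scale); uniform(0, 10) on every standard deviation.
#' Returns `-Inf` outside the support.
#'
#' @inheritParams joint_loglik
#' @param hyper a [community_hyperparams()].
#' @return Scalar log prior density.
#' @export
log_prior <- function(params, re, hyper) {
  fams <- nmix_families()
  mu <- hyper$mu; s <- hyper$sd
  if (any(!is.finite(mu))) return(-Inf)
  if (any(s <= 0 | s > 10)) return(-Inf)
  if (re$sigma_s <= 0 || re$sigma_s > 10 || re$sigma_m <= 0 || re$sigma_m > 10) {
    return(-Inf)
  }
  lp <- 0
  for (f in fams) {
    lp <- lp + sum(dnorm(params[[f]], mu[[f]], s[[f]], log = TRUE))
  }
  lp <- lp + sum(dnorm(re$s, 0, re$sigma_s, log = TRUE)) +
    sum(dnorm(re$m, 0, re$sigma_m, log = TRUE))
  # hyperpriors
  vague <- c("beta_can", "beta_und", "beta1", "alpha1", "alpha2")
  lp <- lp + sum(dnorm(mu[vague], 0, sqrt(1000), log = TRUE))
  lp <- lp + sum(dlogis(mu[c("alpha_can", "alpha_und")], log = TRUE))
  lp <- lp + length(fams) * log(1 / 10) + 2 * log(1 / 10)  # sds + sigma_s/sigma_m
  lp
}
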