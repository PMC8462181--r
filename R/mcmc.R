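#' MCMC configuration
#'
#' Defaults mirror the study's sampler settings: 3 chains of 150,000
#' iterations, 50,000 burn-in, thinning 100 -- which retains 3,000 draws in
#' total. Tests and examples use much smaller settings.
#'
#' @param n_chains number of chains.
#' @param n_iter iterations per chain.
#' @param n_burn burn-in iterations discarded per chain (`< n_iter`).
#' @param thin thinning interval.
#' @param seed integer seed; chain `c` uses `seed + c - 1`, and the seed
#'   fully determines the draw sequence for fixed inputs.
#' @param Nmax_buffer truncation buffer: the latent-abundance support for
#'   each (site, species) is `[max count, max count + Nmax_buffer]`.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 150000, n_burn = 50000,
                        thin = 100, seed = 1, Nmax_buffer = 100) {
  stopifnot(n_chains >= 1, n_iter >= 1, n_burn >= 0, thin >= 1,
            Nmax_buffer >= 1)
  if (n_burn >= n_iter) stop("`n_burn` must be smaller than `n_iter`")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burn = as.integer(n_burn), thin = as.integer(thin),
                 seed = as.integer(seed), Nmax_buffer = as.integer(Nmax_buffer)),
            class = "mcmc_config")
}

#' Number of retained posterior draws
#'
#' `n_chains * floor((n_iter - n_burn) / thin)`; the study settings give
#' 3,000.
#'
#' @param config an [mcmc_config()].
#' @return Integer draw count.
#' @export
retained_samples <- function(config) {
  config$n_chains * ((config$n_iter - config$n_burn) %/% config$thin)
}

hyper_names <- function() {
  c(paste0("mu_", nmix_families()), paste0("sd_", nmix_families()),
    "sigma_s", "sigma_m")
}

default_inits <- function(dh, fixed) {
  K <- dh$n_species
  base <- log(mean(dh$y[rep(dh$mask, dh$n_species)]) + 0.5)
  sp <- cbind(
    beta_can = base + rnorm(K, 0, 0.5),
    beta_und = base + rnorm(K, 0, 0.5),
    beta1 = rnorm(K, 0, 0.2),
    alpha_can = qlogis(runif(1, 0.2, 0.5)) + rnorm(K, 0, 0.5),
    alpha_und = qlogis(runif(1, 0.2, 0.5)) + rnorm(K, 0, 0.5),
    alpha1 = rnorm(K, 0, 0.2),
    alpha2 = rnorm(K, 0, 0.2)
  )
  list(
    species = sp,
    s = rnorm(dh$design$n_su, 0, 0.2),
    m = rnorm(dh$design$n_sm, 0, 0.2),
    sigma_s = runif(1, 0.2, 1), sigma_m = runif(1, 0.2, 1),
    mu = colMeans(sp),
    sd = setNames(runif(7, 0.3, 1.5), colnames(sp)),
    N = min_abundance_bound(dh) + matrix(rpois(dh$n_sites * K, 2),
                                         dh$n_sites, K)
  )
}

#' Fit the multispecies N-mixture model by MCMC
#'
#' Runs a Metropolis-within-Gibbs sampler: integer random-walk updates for
#' the latent abundances on their truncated support, Gaussian random walks
#' for species parameters and random effects (with proposal scales adapted
#' during burn-in only), conjugate draws for community means with normal
#' hyperpriors, and random-walk updates respecting the uniform(0, 10) prior
#' for every standard deviation.
#'
#' @param data a [detection_history()] or a long-format count table accepted
#'   by [as_detection_history()].
#' @param config an [mcmc_config()].
#' @param fixed optional named list pinning blocks of the state at known
#'   values instead of sampling them (useful for validation against
#'   enumeration oracles). Recognized elements: `species` (K x 7 matrix or a
#'   named list of per-family vectors), `s`, `m`, `sigma_s`, `sigma_m`, `mu`
#'   and `sd` (named vectors over parameter families), `N` (sites x species
#'   matrix).
#' @param ... passed to [as_detection_history()] when `data` is a table.
#' @return An object of class `nmix_fit` holding the retained draws of all
#'   hyperparameters, species parameters, random effects and latent
#'   abundance matrices, with chain labels.
#' @export
fit_nmixture <- function(data, config = mcmc_config(), fixed = list(), ...) {
  dh <- if (inherits(data, "detection_history")) data else as_detection_history(data, ...)
  design <- dh$design
  fams <- nmix_families()
  maxy <- min_abundance_bound(dh)
  hi <- maxy + config$Nmax_buffer

  fix_species <- setNames(rep(FALSE, 7), fams)
  fix_mu <- fix_sd <- fix_species
  if (!is.null(fixed$species)) {
    if (is.list(fixed$species)) fix_species[names(fixed$species)] <- TRUE
    else fix_species[] <- TRUE
  }
  if (!is.null(fixed$mu)) fix_mu[names(fixed$mu)] <- TRUE
  if (!is.null(fixed$sd)) fix_sd[names(fixed$sd)] <- TRUE
  # a fixed species family needs no hyper updates either way, but sampling
  # its mu/sd against fixed values remains valid, so flags stay independent
  fix_re <- !is.null(fixed$s) || !is.null(fixed$m)
  fix_sigma <- !is.null(fixed$sigma_s) || !is.null(fixed$sigma_m)
  fix_N <- !is.null(fixed$N)

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    init <- default_inits(dh, fixed)
    if (!is.null(fixed$species)) {
      if (is.list(fixed$species)) {
        for (f in names(fixed$species)) init$species[, f] <- fixed$species[[f]]
      } else init$species <- as.matrix(fixed$species)
    }
    if (!is.null(fixed$s)) init$s <- fixed$s
    if (!is.null(fixed$m)) init$m <- fixed$m
    if (!is.null(fixed$sigma_s)) init$sigma_s <- fixed$sigma_s
    if (!is.null(fixed$sigma_m)) init$sigma_m <- fixed$sigma_m
    if (!is.null(fixed$mu)) init$mu[names(fixed$mu)] <- fixed$mu
    if (!is.null(fixed$sd)) init$sd[names(fixed$sd)] <- fixed$sd
    if (!is.null(fixed$N)) init$N <- fixed$N
    lp0 <- joint_loglik(
      dh, init$N,
      species_params(init$species[, 1], init$species[, 2], init$species[, 3],
                     init$species[, 4], init$species[, 5], init$species[, 6],
                     init$species[, 7]),
      random_effects(init$s, init$m, init$sigma_s, init$sigma_m)
    )
    if (!is.finite(lp0)) stop("non-finite log-posterior at initialization")
    chains[[ch]] <- nmix_mcmc_cpp(
      y = dh$y, mask = dh$mask,
      strata = design$strata, temp_site = design$temp_site,
      su = design$su - 1L, sm = design$sm - 1L,
      n_su = design$n_su, n_sm = design$n_sm,
      date_obs = design$date_obs, temp_obs = design$temp_obs,
      lo = maxy, hi = hi,
      sp_init = init$species, s_init = init$s, m_init = init$m,
      sigma_s_init = init$sigma_s, sigma_m_init = init$sigma_m,
      mu_init = as.numeric(init$mu), sd_init = as.numeric(init$sd),
      N_init = init$N,
      n_iter = config$n_iter, n_burn = config$n_burn, thin = config$thin,
      fix_species = unname(fix_species), fix_mu = unname(fix_mu),
      fix_sd = unname(fix_sd), fix_re = fix_re, fix_sigma = fix_sigma,
      fix_N = fix_N
    )
  }

  n_keep <- (config$n_iter - config$n_burn) %/% config$thin
  hyper <- do.call(rbind, lapply(chains, `[[`, "hyper"))
  colnames(hyper) <- hyper_names()
  species <- abind3(lapply(chains, `[[`, "species"))
  dimnames(species) <- list(NULL, dh$species_labels, fams)
  re <- do.call(rbind, lapply(chains, `[[`, "re"))
  colnames(re) <- c(paste0("s[", seq_len(design$n_su), "]"),
                    paste0("m[", seq_len(design$n_sm), "]"))
  N <- abind3(lapply(chains, `[[`, "N"))
  dimnames(N) <- list(NULL, dh$site_labels, dh$species_labels)
  structure(
    list(hyper = hyper, species = species, re = re, N = N,
         chain = rep(seq_len(config$n_chains), each = n_keep),
         iteration = rep(seq_len(n_keep), config$n_chains),
         config = config, data = dh,
         accept = lapply(chains, `[[`, "accept")),
    class = "nmix_fit"
  )
}

# bind draw arrays (n_keep x a x b) along the first dimension
abind3 <- function(lst) {
  d <- dim(lst[[1L]])
  out <- array(NA_real_, c(sum(vapply(lst, function(x) dim(x)[1L], 0L)), d[2L], d[3L]))
  at <- 0L
  for (x in lst) {
    out[at + seq_len(dim(x)[1L]), , ] <- x
    at <- at + dim(x)[1L]
  }
  out
}

#' @export
print.nmix_fit <- function(x, ...) {
  cat(sprintf(
    "<nmix_fit> %d retained draws (%d chains x %d) | %d sites x %d species\n",
    length(x$chain), x$config$n_chains, sum(x$chain == 1L),
    x$data$n_sites, x$data$n_species
  ))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) R-hat from between- and within-chain variances; the
#' split-chain variant (each chain halved before the computation) is
#' available behind `split = TRUE`. Chains that are all constant and
#' identical give 1 by convention.
#'
#' @param fit an `nmix_fit`, or a numeric matrix with one column per chain.
#' @param pars parameter names (columns of the hyperparameter draw table);
#'   defaults to all hyperparameters.
#' @param split use the split-chain variant.
#' @return Named numeric vector of R-hat values.
#' @export
rhat <- function(fit, pars = NULL, split = FALSE) {
  if (is.matrix(fit) && !inherits(fit, "nmix_fit")) {
    return(c(rhat_core(fit, split)))
  }
  stopifnot(inherits(fit, "nmix_fit"))
  if (fit$config$n_chains < 2L) {
    stop("R-hat is undefined for a single chain")
  }
  if (is.null(pars)) pars <- colnames(fit$hyper)
  vapply(pars, function(p) {
    m <- matrix(fit$hyper[, p], ncol = fit$config$n_chains)
    rhat_core(m, split)
  }, numeric(1))
}

rhat_core <- function(x, split = FALSE) {
  if (ncol(x) < 2L) stop("R-hat is undefined for a single chain")
  if (nrow(x) < 2L) stop("R-hat needs at least 2 draws per chain")
  if (split) {
    half <- nrow(x) %/% 2L
    x <- cbind(x[seq_len(half), , drop = FALSE],
               x[nrow(x) - half + seq_len(half), , drop = FALSE])
  }
  n <- nrow(x)
  means <- colMeans(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior draws of the detection-corrected abundance matrix
#'
#' One site x species integer matrix per retained draw, in draw order.
#'
#' @param fit an `nmix_fit`.
#' @return A list of matrices with site/species dimnames.
#' @export
posterior_abundance_matrices <- function(fit) {
  stopifnot(inherits(fit, "nmix_fit"))
  n <- dim(fit$N)[1L]
  lapply(seq_len(n), function(d) {
    m <- fit$N[d, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, dim(fit$N)[2L], dim(fit$N)[3L])
    dimnames(m) <- dimnames(fit$N)[2:3]
    storage.mode(m) <- "integer"
    m
  })
}

#' @rdname fit_nmixture
#' @param x an `nmix_fit`.
#' @param level credible-interval level for `tidy()`.
#' @method tidy nmix_fit
#' @export
tidy.nmix_fit <- function(x, level = 0.95, ...) {
  a <- (1 - level) / 2
  qs <- c(a, 1 - a)
  summarize_block <- function(draws, terms, kind) {
    tibble::tibble(
      term = terms, kind = kind,
      estimate = colMeans(draws),
      std.error = apply(draws, 2, stats::sd),
      conf.low = apply(draws, 2, quantile, qs[1]),
      conf.high = apply(draws, 2, quantile, qs[2]),
      rhat = if (x$config$n_chains >= 2L) {
        apply(draws, 2, function(v) rhat_core(matrix(v, ncol = x$config$n_chains)))
      } else NA_real_
    )
  }
  sp <- x$species
  sp_flat <- matrix(sp, nrow = dim(sp)[1L])
  sp_terms <- as.vector(outer(dimnames(sp)[[2L]], dimnames(sp)[[3L]],
                              function(s, f) paste0(f, "[", s, "]")))
  dplyr::bind_rows(
    summarize_block(x$hyper, colnames(x$hyper), "hyperparameter"),
    summarize_block(sp_flat, sp_terms, "species"),
    summarize_block(x$re, colnames(x$re), "random_effect")
  )
}

#' @rdname fit_nmixture
#' @method glance nmix_fit
#' @export
glance.nmix_fit <- function(x, ...) {
  rh <- if (x$config$n_chains >= 2L) max(rhat(x)) else NA_real_
  tibble::tibble(
    n_chains = x$config$n_chains,
    n_iter = x$config$n_iter,
    n_burn = x$config$n_burn,
    thin = x$config$thin,
    n_draws = length(x$chain),
    max_rhat = rh
  )
}

#' @rdname fit_nmixture
#' @param object an `nmix_fit`.
#' @method autoplot nmix_fit
#' @export
autoplot.nmix_fit <- function(object, level = 0.95, ...) {
  td <- tidy.nmix_fit(object, level = level)
  td <- td[td$kind == "hyperparameter", ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "posterior mean and credible interval", y = NULL) +
    ggplot2::theme_minimal()
}
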