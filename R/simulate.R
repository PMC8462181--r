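#' Default constants and level grids for metacommunity simulation
#'
#' `sim_constants()` returns the baseline community hyperparameters every
#' simulated metacommunity shares: intermediate abundance means
#' (`log(2)` per-site expected abundance of 2), intermediate detection
#' means (probability 0.3), no covariate effects on average, moderate
#' among-species spread, and mild random-effect variation.
#' `default_sim_levels()` returns the low / intermediate / high values for
#' the four varied parameters: expected abundance 0.5 / 2 / 8 individuals
#' per site, detection probability 0.1 / 0.3 / 0.6. These level values are
#' package defaults (configurable), not values quoted from any particular
#' study.
#'
#' @return `sim_constants()`: a list with a [community_hyperparams()] plus
#'   `sigma_s`, `sigma_m`. `default_sim_levels()`: a named list of
#'   three-value vectors.
#' @export
sim_constants <- function() {
  fams <- nmix_families()
  mu <- setNames(c(log(2), log(2), 0, qlogis(0.3), qlogis(0.3), 0, 0), fams)
  sd <- setNames(c(0.5, 0.5, 0.25, 0.5, 0.5, 0.25, 0.25), fams)
  list(hyper = community_hyperparams(mu, sd), sigma_s = 0.25, sigma_m = 0.25)
}

#' @rdname sim_constants
#' @export
default_sim_levels <- function() {
  list(
    beta_can_mean = setNames(log(c(0.5, 2, 8)), c("low", "intermediate", "high")),
    beta_und_mean = setNames(log(c(0.5, 2, 8)), c("low", "intermediate", "high")),
    alpha_can_mean = setNames(qlogis(c(0.1, 0.3, 0.6)), c("low", "intermediate", "high")),
    alpha_und_mean = setNames(qlogis(c(0.1, 0.3, 0.6)), c("low", "intermediate", "high"))
  )
}

#' Build the 12-setting simulation grid
#'
#' One setting per (varied parameter, level): four parameters (canopy /
#' understory abundance mean, canopy / understory detection mean) times
#' three levels (low, intermediate, high) gives exactly 12 simulated
#' metacommunities, coded A to L in deterministic order. Within a setting
#' only the one varied parameter moves; everything else stays at the
#' constants.
#'
#' @param levels named list giving exactly three values per varied
#'   parameter; see [default_sim_levels()].
#' @param constants baseline parameters; see [sim_constants()].
#' @param n_species,n_sites,n_occasions design sizes. The defaults mirror
#'   the motivating study (35 species, 12 sites as 6 site pairs x 2 strata,
#'   5 occasions); `n_species = 10`--`15` makes a fast preset.
#' @param seed base seed; setting `i` simulates with `seed + i - 1`.
#' @return A tibble with one row per setting: `code`, `parameter`, `level`,
#'   `value`, design sizes and per-setting seed; the constants travel in
#'   the `constants` attribute.
#' @export
build_setting_grid <- function(levels = default_sim_levels(),
                               constants = sim_constants(),
                               n_species = 35, n_sites = 12, n_occasions = 5,
                               seed = 1) {
  if (!all(lengths(levels) == 3L)) {
    stop("each varied parameter needs exactly 3 levels (low, intermediate, high)")
  }
  grid <- tibble::tibble(
    parameter = rep(names(levels), each = 3L),
    level = rep(c("low", "intermediate", "high"), length(levels)),
    value = unname(unlist(lapply(levels, unname)))
  )
  grid$code <- LETTERS[seq_len(nrow(grid))]
  grid$n_species <- n_species
  grid$n_sites <- n_sites
  grid$n_occasions <- n_occasions
  grid$seed <- seed + seq_len(nrow(grid)) - 1L
  out <- grid[, c("code", "parameter", "level", "value",
                  "n_species", "n_sites", "n_occasions", "seed")]
  attr(out, "constants") <- constants
  out
}

# map a varied-parameter name to the hyperparameter family it moves
varied_family <- function(parameter) {
  switch(parameter,
         beta_can_mean = "beta_can", beta_und_mean = "beta_und",
         alpha_can_mean = "alpha_can", alpha_und_mean = "alpha_und",
         stop("unknown varied parameter: ", parameter))
}

#' Simulate a metacommunity under the N-mixture model
#'
#' Draws species parameters from the community hyperdistributions, builds
#' the paired-site design (consecutive site pairs share a sampling unit,
#' strata alternate canopy / understory, months assigned cyclically),
#' assembles expected abundances and detection probabilities exactly as the
#' model's link functions do, then draws latent abundances
#' `N ~ Poisson(lambda)` and observed counts `yobs ~ Binomial(N, p)`.
#'
#' @param setting one row of [build_setting_grid()], or `NULL` to simulate
#'   at the baseline constants.
#' @param constants baseline parameters; defaults to the grid's attribute
#'   or [sim_constants()].
#' @param n_species,n_sites,n_occasions,seed design sizes and seed; default
#'   to the setting's values.
#' @return An object of class `sim_metacommunity`: `$dh` the observed
#'   [detection_history()], `$truth` the generating species parameters,
#'   random effects, latent `N` and the hyperparameter vector (named as in
#'   the fit's draw table).
#' @export
simulate_metacommunity <- function(setting = NULL, constants = NULL,
                                   n_species = NULL, n_sites = NULL,
                                   n_occasions = NULL, seed = NULL) {
  if (!is.null(setting)) {
    stopifnot(nrow(setting) == 1L)
    constants <- constants %||% attr(setting, "constants") %||% sim_constants()
    n_species <- n_species %||% setting$n_species
    n_sites <- n_sites %||% setting$n_sites
    n_occasions <- n_occasions %||% setting$n_occasions
    seed <- seed %||% setting$seed
  } else {
    constants <- constants %||% sim_constants()
    n_species <- n_species %||% 35L
    n_sites <- n_sites %||% 12L
    n_occasions <- n_occasions %||% 5L
    seed <- seed %||% 1L
  }
  if (n_sites %% 2L != 0L) stop("`n_sites` must be even (site pairs x 2 strata)")
  hyper <- constants$hyper
  if (!is.null(setting)) {
    fam <- varied_family(setting$parameter)
    hyper$mu[fam] <- setting$value
  }

  set.seed(seed)
  fams <- nmix_families()
  sp <- lapply(fams, function(f) rnorm(n_species, hyper$mu[f], hyper$sd[f]))
  names(sp) <- fams
  params <- do.call(species_params, sp)

  n_su <- n_sites %/% 2L
  n_sm <- min(5L, n_sites)
  re <- random_effects(
    s = rnorm(n_su, 0, constants$sigma_s),
    m = rnorm(n_sm, 0, constants$sigma_m),
    sigma_s = constants$sigma_s, sigma_m = constants$sigma_m
  )
  design <- site_design(
    strata = rep(c(0L, 1L), n_su),
    temp_site = rnorm(n_sites),
    su = rep(seq_len(n_su), each = 2L),
    sm = ((seq_len(n_sites) - 1L) %% n_sm) + 1L,
    date_obs = matrix(rep(as.vector(scale(seq_len(n_occasions))), each = n_sites),
                      n_sites, n_occasions),
    temp_obs = matrix(rnorm(n_sites * n_occasions), n_sites, n_occasions)
  )

  lam <- lambda_matrix(params, re, design)
  p <- detection_prob_array(params, design)
  N <- matrix(rpois(length(lam), lam), n_sites, n_species)
  y <- array(0L, c(n_sites, n_occasions, n_species))
  for (j in seq_len(n_occasions)) {
    y[, j, ] <- rbinom(length(N), N, p[, j, ])
  }
  dh <- detection_history(y, design)
  dimnames(N) <- list(dh$site_labels, dh$species_labels)

  truth_hyper <- setNames(numeric(16), hyper_names())
  truth_hyper[paste0("mu_", fams)] <- hyper$mu
  truth_hyper[paste0("sd_", fams)] <- hyper$sd
  truth_hyper["sigma_s"] <- constants$sigma_s
  truth_hyper["sigma_m"] <- constants$sigma_m

  structure(
    list(dh = dh,
         truth = list(params = params, re = re, N = N, hyper = truth_hyper),
         setting = if (is.null(setting)) NULL else as.list(setting),
         seed = seed),
    class = "sim_metacommunity"
  )
}

#' @export
print.sim_metacommunity <- function(x, ...) {
  lbl <- if (is.null(x$setting)) "baseline" else
    sprintf("setting %s (%s = %s)", x$setting$code, x$setting$parameter,
            x$setting$level)
  cat(sprintf("<sim_metacommunity> %s | %d sites x %d occasions x %d species, seed %d\n",
              lbl, x$dh$n_sites, x$dh$n_occasions, x$dh$n_species, x$seed))
  invisible(x)
}

#' Credible-interval coverage of the generating parameters
#'
#' For every hyperparameter and species-specific parameter: the generating
#' (true) value, the central credible interval of the posterior draws at
#' the requested level, and whether the truth falls inside. The aggregate
#' hyperparameter coverage fraction is the recovery statistic of the
#' simulation-validation study.
#'
#' @param truth a `sim_metacommunity` (or its `$truth` list).
#' @param fit the [fit_nmixture()] result on the simulated counts.
#' @param level credible-interval level.
#' @return A tibble with columns `term`, `kind`, `truth`, `conf.low`,
#'   `conf.high`, `covered`.
#' @export
recovery_check <- function(truth, fit, level = 0.95) {
  if (inherits(truth, "sim_metacommunity")) truth <- truth$truth
  stopifnot(inherits(fit, "nmix_fit"))
  a <- (1 - level) / 2
  hy <- truth$hyper
  if (!all(names(hy) %in% colnames(fit$hyper))) {
    stop("hyperparameter sets of truth and fit do not match")
  }
  ci_h <- apply(fit$hyper[, names(hy), drop = FALSE], 2, quantile,
                probs = c(a, 1 - a))
  rows_h <- tibble::tibble(
    term = names(hy), kind = "hyperparameter", truth = unname(hy),
    conf.low = unname(ci_h[1, ]), conf.high = unname(ci_h[2, ])
  )
  fams <- nmix_families()
  rows_s <- dplyr::bind_rows(lapply(fams, function(f) {
    tv <- truth$params[[f]]
    dr <- fit$species[, , f, drop = TRUE]
    dr <- matrix(dr, ncol = length(tv))
    ci <- apply(dr, 2, quantile, probs = c(a, 1 - a))
    tibble::tibble(
      term = paste0(f, "[", dimnames(fit$species)[[2L]], "]"),
      kind = "species", truth = tv,
      conf.low = unname(ci[1, ]), conf.high = unname(ci[2, ])
    )
  }))
  out <- dplyr::bind_rows(rows_h, rows_s)
  out$covered <- out$truth >= out$conf.low & out$truth <= out$conf.high
  out
}
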