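#' Hidden diversity of one site for one metric
#'
#' Standardized deviation of the observed diversity value from its
#' detection-corrected posterior distribution:
#' `hd = (div_obs - mean(div_est)) / sd(div_est)`, with the sample standard
#' deviation (n - 1 denominator) over posterior draws. Positive values mean
#' the observed data overestimate diversity relative to the
#' detection-corrected estimate; negative values mean underestimation. A
#' zero spread across draws leaves the statistic undefined and is flagged
#' with an explicit status code rather than reported as 0.
#'
#' @param div_obs observed diversity value.
#' @param div_est_draws numeric vector of the metric evaluated on each
#'   posterior abundance draw (length >= 2).
#' @return A list with elements `hd`, `mean`, `sd`, `status`
#'   (`"ok"` or `"undefined_sd0"`).
#' @export
hidden_diversity_value <- function(div_obs, div_est_draws) {
  div_est_draws <- div_est_draws[is.finite(div_est_draws)]
  if (length(div_est_draws) < 2L) {
    stop("need at least 2 finite posterior draws of the metric")
  }
  m <- mean(div_est_draws)
  s <- stats::sd(div_est_draws)
  if (!is.finite(s) || s == 0) {
    return(list(hd = NA_real_, mean = m, sd = s, status = "undefined_sd0"))
  }
  list(hd = (div_obs - m) / s, mean = m, sd = s, status = "ok")
}

#' Noise / critical-bias quadrant of an SES pair
#'
#' Classifies the (observed SES, detection-corrected SES) pair: opposite
#' signs fall in the critical-bias region (`bias_overestimation` when the
#' observed value is positive and the estimate negative,
#' `bias_underestimation` for the reverse), same signs are `noise` -- the
#' observed pattern holds, only its magnitude shifts. An exact zero on
#' either axis carries no directional pattern and is classified as noise
#' with a warning.
#'
#' @param obs_ses observed standardized effect size(s).
#' @param est_ses_mean posterior-mean standardized effect size(s).
#' @return Character vector over
#'   \{`"noise"`, `"bias_overestimation"`, `"bias_underestimation"`\}.
#' @export
classify_quadrant <- function(obs_ses, est_ses_mean) {
  stopifnot(length(obs_ses) == length(est_ses_mean))
  if (any(!is.finite(obs_ses) | !is.finite(est_ses_mean))) {
    stop("SES values must be finite")
  }
  if (any(obs_ses == 0 | est_ses_mean == 0)) {
    warning("exact zero SES on one axis: classified as noise")
  }
  out <- rep("noise", length(obs_ses))
  out[obs_ses > 0 & est_ses_mean < 0] <- "bias_overestimation"
  out[obs_ses < 0 & est_ses_mean > 0] <- "bias_underestimation"
  out
}

# evaluate one SES family on the observed matrix and on every draw;
# the null randomization is re-run per draw with a draw-indexed seed stream
# so both null and detection uncertainty propagate
ses_over_draws <- function(obs_comm, draws, metric, tree = NULL, dist = NULL,
                           weighted = FALSE, null, obs_null = "once") {
  obs_ses <- if (obs_null == "once") {
    ses(obs_comm, metric, tree = tree, dist = dist, weighted = weighted,
        null = null)$ses
  } else {
    rowMeans(vapply(seq_along(draws), function(d) {
      nd <- null; nd$seed <- null$seed + d
      ses(obs_comm, metric, tree = tree, dist = dist, weighted = weighted,
          null = nd)$ses
    }, numeric(nrow(obs_comm))))
  }
  est <- vapply(seq_along(draws), function(d) {
    nd <- null; nd$seed <- null$seed + d
    ses(draws[[d]], metric, tree = tree, dist = dist, weighted = weighted,
        null = nd)$ses
  }, numeric(nrow(obs_comm)))
  list(obs = obs_ses, est = matrix(est, nrow = nrow(obs_comm)))
}

#' Hidden diversity across posterior abundance draws
#'
#' The full pipeline: evaluates diversity metrics on the observed community
#' matrix and on every posterior draw of the detection-corrected abundance
#' matrix, and summarizes the deviation per site and metric. Taxonomic
#' diversity (TD, species richness) and total abundance are always
#' computed; requesting `"pd"` adds the branch-length standardized effect
#' sizes SES.PD (phylogeny) and SES.FD (functional UPGMA dendrogram built
#' from Gower distances); requesting `"mpd"` adds the distance-based
#' SES.MPD / SES.MFD, plus the incidence variants SES.MPDi / SES.MFDi when
#' `weighted = TRUE`.
#'
#' @param x an [fit_nmixture()] result (observed matrix and posterior draws
#'   are extracted from it), or an observed site x species matrix, in which
#'   case `draws` must be supplied.
#' @param tree `phylo` phylogeny covering the community's species (required
#'   for any phylogenetic metric); pruned internally.
#' @param traits trait table for [gower_distance()] (required for any
#'   functional metric).
#' @param metrics subset of `c("pd", "mpd")`.
#' @param weighted abundance-weight the distance-based metrics.
#' @param binary passed to [gower_distance()].
#' @param null a [null_model_spec()]; draw `d` uses seed `null$seed + d` so
#'   null-model noise propagates together with detection uncertainty.
#' @param obs_null `"once"` (default): observed SES computed once with the
#'   base seed; `"per_draw"`: recomputed under each draw's null stream and
#'   averaged.
#' @param draws list of site x species matrices (or a draws x sites x
#'   species array) when `x` is a plain matrix.
#' @param collapse how the observed matrix is collapsed from the detection
#'   history when `x` is a fit; see [observed_community()].
#' @return A `hidden_diversity` tibble: one row per site x metric with
#'   columns `site`, `metric`, `div_obs`, `div_est_mean`, `div_est_sd`,
#'   `hd`, `raw_difference`, `quadrant` (SES metrics only), `hd_status`.
#' @export
hidden_diversity <- function(x, tree = NULL, traits = NULL,
                             metrics = c("pd", "mpd"), weighted = TRUE,
                             binary = NULL, null = null_model_spec(n_perm = 99),
                             obs_null = c("once", "per_draw"), draws = NULL,
                             collapse = "max") {
  obs_null <- match.arg(obs_null)
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (inherits(x, "nmix_fit")) {
    obs_comm <- observed_community(x$data, collapse = collapse)
    draws <- posterior_abundance_matrices(x)
  } else {
    obs_comm <- as.matrix(x)
    if (is.null(draws)) stop("`draws` required when `x` is a community matrix")
    if (is.array(draws) && length(dim(draws)) == 3L) {
      draws <- lapply(seq_len(dim(draws)[1L]), function(d) {
        m <- draws[d, , , drop = TRUE]
        matrix(m, ncol = ncol(obs_comm), dimnames = dimnames(obs_comm))
      })
    }
  }
  if (!length(draws)) stop("`draws` must be non-empty")
  species <- colnames(obs_comm)
  sites <- rownames(obs_comm) %||% as.character(seq_len(nrow(obs_comm)))

  need_tree <- TRUE  # both pd and mpd families use the phylogeny
  if (need_tree) {
    if (is.null(tree)) stop("`tree` is required")
    missing_sp <- setdiff(species, tree$tip.label)
    if (length(missing_sp)) {
      stop("species present in communities but absent from tree: ",
           paste(missing_sp, collapse = ", "))
    }
    tree <- prune_tree(tree, species)
  }
  if (is.null(traits)) stop("`traits` is required")
  fun_dist <- gower_distance(traits, binary = binary)
  missing_tr <- setdiff(species, rownames(fun_dist))
  if (length(missing_tr)) {
    stop("species present in communities but absent from traits: ",
         paste(missing_tr, collapse = ", "))
  }
  fun_dist <- fun_dist[species, species]

  rows <- list()
  add_raw <- function(name, fn) {
    obs_v <- fn(obs_comm)
    est <- vapply(draws, fn, numeric(nrow(obs_comm)))
    est <- matrix(est, nrow = nrow(obs_comm))
    rows[[length(rows) + 1L]] <<- summarize_hd(sites, name, obs_v, est,
                                               quadrant = FALSE)
  }
  add_raw("TD", function(m) rowSums(m > 0))
  add_raw("abundance", function(m) rowSums(m))

  add_ses <- function(name, metric, tr = NULL, ds = NULL, wtd = FALSE) {
    r <- ses_over_draws(obs_comm, draws, metric, tree = tr, dist = ds,
                        weighted = wtd, null = null, obs_null = obs_null)
    rows[[length(rows) + 1L]] <<- summarize_hd(sites, name, r$obs, r$est,
                                               quadrant = TRUE)
  }
  if ("pd" %in% metrics) {
    fun_tree <- functional_dendrogram(fun_dist)
    add_ses("SES.PD", "pd", tr = tree)
    add_ses("SES.FD", "pd", tr = fun_tree)
  }
  if ("mpd" %in% metrics) {
    phy_dist <- cophenetic(tree)[species, species]
    add_ses("SES.MPD", "mpd", ds = phy_dist, wtd = weighted)
    add_ses("SES.MFD", "mpd", ds = fun_dist, wtd = weighted)
    if (weighted) {
      add_ses("SES.MPDi", "mpd", ds = phy_dist, wtd = FALSE)
      add_ses("SES.MFDi", "mpd", ds = fun_dist, wtd = FALSE)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("hidden_diversity", class(out))
  out
}

summarize_hd <- function(sites, metric, obs_v, est, quadrant) {
  # draws where the metric itself is undefined (e.g. SES of a saturated
  # community under tip shuffle) are dropped, matching hidden_diversity_value
  n_ok <- rowSums(is.finite(est))
  est_mean <- ifelse(n_ok > 0, rowMeans(est, na.rm = TRUE), NA_real_)
  est_sd <- apply(est, 1, function(x) stats::sd(x[is.finite(x)]))
  defined <- n_ok >= 2 & is.finite(est_sd) & est_sd > 0 &
    is.finite(obs_v) & is.finite(est_mean)
  hd <- ifelse(defined, (obs_v - est_mean) / est_sd, NA_real_)
  quad <- rep(NA_character_, length(obs_v))
  if (quadrant) {
    ok <- is.finite(obs_v) & is.finite(est_mean)
    quad[ok] <- suppressWarnings(classify_quadrant(obs_v[ok], est_mean[ok]))
  }
  tibble::tibble(
    site = sites, metric = metric,
    div_obs = as.numeric(obs_v),
    div_est_mean = est_mean, div_est_sd = est_sd,
    hd = hd, raw_difference = as.numeric(obs_v) - est_mean,
    quadrant = quad,
    hd_status = ifelse(defined, "ok",
                       ifelse(is.finite(est_sd) & est_sd == 0,
                              "undefined_sd0", "undefined"))
  )
}

#' @rdname hidden_diversity
#' @param object a `hidden_diversity` table.
#' @param ... unused.
#' @method autoplot hidden_diversity
#' @export
autoplot.hidden_diversity <- function(object, ...) {
  d <- object[grepl("^SES", object$metric) & !is.na(object$quadrant), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$div_obs, y = .data$div_est_mean,
                                  colour = .data$quadrant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "observed SES", y = "detection-corrected SES (posterior mean)") +
    ggplot2::theme_minimal()
}

#' Write / read a hidden-diversity table
#'
#' Plain-CSV serialization of the per-site, per-metric records.
#'
#' @param x a `hidden_diversity` tibble.
#' @param path file path.
#' @return `write_hidden_diversity()` returns `x` invisibly;
#'   `read_hidden_diversity()` returns the table.
#' @export
write_hidden_diversity <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(x)
}

#' @rdname write_hidden_diversity
#' @export
read_hidden_diversity <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(
    path, stringsAsFactors = FALSE,
    colClasses = c(site = "character", metric = "character",
                   quadrant = "character", hd_status = "character")
  ))
  class(out) <- c("hidden_diversity", class(out))
  out
}
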