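#' Site-level and occasion-level design information
#'
#' Bundles the covariates entering the abundance and detection linear
#' predictors: a binary stratum indicator per site (0 = canopy,
#' 1 = understory), a site-level temperature, grouping indices for the
#' sampling-unit and sampling-month random effects, and per-occasion
#' (standardized Julian) date and temperature.
#'
#' @param strata integer vector per site, values in \{0, 1\}.
#' @param temp_site numeric vector per site.
#' @param su integer vector per site: sampling-unit group index (1-based).
#' @param sm integer vector per site: sampling-month group index (1-based).
#'   The month effect can be wired either to whole sites or to site-month
#'   replicates; any site-to-group map is accepted.
#' @param date_obs,temp_obs numeric matrices, sites x occasions.
#' @param standardize if `TRUE`, z-score `temp_site`, `date_obs` and
#'   `temp_obs`; the centering/scaling constants are recorded in the
#'   `standardization` attribute. Zero-variance covariates are centered only.
#' @return An object of class `site_design`.
#' @export
site_design <- function(strata, temp_site, su, sm, date_obs, temp_obs,
                        standardize = FALSE) {
  n_sites <- length(strata)
  if (!all(strata %in% c(0L, 1L))) {
    stop("`strata` must contain only 0 (canopy) and 1 (understory)")
  }
  date_obs <- as.matrix(date_obs)
  temp_obs <- as.matrix(temp_obs)
  stopifnot(
    length(temp_site) == n_sites, length(su) == n_sites,
    length(sm) == n_sites, nrow(date_obs) == n_sites,
    nrow(temp_obs) == n_sites, ncol(date_obs) == ncol(temp_obs)
  )
  su <- as.integer(su); sm <- as.integer(sm)
  if (any(su < 1L) || any(sm < 1L)) stop("group indices must be 1-based positive integers")
  std <- NULL
  if (standardize) {
    zs <- function(x) {
      mu <- mean(x); s <- stats::sd(as.vector(x))
      if (!is.finite(s) || s == 0) s <- 1
      list(z = (x - mu) / s, mean = mu, sd = s)
    }
    a <- zs(temp_site); b <- zs(date_obs); c <- zs(temp_obs)
    temp_site <- a$z; date_obs <- b$z; temp_obs <- c$z
    std <- list(temp_site = a[c("mean", "sd")], date_obs = b[c("mean", "sd")],
                temp_obs = c[c("mean", "sd")])
  }
  if (!all(is.finite(temp_site)) || !all(is.finite(date_obs)) ||
      !all(is.finite(temp_obs))) {
    stop("covariates must be finite")
  }
  structure(
    list(strata = as.integer(strata), temp_site = as.numeric(temp_site),
         su = su, sm = sm, n_su = max(su), n_sm = max(sm),
         date_obs = date_obs, temp_obs = temp_obs,
         standardization = std),
    class = "site_design"
  )
}

#' Repeated-count detection histories
#'
#' The core data container: counts `y[i, j, k]` of species `k` detected at
#' site `i` on occasion `j`, together with the [site_design()] covariates.
#' Unsurveyed (site, occasion) cells may be masked; masked cells are excluded
#' from every likelihood sum.
#'
#' @param y integer array, sites x occasions x species, non-negative.
#' @param design a [site_design()].
#' @param mask optional logical matrix, sites x occasions; `TRUE` marks an
#'   occasion that was actually surveyed. Defaults to all surveyed.
#' @param site_labels,species_labels optional character labels.
#' @return An object of class `detection_history`.
#' @export
detection_history <- function(y, design, mask = NULL,
                              site_labels = NULL, species_labels = NULL) {
  if (length(dim(y)) != 3L) stop("`y` must be a 3-d array: sites x occasions x species")
  if (any(y < 0) || any(y != round(y))) stop("counts must be non-negative integers")
  storage.mode(y) <- "integer"
  n_sites <- dim(y)[1L]; n_occasions <- dim(y)[2L]; n_species <- dim(y)[3L]
  stopifnot(inherits(design, "site_design"),
            length(design$strata) == n_sites,
            ncol(design$date_obs) == n_occasions)
  if (is.null(mask)) mask <- matrix(TRUE, n_sites, n_occasions)
  stopifnot(is.logical(mask), all(dim(mask) == c(n_sites, n_occasions)))
  if (is.null(site_labels)) site_labels <- paste0("site", seq_len(n_sites))
  if (is.null(species_labels)) species_labels <- paste0("sp", seq_len(n_species))
  if (anyDuplicated(species_labels)) stop("species labels must be unique")
  structure(
    list(y = y, mask = mask, design = design,
         n_sites = n_sites, n_occasions = n_occasions, n_species = n_species,
         site_labels = as.character(site_labels),
         species_labels = as.character(species_labels)),
    class = "detection_history"
  )
}

#' @export
print.detection_history <- function(x, ...) {
  cat(sprintf(
    "<detection_history> %d sites x %d occasions x %d species (%d surveyed cells, %d total counts)\n",
    x$n_sites, x$n_occasions, x$n_species, sum(x$mask), sum(x$y)
  ))
  invisible(x)
}

#' Build a detection history from a long-format count table
#'
#' Expects one row per (site, occasion, species) combination with the count
#' of detected individuals, plus the covariate columns `strata`, `temp_site`,
#' `su`, `sm` (constant within site) and `date_obs`, `temp_obs` (constant
#' within site x occasion).
#'
#' @param data a data frame with columns `site`, `occasion`, `species`,
#'   `count`, `strata`, `temp_site`, `su`, `sm`, `date_obs`, `temp_obs`.
#' @param complete if `TRUE` (default) every (site, occasion, species)
#'   combination must be present; if `FALSE`, (site, occasion) pairs with no
#'   rows are treated as unsurveyed and masked.
#' @param standardize passed to [site_design()].
#' @return A `detection_history`.
#' @export
as_detection_history <- function(data, complete = TRUE, standardize = TRUE) {
  required <- c("site", "occasion", "species", "count",
                "strata", "temp_site", "su", "sm", "date_obs", "temp_obs")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(names(data), required)
  if (length(unknown)) {
    stop("unknown columns: ", paste(unknown, collapse = ", "))
  }
  bad <- which(data$count < 0 | data$count != round(data$count))
  if (length(bad)) {
    stop("negative or non-integer counts at data row(s) ",
         paste(head(bad, 5L), collapse = ", "))
  }
  key <- paste(data$site, data$occasion, data$species, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (site, occasion, species) rows at data row(s) ",
         paste(head(dup, 5L), collapse = ", "))
  }

  sites <- sort(unique(as.character(data$site)))
  occasions <- sort(unique(data$occasion))
  species <- sort(unique(as.character(data$species)))
  i <- match(as.character(data$site), sites)
  j <- match(data$occasion, occasions)
  k <- match(as.character(data$species), species)

  n_sites <- length(sites); n_occ <- length(occasions); n_spp <- length(species)
  y <- array(0L, c(n_sites, n_occ, n_spp))
  y[cbind(i, j, k)] <- as.integer(data$count)

  surveyed <- matrix(FALSE, n_sites, n_occ)
  surveyed[unique(cbind(i, j))] <- TRUE
  if (complete && !all(surveyed)) {
    stop("incomplete detection history: some (site, occasion) pairs have no rows; ",
         "use `complete = FALSE` to treat them as unsurveyed")
  }

  site_cov <- function(col) {
    v <- tapply(data[[col]], i, function(x) {
      u <- unique(x)
      if (length(u) != 1L) stop("column `", col, "` is not constant within site")
      u[1L]
    })
    as.vector(v[as.character(seq_len(n_sites))])
  }
  occ_cov <- function(col) {
    m <- matrix(NA_real_, n_sites, n_occ)
    first <- !duplicated(paste(i, j))
    m[cbind(i[first], j[first])] <- data[[col]][first]
    chk <- data[[col]] - m[cbind(i, j)]
    if (any(abs(chk) > 1e-12, na.rm = TRUE)) {
      stop("column `", col, "` is not constant within (site, occasion)")
    }
    m[is.na(m)] <- 0
    m
  }

  design <- site_design(
    strata = site_cov("strata"), temp_site = site_cov("temp_site"),
    su = site_cov("su"), sm = site_cov("sm"),
    date_obs = occ_cov("date_obs"), temp_obs = occ_cov("temp_obs"),
    standardize = standardize
  )
  detection_history(y, design, mask = surveyed,
                    site_labels = sites, species_labels = species)
}

#' Flatten a detection history to the long-format count table
#'
#' Inverse of [as_detection_history()] (masked occasions are omitted).
#' Covariates are written as stored, i.e. standardized if the design was
#' standardized.
#'
#' @param dh a `detection_history`.
#' @return A tibble with the canonical long-format columns.
#' @export
as_count_table <- function(dh) {
  stopifnot(inherits(dh, "detection_history"))
  d <- dh$design
  grid <- expand.grid(i = seq_len(dh$n_sites), j = seq_len(dh$n_occasions),
                      k = seq_len(dh$n_species))
  keep <- dh$mask[cbind(grid$i, grid$j)]
  grid <- grid[keep, , drop = FALSE]
  tibble::tibble(
    site = dh$site_labels[grid$i],
    occasion = grid$j,
    species = dh$species_labels[grid$k],
    count = dh$y[cbind(grid$i, grid$j, grid$k)],
    strata = d$strata[grid$i],
    temp_site = d$temp_site[grid$i],
    su = d$su[grid$i],
    sm = d$sm[grid$i],
    date_obs = d$date_obs[cbind(grid$i, grid$j)],
    temp_obs = d$temp_obs[cbind(grid$i, grid$j)]
  ) |>
    dplyr::arrange(.data$site, .data$occasion, .data$species)
}

#' Observed site-by-species community matrix
#'
#' Collapses the repeated counts into one observed abundance per site and
#' species. The default (`"max"`) is the maximum count over surveyed
#' occasions -- the minimum number of individuals known to be present under
#' the closure assumption, and the observed counterpart of the latent
#' abundance N. `"sum"` totals the counts instead.
#'
#' @param dh a `detection_history`.
#' @param collapse `"max"` (default) or `"sum"`.
#' @return Integer matrix, sites x species, with dimnames.
#' @export
observed_community <- function(dh, collapse = c("max", "sum")) {
  collapse <- match.arg(collapse)
  out <- matrix(0L, dh$n_sites, dh$n_species,
                dimnames = list(dh$site_labels, dh$species_labels))
  for (i in seq_len(dh$n_sites)) {
    js <- which(dh$mask[i, ])
    if (!length(js)) next
    slab <- dh$y[i, js, , drop = FALSE]
    out[i, ] <- if (collapse == "max") apply(slab, 3, max) else apply(slab, 3, sum)
  }
  out
}

#' Per-(site, species) maximum observed count
#'
#' Lower bound of the latent-abundance support: `N[i, k]` can never be below
#' the largest count ever observed there.
#'
#' @param dh a `detection_history`.
#' @return Integer matrix, sites x species.
#' @export
min_abundance_bound <- function(dh) {
  observed_community(dh, collapse = "max")
}

#' Sampling effort in trap-days
#'
#' Study-design arithmetic for a trap-based survey: traps per sampling unit,
#' times sampling units, times days the traps stayed open. The defaults
#' reproduce the design of the motivating butterfly survey (10 traps, 6
#' units, 42 days).
#'
#' @param n_traps traps per sampling unit.
#' @param n_units number of sampling units.
#' @param n_days trap-exposure days.
#' @return Number of trap-days.
#' @export
trap_days <- function(n_traps = 10, n_units = 6, n_days = 42) {
  n_traps * n_units * n_days
}
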