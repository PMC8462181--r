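#' Species richness and total abundance of one site
#'
#' @param comm site x species abundance matrix.
#' @param site site index or row name.
#' @return Integer count of species with positive abundance, or total
#'   abundance.
#' @export
richness <- function(comm, site) {
  sum(comm[site, ] > 0)
}

#' @rdname richness
#' @export
total_abundance <- function(comm, site) {
  sum(comm[site, ])
}

#' Gower distance over a mixed continuous/binary trait table
#'
#' Range-normalized mean per-trait dissimilarity (Gower's coefficient):
#' continuous traits contribute `|x - y| / range`, binary traits a simple
#' mismatch. The range normalization is the standardization step, so the
#' result does not depend on the units of the continuous traits. Zero-range
#' traits carry no information and are dropped with a warning. The distance
#' computation itself is delegated to [vegan::vegdist()].
#'
#' @param traits a data frame with a `species` column plus one column per
#'   trait, or a numeric matrix with species as rownames.
#' @param binary character vector naming the binary trait columns; defaults
#'   to every column containing only 0/1 values. Used for validation (binary
#'   columns must be strictly 0/1).
#' @return Symmetric species x species distance matrix with entries in
#'   [0, 1] and a zero diagonal.
#' @export
gower_distance <- function(traits, binary = NULL) {
  if (is.data.frame(traits)) {
    if (!"species" %in% names(traits)) {
      stop("trait data frame must have a `species` column")
    }
    sp <- as.character(traits$species)
    m <- as.matrix(traits[setdiff(names(traits), "species")])
    rownames(m) <- sp
  } else {
    m <- as.matrix(traits)
    if (is.null(rownames(m))) stop("trait matrix needs species rownames")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate species in trait table")
  if (is.null(binary)) {
    binary <- colnames(m)[apply(m, 2, function(x) all(x %in% c(0, 1)))]
  } else {
    bad <- binary[!vapply(binary, function(b) all(m[, b] %in% c(0, 1)), TRUE)]
    if (length(bad)) {
      stop("binary trait column(s) not strictly 0/1: ", paste(bad, collapse = ", "))
    }
  }
  rng <- apply(m, 2, function(x) diff(range(x)))
  if (any(rng == 0)) {
    warning("dropping zero-range trait(s): ",
            paste(colnames(m)[rng == 0], collapse = ", "))
    m <- m[, rng > 0, drop = FALSE]
    if (!ncol(m)) stop("no informative traits left")
  }
  d <- as.matrix(vegan::vegdist(m, method = "gower"))
  diag(d) <- 0
  d
}

#' UPGMA dendrogram from a functional distance matrix
#'
#' Average-linkage agglomeration, returned as an `ape::phylo` tree whose
#' tip-to-tip cophenetic distances reproduce an ultrametric input exactly.
#' Species are taken in label-sorted order before clustering so that
#' equal-distance ties are broken deterministically by species label.
#'
#' @param dist symmetric distance matrix with species dimnames.
#' @return A rooted `phylo` tree with branch lengths.
#' @export
functional_dendrogram <- function(dist) {
  dist <- as.matrix(dist)
  ord <- order(rownames(dist))
  dist <- dist[ord, ord]
  hc <- hclust(as.dist(dist), method = "average")
  ape::as.phylo(hc)
}

# ---- internal spanning-edge machinery --------------------------------------

# edge x species incidence: A[e, s] = 1 iff edge e lies on the path from the
# root to the tip carrying species s; faith PD of a set of species is then
# the edge-length sum over edges with at least one present descendant
pd_cache <- function(tree, species) {
  tip <- match(species, tree$tip.label)
  if (anyNA(tip)) {
    stop("species missing from tree: ",
         paste(species[is.na(tip)], collapse = ", "))
  }
  n_edge <- nrow(tree$edge)
  child <- tree$edge[, 2]
  parent_edge <- match(seq_len(max(tree$edge)), child)  # edge above each node
  A <- matrix(0, n_edge, length(species))
  for (s in seq_along(species)) {
    node <- tip[s]
    repeat {
      e <- parent_edge[node]
      if (is.na(e)) break
      A[e, s] <- 1
      node <- tree$edge[e, 1]
    }
  }
  list(A = A, edge_length = tree$edge.length)
}

# vectorized faith PD for a sites x species presence matrix
pd_all <- function(P, cache) {
  covered <- (P > 0) %*% t(cache$A) > 0
  as.vector(covered %*% cache$edge_length)
}

# vectorized (optionally abundance-weighted) mean pairwise distance
mpd_all <- function(X, D) {
  num <- rowSums((X %*% D) * X)
  tot <- rowSums(X)
  denom <- tot^2 - rowSums(X^2)
  out <- num / denom
  out[denom <= 0] <- NA_real_
  out
}

#' Faith's phylogenetic diversity of one site
#'
#' Sum of branch lengths of the minimal subtree spanning the species present
#' at the site. The path to the root of the (pruned) tree is included, so a
#' single-species site scores its root-to-tip path length and a site holding
#' every species scores the total branch length of the tree. Empty sites
#' score 0.
#'
#' @param comm site x species abundance matrix with species column names.
#' @param site site index or row name.
#' @param tree a `phylo` tree whose tips cover the community's species.
#' @return Non-negative total branch length.
#' @export
faith_pd <- function(comm, site, tree) {
  cache <- pd_cache(tree, colnames(comm))
  pd_all(comm[site, , drop = FALSE], cache)
}

#' Mean pairwise distance of one site
#'
#' Unweighted: the mean of pairwise distances among species present.
#' Abundance-weighted: pairwise distances weighted by the product of the two
#' species' abundances (diagonal excluded),
#' `sum(n_k n_l d_kl) / sum(n_k n_l)` over unordered pairs.
#'
#' @inheritParams faith_pd
#' @param dist symmetric species x species distance matrix.
#' @param weighted use abundance-product weighting.
#' @return Mean pairwise distance; `NA` (with a warning) for sites with
#'   fewer than two species present.
#' @export
mpd <- function(comm, site, dist, weighted = FALSE) {
  dist <- as.matrix(dist)[colnames(comm), colnames(comm)]
  x <- comm[site, ]
  if (!weighted) x <- as.numeric(x > 0)
  out <- mpd_all(matrix(x, 1), dist)
  if (is.na(out)) warning("mean pairwise distance undefined: fewer than 2 species present")
  out
}

#' Null-model specification for standardized effect sizes
#'
#' `tip_shuffle` permutes the species-to-tip assignment on the phylogeny or
#' functional dendrogram (equivalently, the labels of the distance matrix);
#' `site_shuffle` permutes the sampling units (rows) of the community
#' matrix; `species_shuffle` permutes species identities (columns).
#'
#' @param kind one of `"tip_shuffle"`, `"site_shuffle"`, `"species_shuffle"`.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed making the randomization reproducible.
#' @return An object of class `null_model_spec`.
#' @export
null_model_spec <- function(kind = c("tip_shuffle", "site_shuffle", "species_shuffle"),
                            n_perm = 999, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(n_perm >= 1)
  structure(list(kind = kind, n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "null_model_spec")
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# per-site observed value + null mean/sd for one metric on one community
# matrix; `eval_fn(Xlike, perm)` must return the per-site metric where
# `perm` permutes species identities for the chosen null
ses_engine <- function(comm, null, eval_fn) {
  n_sites <- nrow(comm); S <- ncol(comm)
  obs <- eval_fn(identity_perm = TRUE, perm = seq_len(S))
  nulls <- with_seed(null$seed, {
    vapply(seq_len(null$n_perm), function(r) {
      if (null$kind == "site_shuffle") {
        obs[sample(n_sites)]
      } else {
        eval_fn(identity_perm = FALSE, perm = sample(S))
      }
    }, numeric(n_sites))
  })
  nulls <- matrix(nulls, nrow = n_sites)
  null_mean <- rowMeans(nulls)
  null_sd <- apply(nulls, 1, stats::sd)
  list(obs = obs, null_mean = null_mean, null_sd = null_sd)
}

#' Standardized effect size of a diversity metric under a null model
#'
#' For each site: the observed metric, the mean and standard deviation of
#' the metric over `n_perm` randomized communities, and the standardized
#' effect size `(observed - null mean) / null sd`. Positive SES means the
#' site is more diverse than its null expectation (overdispersion). A null
#' standard deviation of zero leaves the SES undefined (`NA`, flagged), not
#' zero.
#'
#' @param comm site x species abundance matrix with dimnames.
#' @param metric `"pd"` (Faith PD on a tree), `"mpd"` (mean pairwise
#'   distance), or `"richness"`.
#' @param tree `phylo` tree, required for `metric = "pd"`.
#' @param dist species distance matrix, required for `metric = "mpd"`.
#' @param weighted abundance-weight the MPD.
#' @param null a [null_model_spec()].
#' @return A tibble with columns `site`, `obs`, `null_mean`, `null_sd`,
#'   `ses`, `ses_defined`.
#' @export
ses <- function(comm, metric = c("pd", "mpd", "richness"), tree = NULL,
                dist = NULL, weighted = FALSE, null = null_model_spec()) {
  metric <- match.arg(metric)
  comm <- as.matrix(comm)
  species <- colnames(comm)
  eval_fn <- switch(
    metric,
    pd = {
      if (is.null(tree)) stop("`tree` required for metric = 'pd'")
      cache <- pd_cache(tree, species)
      P <- (comm > 0) * 1
      function(identity_perm, perm) {
        A <- if (identity_perm) cache$A else cache$A[, perm, drop = FALSE]
        as.vector(((P %*% t(A)) > 0) %*% cache$edge_length)
      }
    },
    mpd = {
      if (is.null(dist)) stop("`dist` required for metric = 'mpd'")
      D <- as.matrix(dist)[species, species]
      X <- if (weighted) comm else (comm > 0) * 1
      function(identity_perm, perm) {
        Dp <- if (identity_perm) D else D[perm, perm]
        mpd_all(X, Dp)
      }
    },
    richness = {
      P <- (comm > 0) * 1
      function(identity_perm, perm) rowSums(P)
    }
  )
  res <- ses_engine(comm, null, eval_fn)
  defined <- is.finite(res$null_sd) & res$null_sd > 0
  tibble::tibble(
    site = rownames(comm) %||% as.character(seq_len(nrow(comm))),
    obs = res$obs,
    null_mean = res$null_mean,
    null_sd = res$null_sd,
    ses = ifelse(defined, (res$obs - res$null_mean) / res$null_sd, NA_real_),
    ses_defined = defined
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
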