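#' Read a long-format count table from disk
#'
#' The canonical on-disk schema is comma-separated text with exactly the
#' columns `site`, `occasion`, `species`, `count`, `strata`, `temp_site`,
#' `su`, `sm`, `date_obs`, `temp_obs` (any order). Validation failures
#' report 1-based file line numbers (header is line 1).
#'
#' @param path file path.
#' @param complete,standardize passed to [as_detection_history()].
#' @return A [detection_history()].
#' @export
read_counts <- function(path, complete = TRUE, standardize = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("site", "occasion", "species", "count",
                "strata", "temp_site", "su", "sm", "date_obs", "temp_obs")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(names(data), required)
  if (length(unknown)) {
    stop("unknown column(s) in ", path, ": ", paste(unknown, collapse = ", "))
  }
  bad <- which(data$count < 0 | data$count != round(data$count))
  if (length(bad)) {
    stop("negative or non-integer count at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  }
  key <- paste(data$site, data$occasion, data$species, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (site, occasion, species) rows at line(s) ",
         paste(dup + 1L, collapse = ", "), " of ", path)
  }
  as_detection_history(data, complete = complete, standardize = standardize)
}

#' Write a detection history as the long-format count table
#'
#' @param dh a [detection_history()].
#' @param path file path.
#' @return `dh`, invisibly.
#' @export
write_counts <- function(dh, path) {
  utils::write.csv(as.data.frame(as_count_table(dh)), path, row.names = FALSE)
  invisible(dh)
}

#' Read a species x trait table
#'
#' Comma-separated text with a `species` column plus one column per trait.
#'
#' @param path file path.
#' @return A tibble suitable for [gower_distance()].
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a phylogenetic tree from Newick text
#'
#' Branch lengths are required, since every downstream metric consumes
#' them.
#'
#' @param path file path.
#' @return An `ape::phylo` tree.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick tree: ", path)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths: ", path)
  tree
}

#' Prune a tree to a community's species set
#'
#' Retains exactly the requested tips. Pruning to a single species yields a
#' degenerate one-tip tree whose single edge carries the original
#' root-to-tip path length, matching the root-inclusive PD convention.
#'
#' @param tree an `ape::phylo` tree.
#' @param species character vector of tip labels to keep.
#' @return The pruned tree.
#' @export
prune_tree <- function(tree, species) {
  species <- unique(as.character(species))
  missing_sp <- setdiff(species, tree$tip.label)
  if (length(missing_sp)) {
    stop("species absent from tree: ", paste(missing_sp, collapse = ", "))
  }
  if (length(species) == 1L) {
    cache <- pd_cache(tree, species)
    len <- sum(cache$edge_length[cache$A[, 1] > 0])
    out <- list(edge = matrix(c(2L, 1L), 1, 2), edge.length = len,
                Nnode = 1L, tip.label = species)
    class(out) <- "phylo"
    return(out)
  }
  if (length(species) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, species)
}

#' Run configuration for the command-line pipeline
#'
#' A fully serializable bundle of file paths, MCMC settings, null-model
#' settings and metric options; [write_run_config()] /
#' [read_run_config()] round-trip it through plain-text YAML.
#'
#' @param counts,tree,traits,out_dir file paths.
#' @param mcmc an [mcmc_config()].
#' @param null a [null_model_spec()].
#' @param metrics subset of `c("pd", "mpd")`.
#' @param weighted abundance-weighting flag.
#' @param binary binary trait column names (or `NULL` to auto-detect).
#' @param seed top-level seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(counts = "counts.csv", tree = "tree.nwk",
                       traits = "traits.csv", out_dir = ".",
                       mcmc = mcmc_config(), null = null_model_spec(),
                       metrics = c("pd", "mpd"), weighted = TRUE,
                       binary = NULL, seed = 1L) {
  structure(list(counts = counts, tree = tree, traits = traits,
                 out_dir = out_dir, mcmc = unclass(mcmc),
                 null = unclass(null), metrics = metrics,
                 weighted = weighted, binary = binary,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(config)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- run_config(
    counts = x$counts, tree = x$tree, traits = x$traits,
    out_dir = x$out_dir,
    mcmc = do.call(mcmc_config, x$mcmc),
    null = do.call(null_model_spec, x$null),
    metrics = x$metrics, weighted = x$weighted, binary = x$binary,
    seed = x$seed
  )
  cfg
}
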