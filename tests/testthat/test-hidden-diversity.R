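test_that("hidden-diversity value follows the standardized-deviation formula", {
  # observed equal to the draw mean -> exactly zero
  r0 <- hidden_diversity_value(2, c(1, 2, 3))
  expect_equal(r0$hd, 0)

  # hand example: draws {1, 2, 3} have mean 2, sample sd 1; obs 5 -> hd 3
  r3 <- hidden_diversity_value(5, c(1, 2, 3))
  expect_equal(r3$mean, 2)
  expect_equal(r3$sd, 1)
  expect_equal(r3$hd, 3)
  expect_identical(r3$status, "ok")

  # positive = overestimation, negative = underestimation
  expect_gt(hidden_diversity_value(9, c(1, 2, 3))$hd, 0)
  expect_lt(hidden_diversity_value(-1, c(1, 2, 3))$hd, 0)

  # zero spread is flagged, never reported as 0
  rz <- hidden_diversity_value(4, c(2, 2, 2))
  expect_true(is.na(rz$hd))
  expect_identical(rz$status, "undefined_sd0")
  expect_error(hidden_diversity_value(1, 3), "at least 2")

  # scale-free: multiplying obs and draws by c > 0 leaves hd unchanged
  set.seed(44)
  for (rep in 1:10) {
    draws <- rnorm(20, 5, 2); obs <- rnorm(1, 5, 2); c0 <- runif(1, 0.1, 9)
    expect_equal(hidden_diversity_value(c0 * obs, c0 * draws)$hd,
                 hidden_diversity_value(obs, draws)$hd, tolerance = 1e-10)
  }
})

test_that("quadrant classifier matches the four-quadrant truth table", {
  expect_equal(classify_quadrant(1.2, -0.4), "bias_overestimation")
  expect_equal(classify_quadrant(-0.8, 0.3), "bias_underestimation")
  expect_equal(classify_quadrant(-1.0, -0.2), "noise")
  expect_equal(classify_quadrant(0.5, 0.9), "noise")
  # exhaustive sign grid
  g <- expand.grid(obs = c(-1, 1), est = c(-1, 1))
  got <- classify_quadrant(g$obs, g$est)
  expect_equal(got, ifelse(g$obs > 0 & g$est < 0, "bias_overestimation",
                    ifelse(g$obs < 0 & g$est > 0, "bias_underestimation",
                           "noise")))
  # exact zeros carry no direction: noise, with a warning
  expect_warning(q0 <- classify_quadrant(0, -2), "zero")
  expect_equal(q0, "noise")
  expect_error(classify_quadrant(NA_real_, 1), "finite")
})

test_that("pipeline always reports TD and abundance and honors the metric menu", {
  ff <- cached_small_fit()
  tree <- ape::rtree(6); tree$tip.label <- ff$sim$dh$species_labels
  traits <- toy_traits(6, ff$sim$dh$species_labels)
  null <- null_model_spec("tip_shuffle", n_perm = 19, seed = 2)

  hd_pd <- hidden_diversity(ff$fit, tree = tree, traits = traits,
                            metrics = "pd", null = null)
  expect_setequal(unique(hd_pd$metric), c("TD", "abundance", "SES.PD", "SES.FD"))
  expect_equal(nrow(hd_pd), 4 * ff$sim$dh$n_sites)

  hd_mpd <- hidden_diversity(ff$fit, tree = tree, traits = traits,
                             metrics = "mpd", weighted = TRUE, null = null)
  expect_setequal(unique(hd_mpd$metric),
                  c("TD", "abundance", "SES.MPD", "SES.MFD", "SES.MPDi", "SES.MFDi"))
  hd_mpd_u <- hidden_diversity(ff$fit, tree = tree, traits = traits,
                               metrics = "mpd", weighted = FALSE, null = null)
  expect_setequal(unique(hd_mpd_u$metric),
                  c("TD", "abundance", "SES.MPD", "SES.MFD"))

  # detection correction only adds individuals: richness hd <= 0 on any fit
  td <- hd_pd[hd_pd$metric %in% c("TD", "abundance"), ]
  expect_true(all(td$hd[td$hd_status == "ok"] <= 1e-12))
  expect_true(all(is.na(td$quadrant)))

  # SES rows carry a quadrant wherever hd is computable
  sesr <- hd_pd[hd_pd$metric == "SES.PD", ]
  expect_true(all(sesr$quadrant[!is.na(sesr$div_obs)] %in%
                    c("noise", "bias_overestimation", "bias_underestimation")))
  expect_equal(sesr$raw_difference, sesr$div_obs - sesr$div_est_mean)
})

test_that("degenerate draws are flagged undefined, never zero", {
  obs <- rbind(s1 = c(2L, 1L, 0L), s2 = c(1L, 1L, 1L))
  colnames(obs) <- c("spA", "spB", "spC")
  tree <- prune_tree(toy_tree(), colnames(obs))
  traits <- toy_traits(3, colnames(obs))
  hd <- hidden_diversity(obs, draws = list(obs, obs, obs), tree = tree,
                         traits = traits, metrics = "pd",
                         null = null_model_spec(n_perm = 9, seed = 1))
  raw <- hd[hd$metric %in% c("TD", "abundance"), ]
  expect_true(all(raw$hd_status == "undefined_sd0"))
  expect_true(all(is.na(raw$hd)))
})

test_that("species missing from tree or traits raise reconciliation errors", {
  obs <- rbind(s1 = c(1L, 1L)); colnames(obs) <- c("spA", "spZZ")
  expect_error(
    hidden_diversity(obs, draws = list(obs, obs), tree = toy_tree(),
                     traits = toy_traits()),
    "absent from tree.*spZZ")
  obs2 <- rbind(s1 = c(1L, 1L)); colnames(obs2) <- c("spA", "spB")
  tr_missing <- toy_traits()[-2, ]
  expect_error(
    hidden_diversity(obs2, draws = list(obs2, obs2), tree = toy_tree(),
                     traits = tr_missing),
    "absent from traits.*spB")
})

test_that("hidden-diversity tables round-trip through CSV and plot", {
  ff <- cached_small_fit()
  tree <- ape::rtree(6); tree$tip.label <- ff$sim$dh$species_labels
  hd <- hidden_diversity(ff$fit, tree = tree,
                         traits = toy_traits(6, ff$sim$dh$species_labels),
                         metrics = "pd", null = null_model_spec(n_perm = 9, seed = 3))
  path <- tempfile(fileext = ".csv")
  write_hidden_diversity(hd, path)
  back <- read_hidden_diversity(path)
  expect_equal(as.data.frame(back), as.data.frame(hd), tolerance = 1e-12)
  expect_s3_class(autoplot(hd), "ggplot")
})
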