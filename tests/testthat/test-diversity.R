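test_that("richness and total abundance count what is present", {
  comm <- rbind(site1 = c(0, 2, 1), site2 = c(0, 0, 0))
  colnames(comm) <- paste0("sp", 1:3)
  expect_equal(richness(comm, "site1"), 2)
  expect_equal(total_abundance(comm, "site1"), 3)
  expect_equal(richness(comm, "site2"), 0)
  expect_equal(total_abundance(comm, "site2"), 0)
})

test_that("Gower distance mixes continuous and binary traits correctly", {
  # identical rows are at distance zero
  tr <- tibble::tibble(species = c("a", "b", "c"), x = c(1, 1, 4),
                       b1 = c(1, 1, 0))
  d0 <- gower_distance(tr)
  expect_equal(d0["a", "b"], 0)

  # a table with no informative trait is rejected
  flat <- tibble::tibble(species = c("a", "b"), x = c(1, 1), b1 = c(0, 0))
  expect_error(suppressWarnings(gower_distance(flat)), "no informative traits")

  # two species differing in one of t binary traits -> 1/t
  tr2 <- tibble::tibble(species = c("a", "b"), b1 = c(0, 1), b2 = c(1, 1),
                        b3 = c(0, 0))
  expect_warning(d2 <- gower_distance(tr2), "zero-range")  # b2, b3 dropped
  # after dropping uninformative traits only the mismatching one remains
  expect_equal(d2["a", "b"], 1)
  tr2b <- tibble::tibble(species = c("a", "b", "c"),
                         b1 = c(0, 1, 1), b2 = c(1, 1, 0), b3 = c(0, 0, 1))
  d2b <- gower_distance(tr2b)
  expect_equal(d2b["a", "b"], 1 / 3)

  # 3 species x (1 continuous, 1 binary) verified against the hand formula
  tr3 <- tibble::tibble(species = c("a", "b", "c"), cont = c(0, 1, 3),
                        bin = c(0, 1, 1))
  d3 <- gower_distance(tr3)
  expect_equal(d3["a", "b"], ((1 / 3) + 1) / 2)
  expect_equal(d3["a", "c"], ((3 / 3) + 1) / 2)
  expect_equal(d3["b", "c"], ((2 / 3) + 0) / 2)

  # axioms: symmetry, zero diagonal, range [0, 1]
  set.seed(12)
  tr4 <- tibble::tibble(species = letters[1:6], c1 = rnorm(6), c2 = runif(6),
                        b1 = rbinom(6, 1, 0.5))
  d4 <- gower_distance(tr4)
  expect_equal(d4, t(d4))
  expect_equal(unname(diag(d4)), rep(0, 6))
  expect_true(all(d4 >= 0 & d4 <= 1))
  expect_error(gower_distance(tr4, binary = "c1"), "not strictly 0/1")
})

test_that("UPGMA dendrogram reproduces hand-traced agglomeration", {
  # two species at distance d -> a cherry with tip-to-tip path d
  d2 <- matrix(c(0, 0.6, 0.6, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- functional_dendrogram(d2)
  expect_s3_class(t2, "phylo")
  expect_equal(unname(cophenetic(t2)["a", "b"]), 0.6)

  # ultrametric input is a fixed point of UPGMA
  du <- matrix(c(0, 2, 8, 8,
                 2, 0, 8, 8,
                 8, 8, 0, 4,
                 8, 8, 4, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tu <- functional_dendrogram(du)
  expect_equal(cophenetic(tu)[letters[1:4], letters[1:4]], du)

  # hand-executed UPGMA on a non-ultrametric toy: merge (a,b) at 2, then c
  # at mean(6, 8) = 7, then d at mean(10, 12, 14) = 12
  dn <- matrix(c(0, 2, 6, 10,
                 2, 0, 8, 12,
                 6, 8, 0, 14,
                 10, 12, 14, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tn <- functional_dendrogram(dn)
  cp <- cophenetic(tn)
  expect_equal(unname(cp["a", "b"]), 2)
  expect_equal(unname(cp["a", "c"]), 7)
  expect_equal(unname(cp["c", "b"]), 7)
  expect_equal(unname(cp["d", "a"]), 12)
})

test_that("Faith PD sums the root-inclusive spanning subtree", {
  tree <- toy_tree()
  spp <- tree$tip.label
  comm <- rbind(all = rep(1, 4), one = c(1, 0, 0, 0), two = c(0, 1, 0, 1),
                none = rep(0, 4))
  colnames(comm) <- spp
  # full community spans every edge
  expect_equal(faith_pd(comm, "all", tree), sum(tree$edge.length))
  # single species: root-to-tip path (spA: 1 + 1; the stem below the root
  # node is not part of the tree's edge set)
  expect_equal(faith_pd(comm, "one", tree), 2)
  # empty site scores zero
  expect_equal(faith_pd(comm, "none", tree), 0)
  # brute-force edge enumeration oracle + picante cross-check on random trees
  set.seed(5)
  for (rep in 1:3) {
    rt <- ape::rtree(7)
    rt$tip.label <- paste0("t", 1:7)
    cm <- matrix(rbinom(21, 1, 0.6), 3, 7,
                 dimnames = list(paste0("s", 1:3), rt$tip.label))
    cm[1, ] <- 1
    mine <- vapply(1:3, function(i) faith_pd(cm, i, rt), 0)
    ref <- suppressWarnings(picante::pd(cm, rt, include.root = TRUE)$PD)
    keep <- rowSums(cm) > 0
    expect_equal(mine[keep], ref[keep], tolerance = 1e-12)
  }
  # monotone: adding a species never decreases PD
  base <- c(1, 0, 0, 0); richer <- c(1, 0, 1, 0)
  cm2 <- rbind(a = base, b = richer); colnames(cm2) <- spp
  expect_gte(faith_pd(cm2, "b", tree), faith_pd(cm2, "a", tree))
})

test_that("MPD matches closed forms and the abundance-product weighting", {
  D <- matrix(c(0, 1, 2,
                1, 0, 3,
                2, 3, 0), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  comm <- rbind(s1 = c(1, 2, 3), s2 = c(5, 7, 0), s3 = c(1, 0, 0))
  colnames(comm) <- letters[1:3]

  # two species present: the single pairwise distance, any weights
  expect_equal(mpd(comm, "s2", D), 1)
  expect_equal(mpd(comm, "s2", D, weighted = TRUE), 1)

  # weighted hand example: (1*2*1 + 1*3*2 + 2*3*3) / (2 + 3 + 6) = 26/11
  expect_equal(mpd(comm, "s1", D, weighted = TRUE), 26 / 11)
  expect_equal(mpd(comm, "s1", D), mean(c(1, 2, 3)))

  # three equidistant species -> that distance regardless of weighting
  De <- matrix(0.4, 3, 3, dimnames = dimnames(D)); diag(De) <- 0
  expect_equal(mpd(comm, "s1", De, weighted = TRUE), 0.4)

  # fewer than two species is undefined and flagged
  expect_warning(v <- mpd(comm, "s3", D), "fewer than 2")
  expect_true(is.na(v))

  # invariant under species reordering
  ord <- c(3, 1, 2)
  expect_equal(mpd(comm[, ord], "s1", D[ord, ord], weighted = TRUE), 26 / 11)

  # cross-checks against picante: exact for incidence; for the weighted form
  # picante includes self-pairs, so rescale by (sum n)^2 / ((sum n)^2 - sum n^2)
  set.seed(13)
  rt <- ape::rtree(6); rt$tip.label <- paste0("t", 1:6)
  Dp <- cophenetic(rt)
  cm <- matrix(rpois(12, 2), 2, 6, dimnames = list(c("x", "y"), rt$tip.label))
  for (i in 1:2) {
    expect_equal(mpd(cm, i, Dp), picante::mpd(cm, Dp)[i], tolerance = 1e-12)
    n <- cm[i, ]
    adj <- sum(n)^2 / (sum(n)^2 - sum(n^2))
    expect_equal(mpd(cm, i, Dp, weighted = TRUE),
                 picante::mpd(cm, Dp, abundance.weighted = TRUE)[i] * adj,
                 tolerance = 1e-12)
  }
})

test_that("SES engine reproduces exhaustive permutation nulls and conventions", {
  tree <- toy_tree()
  comm <- rbind(s1 = c(1, 2, 0, 0), s2 = c(1, 1, 1, 0), s3 = c(0, 1, 0, 3))
  colnames(comm) <- tree$tip.label

  # richness is invariant under label permutation: sd 0, flagged undefined
  sr <- ses(comm, "richness", null = null_model_spec("tip_shuffle", 30, 1))
  expect_true(all(!sr$ses_defined))
  expect_true(all(is.na(sr$ses)))

  # exhaustive 4! oracle for the PD null distribution
  P <- (comm > 0) * 1
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(x) length(unique(x)) == 4), ]
  ex <- apply(perms, 1, function(pm) {
    cm <- P[, pm, drop = FALSE]; colnames(cm) <- colnames(P)
    vapply(1:3, function(i) faith_pd(cm, i, tree), 0)
  })
  sp <- ses(comm, "pd", tree = tree, null = null_model_spec("tip_shuffle", 3000, 2))
  expect_equal(sp$null_mean, rowMeans(ex), tolerance = 0.02)
  expect_equal(sp$null_sd, apply(ex, 1, sd), tolerance = 0.03)

  # sign convention: observed above the null mean -> positive SES
  expect_equal(sign(sp$ses[sp$ses_defined]),
               sign((sp$obs - sp$null_mean)[sp$ses_defined]))

  # seed-reproducible
  s1 <- ses(comm, "pd", tree = tree, null = null_model_spec("tip_shuffle", 99, 7))
  s2 <- ses(comm, "pd", tree = tree, null = null_model_spec("tip_shuffle", 99, 7))
  expect_identical(s1, s2)

  # site_shuffle permutes sampling units: null values are drawn from the
  # observed per-site values
  ss <- ses(comm, "pd", tree = tree, null = null_model_spec("site_shuffle", 200, 3))
  obs_range <- range(ss$obs)
  expect_true(all(ss$null_mean >= obs_range[1] & ss$null_mean <= obs_range[2]))
})
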