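test_that("simulated trees are ultrametric, sized and rescaled as requested", {
  phy <- simulate_tree(3, seed = 200)
  expect_equal(ape::Ntip(phy), 3L)
  expect_equal(phy$Nnode, 2L)
  expect_silent(validate_chronogram(phy))

  phy100 <- simulate_tree(20, root_age = 100, seed = 201)
  expect_equal(tree_depth(phy100), 100, tolerance = 1e-9)

  # determinism: same seed, same Newick string
  expect_identical(write_newick(simulate_tree(10, seed = 7)),
                   write_newick(simulate_tree(10, seed = 7)))
  expect_error(simulate_tree(10), "seed")
})

test_that("pseudo-posterior ensembles stay ultrametric and centered on the input", {
  phy <- simulate_tree(30, root_age = 50, seed = 210)
  # zero jitter returns identical trees
  ens0 <- make_pseudo_posterior(phy, 3, branch_jitter_sd = 0, seed = 211)
  for (t in ens0$posterior)
    expect_equal(t$edge.length, phy$edge.length, tolerance = 1e-12)

  ens <- make_pseudo_posterior(phy, 200, branch_jitter_sd = 0.08,
                               seed = 212)
  ages <- vapply(ens$posterior, tree_depth, numeric(1))
  for (t in ens$posterior[1:10]) expect_silent(validate_chronogram(t))
  # mean-one lognormal jitter keeps the mean root age within 2 SE of input
  expect_lt(abs(mean(ages) - 50), 2 * sd(ages) / sqrt(length(ages)))

  # NNI topologies keep the tip set and ultrametricity
  ensn <- make_pseudo_posterior(phy, 3, branch_jitter_sd = 0.05, seed = 213,
                                topology = "nni")
  for (t in ensn$posterior) {
    expect_setequal(t$tip.label, phy$tip.label)
    expect_silent(validate_chronogram(t))
  }
})

test_that("trait simulation reproduces the model covariance empirically", {
  phy <- simulate_tree(12, root_age = 10, seed = 220)
  X <- simulate_traits(phy, "BM", list(sigma2 = 2, z0 = 1), seed = 221,
                       n_datasets = 2000)
  C <- phylo_covariance(phy)
  # single-tip variance ~ sigma2 * T
  expect_equal(var(X[1, ]), 2 * 10, tolerance = 0.1 * 20)
  # pick the most correlated tip pair and check its covariance
  ij <- which(C == max(C[upper.tri(C)]), arr.ind = TRUE)[1, ]
  expect_equal(cov(X[ij[1], ], X[ij[2], ]), 2 * C[ij[1], ij[2]],
               tolerance = 0.15 * 2 * C[ij[1], ij[2]])

  # degenerate rate pins every tip at the root state
  X0 <- simulate_traits(phy, "BM", list(sigma2 = 0, z0 = 5), seed = 222)
  expect_equal(unname(X0), rep(5, 12))

  # white noise ignores the tree
  W <- simulate_traits(phy, "white_noise", list(sigma2 = 1, z0 = 0),
                       seed = 223, n_datasets = 500)
  expect_lt(abs(cov(W[ij[1], ], W[ij[2], ])), 0.2)
})

test_that("accession simulation respects the count law and noise level", {
  phy <- simulate_tree(81, seed = 230)
  mu <- setNames(rnorm(81, 10), phy$tip.label)

  # zero within-OTU noise: every OTU mean equals its tip mean
  rec0 <- simulate_accessions(mu, within_otu_sd = 0, seed = 231)
  s0 <- summarize_by_otu(rec0, "bio1")
  expect_equal(s0$mean, unname(mu[s0$otu_id]), tolerance = 1e-12)

  rec <- simulate_accessions(mu, within_otu_sd = 2, seed = 232)
  cnt <- table(rec$otu_id)
  expect_gte(min(cnt), 1)
  expect_lte(max(cnt), 454)

  # pooled SD recovers the generating within-OTU sd at large n
  big <- simulate_accessions(mu, within_otu_sd = 2, seed = 233,
                             counts = rep(40, 81))
  se <- pooled_se(big, "bio1")
  expect_equal(sqrt(attr(se, "pooled_var")), 2, tolerance = 0.1 * 2)
})

test_that("a full synthetic study is reproducible and carries the study shape", {
  st <- simulate_study(n_tips = 20, n_posterior = 4, seed = 240)
  expect_equal(ape::Ntip(st$mcc), 20L)
  expect_length(st$posterior, 4)
  expect_equal(dim(st$tip_means), c(20L, 19L))
  expect_setequal(colnames(st$tip_means), paste0("bio", 1:19))
  expect_true(all(paste0("bio", 1:19) %in% names(st$records)))

  st2 <- simulate_study(n_tips = 20, n_posterior = 4, seed = 240)
  expect_identical(st$tip_means, st2$tip_means)
  expect_identical(st$records, st2$records)

  # round trip through the on-disk formats
  dir <- withr::local_tempdir()
  write_study(st, dir)
  back <- load_study(file.path(dir, "mcc.nwk"), file.path(dir, "posterior.nwk"),
                     file.path(dir, "accessions.csv"),
                     file.path(dir, "groups.yml"), rel_tol = 1e-4)
  expect_equal(sort(back$mcc$tip.label), sort(st$mcc$tip.label))
  expect_length(back$posterior, 4)
  expect_equal(nrow(back$records), nrow(st$records))
})

test_that("derived seeds are deterministic, distinct and within integer range", {
  s1 <- derive_seed(42, "signal", "bio1", "mcc")
  expect_identical(s1, derive_seed(42, "signal", "bio1", "mcc"))
  expect_false(s1 == derive_seed(42, "signal", "bio2", "mcc"))
  expect_false(s1 == derive_seed(43, "signal", "bio1", "mcc"))
  ss <- vapply(1:500, function(i) derive_seed(1, "x", i), integer(1))
  expect_true(all(ss >= 1 & ss <= 2147483646))
  expect_gt(length(unique(ss)), 495)
})
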