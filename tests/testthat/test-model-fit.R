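test_that("model covariances match closed forms", {
  phy <- parse_newick("((A:1,B:1):1,C:2);")
  C <- phylo_covariance(phy)
  expect_equal(model_covariance(phy, "BM", list(sigma2 = 1)), C)
  expect_equal(model_covariance(phy, "BM", list(sigma2 = 2.5)), 2.5 * C)

  # OU with vanishing pull reduces to BM
  V <- model_covariance(phy, "OU", list(sigma2 = 1, alpha = 1e-8))
  expect_equal(V, C, tolerance = 1e-4)

  # OU 2-tip star: diagonal sigma2/(2 alpha) (1 - exp(-2 alpha T)), off-diag 0
  star <- parse_newick("(A:1,B:1);")
  V2 <- model_covariance(star, "OU", list(sigma2 = 2, alpha = 1))
  expect_equal(diag(V2), c(A = 1, B = 1) * (1 - exp(-2)), tolerance = 1e-12)
  expect_equal(V2[1, 2], 0)

  # EB a = 0 is BM; EB matches the transformed-tree covariance
  expect_equal(model_covariance(phy, "EB", list(sigma2 = 1, a = 0)), C)
  a <- -0.9
  Veb <- model_covariance(phy, "EB", list(sigma2 = 1, a = a))
  Ceb <- phylo_covariance(transform_tree(phy, "EB", list(a = a)))
  expect_equal(Veb, Ceb, tolerance = 1e-12)

  nonultra <- parse_newick("((A:1,B:1):1,C:1.5);", ultrametric = "none")
  expect_error(model_covariance(nonultra, "OU",
                                list(sigma2 = 1, alpha = 1)), "ultrametric")
})

test_that("mvn_loglik matches the standard normal, independence, and dense oracle", {
  expect_equal(mvn_loglik(0, 0, matrix(1)), -0.5 * log(2 * pi),
               tolerance = 1e-12)

  # diagonal V: sum of univariate log densities
  x <- c(0.3, -1, 2)
  v <- c(1, 4, 0.25)
  expect_equal(mvn_loglik(x, 0, diag(v)),
               sum(dnorm(x, 0, sqrt(v), log = TRUE)), tolerance = 1e-12)

  set.seed(12)
  A <- matrix(rnorm(25), 5)
  V <- crossprod(A) + diag(5)
  x5 <- rnorm(5)
  expect_equal(mvn_loglik(x5, 0.7, V), bf_mvn_loglik(x5, 0.7, V),
               tolerance = 1e-10)

  expect_error(mvn_loglik(x5, 0, -V), "positive definite")
  expect_error(mvn_loglik(x5, c(0, 1), V), "dimension")
})

test_that("BM parameter recovery on an 81-tip tree", {
  phy <- simulate_tree(81, seed = 80)
  X <- simulate_traits(phy, "BM", list(sigma2 = 1, z0 = 0), seed = 81,
                       n_datasets = 60)
  C <- phylo_covariance(phy)
  fits <- apply(X, 2, function(x) {
    f <- fit_model(phy, x, model = "BM", C = C)
    c(f$sigma2, f$z0)
  })
  expect_equal(mean(fits[1, ]), 1, tolerance = 0.1)
  expect_lt(abs(mean(fits[2, ])), 0.1 * sqrt(tree_depth(phy)))
})

test_that("nested-model identities: EB(a = 0) and OU(alpha -> 0) recover BM", {
  phy <- rand_tree(20, seed = 90)
  x <- setNames(rnorm(20), phy$tip.label)
  bm <- fit_model(phy, x, model = "BM")
  C <- phylo_covariance(phy)
  # lnL of the EB model with a pinned at zero equals the BM lnL exactly
  p0 <- phyniche:::.profile_bm_like(x[phy$tip.label],
                                    model_covariance(phy, "EB",
                                                     list(sigma2 = 1, a = 0),
                                                     C = C),
                                    rep(0, 20),
                                    phyniche:::.sigma2_bounds(x, tree_depth(phy)))
  expect_identical(p0$lnL, bm$lnL)
  # near-zero OU pull approaches the BM likelihood
  pou <- phyniche:::.profile_bm_like(x[phy$tip.label],
                                     model_covariance(phy, "OU",
                                                      list(sigma2 = 1,
                                                           alpha = 1e-8),
                                                      C = C),
                                     rep(0, 20),
                                     phyniche:::.sigma2_bounds(x, tree_depth(phy)))
  expect_equal(pou$lnL, bm$lnL, tolerance = 1e-4)
})

test_that("OU equals accelerating-rates EB on ultrametric trees", {
  # OU with pull alpha is, on an ultrametric tree, an accelerating-rates
  # model with exponent a = 2*alpha; moderate pull keeps both optima
  # interior to their parameter bounds
  phy <- rand_tree(25, seed = 95)
  Td <- tree_depth(phy)
  x <- simulate_traits(phy, "OU",
                       list(sigma2 = 1, z0 = 0, alpha = 2 / Td), seed = 96)
  ou <- fit_model(phy, x, model = "OU")
  ac <- fit_model(phy, x, model = "EB", ac_mode = TRUE)
  expect_equal(ac$lnL, ou$lnL, tolerance = 1e-4)
  expect_equal(ac$a, 2 * ou$alpha, tolerance = 0.05)
})

test_that("the optimum beats random admissible parameter draws", {
  phy <- rand_tree(15, seed = 99)
  x <- setNames(cumsum(rnorm(15)), phy$tip.label)
  C <- phylo_covariance(phy)
  Td <- tree_depth(phy)
  ou <- fit_model(phy, x, model = "OU", C = C)
  set.seed(100)
  for (i in 1:20) {
    alpha <- exp(runif(1, log(1e-6), log(50 / Td)))
    s2 <- exp(runif(1, log(1e-4), log(1e2))) * var(x) / Td
    V <- model_covariance(phy, "OU", list(sigma2 = s2, alpha = alpha), C = C)
    mu <- phylogenetic_mean(x[phy$tip.label], V)
    expect_gte(ou$lnL + 1e-8, mvn_loglik(x[phy$tip.label], mu, V))
  }
})

test_that("AICc weights follow the closed form and sum to one", {
  mk <- function(aicc) list(model = "BM", AICc = aicc, lnL = 0, k = 2L,
                            n = 30L)
  fits <- aicc_weights(list(a = mk(10), b = mk(10), c = mk(10)))
  expect_equal(vapply(fits, `[[`, numeric(1), "weight"),
               c(a = 1, b = 1, c = 1) / 3)
  two <- aicc_weights(list(a = mk(10), b = mk(12)))
  expect_equal(unname(two$a$weight / two$b$weight), exp(1),
               tolerance = 1e-12)
  expect_equal(sum(vapply(two, `[[`, numeric(1), "weight")), 1,
               tolerance = 1e-12)
  expect_error(aicc_weights(list(mk(1))), "at least 2")
  bad <- list(a = mk(1), b = modifyList(mk(2), list(n = 10L)))
  expect_error(aicc_weights(bad), "different sizes")
})

test_that("AICc bookkeeping: parameter counts and the correction term", {
  phy <- rand_tree(12, seed = 101)
  x <- setNames(rnorm(12), phy$tip.label)
  bm <- fit_model(phy, x, model = "BM")
  ou <- fit_model(phy, x, model = "OU")
  expect_equal(bm$k, 2L)
  expect_equal(ou$k, 3L)
  expect_equal(bm$AICc, -2 * bm$lnL + 2 * 2 + 2 * 2 * 3 / (12 - 3),
               tolerance = 1e-12)
})

test_that("measurement error damps sensitivity to single-tip perturbation", {
  phy <- simulate_tree(40, seed = 110)
  x <- simulate_traits(phy, "BM", list(sigma2 = 1, z0 = 0), seed = 111)
  C <- phylo_covariance(phy)
  xx <- x[phy$tip.label]
  # fixed-parameter finite difference: with known error variance on the
  # diagonal, a jolt to any single tip moves the likelihood less
  delta <- function(se2, tip) {
    V <- C + diag(se2, 40)
    mu <- phylogenetic_mean(xx, V)
    up <- xx; up[tip] <- up[tip] + 5
    dn <- xx; dn[tip] <- dn[tip] - 5
    # symmetric difference isolates the curvature (V^-1 diagonal) term
    abs(mvn_loglik(up, mu, V) + mvn_loglik(dn, mu, V) -
          2 * mvn_loglik(xx, mu, V))
  }
  for (tip in c(1, 10, 25))
    expect_lt(delta(25, tip), delta(0, tip))
})
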