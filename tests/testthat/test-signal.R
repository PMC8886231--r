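test_that("phylogenetic mean solves the GLS system", {
  phy <- parse_newick("((A:1,B:1):1,C:2);")
  C <- phylo_covariance(phy)
  expect_equal(phylogenetic_mean(rep(4, 3), C), 4)

  # star tree: GLS mean is the arithmetic mean
  star <- diag(3)
  x <- c(1, 5, 9)
  expect_equal(phylogenetic_mean(x, star), mean(x))

  # explicit dense solve on the 3-tip tree
  xx <- c(A = 0, B = 0, C = 3)[colnames(C)]
  Cinv <- solve(C)
  one <- rep(1, 3)
  expect_equal(phylogenetic_mean(xx, C),
               drop(t(one) %*% Cinv %*% xx) / drop(t(one) %*% Cinv %*% one),
               tolerance = 1e-12)

  expect_error(phylogenetic_mean(1:2, C), "dimension")
})

test_that("K is exactly 1 on a star tree and matches the dense-matrix oracle", {
  star <- ape::stree(8, type = "star")
  star$edge.length <- rep(1, 8)
  x <- setNames(rnorm(8), star$tip.label)
  expect_equal(blomberg_k(star, x)$K, 1, tolerance = 1e-12)

  for (seed in 1:12) {
    n <- sample(5:15, 1)
    phy <- rand_tree(n, seed = 900 + seed)
    x <- setNames(rnorm(n), phy$tip.label)
    expect_equal(blomberg_k(phy, x)$K, bf_k(phy, x), tolerance = 1e-10)
  }
})

test_that("error-aware K agrees with a dense-matrix recomputation", {
  # independent route: ML sigma2 by dense optimize over the full MVN
  # likelihood, then the K pieces via explicit solve() on C + E/sigma2
  for (seed in 1:4) {
    n <- 10 + seed
    phy <- rand_tree(n, seed = 700 + seed)
    set.seed(800 + seed)
    x <- setNames(rnorm(n), phy$tip.label)
    se <- setNames(runif(n, 0.05, 0.5), phy$tip.label)
    C <- phylo_covariance(phy)
    dense_lnl <- function(s2) {
      V <- s2 * C + diag(se[phy$tip.label]^2)
      Vi <- solve(V)
      one <- rep(1, n)
      mu <- drop(t(one) %*% Vi %*% x[phy$tip.label]) /
        drop(t(one) %*% Vi %*% one)
      bf_mvn_loglik(x[phy$tip.label], mu, V)
    }
    o <- optimize(function(ls) -dense_lnl(exp(ls)), c(log(1e-6), log(1e4)),
                  tol = 1e-12)
    s2 <- exp(o$minimum)
    Ct <- C + diag(se[phy$tip.label]^2) / s2
    Ci <- solve(Ct)
    one <- rep(1, n)
    ahat <- drop(t(one) %*% Ci %*% x[phy$tip.label]) /
      drop(t(one) %*% Ci %*% one)
    MSE0 <- drop(crossprod(x[phy$tip.label] - ahat)) / (n - 1)
    MSE <- drop(t(x[phy$tip.label] - ahat) %*% Ci %*%
                  (x[phy$tip.label] - ahat)) / (n - 1)
    RBM <- (sum(diag(Ct)) - n / drop(t(one) %*% Ci %*% one)) / (n - 1)
    k_dense <- (MSE0 / MSE) / RBM
    fit <- blomberg_k(phy, x, se)
    expect_equal(fit$K, k_dense, tolerance = 1e-7)
    expect_equal(fit$sigma2_hat, s2, tolerance = 1e-5)
  }
})

test_that("K is invariant to affine trait transforms", {
  phy <- rand_tree(20, seed = 21)
  x <- setNames(rnorm(20), phy$tip.label)
  se <- setNames(runif(20, 0, 0.3), phy$tip.label)
  k0 <- blomberg_k(phy, x, se)$K
  k1 <- blomberg_k(phy, -2.5 * x + 7, 2.5 * se)$K
  expect_equal(k1, k0, tolerance = 1e-6)
})

test_that("K distinguishes Brownian from phylogeny-free traits", {
  phy <- simulate_tree(81, seed = 300)
  Xbm <- simulate_traits(phy, "BM", list(sigma2 = 1, z0 = 0), seed = 301,
                         n_datasets = 60)
  Xwn <- simulate_traits(phy, "white_noise", list(sigma2 = 1, z0 = 0),
                         seed = 302, n_datasets = 60)
  C <- phylo_covariance(phy)
  k_bm <- apply(Xbm, 2, function(x) blomberg_k(phy, x, C = C)$K)
  k_wn <- apply(Xwn, 2, function(x) blomberg_k(phy, x, C = C)$K)
  expect_gt(mean(k_bm), 0.8)
  expect_lt(mean(k_wn), 0.5)
})

test_that("errors propagate: constant traits and tiny trees are rejected", {
  phy <- rand_tree(5, seed = 1)
  expect_error(blomberg_k(phy, setNames(rep(1, 5), phy$tip.label)),
               "zero trait variance")
  two <- parse_newick("(A:1,B:1);")
  expect_error(blomberg_k(two, c(A = 0, B = 1)), "at least 3")
  expect_error(blomberg_k(phy, setNames(rnorm(5), phy$tip.label), se = -1),
               "se")
})

test_that("randomization p is exact on a separable 4-tip fixture", {
  phy <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  x <- c(A = 0, B = 0, C = 10, D = 10)
  # by exhaustive enumeration of the 4! relabelings, only the 8 that keep
  # sister pairs intact attain K >= K_obs, so the exact p is 8/24 = 1/3;
  # with the two-block structure the observed K is the maximum, and the
  # proportion of permutations with K_perm >= K_obs must converge there
  perms <- matrix(unlist(combinat_perms(4)), ncol = 4, byrow = TRUE)
  C <- phylo_covariance(phy)
  k_all <- apply(perms, 1, function(ix) {
    xx <- setNames(x[ix], phy$tip.label)
    blomberg_k(phy, xx)$K
  })
  k_obs <- blomberg_k(phy, x)$K
  exact_p <- mean(k_all >= k_obs - 1e-12)
  r <- k_randomization_test(phy, x, n_rand = 1000, seed = 42)
  expect_equal(r$p, exact_p, tolerance = 0.05)
  expect_lte(r$p, 0.5)

  # symmetry: on a star tree K is permutation-invariant, so p = 1
  star <- ape::stree(6, type = "star")
  star$edge.length <- rep(1, 6)
  xs <- setNames(rnorm(6), star$tip.label)
  rs <- k_randomization_test(star, xs, n_rand = 200, seed = 9)
  expect_equal(rs$p, 1)

  # defaults and bookkeeping
  expect_equal(formals(k_randomization_test)$n_rand, 1000)
  expect_equal(r$n_rand, 1000L)
  expect_error(k_randomization_test(phy, x, n_rand = 10), "seed")
})

test_that("joint permutation of (x, se) keeps the error structure attached", {
  phy <- rand_tree(10, seed = 77)
  x <- setNames(rnorm(10), phy$tip.label)
  se <- setNames(runif(10, 0.1, 0.4), phy$tip.label)
  r1 <- k_randomization_test(phy, x, se, n_rand = 50, seed = 5)
  r2 <- k_randomization_test(phy, x, se, n_rand = 50, seed = 5,
                             reestimate_sigma2 = FALSE)
  expect_true(is.finite(r1$p) && is.finite(r2$p))
  expect_length(r1$K_perm, 50)
  # identical seeds give identical permutation streams
  r3 <- k_randomization_test(phy, x, se, n_rand = 50, seed = 5)
  expect_identical(r1$K_perm, r3$K_perm)
})
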