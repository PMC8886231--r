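#' Phylogenetic (GLS) mean
#'
#' The generalized least squares estimate of the root state,
#' `a_hat = (1' C^-1 1)^-1 1' C^-1 x`. If C is numerically singular a tiny
#' ridge (1e-12 of the mean diagonal) is added, with a message.
#'
#' @param x Numeric tip values.
#' @param C Phylogenetic covariance matrix (same order as `x`).
#' @return Scalar GLS mean.
#' @export
phylogenetic_mean <- function(x, C) {
  if (length(x) != nrow(C) || nrow(C) != ncol(C))
    stop("dimension mismatch between x and C", call. = FALSE)
  L <- tryCatch(chol(C), error = function(e) {
    message("covariance singular; adding 1e-12 ridge")
    chol(C + diag(1e-12 * mean(diag(C)), nrow(C)))
  })
  xi <- backsolve(L, x, transpose = TRUE)
  oi <- backsolve(L, rep(1, length(x)), transpose = TRUE)
  sum(oi * xi) / sum(oi * oi)
}

# Fast exact path for K with strictly positive errors. One symmetric
# eigendecomposition of M = D^-1/2 C D^-1/2 (D = diag(se^2)) turns every
# sigma2 evaluation into O(n): V = sigma2*C + D = D^1/2 (sigma2*M + I) D^1/2,
# so log-determinants, GLS solves and the K quadratic forms are all sums
# over eigenvalues. Algebraically identical to the Cholesky route.
.k_se_fast <- function(C, x, se, sigma2_bounds, trC = sum(diag(C))) {
  n <- length(x)
  d <- se
  M <- C / tcrossprod(d)
  eig <- eigen(M, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  u <- crossprod(eig$vectors, x / d)
  o <- crossprod(eig$vectors, 1 / d)
  logdetD <- 2 * sum(log(d))
  eval_s2 <- function(log_s2) {
    s2 <- exp(log_s2)
    w <- 1 / (s2 * lam + 1)
    ahat <- sum(o * u * w) / sum(o * o * w)
    quad <- sum((u - ahat * o)^2 * w)
    -0.5 * (n * log(2 * pi) + sum(log(s2 * lam + 1)) + logdetD + quad)
  }
  cuts <- seq(log(sigma2_bounds[1]), log(sigma2_bounds[2]), length.out = 4)
  best_ls <- cuts[1]; best_l <- -Inf
  for (k in 1:3) {
    opt <- stats::optimize(function(ls) -eval_s2(ls),
                           interval = c(cuts[k], cuts[k + 1]), tol = 1e-10)
    if (-opt$objective > best_l) { best_l <- -opt$objective
                                   best_ls <- opt$minimum }
  }
  s2 <- exp(best_ls)
  w <- 1 / (s2 * lam + 1)
  ahat <- sum(o * u * w) / sum(o * o * w)
  # C-tilde = C + D/s2 = V/s2, so its inverse quadratic forms are s2 * (V
  # forms) in the same eigenbasis
  MSE0 <- sum((x - ahat)^2) / (n - 1)
  MSE <- s2 * sum((u - ahat * o)^2 * w) / (n - 1)
  R_BM <- (trC + sum(d^2) / s2 - n / (s2 * sum(o * o * w))) / (n - 1)
  list(K = (MSE0 / MSE) / R_BM, sigma2 = s2, ahat = ahat)
}

# Core K statistic given C-tilde = C + E/sigma2_hat. Returns K plus its
# pieces so the randomization test can reuse them.
.k_core <- function(x, Ctilde) {
  n <- length(x)
  L <- chol(Ctilde)
  xi <- backsolve(L, x, transpose = TRUE)
  oi <- backsolve(L, rep(1, n), transpose = TRUE)
  ahat <- sum(oi * xi) / sum(oi * oi)
  MSE0 <- sum((x - ahat)^2) / (n - 1)
  MSE <- sum((xi - ahat * oi)^2) / (n - 1)
  R_BM <- (sum(diag(Ctilde)) - n / sum(oi * oi)) / (n - 1)
  list(K = (MSE0 / MSE) / R_BM, ahat = ahat, MSE0 = MSE0, MSE = MSE)
}

#' Blomberg's K with sampling error
#'
#' The K statistic compares the observed ratio of non-phylogenetic to
#' phylogenetically corrected mean squared error against its Brownian-motion
#' expectation on the same tree; K = 1 is the BM expectation, K near 0 means
#' trait values are unrelated to phylogeny. Sampling error of the tip means
#' is folded in by maximizing the BM likelihood with covariance
#' `sigma2 * C + diag(se^2)` and evaluating K on
#' `C-tilde = C + diag(se^2)/sigma2_hat`; with all `se = 0` this reduces
#' exactly to the classical statistic.
#'
#' @param phy A validated chronogram.
#' @param x Named tip values.
#' @param se Per-tip standard errors (scalar recycled).
#' @param C Optional precomputed [phylo_covariance()].
#' @return List (`signal_fit`) with `K`, `sigma2_hat`, `ahat`, `n`.
#' @export
blomberg_k <- function(phy, x, se = 0, C = NULL) {
  x <- .align_to_tips(phy, x, "x")
  se <- .align_to_tips(phy, se, "se", recycle = TRUE)
  n <- length(x)
  if (n < 3) stop("need at least 3 tips for K", call. = FALSE)
  if (stats::var(x) == 0) stop("zero trait variance: K is undefined",
                               call. = FALSE)
  if (any(se < 0)) stop("se must be >= 0", call. = FALSE)
  if (is.null(C)) C <- phylo_covariance(phy)
  if (all(se > 0)) {
    f <- .k_se_fast(C, x, se, .sigma2_bounds(x, max(diag(C))))
    return(structure(list(K = f$K, sigma2_hat = f$sigma2, ahat = f$ahat,
                          n = n), class = "signal_fit"))
  }
  prof <- .profile_bm_like(x, C, se,
                           .sigma2_bounds(x, max(diag(C))))
  Ctilde <- C
  if (any(se > 0)) diag(Ctilde) <- diag(Ctilde) + se^2 / prof$sigma2
  k <- .k_core(x, Ctilde)
  structure(list(K = k$K, sigma2_hat = prof$sigma2, ahat = k$ahat, n = n),
            class = "signal_fit")
}

#' Randomization test for phylogenetic signal
#'
#' Permutes trait values (jointly with their standard errors, so the error
#' structure follows the data) across the tips `n_rand` times and reports
#' the proportion of permutations whose K is at least the observed K.
#'
#' @inheritParams blomberg_k
#' @param n_rand Number of randomizations (default 1000).
#' @param seed Integer seed (required, for reproducibility).
#' @param reestimate_sigma2 Re-estimate the error-correction sigma2 for each
#'   permutation (default) or reuse the observed-data estimate.
#' @param smoothed Use the add-one p-value `(count + 1)/(n_rand + 1)`
#'   instead of the plain proportion.
#' @return List (`signal_test`) with `K`, `p`, `n_rand`, `sigma2_hat`,
#'   `K_perm` (the permutation distribution).
#' @export
k_randomization_test <- function(phy, x, se = 0, n_rand = 1000, seed,
                                 reestimate_sigma2 = TRUE, smoothed = FALSE,
                                 C = NULL) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_rand < 1) stop("n_rand must be >= 1", call. = FALSE)
  x <- .align_to_tips(phy, x, "x")
  se <- .align_to_tips(phy, se, "se", recycle = TRUE)
  if (is.null(C)) C <- phylo_covariance(phy)
  obs <- blomberg_k(phy, stats::setNames(x, phy$tip.label),
                    stats::setNames(se, phy$tip.label), C = C)
  n <- length(x)
  has_se <- any(se > 0)
  all_se <- all(se > 0)
  s2b <- .sigma2_bounds(x, max(diag(C)))
  trC <- sum(diag(C))
  set.seed(as.integer(seed))
  K_perm <- vapply(seq_len(n_rand), function(i) {
    idx <- sample.int(n)
    xp <- x[idx]; sp <- se[idx]
    if (!has_se) {
      .k_core(xp, C)$K
    } else if (reestimate_sigma2) {
      if (all_se) .k_se_fast(C, xp, sp, s2b, trC = trC)$K
      else blomberg_k(phy, stats::setNames(xp, phy$tip.label),
                      stats::setNames(sp, phy$tip.label), C = C)$K
    } else {
      Ct <- C
      diag(Ct) <- diag(Ct) + sp^2 / obs$sigma2_hat
      .k_core(xp, Ct)$K
    }
  }, numeric(1))
  count <- sum(K_perm >= obs$K)
  p <- if (smoothed) (count + 1) / (n_rand + 1) else count / n_rand
  structure(list(K = obs$K, p = p, n_rand = n_rand,
                 sigma2_hat = obs$sigma2_hat, K_perm = K_perm),
            class = "signal_test")
}
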