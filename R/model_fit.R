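#' Tip covariance implied by a trait-evolution model
#'
#' Builds the expected covariance matrix of tip values under Brownian motion
#' (BM), a non-stationary Ornstein-Uhlenbeck process started at the root
#' state (OU), or an early-burst exponential rate change (EB).
#'
#' With C the phylogenetic covariance ([phylo_covariance()]), T the tree
#' depth and s = C\[i, j\] the shared time of a tip pair:
#' \itemize{
#'   \item BM: `V = sigma2 * C`
#'   \item OU: `V[i, j] = sigma2/(2*alpha) * exp(-2*alpha*(T - s)) *
#'     (1 - exp(-2*alpha*s))` — variance is zero at the root, i.e. the root
#'     state is a parameter, not a stationary draw
#'   \item EB: `V[i, j] = sigma2 * (exp(a*s) - 1)/a` (the BM covariance of
#'     the EB-transformed tree); `a = 0` reduces to BM
#' }
#'
#' @param phy A validated chronogram (must be ultrametric for OU/EB).
#' @param model `"BM"`, `"OU"`, or `"EB"`.
#' @param params Named list with `sigma2` (> 0) and, as needed, `alpha`
#'   (> 0, OU) or `a` (EB; any sign is accepted here, sign policy is
#'   enforced at fitting/transform level).
#' @param C Optional precomputed [phylo_covariance()] of `phy`.
#' @return An n x n covariance matrix with tip labels as dimnames.
#' @export
model_covariance <- function(phy, model = c("BM", "OU", "EB"),
                             params = list(sigma2 = 1), C = NULL) {
  model <- match.arg(model)
  if (is.null(C)) C <- phylo_covariance(phy)
  sigma2 <- params$sigma2
  if (is.null(sigma2) || sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  if (model == "BM") return(sigma2 * C)
  d <- diag(C)
  if (diff(range(d)) > 1e-6 * max(d))
    stop(model, " covariance requires an ultrametric tree", call. = FALSE)
  T_depth <- max(d)
  if (model == "OU") {
    alpha <- params$alpha
    if (is.null(alpha) || alpha <= 0) stop("OU requires alpha > 0",
                                           call. = FALSE)
    V <- sigma2 / (2 * alpha) * exp(-2 * alpha * (T_depth - C)) *
      (1 - exp(-2 * alpha * C))
    dimnames(V) <- dimnames(C)
    return(V)
  }
  a <- params$a
  if (is.null(a)) stop("EB requires parameter 'a'", call. = FALSE)
  if (a == 0) return(sigma2 * C)
  V <- sigma2 * (exp(a * C) - 1) / a
  dimnames(V) <- dimnames(C)
  V
}

#' Multivariate normal log-likelihood
#'
#' Log density of `x ~ MVN(mu, V)` via Cholesky factorization.
#'
#' @param x Numeric vector.
#' @param mu Mean vector (scalar recycled).
#' @param V Symmetric positive-definite covariance matrix.
#' @return Log density (scalar).
#' @export
mvn_loglik <- function(x, mu, V) {
  n <- length(x)
  if (length(mu) == 1L) mu <- rep(mu, n)
  if (length(mu) != n || nrow(V) != n || ncol(V) != n)
    stop("dimension mismatch between x, mu and V", call. = FALSE)
  L <- tryCatch(chol(V), error = function(e) {
    ev <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
    stop(sprintf("covariance is not positive definite (smallest eigenvalue %.3g)",
                 ev), call. = FALSE)
  })
  z <- backsolve(L, x - mu, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

# Profile log-likelihood pieces shared by fitting, signal and reconstruction.
# Given unit-rate structure V0 and error variances se^2, returns the
# maximized-over-(z0, sigma2) log-likelihood together with the profiled
# estimates. When all se are zero sigma2 has the closed form Q/n; otherwise
# a 1-D Brent search on log(sigma2) is used.
.profile_bm_like <- function(x, V0, se, sigma2_bounds) {
  n <- length(x)
  if (all(se == 0)) {
    L <- chol(V0)
    xi <- backsolve(L, x, transpose = TRUE)
    oi <- backsolve(L, rep(1, n), transpose = TRUE)
    z0 <- sum(oi * xi) / sum(oi * oi)
    r <- xi - z0 * oi
    Q <- sum(r^2)
    sigma2 <- Q / n
    if (sigma2 <= 0) sigma2 <- .Machine$double.eps
    lnL <- -0.5 * (n * log(2 * pi) + n * log(sigma2) +
                     2 * sum(log(diag(L))) + Q / sigma2)
    return(list(lnL = lnL, sigma2 = sigma2, z0 = z0))
  }
  if (all(se > 0)) {
    # one symmetric eigendecomposition of D^-1/2 V0 D^-1/2 (D = diag(se^2))
    # makes every sigma2 evaluation O(n); algebraically identical to the
    # Cholesky route below
    d <- se
    eig <- eigen(V0 / tcrossprod(d), symmetric = TRUE)
    lam <- pmax(eig$values, 0)
    u <- crossprod(eig$vectors, x / d)
    o <- crossprod(eig$vectors, rep(1, n) / d)
    logdetD <- 2 * sum(log(d))
    eval_fast <- function(log_s2) {
      s2 <- exp(log_s2)
      w <- 1 / (s2 * lam + 1)
      z0 <- sum(o * u * w) / sum(o * o * w)
      quad <- sum((u - z0 * o)^2 * w)
      list(lnL = -0.5 * (n * log(2 * pi) + sum(log(s2 * lam + 1)) +
                           logdetD + quad),
           z0 = z0, sigma2 = s2)
    }
    cuts <- seq(log(sigma2_bounds[1]), log(sigma2_bounds[2]),
                length.out = 4)
    best <- NULL
    for (k in 1:3) {
      opt <- stats::optimize(function(ls) -eval_fast(ls)$lnL,
                             interval = c(cuts[k], cuts[k + 1]), tol = 1e-10)
      cand <- eval_fast(opt$minimum)
      if (is.null(best) || cand$lnL > best$lnL) best <- cand
    }
    return(best)
  }
  E <- se^2
  eval_s2 <- function(log_s2) {
    s2 <- exp(log_s2)
    V <- s2 * V0
    diag(V) <- diag(V) + E
    L <- chol(V)
    xi <- backsolve(L, x, transpose = TRUE)
    oi <- backsolve(L, rep(1, n), transpose = TRUE)
    z0 <- sum(oi * xi) / sum(oi * oi)
    r <- xi - z0 * oi
    lnL <- -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(L))) + sum(r^2))
    list(lnL = lnL, z0 = z0, sigma2 = s2)
  }
  lo <- log(sigma2_bounds[1]); hi <- log(sigma2_bounds[2])
  # three restarts over subintervals guard against flat/multimodal profiles
  cuts <- seq(lo, hi, length.out = 4)
  best <- NULL
  for (k in 1:3) {
    opt <- stats::optimize(function(ls) -eval_s2(ls)$lnL,
                           interval = c(cuts[k], cuts[k + 1]), tol = 1e-10)
    cand <- eval_s2(opt$minimum)
    if (is.null(best) || cand$lnL > best$lnL) best <- cand
  }
  best
}

.sigma2_bounds <- function(x, T_depth) {
  scale <- stats::var(x) / T_depth
  if (!is.finite(scale) || scale <= 0) scale <- 1
  c(1e-10, 1e6) * scale
}

#' Fit a trait-evolution model by maximum likelihood
#'
#' Maximizes the likelihood of `x ~ MVN(z0 * 1, V_model + diag(se^2))`. The
#' root state z0 is profiled by GLS at every evaluation; sigma2 is profiled
#' analytically when `se` is all-zero and by a bounded 1-D search otherwise;
#' the OU pull `alpha` and the EB exponent `a` are optimized with
#' multi-start bounded searches (5 log-spaced subintervals for `alpha` in
#' \[1e-8, 50/T\]; linear subintervals for `a` in \[log(1e-5)/T, 0\],
#' extended symmetrically in AC mode).
#'
#' Parameter counts for AICc are k = 2 (BM: z0, sigma2) and k = 3 (OU, EB).
#'
#' @param phy A validated chronogram.
#' @param x Named tip values (names matched to tip labels) or vector in tip
#'   order.
#' @param se Per-tip standard errors (fixed, known); scalar recycled.
#' @param model `"BM"`, `"OU"`, or `"EB"`.
#' @param ac_mode Allow the EB exponent to be positive (accelerating
#'   rates), used for the OU/AC equivalence on ultrametric trees.
#' @param C Optional precomputed [phylo_covariance()].
#' @return A `model_fit` list: `model`, `sigma2`, `z0`, `alpha`/`a` where
#'   applicable, `lnL`, `k`, `n`, `AICc`.
#' @export
fit_model <- function(phy, x, se = 0, model = c("BM", "OU", "EB"),
                      ac_mode = FALSE, C = NULL) {
  model <- match.arg(model)
  x <- .align_to_tips(phy, x, "x")
  se <- .align_to_tips(phy, se, "se", recycle = TRUE)
  n <- length(x)
  if (n < 4) stop("need at least 4 tips to fit trait-evolution models",
                  call. = FALSE)
  if (any(se < 0)) stop("se must be >= 0", call. = FALSE)
  if (is.null(C)) C <- phylo_covariance(phy)
  T_depth <- max(diag(C))
  s2b <- .sigma2_bounds(x, T_depth)

  prof_shape <- function(shape) {
    V0 <- switch(model,
      OU = model_covariance(phy, "OU", list(sigma2 = 1, alpha = shape), C = C),
      EB = if (shape == 0) C else
        model_covariance(phy, "EB", list(sigma2 = 1, a = shape), C = C))
    .profile_bm_like(x, V0, se, s2b)
  }

  if (model == "BM") {
    p <- .profile_bm_like(x, C, se, s2b)
    fit <- list(model = "BM", sigma2 = p$sigma2, z0 = p$z0, lnL = p$lnL,
                k = 2L, n = n)
  } else if (model == "OU") {
    lo <- log(1e-8); hi <- log(50 / T_depth)
    cuts <- seq(lo, hi, length.out = 6)
    best <- NULL; best_shape <- NA
    for (k in 1:5) {
      opt <- stats::optimize(function(la) -prof_shape(exp(la))$lnL,
                             interval = c(cuts[k], cuts[k + 1]), tol = 1e-10)
      cand <- prof_shape(exp(opt$minimum))
      if (is.null(best) || cand$lnL > best$lnL) {
        best <- cand; best_shape <- exp(opt$minimum)
      }
    }
    fit <- list(model = "OU", sigma2 = best$sigma2, z0 = best$z0,
                alpha = best_shape, lnL = best$lnL, k = 3L, n = n)
  } else {
    lo <- log(1e-5) / T_depth
    hi <- if (ac_mode) -lo else 0
    cuts <- seq(lo, hi, length.out = 6)
    best <- NULL; best_shape <- NA
    for (k in 1:5) {
      opt <- stats::optimize(function(a) -prof_shape(a)$lnL,
                             interval = c(cuts[k], cuts[k + 1]), tol = 1e-12)
      cand <- prof_shape(opt$minimum)
      if (is.null(best) || cand$lnL > best$lnL) {
        best <- cand; best_shape <- opt$minimum
      }
    }
    # boundary a = 0 (pure BM) is admissible and sometimes the optimum
    cand0 <- prof_shape(0)
    if (cand0$lnL >= best$lnL) { best <- cand0; best_shape <- 0 }
    fit <- list(model = "EB", sigma2 = best$sigma2, z0 = best$z0,
                a = best_shape, lnL = best$lnL, k = 3L, n = n)
  }
  fit$AICc <- -2 * fit$lnL + 2 * fit$k +
    2 * fit$k * (fit$k + 1) / (n - fit$k - 1)
  class(fit) <- "model_fit"
  fit
}

#' Fit BM, OU and EB to the same data and attach AICc weights
#'
#' @inheritParams fit_model
#' @param models Character vector of models to fit.
#' @return A list of `model_fit` objects (one per model) with `weight`
#'   fields added; attribute `best` holds the name of the AICc-best model,
#'   ties broken toward the simpler model (fewer parameters, then
#'   alphabetical).
#' @export
fit_all_models <- function(phy, x, se = 0, models = c("BM", "OU", "EB"),
                           C = NULL) {
  fits <- lapply(models, function(m) fit_model(phy, x, se = se, model = m,
                                               C = C))
  names(fits) <- models
  fits <- aicc_weights(fits)
  aicc <- vapply(fits, `[[`, numeric(1), "AICc")
  kpar <- vapply(fits, `[[`, integer(1), "k")
  ord <- order(round(aicc, 10), kpar, names(fits))
  attr(fits, "best") <- names(fits)[ord[1]]
  fits
}

#' Akaike weights from AICc values
#'
#' `delta_i = AICc_i - min(AICc)`; `w_i = exp(-delta_i/2) /
#' sum(exp(-delta_j/2))`.
#'
#' @param fits List of `model_fit` objects fit to identical data.
#' @return The same list with a `weight` field added to each fit.
#' @export
aicc_weights <- function(fits) {
  if (length(fits) < 2) stop("need at least 2 fits to compute weights",
                             call. = FALSE)
  ns <- vapply(fits, `[[`, integer(1), "n")
  if (length(unique(ns)) != 1)
    stop("fits were made on data of different sizes", call. = FALSE)
  aicc <- vapply(fits, `[[`, numeric(1), "AICc")
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  for (i in seq_along(fits)) fits[[i]]$weight <- w[i]
  fits
}

# Align a tip-indexed vector to the tree's tip order; scalars recycle when
# permitted (se). Errors on missing or extraneous names.
.align_to_tips <- function(phy, v, what, recycle = FALSE) {
  n <- ape::Ntip(phy)
  if (recycle && length(v) == 1L) return(rep(as.numeric(v), n))
  if (!is.null(names(v))) {
    missing <- setdiff(phy$tip.label, names(v))
    if (length(missing))
      stop(what, " is missing values for tips: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    v <- v[phy$tip.label]
  } else if (length(v) != n) {
    stop(what, " has length ", length(v), " but the tree has ", n, " tips",
         call. = FALSE)
  }
  as.numeric(v)
}
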