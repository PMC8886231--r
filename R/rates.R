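# Joint covariance of internal nodes with tips (and the tip block) under a
# trait-evolution model. Shared times come from MRCA depths over all node
# pairs; individual depths from root-to-node path lengths. Under the
# non-stationary OU the covariance of two points at depths tu, tw with
# shared time s is sigma2/(2*alpha) * exp(-alpha*(tu + tw - 2*s)) *
# (1 - exp(-2*alpha*s)).
.node_tip_covariance <- function(phy, model, params) {
  n <- ape::Ntip(phy)
  nn <- phy$Nnode
  depth <- ape::node.depth.edgelength(phy)
  mr <- ape::mrca(phy, full = TRUE)       # (n+nn) x (n+nn) node ids
  s <- matrix(depth[mr], n + nn, n + nn)  # shared times
  sigma2 <- params$sigma2
  cov_fun <- switch(model,
    BM = function(s, tu, tw) sigma2 * s,
    EB = {
      a <- params$a
      if (a == 0) function(s, tu, tw) sigma2 * s
      else function(s, tu, tw) sigma2 * (exp(a * s) - 1) / a
    },
    OU = {
      alpha <- params$alpha
      function(s, tu, tw) sigma2 / (2 * alpha) *
        exp(-alpha * (tu + tw - 2 * s)) * (1 - exp(-2 * alpha * s))
    },
    stop("unknown model ", model, call. = FALSE))
  tu <- matrix(depth, n + nn, n + nn)
  V <- cov_fun(s, tu, t(tu))
  tips <- seq_len(n)
  nodes <- (n + 1):(n + nn)
  list(tips = V[tips, tips, drop = FALSE],
       nodes_tips = V[nodes, tips, drop = FALSE],
       node_ids = nodes, depth = depth)
}

#' Ancestral state reconstruction under a fitted model
#'
#' GLS/ML reconstruction of internal-node states: with root state z0
#' estimated by GLS, the state of node v is the conditional mean
#' `z0 + Cov(v, tips) V^-1 (x - z0 * 1)` where V is the model-implied tip
#' covariance (plus `diag(se^2)` when sampling error is supplied). For
#' Brownian motion this is the familiar GLS reconstruction; for OU/EB the
#' covariances come from the fitted model, which is how reconstruction "on
#' the transformed tree" is realized here.
#'
#' @param phy A validated chronogram.
#' @param x Named tip values.
#' @param fit A `model_fit` (from [fit_model()]); or pass `model`/`params`.
#' @param se Per-tip standard errors folded into the tip covariance.
#' @param model,params Used when `fit` is NULL.
#' @return Numeric vector of internal-node states, named by node id
#'   (ape numbering, root first element).
#' @export
ancestral_states <- function(phy, x, fit = NULL, se = 0,
                             model = "BM", params = list(sigma2 = 1)) {
  x <- .align_to_tips(phy, x, "x")
  se <- .align_to_tips(phy, se, "se", recycle = TRUE)
  if (!is.null(fit)) {
    model <- fit$model
    params <- list(sigma2 = fit$sigma2, alpha = fit$alpha, a = fit$a)
  }
  vc <- .node_tip_covariance(phy, model, params)
  W <- vc$tips
  diag(W) <- diag(W) + se^2
  z0 <- phylogenetic_mean(x, W)
  sol <- solve(W, x - z0)
  est <- z0 + as.vector(vc$nodes_tips %*% sol)
  names(est) <- as.character(vc$node_ids)
  est
}

#' Absolute per-tip rates of trait change
#'
#' Reconstructs ancestral states on the best-fit model's covariance, then
#' for each tip divides the absolute difference between the tip value and
#' its immediate ancestor's state by the tip's branch duration on the
#' original chronogram — keeping the rate in trait units per Myr
#' regardless of the model transform. `denominator = "transformed"` instead
#' divides by the model-rescaled branch length (BM/EB only).
#'
#' @param phy The untransformed chronogram.
#' @param x Named tip values.
#' @param fit Best-fit `model_fit` used for the reconstruction.
#' @param se Per-tip standard errors; used in reconstruction when the fit
#'   used them (pass 0 to disable).
#' @param denominator `"original"` (default) or `"transformed"`.
#' @return data.frame with `tip_label`, `rate`, `anc_state`, `tip_value`,
#'   `dt` (Myr). Zero-length terminal branches yield `NA` rates with a
#'   warning.
#' @export
absolute_tip_rates <- function(phy, x, fit, se = 0,
                               denominator = c("original", "transformed")) {
  denominator <- match.arg(denominator)
  x <- .align_to_tips(phy, x, "x")
  anc <- ancestral_states(phy, stats::setNames(x, phy$tip.label), fit = fit,
                          se = se)
  n <- ape::Ntip(phy)
  tip_edge <- match(seq_len(n), phy$edge[, 2])
  parent <- phy$edge[tip_edge, 1]
  dt <- phy$edge.length[tip_edge]
  if (denominator == "transformed") {
    if (fit$model == "OU")
      stop("transformed-denominator rates are unavailable for OU (covariance-space transform)",
           call. = FALSE)
    tphy <- transform_tree(phy, fit$model,
                           params = list(a = fit$a), ac_mode = TRUE)
    dt <- tphy$edge.length[tip_edge]
  }
  rate <- abs(x - anc[as.character(parent)]) / dt
  if (any(dt == 0)) {
    warning("zero-length terminal branch: rate undefined for ",
            paste(phy$tip.label[dt == 0], collapse = ", "), call. = FALSE)
    rate[dt == 0] <- NA_real_
  }
  data.frame(tip_label = phy$tip.label, rate = unname(rate),
             anc_state = unname(anc[as.character(parent)]),
             tip_value = x, dt = dt, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval containing at least `mass` of the
#' sample: sort the values, scan all windows of `ceiling(mass * N)` points,
#' return the narrowest (leftmost on ties).
#'
#' @param values Numeric vector (>= 2 finite values).
#' @param mass Probability mass (default 0.95).
#' @return List with `lo`, `hi`, `mass`.
#' @export
hpd_interval <- function(values, mass = 0.95) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 finite values for an HPD",
                               call. = FALSE)
  if (mass <= 0 || mass > 1) stop("mass must be in (0, 1]", call. = FALSE)
  s <- sort(values)
  N <- length(s)
  m <- ceiling(mass * N)
  if (m >= N) return(list(lo = s[1], hi = s[N], mass = mass))
  starts <- seq_len(N - m + 1)
  widths <- s[starts + m - 1] - s[starts]
  i <- starts[which.min(widths)]          # which.min takes the leftmost tie
  list(lo = s[i], hi = s[i + m - 1], mass = mass)
}

#' Compare diffusion rates between two variables across a tree ensemble
#'
#' For each tree, takes the sigma2 of each variable's best-fit model and
#' summarizes the paired ensemble: MCC point estimates, 95% HPDs, the
#' fraction of trees with `sigma2_A < sigma2_B`, and the overlap of the two
#' HPD intervals as a fraction of the narrower interval (0 = fully
#' segregated distributions).
#'
#' @param fitsA,fitsB data.frames with columns `tree_id` and `sigma2`
#'   (one row per tree; `tree_id` `"mcc"` marks the MCC tree), e.g. built
#'   from the model stage's best-fit registry.
#' @param mass HPD mass (default 0.95).
#' @return List with `mcc_A`, `mcc_B`, `hpd_A`, `hpd_B`,
#'   `frac_A_lt_B` (posterior trees only), `hpd_overlap`.
#' @export
compare_sigma2 <- function(fitsA, fitsB, mass = 0.95) {
  if (!setequal(fitsA$tree_id, fitsB$tree_id) ||
      nrow(fitsA) != nrow(fitsB))
    stop("fit tables cover different tree ensembles", call. = FALSE)
  fitsB <- fitsB[match(fitsA$tree_id, fitsB$tree_id), ]
  post <- fitsA$tree_id != "mcc"
  sA <- fitsA$sigma2[post]; sB <- fitsB$sigma2[post]
  if (sum(post) < 2) { sA <- fitsA$sigma2; sB <- fitsB$sigma2 }
  hA <- hpd_interval(sA, mass); hB <- hpd_interval(sB, mass)
  inter <- max(0, min(hA$hi, hB$hi) - max(hA$lo, hB$lo))
  narrow <- min(hA$hi - hA$lo, hB$hi - hB$lo)
  overlap <- if (narrow > 0) inter / narrow else as.numeric(inter > 0)
  list(mcc_A = fitsA$sigma2[fitsA$tree_id == "mcc"][1],
       mcc_B = fitsB$sigma2[fitsB$tree_id == "mcc"][1],
       hpd_A = hA, hpd_B = hB,
       frac_A_lt_B = mean(sA < sB),
       hpd_overlap = overlap)
}
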