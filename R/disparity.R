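#' Average squared Euclidean disparity
#'
#' Mean over unordered pairs of `(x_i - x_j)^2`; a singleton has disparity
#' zero by convention.
#'
#' @param values Numeric vector (length >= 1).
#' @return Scalar disparity.
#' @export
disparity_avg_sq <- function(values) {
  if (!length(values)) stop("empty input", call. = FALSE)
  m <- length(values)
  if (m == 1L) return(0)
  # sum over unordered pairs of (xi - xj)^2 = m*sum(x^2) - (sum x)^2
  (m * sum(values^2) - sum(values)^2) / (m * (m - 1) / 2)
}

# Precompute the grid and lineage structure for disparity-through-time on a
# fixed tree: for each internal-node time t (sorted ascending, excluding the
# root time and including the present), the edges alive just before t — the
# rule t(parent) < t <= t(child) — partition the tip set, so each grid time
# contributes exactly n tip indices. Stored as flat index/group vectors so
# many datasets can be pushed through a single rowsum() call.
.dtt_precompute <- function(phy) {
  n <- ape::Ntip(phy)
  depth <- ape::node.depth.edgelength(phy)
  T_depth <- max(depth[seq_len(n)])
  node_times <- sort(depth[(n + 1):(n + phy$Nnode)])
  grid <- c(node_times, T_depth)          # root time first, present last
  inner <- grid[-1]                       # times evaluated via lineages
  # descendant tips of every node
  desc <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  for (e in ape::postorder(phy)) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  tp <- depth[phy$edge[, 1]]
  tc <- depth[phy$edge[, 2]]
  idx <- integer(0); grp <- integer(0); grp_time <- integer(0)
  gid <- 0L
  for (k in seq_along(inner)) {
    t <- inner[k]
    alive <- which(tp < t & t <= tc + 1e-9 * T_depth)
    for (e in alive) {
      gid <- gid + 1L
      tips <- desc[[phy$edge[e, 2]]]
      idx <- c(idx, tips)
      grp <- c(grp, rep.int(gid, length(tips)))
      grp_time <- c(grp_time, k)
    }
  }
  grp_sizes <- tabulate(grp, gid)
  list(n = n, T_depth = T_depth, grid = grid, rel_times = grid / T_depth,
       idx = idx, grp = grp, grp_sizes = grp_sizes,
       time_of_grp = grp_time, n_inner = length(inner))
}

# Relative-disparity curves for one or many datasets (columns of X) on a
# precomputed structure. Returns a matrix: length(grid) x ncol(X); first row
# is 1 (whole clade), last row 0 (all singleton lineages at the present).
.dtt_curves <- function(pre, X) {
  X <- as.matrix(X)
  Xi <- X[pre$idx, , drop = FALSE]
  S1 <- rowsum(Xi, pre$grp, reorder = TRUE)
  S2 <- rowsum(Xi^2, pre$grp, reorder = TRUE)
  m <- pre$grp_sizes
  pairs <- m * (m - 1) / 2
  disp <- (m * S2 - S1^2)
  disp[pairs > 0, ] <- disp[pairs > 0, , drop = FALSE] / pairs[pairs > 0]
  disp[pairs == 0, ] <- 0
  whole <- apply(X, 2, disparity_avg_sq)
  if (any(whole == 0))
    stop("constant trait values: whole-tree disparity is zero", call. = FALSE)
  means <- rowsum(disp, pre$time_of_grp, reorder = TRUE) /
    as.vector(tabulate(pre$time_of_grp, pre$n_inner))
  rel <- sweep(means, 2, whole, "/")
  rbind(rep(1, ncol(X)), rel)
}

#' Disparity-through-time curve
#'
#' Traces mean relative subclade disparity from the root to the present.
#' The grid is the sorted internal-node times plus the present; at each
#' time the lineages crossing it (just before the divergence) contribute
#' the disparity of their descendant tip values, normalized by the
#' whole-tree disparity, and the curve value is the mean over lineages.
#' The root point is 1 by construction and the present-day point is 0
#' (every lineage is a singleton tip).
#'
#' @param phy A validated, ultrametric chronogram.
#' @param x Named tip values.
#' @return List with `rel_times` (in \[0, 1\]; 0 = root) and `observed`.
#' @export
dtt_curve <- function(phy, x) {
  x <- .align_to_tips(phy, x, "x")
  pre <- .dtt_precompute(phy)
  obs <- .dtt_curves(pre, matrix(x, ncol = 1))[, 1]
  list(rel_times = pre$rel_times, observed = unname(obs))
}

#' Morphological disparity index (MDI)
#'
#' Signed area between an observed relative-disparity curve and a reference
#' curve over the relative-time grid. The default is the left-endpoint
#' rectangle rule `sum((obs_k - ref_k) * dt_k)`; `method = "trapezoid"`
#' averages adjacent differences.
#'
#' @param observed,reference Curves on the same grid.
#' @param rel_times Increasing grid in \[0, 1\].
#' @param method `"rectangle"` (default) or `"trapezoid"`.
#' @return Signed area (positive = disparity above the reference).
#' @export
mdi <- function(observed, reference, rel_times,
                method = c("rectangle", "trapezoid")) {
  method <- match.arg(method)
  if (length(observed) != length(reference) ||
      length(observed) != length(rel_times))
    stop("curve/grid length mismatch", call. = FALSE)
  d <- observed - reference
  dt <- diff(rel_times)
  if (method == "rectangle") sum(d[-length(d)] * dt)
  else sum((d[-length(d)] + d[-1]) / 2 * dt)
}

#' Disparity-through-time test against Brownian motion
#'
#' Simulates `n_sim` Brownian-motion datasets on the tree (rate fit by
#' maximum likelihood to the observed data), builds the median reference
#' curve and 95% envelope, and computes the MDI of the observed curve and
#' of every simulation against that reference. The reported `p` is the
#' proportion of simulations whose MDI the observed MDI equals or exceeds —
#' the probability of an MDI as negative as observed; `1 - p` is the
#' relevant tail for a positive MDI.
#'
#' @param phy A validated, ultrametric chronogram.
#' @param x Named tip values.
#' @param n_sim Number of BM simulations (default 1000).
#' @param seed Integer seed (required).
#' @param mdi_method Passed to [mdi()].
#' @return List (`dtt_result`) with `rel_times`, `observed`, `sim_median`,
#'   `sim_lo95`, `sim_hi95`, `MDI`, `MDI_sim` (per-simulation values, kept
#'   for audit), `p`, `n_sim`, `sigma2_hat`.
#' @export
dtt_test <- function(phy, x, n_sim = 1000, seed,
                     mdi_method = c("rectangle", "trapezoid")) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_sim < 2) stop("n_sim must be >= 2", call. = FALSE)
  mdi_method <- match.arg(mdi_method)
  x <- .align_to_tips(phy, x, "x")
  pre <- .dtt_precompute(phy)
  C <- phylo_covariance(phy)
  prof <- .profile_bm_like(x, C, rep(0, length(x)),
                           .sigma2_bounds(x, max(diag(C))))
  set.seed(as.integer(seed))
  L <- chol(prof$sigma2 * C)
  Z <- matrix(stats::rnorm(length(x) * n_sim), length(x), n_sim)
  sims <- prof$z0 + crossprod(L, Z)
  curves <- .dtt_curves(pre, cbind(x, sims))
  obs <- curves[, 1]
  simc <- curves[, -1, drop = FALSE]
  ref <- apply(simc, 1, stats::median)
  lo <- apply(simc, 1, stats::quantile, probs = 0.025, names = FALSE)
  hi <- apply(simc, 1, stats::quantile, probs = 0.975, names = FALSE)
  MDI_obs <- mdi(obs, ref, pre$rel_times, method = mdi_method)
  MDI_sim <- vapply(seq_len(n_sim), function(j)
    mdi(simc[, j], ref, pre$rel_times, method = mdi_method), numeric(1))
  p <- mean(MDI_obs >= MDI_sim)
  structure(list(rel_times = pre$rel_times, observed = unname(obs),
                 sim_median = ref, sim_lo95 = lo, sim_hi95 = hi,
                 MDI = MDI_obs, MDI_sim = MDI_sim, p = p, n_sim = n_sim,
                 sigma2_hat = prof$sigma2),
            class = "dtt_result")
}
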