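# Independent brute-force oracles. These deliberately avoid the package's
# computational paths (Cholesky solves, rowsum batching): everything here is
# path enumeration and dense solve().

# edge path from the root to a node, as a vector of edge indices
path_edges <- function(phy, node) {
  root <- ape::Ntip(phy) + 1L
  path <- integer(0)
  while (node != root) {
    e <- which(phy$edge[, 2] == node)
    path <- c(e, path)
    node <- phy$edge[e, 1]
  }
  path
}

# shared root-to-MRCA path length for any two nodes (tips or internal)
bf_shared_time <- function(phy, i, j) {
  pi <- path_edges(phy, i)
  pj <- path_edges(phy, j)
  sum(phy$edge.length[intersect(pi, pj)])
}

bf_node_depth <- function(phy, i) sum(phy$edge.length[path_edges(phy, i)])

# brute-force phylogenetic covariance over all tip pairs
bf_vcv <- function(phy) {
  n <- ape::Ntip(phy)
  C <- matrix(0, n, n, dimnames = list(phy$tip.label, phy$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      C[i, j] <- if (i == j) bf_node_depth(phy, i)
                 else bf_shared_time(phy, i, j)
    }
  }
  C
}

# dense-inverse multivariate normal log density
bf_mvn_loglik <- function(x, mu, V) {
  n <- length(x)
  if (length(mu) == 1) mu <- rep(mu, n)
  r <- x - mu
  -0.5 * (n * log(2 * pi) + log(det(V)) +
            drop(t(r) %*% solve(V) %*% r))
}

# textbook Blomberg K from explicit dense-matrix formulas (no error term)
bf_k <- function(phy, x) {
  C <- bf_vcv(phy)
  x <- x[phy$tip.label]
  n <- length(x)
  Cinv <- solve(C)
  one <- rep(1, n)
  ahat <- drop(t(one) %*% Cinv %*% x) / drop(t(one) %*% Cinv %*% one)
  MSE0 <- drop(t(x - ahat) %*% (x - ahat)) / (n - 1)
  MSE <- drop(t(x - ahat) %*% Cinv %*% (x - ahat)) / (n - 1)
  expected <- (sum(diag(C)) - n / drop(t(one) %*% Cinv %*% one)) / (n - 1)
  (MSE0 / MSE) / expected
}

# disparity by literal pair enumeration
bf_disparity <- function(v) {
  m <- length(v)
  if (m < 2) return(0)
  tot <- 0; cnt <- 0
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    tot <- tot + (v[i] - v[j])^2; cnt <- cnt + 1
  }
  tot / cnt
}

# DTT curve by literal lineage enumeration: at each grid time, the edges
# with t(parent) < t <= t(child) contribute the disparity of their
# descendant tips relative to the whole clade
bf_dtt_curve <- function(phy, x) {
  x <- x[phy$tip.label]
  n <- ape::Ntip(phy)
  depth <- sapply(seq_len(n + phy$Nnode), function(k) bf_node_depth(phy, k))
  T_depth <- max(depth[seq_len(n)])
  grid <- c(sort(depth[(n + 1):(n + phy$Nnode)]), T_depth)
  whole <- bf_disparity(x)
  tips_below <- function(node) {
    if (node <= n) return(node)
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  obs <- sapply(grid[-1], function(t) {
    alive <- which(depth[phy$edge[, 1]] < t &
                     t <= depth[phy$edge[, 2]] + 1e-9 * T_depth)
    mean(sapply(alive, function(e)
      bf_disparity(x[tips_below(phy$edge[e, 2])]))) / whole
  })
  list(rel_times = unname(grid / T_depth), observed = unname(c(1, obs)))
}

# conditional-MVN ancestral states by dense solve over a brute-force joint
# covariance (BM only; sufficient for the oracle tests)
bf_ancestral_bm <- function(phy, x, sigma2 = 1, se = 0) {
  n <- ape::Ntip(phy)
  x <- x[phy$tip.label]
  nodes <- (n + 1):(n + phy$Nnode)
  all_ids <- c(seq_len(n), nodes)
  S <- outer(all_ids, all_ids, Vectorize(function(i, j)
    if (i == j) bf_node_depth(phy, i) else bf_shared_time(phy, i, j)))
  V <- sigma2 * S
  Vt <- V[seq_len(n), seq_len(n)] + diag(rep(se^2, length.out = n), n)
  Vnt <- V[n + seq_len(phy$Nnode), seq_len(n), drop = FALSE]
  one <- rep(1, n)
  Wi <- solve(Vt)
  z0 <- drop(t(one) %*% Wi %*% x) / drop(t(one) %*% Wi %*% one)
  drop(z0 + Vnt %*% Wi %*% (x - z0))
}

# exhaustive-window HPD
bf_hpd <- function(values, mass = 0.95) {
  s <- sort(values)
  N <- length(s)
  m <- ceiling(mass * N)
  best <- c(s[1], s[N])
  if (m < N) {
    for (i in 1:(N - m + 1)) {
      if (s[i + m - 1] - s[i] < best[2] - best[1] - 1e-15) {
        best <- c(s[i], s[i + m - 1])
      }
    }
  }
  best
}

# all permutations of 1..n (recursive; used only for tiny n)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in combinat_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

# random ultrametric test tree with a fixed seed
rand_tree <- function(n, seed) {
  set.seed(seed)
  phy <- ape::rcoal(n)
  phy$tip.label <- paste0("t", seq_len(n))
  phy
}
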