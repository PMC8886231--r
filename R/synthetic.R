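#' Simulate an ultrametric chronogram
#'
#' Birth-death tree conditioned on the number of tips, rescaled so the root
#' age equals `root_age`. Tips are labelled `otu_1..otu_n`.
#'
#' @param n_tips Number of tips (>= 3); default 81, the size of an
#'   accession-rich genus-level OTU phylogeny.
#' @param birth,death Per-lineage rates (1/Myr).
#' @param root_age Crown age in Myr (default 100).
#' @param seed Integer seed (required).
#' @return A validated `phylo` chronogram.
#' @export
simulate_tree <- function(n_tips = 81, birth = 0.1, death = 0,
                          root_age = 100, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_tips < 3) stop("n_tips must be >= 3", call. = FALSE)
  set.seed(as.integer(seed))
  phy <- NULL
  for (try in 1:50) {
    phy <- tryCatch(ape::rphylo(n_tips, birth = birth, death = death,
                                fossils = FALSE),
                    error = function(e) NULL)
    if (!is.null(phy)) break
  }
  if (is.null(phy))
    stop("birth-death simulation failed after 50 attempts", call. = FALSE)
  phy$edge.length <- phy$edge.length * (root_age / tree_depth(phy))
  phy$tip.label <- paste0("otu_", seq_len(n_tips))
  validate_chronogram(phy)
}

#' Perturb a chronogram into a pseudo-posterior ensemble
#'
#' Emulates a Bayesian posterior tree sample by jittering node ages with
#' mean-one lognormal noise (`meanlog = -sd^2/2`) and, optionally,
#' perturbing the topology by random NNI moves (node ages for perturbed
#' topologies are regenerated from a Grafen-style depth assignment before
#' jittering). Parent ages are clamped above child ages, so every tree is
#' ultrametric by construction and shares the input tip set.
#'
#' @param phy Input chronogram.
#' @param n Number of trees (>= 0).
#' @param branch_jitter_sd Lognormal sdlog of the age jitter (default 0.05).
#' @param seed Integer seed (required when n > 0).
#' @param topology `"fixed"` (default) or `"nni"`.
#' @param nni_moves NNI moves per tree when `topology = "nni"`.
#' @return List with `mcc` (the input) and `posterior` (a `multiPhylo`).
#' @export
make_pseudo_posterior <- function(phy, n, branch_jitter_sd = 0.05, seed,
                                  topology = c("fixed", "nni"),
                                  nni_moves = 2) {
  topology <- match.arg(topology)
  if (n > 0 && missing(seed)) stop("seed is required", call. = FALSE)
  post <- vector("list", n)
  if (n > 0) {
    set.seed(as.integer(seed))
    root_age <- tree_depth(phy)
    for (i in seq_len(n)) {
      base <- phy
      if (topology == "nni") {
        base <- phangorn::rNNI(phy, moves = nni_moves)
        base <- ape::compute.brlen(base, method = "Grafen")
        base$edge.length <- base$edge.length * (root_age / tree_depth(base))
      }
      post[[i]] <- .jitter_node_ages(base, branch_jitter_sd)
    }
  }
  post <- structure(post, class = "multiPhylo")
  list(mcc = phy, posterior = post)
}

# Multiply internal-node ages by mean-one lognormal factors, processed in
# preorder with each child capped just below its parent, then rebuild edge
# lengths. The root age is jittered without any cap, so its ensemble mean
# stays at the input root age. sd = 0 returns the tree unchanged.
.jitter_node_ages <- function(phy, sd) {
  if (sd == 0) return(phy)
  n <- ape::Ntip(phy)
  depth <- ape::node.depth.edgelength(phy)
  T_depth <- max(depth[seq_len(n)])
  age <- numeric(n + phy$Nnode)
  nodes <- (n + 1):(n + phy$Nnode)
  age[nodes] <- T_depth - depth[nodes]
  fac <- stats::setNames(
    stats::rlnorm(phy$Nnode, meanlog = -sd^2 / 2, sdlog = sd), nodes)
  parent_of <- stats::setNames(phy$edge[, 1], phy$edge[, 2])
  for (v in nodes[order(depth[nodes])]) {      # preorder: root first
    new_age <- age[v] * fac[as.character(v)]
    p <- parent_of[as.character(v)]
    if (!is.na(p)) new_age <- min(new_age, age[p] * (1 - 1e-8))
    age[v] <- new_age
  }
  out <- phy
  out$edge.length <- age[phy$edge[, 1]] - age[phy$edge[, 2]]
  out
}

#' Simulate tip trait values under a trait-evolution model
#'
#' Draws from `MVN(z0 * 1, V_model)` using [model_covariance()];
#' `model = "white_noise"` draws i.i.d. normals that ignore the tree.
#'
#' @param phy A validated chronogram.
#' @param model `"BM"`, `"OU"`, `"EB"`, or `"white_noise"`.
#' @param params Named list: `sigma2`, `z0`, and `alpha`/`a` as required.
#'   For white noise `sigma2` is the per-tip variance.
#' @param seed Integer seed (required).
#' @param n_datasets Number of independent replicate datasets.
#' @return Named vector (one dataset) or n x n_datasets matrix.
#' @export
simulate_traits <- function(phy, model = "BM",
                            params = list(sigma2 = 1, z0 = 0), seed,
                            n_datasets = 1) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  z0 <- if (is.null(params$z0)) 0 else params$z0
  n <- ape::Ntip(phy)
  set.seed(as.integer(seed))
  if (model == "white_noise") {
    X <- matrix(stats::rnorm(n * n_datasets, z0, sqrt(params$sigma2)),
                n, n_datasets)
  } else {
    V <- model_covariance(phy, model, params)
    if (params$sigma2 == 0) {
      X <- matrix(z0, n, n_datasets)
    } else {
      L <- chol(V)
      Z <- matrix(stats::rnorm(n * n_datasets), n, n_datasets)
      X <- z0 + crossprod(L, Z)
    }
  }
  rownames(X) <- phy$tip.label
  if (n_datasets == 1) stats::setNames(X[, 1], phy$tip.label) else X
}

#' Simulate accession-level records around tip means
#'
#' Per OTU, draws an accession count from a heavy-tailed rounded lognormal
#' (defaults chosen to give roughly 29 accessions per OTU on average,
#' clipped to \[1, 454\]) and scatters accession values around the tip mean
#' with independent normal noise.
#'
#' @param tip_means Named vector (one variable) or matrix (OTUs x
#'   variables, rownames = OTU ids, colnames = variable names).
#' @param within_otu_sd Accession-level standard deviation; scalar or one
#'   per variable.
#' @param count_meanlog,count_sdlog Lognormal parameters of the count law.
#' @param count_max Cap on accessions per OTU (default 454).
#' @param seed Integer seed (required).
#' @param counts Optional explicit per-OTU counts (named or in OTU order),
#'   overriding the law.
#' @return data.frame with `otu_id` plus one column per variable,
#'   one row per accession.
#' @export
simulate_accessions <- function(tip_means, within_otu_sd = 2,
                                count_meanlog = 2.52, count_sdlog = 1.3,
                                count_max = 454, seed, counts = NULL) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (is.null(dim(tip_means)))
    tip_means <- matrix(tip_means, ncol = 1,
                        dimnames = list(names(tip_means), "bio1"))
  n_otu <- nrow(tip_means)
  n_var <- ncol(tip_means)
  within_otu_sd <- rep(within_otu_sd, length.out = n_var)
  set.seed(as.integer(seed))
  if (is.null(counts)) {
    counts <- pmin(count_max,
                   pmax(1L, round(stats::rlnorm(n_otu, count_meanlog,
                                                count_sdlog))))
  } else {
    if (!is.null(names(counts))) counts <- counts[rownames(tip_means)]
    counts <- pmin(count_max, pmax(1L, as.integer(counts)))
  }
  otu_id <- rep(rownames(tip_means), counts)
  vals <- matrix(NA_real_, sum(counts), n_var,
                 dimnames = list(NULL, colnames(tip_means)))
  for (j in seq_len(n_var)) {
    mu <- rep(tip_means[, j], counts)
    vals[, j] <- mu + stats::rnorm(length(mu), 0, within_otu_sd[j])
  }
  data.frame(otu_id = otu_id, vals, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Simulate a complete synthetic study
#'
#' Generates the full input set the pipeline consumes: a chronogram, a
#' pseudo-posterior ensemble, 19 correlated bioclim-like variables, and
#' accession-level records. Variables are built as one latent factor per
#' variable group plus a same-model idiosyncratic component (a sum of two
#' independent processes of the same model class stays in that class), so
#' within-group correlation mimics real bioclim structure. Groups 1–3
#' evolve under Brownian motion; Groups 4–6 (and the ungrouped bio2) under
#' a strong Ornstein-Uhlenbeck pull — the two qualitative regimes a
#' genus-level climatic-niche analysis must distinguish.
#'
#' @param n_tips,root_age,birth,death Passed to [simulate_tree()].
#' @param n_posterior Pseudo-posterior size (default 20 for a desk-scale
#'   study; use 1000 to emulate a full posterior sample).
#' @param branch_jitter_sd Passed to [make_pseudo_posterior()].
#' @param bm_sigma2,ou_sigma2 Latent-factor rates (trait units^2/Myr).
#' @param ou_alpha OU pull (1/Myr); the default 0.05 gives alpha*T = 5 at
#'   the default root age.
#' @param within_otu_sd Accession-level noise sd.
#' @param seed Integer seed (required); all internal seeds derive from it.
#' @return List with `mcc`, `posterior`, `tip_means` (matrix), `records`
#'   (accession data.frame), `groups` (variable-group map), `config`.
#' @export
simulate_study <- function(n_tips = 81, root_age = 100, birth = 0.1,
                           death = 0, n_posterior = 20,
                           branch_jitter_sd = 0.05,
                           bm_sigma2 = 0.05, ou_sigma2 = 0.05,
                           ou_alpha = 0.05, within_otu_sd = 2, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  seed <- as.integer(seed)
  phy <- simulate_tree(n_tips, birth, death, root_age,
                       seed = derive_seed(seed, "tree"))
  ens <- make_pseudo_posterior(phy, n_posterior, branch_jitter_sd,
                               seed = derive_seed(seed, "posterior"))
  groups <- default_variable_groups()
  vars <- names(groups)
  bm_groups <- c("1", "2", "3")
  # latent factor per group; z0 loosely spread so variables differ in level
  latents <- list()
  for (g in unique(groups)) {
    model <- if (g %in% bm_groups) "BM" else "OU"
    params <- if (model == "BM") list(sigma2 = bm_sigma2, z0 = 10)
              else list(sigma2 = ou_sigma2, z0 = 10, alpha = ou_alpha)
    latents[[g]] <- simulate_traits(phy, model, params,
                                    seed = derive_seed(seed, "latent", g))
  }
  tip_means <- matrix(NA_real_, n_tips, length(vars),
                      dimnames = list(phy$tip.label, vars))
  for (j in seq_along(vars)) {
    g <- groups[j]
    model <- if (g %in% bm_groups) "BM" else "OU"
    params <- if (model == "BM") list(sigma2 = bm_sigma2 / 4, z0 = 0)
              else list(sigma2 = ou_sigma2 / 4, z0 = 0, alpha = ou_alpha)
    idio <- simulate_traits(phy, model, params,
                            seed = derive_seed(seed, "idio", vars[j]))
    tip_means[, j] <- latents[[g]] + idio
  }
  records <- simulate_accessions(tip_means, within_otu_sd = within_otu_sd,
                                 seed = derive_seed(seed, "accessions"))
  list(mcc = phy, posterior = ens$posterior, tip_means = tip_means,
       records = records, groups = groups,
       config = list(n_tips = n_tips, root_age = root_age,
                     n_posterior = n_posterior,
                     branch_jitter_sd = branch_jitter_sd,
                     bm_sigma2 = bm_sigma2, ou_sigma2 = ou_sigma2,
                     ou_alpha = ou_alpha, within_otu_sd = within_otu_sd,
                     seed = seed))
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Emits `mcc.nwk`, `posterior.nwk` (one tree per line), `accessions.csv`
#' and `groups.yml` into `dir`.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(write_newick(study$mcc), file.path(dir, "mcc.nwk"))
  if (length(study$posterior))
    writeLines(vapply(study$posterior, write_newick, character(1)),
               file.path(dir, "posterior.nwk"))
  utils::write.csv(study$records, file.path(dir, "accessions.csv"),
                   row.names = FALSE)
  yaml::write_yaml(as.list(study$groups), file.path(dir, "groups.yml"))
  invisible(dir)
}
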