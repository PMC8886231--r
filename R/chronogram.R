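#' Parse a Newick string into a validated chronogram
#'
#' Reads a single rooted, time-scaled (ultrametric) tree from a Newick
#' string. Branch lengths are interpreted as durations in Myr throughout the
#' package. Internal node labels and support values are tolerated and
#' ignored; quoted labels and `[]` comments are accepted; a root edge length,
#' if present, is ignored.
#'
#' @param text Newick string (must end in `;`).
#' @param ultrametric How to treat ultrametricity violations beyond
#'   `rel_tol`: `"error"` (default), `"warn"`, or `"none"`.
#' @param rel_tol Relative tolerance on root-to-tip depth spread, as a
#'   fraction of tree depth. The default 1e-6 absorbs rounding noise in
#'   chronograms written by Bayesian dating software.
#' @return An object of class `phylo` that has passed chronogram validation.
#' @export
parse_newick <- function(text, ultrametric = c("error", "warn", "none"),
                         rel_tol = 1e-6) {
  stopifnot(is.character(text), length(text) == 1L)
  .check_newick_syntax(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("Newick parse error: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(phy)) stop("Newick parse error: no tree found in string",
                         call. = FALSE)
  validate_chronogram(phy, ultrametric = match.arg(ultrametric),
                      rel_tol = rel_tol)
}

#' Read a chronogram from a Newick file
#'
#' @param file Path to a file containing one Newick tree.
#' @inheritParams parse_newick
#' @return A validated `phylo` object.
#' @export
read_chronogram <- function(file, ultrametric = c("error", "warn", "none"),
                            rel_tol = 1e-6) {
  txt <- paste(readLines(file, warn = FALSE), collapse = "\n")
  parse_newick(txt, ultrametric = match.arg(ultrametric), rel_tol = rel_tol)
}

# Cheap structural pre-check so malformed input fails with a character offset
# rather than an opaque message from the parser.
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_quote <- FALSE
  in_comment <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (in_quote) { if (ch == "'") in_quote <- FALSE; next }
    if (in_comment) { if (ch == "]") in_comment <- FALSE; next }
    if (ch == "'") in_quote <- TRUE
    else if (ch == "[") in_comment <- TRUE
    else if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unbalanced ')' at character ", i,
             call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("Newick parse error: ", depth, " unclosed '(' by character ",
         length(chars), call. = FALSE)
  if (!grepl(";", text, fixed = TRUE))
    stop("Newick parse error: missing terminating ';' at character ",
         length(chars), call. = FALSE)
  invisible(TRUE)
}

#' Validate a tree as a chronogram
#'
#' Checks the invariants the rest of the pipeline relies on: rooted
#' topology, branch lengths present and non-negative on every non-root
#' edge, unique tip labels, and (optionally) ultrametricity within a
#' relative tolerance of tree depth.
#'
#' @param phy A `phylo` object.
#' @inheritParams parse_newick
#' @return The validated tree, invisibly unchanged.
#' @export
validate_chronogram <- function(phy, ultrametric = c("error", "warn", "none"),
                                rel_tol = 1e-6) {
  ultrametric <- match.arg(ultrametric)
  if (!inherits(phy, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  if (!ape::is.rooted(phy)) stop("tree must be rooted", call. = FALSE)
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  bad <- which(is.na(phy$edge.length))
  if (length(bad)) {
    node <- phy$edge[bad[1], 2]
    lab <- if (node <= ape::Ntip(phy)) phy$tip.label[node]
           else paste0("internal node ", node)
    stop("missing branch length on edge leading to ", lab, call. = FALSE)
  }
  if (any(phy$edge.length < 0))
    stop("negative branch length", call. = FALSE)
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (ultrametric != "none") {
    d <- tip_depths(phy)
    spread <- diff(range(d))
    if (spread > rel_tol * max(d)) {
      msg <- sprintf(
        "tree is not ultrametric: tip depths span [%.6g, %.6g] (rel. spread %.3g > %.3g)",
        min(d), max(d), spread / max(d), rel_tol)
      if (ultrametric == "error") stop(msg, call. = FALSE) else warning(msg,
                                                                call. = FALSE)
    }
  }
  phy
}

#' Serialize a chronogram to Newick
#'
#' Writes branch lengths with 10 significant digits so that a
#' parse/serialize/parse round trip preserves them to well below the
#' ultrametricity tolerance.
#'
#' @param phy A `phylo` object.
#' @return A Newick string.
#' @export
write_newick <- function(phy) {
  ape::write.tree(phy, digits = 10)
}

#' Root-to-tip depths
#'
#' @param phy A `phylo` object.
#' @return Named numeric vector of root-to-tip path lengths (Myr), in
#'   tip-label order.
#' @export
tip_depths <- function(phy) {
  d <- ape::node.depth.edgelength(phy)[seq_len(ape::Ntip(phy))]
  names(d) <- phy$tip.label
  d
}

#' Tree depth (root age)
#'
#' @param phy A `phylo` object.
#' @return Maximum root-to-tip path length, in Myr.
#' @export
tree_depth <- function(phy) max(ape::node.depth.edgelength(phy))

#' Phylogenetic covariance matrix
#'
#' The Brownian-motion structure matrix C with `C[i, j]` the shared
#' root-to-MRCA path length (Myr) of tips i and j and `C[i, i]` the
#' root-to-tip depth. On an ultrametric tree every diagonal entry equals the
#' tree depth.
#'
#' @param phy A validated chronogram.
#' @return An n x n symmetric matrix with tip labels as dimnames.
#' @export
phylo_covariance <- function(phy) {
  ape::vcv.phylo(phy)
}

#' Transform a chronogram under a trait-evolution model
#'
#' Rescales branches so that Brownian motion on the transformed object has
#' the covariance implied by the fitted model. `BM` returns an identical
#' copy. `EB` with exponent `a` maps a branch spanning absolute times
#' t1 -> t2 (from the root) onto length `(exp(a*t2) - exp(a*t1)) / a`
#' (`a = 0` leaves the tree unchanged). The non-stationary `OU` covariance
#' is not exactly representable as a tree for all `alpha`, so the OU
#' transform is returned as a covariance object (class
#' `transformed_covariance`) that downstream consumers such as
#' [ancestral_states()] accept in place of a tree.
#'
#' @param phy A validated chronogram (never mutated).
#' @param model One of `"BM"`, `"OU"`, `"EB"`.
#' @param params Named list: `alpha` (> 0) for OU, `a` (<= 0) for EB.
#' @param ac_mode Allow `a > 0` (accelerating rates) for EB.
#' @return A `phylo` for BM/EB; a `transformed_covariance` list
#'   (fields `V`, `tip.label`, `model`, `params`, `tree`) for OU.
#' @export
transform_tree <- function(phy, model = c("BM", "OU", "EB"), params = list(),
                           ac_mode = FALSE) {
  model <- match.arg(model)
  if (model == "BM") return(phy)
  if (model == "EB") {
    a <- params$a
    if (is.null(a)) stop("EB transform requires parameter 'a'", call. = FALSE)
    if (a > 0 && !ac_mode)
      stop("EB exponent a > 0; set ac_mode = TRUE for accelerating rates",
           call. = FALSE)
    if (a == 0) return(phy)
    out <- phy
    depth <- ape::node.depth.edgelength(phy)
    t1 <- depth[phy$edge[, 1]]
    t2 <- depth[phy$edge[, 2]]
    out$edge.length <- (exp(a * t2) - exp(a * t1)) / a
    return(out)
  }
  # OU: covariance-space rescaling
  alpha <- params$alpha
  if (is.null(alpha) || alpha <= 0)
    stop("OU transform requires alpha > 0", call. = FALSE)
  V <- model_covariance(phy, "OU", list(sigma2 = 1, alpha = alpha))
  structure(list(V = V, tip.label = phy$tip.label, model = "OU",
                 params = list(alpha = alpha), tree = phy),
            class = "transformed_covariance")
}

#' Load an MCC tree plus a posterior tree ensemble
#'
#' @param mcc Path to the MCC tree (single Newick).
#' @param posterior Optional path to a multi-tree Newick file (one tree per
#'   line). `NULL` gives MCC-only mode.
#' @inheritParams parse_newick
#' @return List with `mcc` (a `phylo`) and `posterior` (a `multiPhylo`,
#'   possibly empty); all trees validated and sharing the MCC tip set.
#' @export
read_tree_ensemble <- function(mcc, posterior = NULL,
                               ultrametric = c("error", "warn", "none"),
                               rel_tol = 1e-6) {
  ultrametric <- match.arg(ultrametric)
  mcc_tree <- read_chronogram(mcc, ultrametric = ultrametric,
                              rel_tol = rel_tol)
  post <- list()
  if (!is.null(posterior)) {
    trees <- ape::read.tree(posterior)
    if (inherits(trees, "phylo")) trees <- list(trees)
    post <- lapply(trees, validate_chronogram, ultrametric = ultrametric,
                   rel_tol = rel_tol)
    for (i in seq_along(post)) {
      if (!setequal(post[[i]]$tip.label, mcc_tree$tip.label))
        stop("posterior tree ", i, " has a different tip set from the MCC tree",
             call. = FALSE)
    }
  }
  class(post) <- "multiPhylo"
  list(mcc = mcc_tree, posterior = post)
}
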