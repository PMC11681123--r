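#' Minimum-branch-length time-scaling from first appearance dates
#'
#' A posteriori dating of a rooted topology: tip ages are set to their
#' first appearance dates (FADs, Ma), and each node's age is the maximum
#' over its children of (child age + `mbl`), so nodes appear in order of
#' the first appearance of their oldest descendant and every branch is at
#' least `mbl` Myr long. Polytomies are retained. Ultrametricity is not
#' required (fossil tips keep their ages).
#'
#' @param topology A rooted `phylo` (branch lengths, if any, are ignored).
#' @param fads Named numeric vector of first appearance dates (Ma, >= 0),
#'   one per tip label.
#' @param mbl Minimum branch length in Myr (default 1).
#' @return Object of class `dated_tree`: `phylo` (the topology with branch
#'   lengths in Myr), `node_ages` (ages of all tips then internal nodes,
#'   Ma), `tip_ages`, `mbl`.
#' @export
mbl_timescale <- function(topology, fads, mbl = 1.0) {
  if (!inherits(topology, "phylo")) stop("topology must be an ape 'phylo'")
  if (!ape::is.rooted(topology)) stop("topology must be rooted")
  if (mbl <= 0) stop("mbl must be positive")
  tips <- topology$tip.label
  miss <- setdiff(tips, names(fads))
  if (length(miss)) stop("missing FADs for: ", paste(miss, collapse = ", "))
  fad <- fads[tips]
  if (any(fad < 0)) stop("negative first appearance dates: ",
                         paste(tips[fad < 0], collapse = ", "))
  n <- length(tips)
  m <- topology$Nnode
  age <- c(as.numeric(fad), rep(-Inf, m))
  po <- ape::reorder.phylo(topology, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]; child <- po$edge[e, 2L]
    age[par] <- max(age[par], age[child] + mbl)
  }
  out <- topology
  out$edge.length <- age[topology$edge[, 1L]] - age[topology$edge[, 2L]]
  structure(list(phylo = out,
                 node_ages = age,
                 tip_ages = stats::setNames(age[seq_len(n)], tips),
                 mbl = mbl),
            class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  cat("Time-scaled tree:", length(x$phylo$tip.label), "tips; root age",
      sprintf("%.2f Ma;", max(x$node_ages)), "minimum branch length",
      x$mbl, "Myr\n")
  invisible(x)
}

as_phylo_tree <- function(tree) {
  if (inherits(tree, "dated_tree")) tree$phylo else tree
}

#' Brownian-motion maximum-likelihood ancestral states
#'
#' ML/GLS reconstruction of a continuous trait under Brownian motion:
#' internal-node states solve the weighted least-squares system that
#' minimizes the sum over branches of squared state change divided by
#' branch length (the sparse-Laplacian form of the ML estimator; the
#' estimates coincide with the re-rooted GLS/three-point estimator).
#' Node variances are the conditional variances of the internal states
#' given the tips, scaled by the ML Brownian rate
#' `sigma^2 = (x - mu)' C^{-1} (x - mu) / n`, and 95% CIs use the normal
#' approximation (±1.96 sd).
#'
#' @param tree A `dated_tree` or a rooted `phylo` with positive branch
#'   lengths (zero-length branches are perturbed to 1e-8 with a warning).
#' @param trait Named numeric vector of tip values.
#' @return Object of class `ancestral_states`: `estimates`, `variances`,
#'   `ci_lower`, `ci_upper` (one per internal node, named by ape node
#'   number), `sigma2`, `root_estimate`, `tree`.
#' @export
bm_ancestral_states <- function(tree, trait) {
  phy <- as_phylo_tree(tree)
  if (!inherits(phy, "phylo")) stop("tree must be a 'phylo' or 'dated_tree'")
  miss <- setdiff(phy$tip.label, names(trait))
  if (length(miss)) stop("missing trait values for: ", paste(miss, collapse = ", "))
  x <- as.numeric(trait[phy$tip.label])
  n <- length(phy$tip.label)
  m <- phy$Nnode
  len <- phy$edge.length
  if (is.null(len)) stop("tree has no branch lengths")
  if (any(len < 0)) stop("negative branch lengths")
  if (any(len == 0)) {
    warning("zero-length branches perturbed to 1e-8")
    len[len == 0] <- 1e-8
  }
  w <- 1 / len
  # Laplacian system over internal nodes (numbered n+1 .. n+m in ape)
  L <- matrix(0, m, m)
  rhs <- numeric(m)
  for (e in seq_along(w)) {
    par <- phy$edge[e, 1L] - n
    child <- phy$edge[e, 2L]
    L[par, par] <- L[par, par] + w[e]
    if (child > n) {
      ci <- child - n
      L[ci, ci] <- L[ci, ci] + w[e]
      L[par, ci] <- L[par, ci] - w[e]
      L[ci, par] <- L[ci, par] - w[e]
    } else {
      rhs[par] <- rhs[par] + w[e] * x[child]
    }
  }
  Linv <- solve(L)
  est <- as.vector(Linv %*% rhs)

  # ML rate from the tip covariance (shared path lengths from the root)
  C <- ape::vcv(phy)
  Cix <- solve(C, x)
  Ci1 <- solve(C, rep(1, n))
  mu <- sum(Cix) / sum(Ci1)
  dev <- x - mu
  sigma2 <- as.numeric(crossprod(dev, solve(C, dev))) / n

  vars <- sigma2 * diag(Linv)
  node_ids <- n + seq_len(m)
  structure(list(
    estimates = stats::setNames(est, node_ids),
    variances = stats::setNames(vars, node_ids),
    ci_lower = stats::setNames(est - 1.96 * sqrt(vars), node_ids),
    ci_upper = stats::setNames(est + 1.96 * sqrt(vars), node_ids),
    sigma2 = sigma2,
    root_estimate = est[1L],
    tree = phy), class = "ancestral_states")
}

#' @export
print.ancestral_states <- function(x, ...) {
  r <- names(x$estimates)[1L]
  cat(sprintf(
    "BM ancestral states: %d nodes; sigma^2 = %.4g\n  root (node %s): %.4g (95%% CI %.4g-%.4g)\n",
    length(x$estimates), x$sigma2, r, x$root_estimate,
    x$ci_lower[1L], x$ci_upper[1L]))
  invisible(x)
}

#' Tabulated trait history along branches
#'
#' Linear interpolation of the reconstructed trait along every branch
#' between the parent and child estimates (tips use their observed
#' values) — a tabular equivalent of a painted-branch trait map.
#'
#' @param tree A `dated_tree` or `phylo` (the one used for the states).
#' @param states An `ancestral_states` from [bm_ancestral_states()].
#' @param trait Named tip trait vector (for branch endpoints at tips).
#' @param n_steps Number of interpolation points per branch (default 10).
#' @return Data frame: `parent`, `child`, `position` (0 at parent to 1 at
#'   child), `state`.
#' @export
map_trait_history <- function(tree, states, trait, n_steps = 10L) {
  phy <- as_phylo_tree(tree)
  n <- length(phy$tip.label)
  node_state <- function(id) {
    if (id <= n) as.numeric(trait[phy$tip.label[id]])
    else unname(states$estimates[as.character(id)])
  }
  pos <- seq(0, 1, length.out = n_steps)
  rows <- lapply(seq_len(nrow(phy$edge)), function(e) {
    a <- node_state(phy$edge[e, 1L]); b <- node_state(phy$edge[e, 2L])
    data.frame(parent = phy$edge[e, 1L], child = phy$edge[e, 2L],
               position = pos, state = a + (b - a) * pos)
  })
  do.call(rbind, rows)
}
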