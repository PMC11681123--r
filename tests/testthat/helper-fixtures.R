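# Fixtures are generated in code; no data files.

random_config <- function(p = 8L, rib_index = 1L, id = "fix", sd = 1) {
  landmark_config(matrix(rnorm(3L * p, sd = sd), p, 3L),
                  rib_index = rib_index, specimen_id = id)
}

random_config_list <- function(n = 5L, p = 8L, prefix = "fix") {
  lapply(seq_len(n), function(i) {
    random_config(p, rib_index = i, id = sprintf("%s_%02d", prefix, i))
  })
}

# simple full rib series with smooth shape change, n <= 50 (no subsampling)
smooth_series <- function(n = 12L, p = 8L, seed = 1L) {
  set.seed(seed)
  base <- matrix(rnorm(3L * p), p, 3L)
  dir <- matrix(rnorm(3L * p), p, 3L); dir <- dir / sqrt(sum(dir^2))
  cfgs <- lapply(seq_len(n), function(i) {
    landmark_config(base + (i / n) * dir, rib_index = i,
                    specimen_id = sprintf("r%02d", i))
  })
  rib_series(cfgs, n_ribs_total = n, body_type = "limbed", species = "smooth")
}

# brute-force minimum-RSS segmentation by enumerating all breakpoint sets
brute_force_best <- function(positions, scores, k, min_seg = 3L) {
  n <- length(positions)
  seg_rss <- function(i, j) {
    x <- positions[i:j]; y <- as.matrix(scores)[i:j, , drop = FALSE]
    xc <- x - mean(x)
    yc <- sweep(y, 2L, colMeans(y))
    sum(colSums(yc^2) - as.vector(crossprod(xc, yc))^2 / sum(xc^2))
  }
  if (k == 1L) return(list(rss = seg_rss(1L, n), ends = integer(0)))
  best <- list(rss = Inf, ends = integer(0))
  cuts <- utils::combn(seq_len(n - 1L), k - 1L)
  for (c_i in seq_len(ncol(cuts))) {
    ends <- cuts[, c_i]
    lens <- diff(c(0L, ends, n))
    if (any(lens < min_seg)) next
    bounds <- c(0L, ends, n)
    tot <- 0
    for (s in seq_len(k)) tot <- tot + seg_rss(bounds[s] + 1L, bounds[s + 1L])
    if (tot < best$rss) best <- list(rss = tot, ends = ends)
  }
  best
}

# ordinary two-shape Procrustes distance by brute-force search over rotations
# about the z axis (for planar shapes) -- independent of the SVD route
grid_rotation_distance <- function(a, b, n_grid = 20000L) {
  thetas <- seq(0, 2 * pi, length.out = n_grid)
  best <- Inf
  for (th in thetas) {
    r <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3L, 3L)
    d <- sqrt(sum((a - b %*% r)^2))
    if (d < best) best <- d
  }
  best
}

# GLS ancestral-state solve from the full Brownian covariance of tips and
# internal nodes (independent of the sparse Laplacian route)
gls_ancestral_states <- function(tree, trait) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  x <- as.numeric(trait[tree$tip.label])
  # node depths (shared path length from root) for all tips+nodes
  nn <- n + m
  depth <- numeric(nn)
  cw <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(cw$edge))) {
    depth[cw$edge[e, 2L]] <- depth[cw$edge[e, 1L]] + cw$edge.length[e]
  }
  # pairwise shared path = depth of MRCA
  anc_path <- function(v) {
    path <- v
    repeat {
      e <- which(tree$edge[, 2L] == v)
      if (!length(e)) break
      v <- tree$edge[e, 1L]
      path <- c(path, v)
    }
    path
  }
  paths <- lapply(seq_len(nn), anc_path)
  mrca_depth <- function(i, j) {
    common <- intersect(paths[[i]], paths[[j]])
    max(depth[common])
  }
  C <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    C[i, j] <- if (i == j) depth[i] else mrca_depth(i, j)
  }
  ones <- rep(1, n)
  Ci <- solve(C)
  mu <- as.numeric(crossprod(ones, Ci %*% x) / crossprod(ones, Ci %*% ones))
  # E[a_node | x] under BM with root state mu: mu + cov(node, tips) C^{-1} (x - mu)
  est <- numeric(m)
  for (kk in seq_len(m)) {
    node <- n + kk
    cv <- vapply(seq_len(n), function(i) mrca_depth(node, i), numeric(1))
    est[kk] <- mu + as.numeric(crossprod(cv, Ci %*% (x - mu)))
  }
  est
}
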