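#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of all landmarks from
#' their centroid — the standard geometric-morphometric size variable. It
#' scales linearly under isotropic scaling and is unaffected by rotation
#' or translation.
#'
#' @param config A [landmark_config] or a numeric p x 3 matrix.
#' @return Positive scalar in the configuration's units.
#' @export
centroid_size <- function(config) {
  m <- if (inherits(config, "landmark_config")) config$points else as.matrix(config)
  if (nrow(m) < 2L) stop("need at least 2 landmarks")
  cen <- sweep(m, 2L, colMeans(m))
  cs <- sqrt(sum(cen^2))
  if (cs <= .Machine$double.eps^0.5) stop("degenerate configuration: all points coincident")
  cs
}

# Optimal proper rotation R minimizing ||a - b %*% R||_F (Kabsch via SVD;
# det(R) = +1 always, reflections disallowed because ribs come from one
# bilateral half and chirality is meaningful).
optimal_rotation <- function(b, a) {
  m <- crossprod(b, a)
  s <- svd(m)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# Center at origin and scale to unit centroid size.
center_scale <- function(m) {
  cen <- sweep(m, 2L, colMeans(m))
  cen / sqrt(sum(cen^2))
}

#' Generalized Procrustes analysis of a rib series
#'
#' Iterative superimposition removing translation (centering), size
#' (scaling to unit centroid size) and orientation (optimal proper rotation
#' to the running consensus via singular value decomposition). The consensus
#' is the arithmetic mean of aligned shapes re-normalized to unit centroid
#' size; iteration stops when its root-mean-square change falls below
#' `tol`. Semilandmarks are treated as fixed points; an optional sliding
#' step minimizes each semilandmark's residual along the discrete curve
#' tangent, alternated with re-superimposition.
#'
#' @param x A [rib_series] or a list of [landmark_config] objects (at least
#'   two, equal point counts).
#' @param tol Convergence tolerance on consensus RMS change (default 1e-9).
#' @param max_iter Maximum iterations (default 500; very dissimilar
#'   shape pairs converge slowly).
#' @param slide If `TRUE`, slide semilandmarks along their curve tangents
#'   between superimposition passes (default `FALSE`, the simplest
#'   reproducible treatment).
#' @return Object of class `gpa_fit`: `coords` (p x 3 x n aligned array,
#'   each shape centered with unit centroid size), `consensus` (p x 3),
#'   `csize` and `log_cs` (per-rib centroid sizes in input units and their
#'   natural logs), `converged`, `iterations`, and the source `series`
#'   when available.
#' @export
gpa <- function(x, tol = 1e-9, max_iter = 500L, slide = FALSE) {
  series <- NULL
  if (inherits(x, "rib_series")) {
    series <- x
    coords <- x$coords
    n_fixed <- x$n_fixed; n_semi <- x$n_semi
  } else if (is.list(x)) {
    np <- vapply(x, function(cf) nrow(cf$points), integer(1))
    if (length(unique(np)) != 1L) stop("configurations differ in point count")
    coords <- array(NA_real_, c(np[1L], 3L, length(x)))
    for (i in seq_along(x)) coords[, , i] <- x[[i]]$points
    n_fixed <- x[[1L]]$n_fixed; n_semi <- x[[1L]]$n_semi
  } else if (is.array(x) && length(dim(x)) == 3L) {
    coords <- x; n_fixed <- dim(x)[1L]; n_semi <- 0L
  } else stop("x must be a rib_series, a list of landmark_config, or a p x 3 x n array")

  n <- dim(coords)[3L]
  if (n < 2L) stop("GPA needs at least 2 configurations")

  csize <- apply(coords, 3L, centroid_size)
  aligned <- coords
  for (i in seq_len(n)) aligned[, , i] <- center_scale(coords[, , i])

  consensus <- center_scale(apply(aligned, c(1L, 2L), mean))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      aligned[, , i] <- aligned[, , i] %*% optimal_rotation(aligned[, , i], consensus)
    }
    if (slide && n_semi > 1L) {
      for (i in seq_len(n)) {
        aligned[, , i] <- center_scale(
          slide_semilandmarks(aligned[, , i], consensus, n_fixed, n_semi))
      }
    }
    new_consensus <- center_scale(apply(aligned, c(1L, 2L), mean))
    delta <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("GPA failed to converge after ", max_iter,
         " iterations (last consensus RMS change ", format(delta), ")")
  }
  structure(list(coords = aligned, consensus = consensus, csize = csize,
                 log_cs = log(csize), converged = converged, iterations = iter,
                 series = series),
            class = "gpa_fit")
}

# Move each semilandmark along its discrete curve tangent to the position
# minimizing its residual from the consensus (orthogonal projection of the
# residual onto the unit tangent).
slide_semilandmarks <- function(shape, consensus, n_fixed, n_semi) {
  idx <- n_fixed + seq_len(n_semi)
  for (j in seq_along(idx)) {
    i <- idx[j]
    prev <- if (j == 1L) i else idx[j - 1L]
    nxt <- if (j == n_semi) i else idx[j + 1L]
    tangent <- consensus[nxt, ] - consensus[prev, ]
    len <- sqrt(sum(tangent^2))
    if (len < .Machine$double.eps) next
    tangent <- tangent / len
    shape[i, ] <- shape[i, ] + sum((consensus[i, ] - shape[i, ]) * tangent) * tangent
  }
  shape
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("Generalized Procrustes fit:", dim(x$coords)[3L], "shapes,",
      dim(x$coords)[1L], "landmarks; converged in", x$iterations, "iterations\n")
  invisible(x)
}

#' Partial Procrustes distance between two aligned shapes
#'
#' Square root of the summed squared coordinate differences after the
#' optimal proper rotation of `b` onto `a`. Both shapes must be centered
#' with unit centroid size (as produced by [gpa()]); no additional scaling
#' is applied, so this is the partial (not full) Procrustes distance.
#'
#' @param a,b Numeric p x 3 matrices, centered, unit centroid size.
#' @return Non-negative scalar; zero iff the shapes are identical up to a
#'   proper rotation.
#' @export
procrustes_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("shapes differ in dimension")
  rb <- b %*% optimal_rotation(b, a)
  sqrt(sum((a - rb)^2))
}

#' Export aligned coordinates as a flat matrix
#'
#' Flattens a p x 3 x n aligned array to an n x 3p matrix with columns
#' x1, y1, z1, x2, ... — the row layout used for PCA and regression.
#'
#' @param fit A `gpa_fit` (or a p x 3 x n array).
#' @return Numeric n x 3p matrix.
#' @export
flatten_shapes <- function(fit) {
  coords <- if (inherits(fit, "gpa_fit")) fit$coords else fit
  p <- dim(coords)[1L]; n <- dim(coords)[3L]
  out <- matrix(NA_real_, n, 3L * p)
  for (i in seq_len(n)) out[i, ] <- as.vector(t(coords[, , i]))
  colnames(out) <- paste0(rep(c("x", "y", "z"), p), rep(seq_len(p), each = 3L))
  out
}

# Inverse of flatten_shapes row layout.
unflatten_shapes <- function(mat) {
  n <- nrow(mat); p <- ncol(mat) / 3L
  coords <- array(NA_real_, c(p, 3L, n))
  for (i in seq_len(n)) coords[, , i] <- matrix(mat[i, ], ncol = 3L, byrow = TRUE)
  coords
}
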