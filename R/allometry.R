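#' Multivariate regression of shape on log centroid size
#'
#' Regresses the flattened Procrustes shape coordinates on log centroid
#' size (ordinary least squares per coordinate, equivalent to the
#' multivariate regression underlying a Procrustes ANOVA of shape on
#' size). `r_squared` is the proportion of total Procrustes variance
#' explained by size; significance is assessed by permutation of the size
#' vector against the shape rows.
#'
#' @param aligned A `gpa_fit` from [gpa()] (supplies both shapes and
#'   centroid sizes).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream (required, recorded
#'   in the result).
#' @return Object of class `allometry_fit`: `slope` and `intercept`
#'   vectors over flattened coordinates, `r_squared`, `perm_p`,
#'   `ss_model`, `ss_total`, `residual_shapes` (p x 3 x n array of
#'   consensus-plus-residual coordinates), `log_cs`, `seed`, `n_perm`.
#' @export
fit_allometry <- function(aligned, n_perm = 999L, seed = 1L) {
  stopifnot(inherits(aligned, "gpa_fit"))
  y <- flatten_shapes(aligned)
  x <- aligned$log_cs
  n <- nrow(y)
  if (n < 4L) stop("need at least 4 ribs for the size regression")
  if (stats::sd(x) < .Machine$double.eps^0.5) {
    stop("log centroid size is constant: size regression is collinear")
  }
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  ybar <- colMeans(y)
  yc <- sweep(y, 2L, ybar)
  slope <- as.vector(crossprod(xc, yc)) / sxx
  intercept <- ybar - slope * mean(x)
  fitted_c <- outer(xc, slope)
  resid <- yc - fitted_c
  ss_total <- sum(yc^2)
  ss_model <- sum(fitted_c^2)
  r2 <- ss_model / ss_total

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    xp <- xc[sample.int(n)]
    ssm <- sum(as.vector(crossprod(xp, yc))^2) / sum(xp^2)
    if (ssm >= ss_model) exceed <- exceed + 1L
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  perm_p <- (exceed + 1L) / (n_perm + 1L)

  # residual shapes live in coordinate space: consensus + row residual
  resid_mat <- sweep(resid, 2L, ybar, `+`)
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r2, perm_p = perm_p,
                 ss_model = ss_model, ss_total = ss_total,
                 residual_shapes = unflatten_shapes(resid_mat),
                 log_cs = x, seed = seed, n_perm = as.integer(n_perm)),
            class = "allometry_fit")
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat("Allometric regression of shape on log centroid size\n")
  cat(sprintf("  R^2 = %.4f, permutation p = %.4g (%d permutations, seed %d)\n",
              x$r_squared, x$perm_p, x$n_perm, x$seed))
  invisible(x)
}

#' Regionalization of the size-independent shape component
#'
#' Repeats the full PCA + segmented-regression pipeline on the residual
#' shape coordinates from [fit_allometry()], detecting boundaries that are
#' independent of allometric variation (non-allometric boundaries).
#'
#' @param allom An `allometry_fit`.
#' @param n_retained PCs to retain for the residual shape space (default 6).
#' @param series Optional [rib_series] for boundary percentages.
#' @param ... Passed to [slra()] (`max_regions`, `min_seg`, ...).
#' @return A `regionalization` of the residual shapes.
#' @export
nonallometric_regionalization <- function(allom, n_retained = 6L, series = NULL, ...) {
  stopifnot(inherits(allom, "allometry_fit"))
  space <- shape_pca(flatten_shapes(allom$residual_shapes), n_retained = n_retained)
  slra(space, series = series, ...)
}

#' Allometric boundary count and region-score drop
#'
#' The number of allometric boundaries is the difference between the
#' best-fit region count of the full shape variables and that of the
#' size-independent residuals; the region-score drop is the corresponding
#' difference in Akaike-weighted region scores. Negative counts (residuals
#' supporting more regions than the full shapes) are reported, not
#' clamped, with a warning flag.
#'
#' @param full `regionalization` of the full shape variables.
#' @param residual `regionalization` of the non-allometric residuals.
#' @return List: `allometric_boundaries` (signed integer),
#'   `region_score_drop`, `k_full`, `k_residual`, `score_full`,
#'   `score_residual`, `negative_flag`.
#' @export
allometric_boundary_count <- function(full, residual) {
  a <- full$best_overall$k - residual$best_overall$k
  neg <- a < 0L
  if (neg) warning("residual model has more regions than the full model (A = ", a, ")")
  list(allometric_boundaries = as.integer(a),
       region_score_drop = full$region_score - residual$region_score,
       k_full = full$best_overall$k,
       k_residual = residual$best_overall$k,
       score_full = full$region_score,
       score_residual = residual$region_score,
       negative_flag = neg)
}
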