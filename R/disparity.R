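#' Axial heterogeneity of a rib skeleton
#'
#' Within-specimen spread of rib shapes: the range of partial Procrustes
#' distances across all ribs in a sample. The primary definition is the
#' maximum pairwise distance (the diameter of the shape scatter); the
#' alternative reading — maximum minus minimum distance to the consensus —
#' is also reported.
#'
#' @param aligned A `gpa_fit` from [gpa()] over one specimen's ribs.
#' @return Object of class `heterogeneity`: `H` (max pairwise distance),
#'   `H_consensus_range` (max - min distance to consensus), `pairwise_d`
#'   (symmetric distance matrix), `d_to_consensus`.
#' @export
axial_heterogeneity <- function(aligned) {
  stopifnot(inherits(aligned, "gpa_fit"))
  n <- dim(aligned$coords)[3L]
  if (n < 2L) stop("heterogeneity needs at least 2 ribs")
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- procrustes_distance(aligned$coords[, , i],
                                                aligned$coords[, , j])
    }
  }
  dc <- vapply(seq_len(n), function(i) {
    procrustes_distance(aligned$consensus, aligned$coords[, , i])
  }, numeric(1))
  structure(list(H = max(d), H_consensus_range = max(dc) - min(dc),
                 pairwise_d = d, d_to_consensus = dc),
            class = "heterogeneity")
}

#' @export
print.heterogeneity <- function(x, ...) {
  cat(sprintf("Axial heterogeneity: H = %.4f (max pairwise); %.4f (consensus range)\n",
              x$H, x$H_consensus_range))
  invisible(x)
}

#' Shape distance of the axial extremes to the mid-point rib
#'
#' Compares the rib shapes at 4% and 96% of the axis to the mid-point rib
#' by partial Procrustes distance. On a 4% sampling grid an exact 50% rib
#' rarely exists; the mid rib is the sampled rib whose original index is
#' closest to `round(0.5 * (n_ribs_total - 1)) + 1` (48% or 52%,
#' whichever is nearer; anterior wins ties).
#'
#' @param aligned A `gpa_fit` over the specimen's sampled ribs.
#' @param series The matching [rib_series] (supplies axial fractions).
#' @return List: `d_ant_mid`, `d_post_mid`, and the sampled positions
#'   used (`ant_index`, `mid_index`, `post_index`, original rib indices).
#' @export
extreme_vs_mid <- function(aligned, series) {
  stopifnot(inherits(aligned, "gpa_fit"), inherits(series, "rib_series"))
  n <- length(series$rib_index)
  if (dim(aligned$coords)[3L] != n) stop("aligned shapes and series disagree in rib count")
  af <- series$axial_fraction
  pick <- function(target) which.min(abs(af - target))
  ant <- pick(0.04); post <- pick(0.96)
  mid_target <- floor(0.5 * (series$n_ribs_total - 1) + 0.5) + 1
  mid <- which.min(abs(series$rib_index - mid_target))
  if (length(unique(c(ant, mid, post))) < 3L) {
    stop("series does not span the 4%, mid and 96% axial positions")
  }
  list(d_ant_mid = procrustes_distance(aligned$coords[, , mid], aligned$coords[, , ant]),
       d_post_mid = procrustes_distance(aligned$coords[, , mid], aligned$coords[, , post]),
       ant_index = series$rib_index[ant],
       mid_index = series$rib_index[mid],
       post_index = series$rib_index[post])
}

#' Inter-species shape disparity at one axial interval
#'
#' Procrustes variance of one rib per species, all taken at the same
#' relative axial position and jointly superimposed (a fresh GPA per
#' interval, so distances live in one shape space): the mean squared
#' partial Procrustes distance to the interval consensus.
#'
#' @param configs List of [landmark_config] (one per species, all at the
#'   same axial interval) or a p x 3 x n array.
#' @return List: `variance` (Procrustes variance), `n` (species used),
#'   `fit` (the joint `gpa_fit`).
#' @export
interspecies_disparity <- function(configs) {
  fit <- gpa(configs)
  n <- dim(fit$coords)[3L]
  if (n < 3L) stop("disparity needs ribs from at least 3 species")
  d2 <- vapply(seq_len(n), function(i) {
    procrustes_distance(fit$consensus, fit$coords[, , i])^2
  }, numeric(1))
  list(variance = mean(d2), n = n, fit = fit)
}

#' Procrustes ANOVA between groups at one axial interval
#'
#' One-way analysis of variance on jointly superimposed shape coordinates:
#' `F = (SS_between/df_between) / (SS_within/df_within)` with significance
#' from permutation of the group labels.
#'
#' @param fit A joint `gpa_fit` of the interval's ribs across species.
#' @param groups Factor (or vector) of group labels, one per shape; two
#'   groups with at least 3 members each.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed (required for reproducibility).
#' @return List: `F`, `p`, `ss_between`, `ss_within`, `df_between`,
#'   `df_within`, `seed`, `n_perm`.
#' @export
procrustes_anova_groups <- function(fit, groups, n_perm = 999L, seed = 1L) {
  stopifnot(inherits(fit, "gpa_fit"))
  y <- flatten_shapes(fit)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) stop("need at least two non-empty groups")
  if (any(table(groups) < 3L)) stop("each group needs at least 3 members")
  n <- nrow(y)
  g <- nlevels(groups)
  yc <- sweep(y, 2L, colMeans(y))
  ss_total <- sum(yc^2)
  ssb <- function(lab) {
    s <- 0
    for (lv in levels(lab)) {
      rows <- lab == lv
      s <- s + sum(rows) * sum(colMeans(yc[rows, , drop = FALSE])^2)
    }
    s
  }
  ss_between <- ssb(groups)
  ss_within <- ss_total - ss_between
  df_b <- g - 1L; df_w <- n - g
  f_obs <- (ss_between / df_b) / (ss_within / df_w)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    sb <- ssb(groups[sample.int(n)])
    fp <- (sb / df_b) / ((ss_total - sb) / df_w)
    if (fp >= f_obs) exceed <- exceed + 1L
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  list(F = f_obs, p = (exceed + 1L) / (n_perm + 1L),
       ss_between = ss_between, ss_within = ss_within,
       df_between = df_b, df_within = df_w,
       seed = seed, n_perm = as.integer(n_perm))
}

#' Welch two-sample contrast
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom,
#' the form used for all group contrasts (region score, boundary
#' positions, heterogeneity, region-score drop) between body types.
#'
#' @param values_a,values_b Numeric vectors (each at least 2 values).
#' @param labels Length-2 character vector naming the groups.
#' @return Object of class `group_contrast`: `t`, `df`, `p` (two-sided),
#'   `mean_a`, `mean_b`, `labels`.
#' @export
welch_t <- function(values_a, values_b, labels = c("a", "b")) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs at least 2 values")
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0 &&
      mean(values_a) == mean(values_b)) {
    stop("zero variance in both groups with equal means: t undefined")
  }
  ht <- stats::t.test(values_a, values_b, var.equal = FALSE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value,
                 mean_a = mean(values_a), mean_b = mean(values_b),
                 labels = labels),
            class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("%s vs %s: means %.4g / %.4g; t(%.2f) = %.3f, p = %.3g\n",
              x$labels[1L], x$labels[2L], x$mean_a, x$mean_b, x$df, x$t, x$p))
  invisible(x)
}
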