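#' Principal-component shape space from aligned shapes
#'
#' PCA of the mean-centered flattened aligned coordinates. The first few
#' components (six by default, typically ~95% of shape variation in rib
#' data) are retained as the shape variables for segmented regression.
#'
#' @param aligned A `gpa_fit` from [gpa()], or an n x q matrix of shape
#'   variables (rows = ribs).
#' @param n_retained Number of PCs to retain (default 6); capped at the
#'   matrix rank.
#' @return Object of class `shape_space`: `scores` (n x n_retained),
#'   `eigenvalues` (all, nonincreasing), `variance_fraction`, `n_retained`,
#'   `rotation`, `center`.
#' @export
shape_pca <- function(aligned, n_retained = 6L) {
  mat <- if (inherits(aligned, "gpa_fit")) flatten_shapes(aligned) else as.matrix(aligned)
  if (nrow(mat) < 3L) stop("need at least 3 shapes for a shape space")
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  rank <- sum(ev > max(ev) * 1e-12)
  if (rank == 0L) stop("degenerate variation: all shapes identical")
  k <- min(as.integer(n_retained), rank)
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 eigenvalues = ev,
                 variance_fraction = ev / sum(ev),
                 n_retained = k,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 center = pc$center),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat("Shape space:", nrow(x$scores), "ribs,", x$n_retained, "PCs retained (",
      sprintf("%.1f%%", 100 * sum(x$variance_fraction[seq_len(x$n_retained)])),
      "of variance )\n")
  invisible(x)
}

#' Residual sum of squares of one candidate segment
#'
#' Sum over retained PCs of the ordinary-least-squares residual sum of
#' squares of score against axial position over rows `i..j`. Segments are
#' fit independently per PC with their own slope and intercept (no
#' continuity constraint across segments).
#'
#' @param positions Ordered numeric axial positions (sampled rib ordinals).
#' @param scores Numeric matrix of PC scores, rows matching `positions`.
#' @param i,j 1-based start and end rows of the segment.
#' @param min_seg Minimum segment length (default 3; two points fit a line
#'   exactly and would saturate the likelihood).
#' @return Non-negative total RSS of the segment.
#' @export
segment_rss <- function(positions, scores, i, j, min_seg = 3L) {
  if (j - i + 1L < min_seg) {
    stop("segment ", i, "..", j, " shorter than min_seg = ", min_seg)
  }
  x <- positions[i:j]
  y <- as.matrix(scores)[i:j, , drop = FALSE]
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  yc <- sweep(y, 2L, colMeans(y))
  sxy <- as.vector(crossprod(xc, yc))
  syy <- colSums(yc^2)
  sum(syy - sxy^2 / sxx)
}

# Cost matrix: cost[i, j] = segment_rss(positions, scores, i, j) for all
# valid spans (j - i + 1 >= min_seg), NA elsewhere. O(n^2 * npc) via
# cumulative sums.
segment_cost_matrix <- function(positions, scores, min_seg = 3L) {
  x <- as.numeric(positions)
  y <- as.matrix(scores)
  n <- length(x)
  cost <- matrix(NA_real_, n, n)
  cx <- cumsum(x); cxx <- cumsum(x^2)
  cy <- apply(y, 2L, cumsum)
  cyy <- apply(y^2, 2L, cumsum)
  cxy <- apply(y * x, 2L, cumsum)
  at <- function(c, i) if (i == 0L) 0 else c[i]
  atm <- function(c, i) if (i == 0L) rep(0, ncol(c)) else c[i, ]
  for (i in seq_len(n)) {
    if (i + min_seg - 1L > n) break
    for (j in (i + min_seg - 1L):n) {
      m <- j - i + 1L
      sx <- at(cx, j) - at(cx, i - 1L)
      sxx <- at(cxx, j) - at(cxx, i - 1L)
      sy <- atm(cy, j) - atm(cy, i - 1L)
      syy <- atm(cyy, j) - atm(cyy, i - 1L)
      sxy <- atm(cxy, j) - atm(cxy, i - 1L)
      vxx <- sxx - sx^2 / m
      vyy <- syy - sy^2 / m
      vxy <- sxy - sx * sy / m
      cost[i, j] <- sum(pmax(vyy - vxy^2 / vxx, 0))
    }
  }
  cost
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = N * log(RSS/N) + 2p + 2p(p+1)/(N - p - 1)` with constant terms
#' dropped consistently across models. A saturated model (`RSS = 0`)
#' returns `-Inf` with a warning.
#'
#' @param rss_total Total residual sum of squares (>= 0).
#' @param n_obs Effective number of observations `N` (ribs x retained PCs).
#' @param n_params Parameter count `p`.
#' @return The AICc value (possibly `-Inf`).
#' @export
aicc <- function(rss_total, n_obs, n_params) {
  if (n_obs - n_params - 1 <= 0) {
    stop("undefined AICc penalty: N - p - 1 <= 0 (N = ", n_obs, ", p = ", n_params, ")")
  }
  if (rss_total <= 0) {
    warning("RSS = 0: model saturates; AICc set to -Inf")
    return(-Inf)
  }
  n_obs * log(rss_total / n_obs) + 2 * n_params +
    2 * n_params * (n_params + 1) / (n_obs - n_params - 1)
}

#' Akaike weights (model probabilities)
#'
#' `w_m = exp(-delta_m / 2) / sum(exp(-delta / 2))` with
#' `delta_m = AICc_m - min(AICc)`. If any model saturates (`-Inf` AICc),
#' all weight is assigned to the first saturated model in the list —
#' with models ordered by region count this is the most parsimonious
#' exactly-fitting model.
#'
#' @param aicc_values Numeric vector of AICc values (at least one finite
#'   or `-Inf`).
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  if (!length(aicc_values) || all(is.infinite(aicc_values) & aicc_values > 0)) {
    stop("no model with usable AICc")
  }
  if (any(aicc_values == -Inf)) {
    w <- numeric(length(aicc_values))
    w[which(aicc_values == -Inf)[1L]] <- 1
    return(w)
  }
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  w / sum(w)
}

# M-best segmentation by dynamic programming: for each region count k,
# the M lowest-RSS partitions of positions 1..n into k contiguous segments
# of length >= min_seg. Returns per k a list of (rss, ends) where `ends`
# are the last positions of segments 1..k-1 (the breakpoints).
mbest_segmentations <- function(cost, max_regions, min_seg, m_best = 8L) {
  n <- nrow(cost)
  # dp[[k]][[j]]: list of up to m_best candidates (total, ends) for prefix 1..j
  dp <- vector("list", max_regions)
  for (k in seq_len(max_regions)) dp[[k]] <- vector("list", n)
  for (j in seq_len(n)) {
    if (!is.na(cost[1L, j])) {
      dp[[1L]][[j]] <- list(list(total = cost[1L, j], ends = integer(0)))
    }
  }
  if (max_regions >= 2L) {
    for (k in 2L:max_regions) {
      for (j in seq_len(n)) {
        if (j < k * min_seg) next
        cands <- list()
        for (i in (min_seg * (k - 1L) + 1L):(j - min_seg + 1L)) {
          if (is.na(cost[i, j])) next
          prev <- dp[[k - 1L]][[i - 1L]]
          if (is.null(prev)) next
          for (pmod in prev) {
            cands[[length(cands) + 1L]] <- list(
              total = pmod$total + cost[i, j],
              ends = c(pmod$ends, i - 1L))
          }
        }
        if (length(cands)) {
          ord <- order(vapply(cands, `[[`, numeric(1), "total"))
          dp[[k]][[j]] <- cands[ord[seq_len(min(m_best, length(ord)))]]
        }
      }
    }
  }
  lapply(seq_len(max_regions), function(k) dp[[k]][[n]])
}

#' Segmented linear regression analysis of a shape space
#'
#' The core region-detection machinery: for each candidate region count
#' `k = 1..max_regions`, an exact search (dynamic programming over
#' precomputed per-span costs) finds the breakpoint placement minimizing
#' the total residual sum of squares of independent per-segment, per-PC
#' linear fits of score against axial position. The best model per `k` is
#' scored by AICc (`N` = ribs x retained PCs stacked observations,
#' `p = 2 k npc + 1`: slope and intercept per segment per PC plus one
#' pooled variance), Akaike weights are computed across the per-`k` best
#' models, and the region score is the weight-averaged region count.
#' Ties in AICc break toward smaller `k` (parsimony).
#'
#' @param space A `shape_space` from [shape_pca()] (or a score matrix).
#' @param positions Axial regressor values, one per rib; defaults to the
#'   sampled rib ordinals `1..n` (affinely equivalent to percentages on a
#'   uniform grid, and keeps breakpoints integral).
#' @param max_regions Largest region count considered (default 6).
#' @param min_seg Minimum ribs per segment (default 3).
#' @param series Optional [rib_series] the scores came from; enables
#'   boundary positions as percentages of the total rib count.
#' @param m_best Models retained per `k` for the ranked list used by the
#'   stability rule (default 8).
#' @return Object of class `regionalization`: `best_per_k` (one
#'   `segmented_model` per k), `best_overall`, `weights`, `region_score`,
#'   `ranked` (cross-k model table sorted by AICc), `boundary_percent`,
#'   `accepted` (stability flag; `NA` if indeterminate), plus bookkeeping.
#' @export
slra <- function(space, positions = NULL, max_regions = 6L, min_seg = 3L,
                 series = NULL, m_best = 8L) {
  scores <- if (inherits(space, "shape_space")) space$scores else as.matrix(space)
  n <- nrow(scores)
  npc <- ncol(scores)
  if (is.null(positions)) positions <- seq_len(n)
  if (length(positions) != n) stop("positions length must match score rows")
  if (n < min_seg) stop("need at least min_seg = ", min_seg, " positions")
  max_k <- min(max_regions, n %/% min_seg)
  if (max_k < 1L) stop("insufficient positions for any segmentation")

  cost <- segment_cost_matrix(positions, scores, min_seg)
  cand <- mbest_segmentations(cost, max_k, min_seg, m_best)

  n_obs <- n * npc
  # an RSS this far below the data scale is an exact fit up to floating
  # point; treat it as saturated so parsimony picks the smallest such k
  rss_floor <- 1e-9 * max(sum(scores^2), .Machine$double.eps)
  best_per_k <- vector("list", max_k)
  ranked_rows <- list()
  for (k in seq_len(max_k)) {
    if (is.null(cand[[k]])) next
    p <- 2L * k * npc + 1L
    if (n_obs - p - 1L <= 0L) { cand[k] <- list(NULL); next }
    for (r in seq_along(cand[[k]])) {
      mod <- cand[[k]][[r]]
      a <- suppressWarnings(aicc(if (mod$total <= rss_floor) 0 else mod$total,
                                 n_obs, p))
      ranked_rows[[length(ranked_rows) + 1L]] <- list(
        k = k, rank_within_k = r, rss = mod$total, aicc = a, ends = mod$ends)
      if (r == 1L) {
        best_per_k[[k]] <- new_segmented_model(k, mod$ends, mod$total, a,
                                               positions, scores)
      }
    }
  }
  keep <- !vapply(best_per_k, is.null, logical(1))
  best_per_k <- best_per_k[keep]
  if (!length(best_per_k)) stop("no admissible segmented model could be fit")
  ks <- vapply(best_per_k, `[[`, integer(1), "k")
  aiccs <- vapply(best_per_k, `[[`, numeric(1), "aicc")
  w <- akaike_weights(aiccs)
  for (i in seq_along(best_per_k)) best_per_k[[i]]$weight <- w[i]
  # argmin AICc, ties toward smaller k (best_per_k is ordered by k)
  best_i <- which(aiccs == min(aiccs))[1L]
  best_overall <- best_per_k[[best_i]]
  score <- sum(w * ks)

  ranked <- data.frame(
    k = vapply(ranked_rows, `[[`, integer(1), "k"),
    rank_within_k = vapply(ranked_rows, `[[`, integer(1), "rank_within_k"),
    rss = vapply(ranked_rows, `[[`, numeric(1), "rss"),
    aicc = vapply(ranked_rows, `[[`, numeric(1), "aicc"))
  ranked$breakpoints <- lapply(ranked_rows, `[[`, "ends")
  ord <- order(ranked$aicc, ranked$k)
  ranked <- ranked[ord, , drop = FALSE]
  rownames(ranked) <- NULL

  res <- structure(list(
    best_per_k = best_per_k, best_overall = best_overall,
    weights = stats::setNames(w, paste0("k", ks)),
    region_score = score,
    ranked = ranked,
    positions = positions,
    n_pcs = npc,
    min_seg = min_seg, max_regions = max_regions,
    series = series,
    boundary_percent = if (!is.null(series)) {
      boundary_percent(best_overall, series)
    } else NULL,
    accepted = NA), class = "regionalization")
  res$accepted <- stability_check(res)$accepted
  res
}

new_segmented_model <- function(k, ends, rss, aicc_val, positions, scores) {
  bounds <- c(0L, ends, length(positions))
  coef <- vector("list", k)
  for (s in seq_len(k)) {
    i <- bounds[s] + 1L; j <- bounds[s + 1L]
    x <- positions[i:j]
    y <- scores[i:j, , drop = FALSE]
    xc <- x - mean(x)
    slope <- as.vector(crossprod(xc, sweep(y, 2L, colMeans(y)))) / sum(xc^2)
    coef[[s]] <- list(slope = slope,
                      intercept = colMeans(y) - slope * mean(x))
  }
  structure(list(k = as.integer(k), breakpoints = as.integer(ends),
                 coef = coef, rss = rss, aicc = aicc_val, weight = NA_real_),
            class = "segmented_model")
}

#' @export
print.segmented_model <- function(x, ...) {
  cat("Segmented model: k =", x$k,
      if (x$k > 1L) paste0("(breakpoints after sampled ribs ",
                           paste(x$breakpoints, collapse = ", "), ")") else "",
      "\n  RSS =", format(x$rss), " AICc =", format(x$aicc), "\n")
  invisible(x)
}

#' @export
print.regionalization <- function(x, ...) {
  cat("Regionalization:", length(x$positions), "sampled ribs,",
      x$n_pcs, "PCs\n")
  cat("  best model: k =", x$best_overall$k,
      " region score =", sprintf("%.3f", x$region_score),
      " accepted =", x$accepted, "\n")
  if (!is.null(x$boundary_percent) && length(x$boundary_percent)) {
    cat("  boundaries at", paste(sprintf("%.1f%%", x$boundary_percent),
                                 collapse = ", "), "of the rib count\n")
  }
  invisible(x)
}

#' Akaike-weighted region score
#'
#' The average number of regions across the per-`k` best models, weighted
#' by Akaike model probability — a continuous summary of regionalization.
#'
#' @param result A `regionalization` from [slra()].
#' @return Scalar in `[1, max_regions]`.
#' @export
region_score <- function(result) {
  stopifnot(inherits(result, "regionalization"))
  result$region_score
}

#' Region boundaries as percentages of the total rib count
#'
#' Maps each breakpoint (last sampled rib of a segment) back to its
#' original rib index in the full series and expresses it as
#' `100 * rib_index / n_ribs_total`.
#'
#' @param model A `segmented_model`.
#' @param series The [rib_series] the model was fitted on (possibly
#'   subsampled; its `rib_index` provides the back-mapping).
#' @return Numeric vector of length `k - 1` (empty for `k = 1`).
#' @export
boundary_percent <- function(model, series) {
  if (!length(model$breakpoints)) return(numeric(0))
  if (any(model$breakpoints > length(series$rib_index))) {
    stop("breakpoint outside the sampled series")
  }
  orig <- series$rib_index[model$breakpoints]
  100 * orig / series$n_ribs_total
}

#' Stability rule for accepting a best-fit model
#'
#' A best-fit model is accepted if the next five top-ranked models are
#' consistent with it in boundary position. Models with different region
#' counts are compared on the boundaries they share: the sorted boundary
#' lists are greedily matched one-to-one within `tol_positions` sampled
#' positions, and a runner-up is consistent if the number of matched
#' pairs equals the smaller boundary count (so a model that adds an extra
#' boundary while preserving the best model's boundaries is consistent,
#' while one that displaces a shared boundary is not). Ranking is across
#' all region counts by AICc by default; `ranking = "within_k"` instead
#' compares the next five models with the same region count as the best.
#'
#' @param result A `regionalization` from [slra()].
#' @param tol_positions Tolerance in sampled positions (default 1).
#' @param ranking `"cross_k"` (default) or `"within_k"`.
#' @return List with `accepted` (`TRUE`/`FALSE`, or `NA` when fewer than
#'   six ranked models exist) and `n_compared`.
#' @export
stability_check <- function(result, tol_positions = 1L, ranking = c("cross_k", "within_k")) {
  ranking <- match.arg(ranking)
  ranked <- result$ranked
  if (ranking == "within_k") {
    ranked <- ranked[ranked$k == result$best_overall$k, , drop = FALSE]
  }
  if (nrow(ranked) < 6L) return(list(accepted = NA, n_compared = nrow(ranked) - 1L))
  best_b <- sort(ranked$breakpoints[[1L]])
  ok <- TRUE
  for (r in 2:6) {
    b <- sort(ranked$breakpoints[[r]])
    if (!matched_within(b, best_b, tol_positions)) { ok <- FALSE; break }
  }
  list(accepted = ok, n_compared = 5L)
}

# greedy one-to-one matching of two sorted boundary lists; TRUE when the
# number of pairs within tol equals the smaller list length
matched_within <- function(a, b, tol) {
  need <- min(length(a), length(b))
  if (need == 0L) return(TRUE)
  i <- 1L; j <- 1L; matched <- 0L
  while (i <= length(a) && j <= length(b)) {
    if (abs(a[i] - b[j]) <= tol) {
      matched <- matched + 1L; i <- i + 1L; j <- j + 1L
    } else if (a[i] < b[j]) i <- i + 1L else j <- j + 1L
  }
  matched >= need
}
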