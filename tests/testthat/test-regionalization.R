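test_that("shape PCA matches a direct covariance eigendecomposition", {
  set.seed(10)
  mat <- matrix(rnorm(9 * 12), 9, 12)
  sp <- shape_pca(mat, n_retained = 4L)
  ev <- eigen(stats::cov(mat), symmetric = TRUE)$values
  expect_equal(sp$eigenvalues[seq_len(4L)], ev[seq_len(4L)], tolerance = 1e-10)
  # scores have zero column means and variances equal to the eigenvalues
  expect_lt(max(abs(colMeans(sp$scores))), 1e-10)
  expect_equal(apply(sp$scores, 2L, stats::var), ev[1:4], tolerance = 1e-10,
               ignore_attr = TRUE)
  # total variance is conserved
  expect_equal(sum(sp$eigenvalues), sum(diag(stats::cov(mat))), tolerance = 1e-10)
})

test_that("rank bounds the retained components", {
  set.seed(11)
  base <- matrix(rnorm(30), 1, 30)
  mat <- rbind(base, base + rnorm(30, sd = 0.1), base + rnorm(30, sd = 0.1))
  sp <- shape_pca(mat, n_retained = 6L)
  expect_lte(sp$n_retained, 2L)
  expect_error(shape_pca(mat[c(1, 1, 1), ]), "degenerate")
})

test_that("segment RSS matches hand and normal-equation solutions", {
  expect_equal(segment_rss(c(1, 2, 3), cbind(c(0, 1, 0)), 1, 3), 2 / 3)
  # perfectly linear scores fit exactly
  x <- 1:10
  y <- cbind(2 * x - 3, -0.5 * x + 1)
  expect_lt(segment_rss(x, y, 1, 10), 1e-12)
  # random span against lm()
  set.seed(12)
  x <- sort(runif(15))
  y <- matrix(rnorm(15 * 3), 15, 3)
  got <- segment_rss(x, y, 4, 12)
  want <- sum(vapply(1:3, function(j) {
    sum(stats::resid(stats::lm(y[4:12, j] ~ x[4:12]))^2)
  }, numeric(1)))
  expect_equal(got, want, tolerance = 1e-10)
  expect_error(segment_rss(x, y, 4, 5), "min_seg")
})

test_that("AICc follows the corrected formula and its limits", {
  expect_equal(aicc(156, 156, 13), 26 + 2 * 13 * 14 / 142)
  expect_equal(aicc(156, 156, 13), 28.5634, tolerance = 1e-4)
  expect_lt(aicc(10, 100, 5), aicc(20, 100, 5))
  expect_warning(a0 <- aicc(0, 100, 5), "saturates")
  expect_identical(a0, -Inf)
  expect_error(aicc(10, 10, 9), "N - p - 1")
  # penalty blows up as p approaches N - 1
  expect_gt(aicc(10, 20, 18), aicc(10, 20, 5))
})

test_that("Akaike weights normalize and match the logistic closed form", {
  expect_equal(akaike_weights(5), 1)
  expect_equal(akaike_weights(c(3, 3)), c(0.5, 0.5))
  w <- akaike_weights(c(10, 12))
  expect_equal(w, c(0.7311, 0.2689), tolerance = 1e-4)
  expect_equal(sum(akaike_weights(c(1, 5, 9, 2))), 1)
  expect_equal(akaike_weights(c(-Inf, 10)), c(1, 0))
})

test_that("a noiseless step series is segmented exactly at the step", {
  scores <- cbind(c(rep(0, 13), rep(1, 13)))
  res <- slra(scores)
  expect_equal(res$best_overall$k, 2L)
  expect_equal(res$best_overall$breakpoints, 13L)
  expect_lt(res$best_overall$rss, 1e-20)
  expect_gt(res$weights[["k2"]], 0.99)
  expect_equal(region_score(res), 2, tolerance = 0.01)
})

test_that("a noiseless global linear trend selects a single region", {
  scores <- cbind(seq(0, 1, length.out = 26), seq(3, -1, length.out = 26))
  res <- slra(scores)
  expect_equal(res$best_overall$k, 1L)
  expect_length(res$best_overall$breakpoints, 0L)
})

test_that("best RSS is nonincreasing in the region count", {
  set.seed(13)
  for (rep_i in 1:5) {
    scores <- matrix(rnorm(20 * 3), 20, 3)
    res <- slra(scores, max_regions = 5L)
    rss <- vapply(res$best_per_k, `[[`, numeric(1), "rss")
    expect_true(all(diff(rss) <= 1e-10))
  }
})

test_that("the dynamic program equals brute-force enumeration on small series", {
  set.seed(14)
  for (rep_i in 1:6) {
    n <- sample(9:15, 1L)
    scores <- matrix(rnorm(n * 2), n, 2)
    res <- slra(scores, max_regions = 4L)
    for (mod in res$best_per_k) {
      bf <- brute_force_best(seq_len(n), scores, mod$k)
      expect_equal(mod$rss, bf$rss, tolerance = 1e-9)
    }
  }
})

test_that("region score is the weight-averaged region count", {
  set.seed(15)
  scores <- matrix(rnorm(26 * 4), 26, 4)
  res <- slra(scores)
  ks <- vapply(res$best_per_k, `[[`, integer(1), "k")
  expect_equal(region_score(res), sum(res$weights * ks))
  expect_gte(region_score(res), 1)
  expect_lte(region_score(res), 6)
  # hand check of the weighted average with two models
  expect_equal(sum(c(0.7311, 0.2689) * c(3, 4)), 3.2689)
})

test_that("boundary positions map back to percentages of the rib count", {
  s <- smooth_series(n = 20L)
  mod <- list(breakpoints = 15L, k = 2L)
  class(mod) <- "segmented_model"
  s$n_ribs_total <- 100L
  s$rib_index <- seq_len(20L)
  expect_equal(boundary_percent(mod, s), 15.0)
  mod1 <- list(breakpoints = integer(0), k = 1L)
  class(mod1) <- "segmented_model"
  expect_length(boundary_percent(mod1, s), 0L)
  # subsampled back-mapping: sampled rib 13 of a 101-rib series is rib 49
  set.seed(16)
  g <- generate_rib_series(synthetic_rib_spec(n_ribs = 101L))
  sub <- subsample_axis(g$series)
  mod2 <- list(breakpoints = 13L, k = 2L)
  class(mod2) <- "segmented_model"
  expect_equal(boundary_percent(mod2, sub), 100 * 49 / 101, tolerance = 1e-10)
  mod3 <- list(breakpoints = 40L, k = 2L)
  class(mod3) <- "segmented_model"
  expect_error(boundary_percent(mod3, sub), "outside")
})

test_that("the stability rule accepts consistent and rejects displaced runner-ups", {
  mk <- function(brks, aiccs) {
    ranked <- data.frame(k = lengths(brks) + 1L,
                         rank_within_k = 1L,
                         rss = seq_along(brks),
                         aicc = aiccs)
    ranked$breakpoints <- brks
    structure(list(ranked = ranked,
                   best_overall = list(k = ranked$k[1L])),
              class = "regionalization")
  }
  consistent <- mk(c(list(c(5L, 12L)), replicate(5, c(5L, 12L), simplify = FALSE)),
                   1:6)
  expect_true(stability_check(consistent)$accepted)
  displaced <- mk(list(c(5L, 12L), c(10L, 12L), c(5L, 12L), c(5L, 12L),
                       c(5L, 12L), c(5L, 12L)), 1:6)
  expect_false(stability_check(displaced)$accepted)
  within_tol <- mk(list(c(5L, 12L), c(6L, 12L), c(5L, 11L), c(5L, 13L),
                        c(4L, 12L), c(5L, 12L)), 1:6)
  expect_true(stability_check(within_tol)$accepted)
  few <- mk(list(c(5L), c(5L)), 1:2)
  expect_true(is.na(stability_check(few)$accepted))
})

test_that("noise level separates accepted from rejected stability flags", {
  n_seeds <- 30L
  acc_low <- acc_high <- logical(n_seeds)
  mk <- function(seed, noise) {
    synthetic_rib_spec(n_ribs = 101L, true_boundaries = c(25L, 50L, 75L),
                       allometric_boundaries = integer(0), shift = 0.06,
                       slope = 0.01, size_gradient = 0.3,
                       allometry_strength = 0, noise_sd = noise, seed = seed)
  }
  for (s in seq_len(n_seeds)) {
    res_l <- slra(shape_pca(gpa(subsample_axis(
      generate_rib_series(mk(s, 0.002))$series))))
    res_h <- slra(shape_pca(gpa(subsample_axis(
      generate_rib_series(mk(s, 0.01))$series))))
    acc_low[s] <- isTRUE(res_l$accepted)
    acc_high[s] <- isTRUE(res_h$accepted)
  }
  expect_gt(mean(acc_low), 0.5)
  expect_lt(mean(acc_high), 0.5)
})
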