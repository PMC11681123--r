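# aligned shapes with an exact linear size-shape relationship, assembled
# directly as a gpa_fit so the regression machinery is tested in isolation
pure_allometry_fit <- function(n = 12L, p = 8L, seed = 1L, beta = 0.3) {
  set.seed(seed)
  template <- ribregions:::center_scale(matrix(rnorm(3 * p), p, 3))
  dir <- matrix(rnorm(3 * p), p, 3)
  dir <- dir / sqrt(sum(dir^2))
  log_cs <- seq(1, 2, length.out = n)
  coords <- array(NA_real_, c(p, 3, n))
  for (i in seq_len(n)) {
    coords[, , i] <- template + beta * (log_cs[i] - mean(log_cs)) * dir
  }
  structure(list(coords = coords, consensus = template,
                 csize = exp(log_cs), log_cs = log_cs,
                 converged = TRUE, iterations = 0L, series = NULL),
            class = "gpa_fit")
}

test_that("an exact size-shape construction is fully explained by size", {
  fit <- pure_allometry_fit(seed = 21)
  allom <- fit_allometry(fit, n_perm = 99, seed = 1)
  expect_equal(allom$r_squared, 1, tolerance = 1e-10)
  # residual shapes are constant up to numerical error
  res <- flatten_shapes(allom$residual_shapes)
  expect_lt(max(apply(res, 2, stats::sd)), 1e-10)
  expect_equal(allom$perm_p, 1 / 100)
})

test_that("size-independent shapes show near-zero allometric signal", {
  set.seed(22)
  p <- 8L
  template <- matrix(rnorm(3 * p), p, 3)
  cfgs <- lapply(1:14, function(i) {
    landmark_config((template + matrix(rnorm(3 * p, sd = 0.05), p, 3)) *
                      exp(seq(1, 2, length.out = 14)[i]), rib_index = i)
  })
  fit <- gpa(cfgs)
  allom <- fit_allometry(fit, n_perm = 199, seed = 3)
  expect_lt(allom$r_squared, 0.35)
  expect_gte(allom$perm_p, 1 / 200)
  expect_lte(allom$perm_p, 1)
})

test_that("the variance decomposition is exact and residuals are orthogonal to the fit", {
  set.seed(23)
  fit <- gpa(random_config_list(10L, p = 6L))
  allom <- fit_allometry(fit, n_perm = 49, seed = 2)
  expect_equal(allom$ss_model + (allom$ss_total - allom$ss_model),
               allom$ss_total, tolerance = 1e-12)
  y <- flatten_shapes(fit)
  yc <- sweep(y, 2, colMeans(y))
  xc <- fit$log_cs - mean(fit$log_cs)
  fitted_c <- outer(xc, allom$slope)
  resid <- yc - fitted_c
  expect_lt(abs(sum(fitted_c * resid)) / sum(fitted_c^2), 1e-8)
  expect_equal(sum(fitted_c^2) + sum(resid^2), sum(yc^2), tolerance = 1e-8)
  expect_gte(allom$r_squared, 0)
  expect_lte(allom$r_squared, 1)
})

test_that("jointly permuting rib order leaves the fitted slope unchanged", {
  set.seed(24)
  cfgs <- random_config_list(9L, p = 6L)
  fit <- gpa(cfgs)
  allom <- fit_allometry(fit, n_perm = 9, seed = 1)
  perm <- sample(9L)
  fit_p <- fit
  fit_p$coords <- fit$coords[, , perm]
  fit_p$csize <- fit$csize[perm]
  fit_p$log_cs <- fit$log_cs[perm]
  allom_p <- fit_allometry(fit_p, n_perm = 9, seed = 1)
  expect_equal(allom_p$slope, allom$slope, tolerance = 1e-10)
  expect_equal(allom_p$r_squared, allom$r_squared, tolerance = 1e-10)
})

test_that("residual regionalization removes purely allometric boundaries", {
  # all boundaries size-coupled: the residual series should be one region
  g <- generate_rib_series(synthetic_rib_spec(seed = 31))
  sub <- subsample_axis(g$series)
  fit <- gpa(sub)
  allom <- fit_allometry(fit, n_perm = 1, seed = 1)
  res <- nonallometric_regionalization(allom, series = sub)
  expect_equal(res$best_overall$k, 1L)
})

test_that("size-independent boundaries survive the residual analysis", {
  # no size coupling at all: residual regions equal the full regions
  g <- generate_rib_series(synthetic_rib_spec(
    n_ribs = 36L, true_boundaries = c(9L, 18L, 27L),
    allometric_boundaries = integer(0), shift = 0.1, slope = 0.03,
    size_gradient = 0.3, allometry_strength = 0, seed = 32),
    body_type = "limbed")
  fit <- gpa(g$series)
  full <- slra(shape_pca(fit), series = g$series)
  allom <- fit_allometry(fit, n_perm = 1, seed = 1)
  res <- nonallometric_regionalization(allom, series = g$series)
  expect_equal(full$best_overall$k, 4L)
  expect_equal(res$best_overall$k, 4L)
  expect_true(all(abs(res$best_overall$breakpoints -
                        full$best_overall$breakpoints) <= 1L))
})

test_that("allometric boundary counting is a signed difference with a warning flag", {
  mk <- function(k, score) {
    structure(list(best_overall = list(k = k), region_score = score),
              class = "regionalization")
  }
  d <- allometric_boundary_count(mk(4L, 3.9), mk(1L, 1.1))
  expect_equal(d$allometric_boundaries, 3L)
  expect_equal(d$region_score_drop, 2.8)
  expect_false(d$negative_flag)
  same <- allometric_boundary_count(mk(3L, 3), mk(3L, 3))
  expect_equal(same$allometric_boundaries, 0L)
  expect_equal(same$region_score_drop, 0)
  expect_warning(neg <- allometric_boundary_count(mk(3L, 3), mk(4L, 4)),
                 "more regions")
  expect_equal(neg$allometric_boundaries, -1L)
  expect_true(neg$negative_flag)
})
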