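test_that("heterogeneity is zero for identical ribs and equals the pair distance for two", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.4, 0.4, 0.5))
  fit <- gpa(lapply(1:3, function(i) landmark_config(tri, rib_index = i)))
  h <- axial_heterogeneity(fit)
  expect_equal(h$H, 0, tolerance = 1e-10)
  expect_equal(h$H_consensus_range, 0, tolerance = 1e-10)

  set.seed(41)
  two <- gpa(random_config_list(2L, p = 6L))
  h2 <- axial_heterogeneity(two)
  expect_equal(h2$H,
               procrustes_distance(two$coords[, , 1L], two$coords[, , 2L]))
  expect_true(isSymmetric(h2$pairwise_d))
  expect_equal(diag(h2$pairwise_d), c(0, 0))
})

test_that("heterogeneity is invariant to rib order and duplication", {
  set.seed(42)
  cfgs <- random_config_list(5L, p = 7L)
  H0 <- axial_heterogeneity(gpa(cfgs))$H
  H_perm <- axial_heterogeneity(gpa(cfgs[c(3, 1, 5, 2, 4)]))$H
  expect_equal(H_perm, H0, tolerance = 1e-6)
  dup <- c(cfgs, cfgs[3L])
  dup[[6L]]$rib_index <- 6L
  H_dup <- axial_heterogeneity(gpa(dup))$H
  expect_equal(H_dup, H0, tolerance = 1e-4)
})

test_that("extreme-vs-mid distances find the right ribs and respect symmetry", {
  # mirror-symmetric series about the midpoint
  set.seed(43)
  p <- 8L
  base <- matrix(rnorm(3 * p), p, 3)
  dir <- matrix(rnorm(3 * p), p, 3); dir <- dir / sqrt(sum(dir^2))
  n <- 25L
  cfgs <- lapply(seq_len(n), function(i) {
    amp <- abs(i - 13L) / 12
    landmark_config(base + amp * dir, rib_index = i)
  })
  s <- rib_series(cfgs, n_ribs_total = n, body_type = "limbed")
  fit <- gpa(s)
  em <- extreme_vs_mid(fit, s)
  expect_equal(em$mid_index, 13L)
  expect_equal(em$d_ant_mid, em$d_post_mid, tolerance = 1e-6)

  # anterior rib equal to the mid rib gives a zero anterior distance
  cfgs2 <- cfgs
  cfgs2[[2L]] <- landmark_config(cfgs[[13L]]$points, rib_index = 2L)
  s2 <- rib_series(cfgs2, n_ribs_total = n, body_type = "limbed")
  fit2 <- gpa(s2)
  em2 <- extreme_vs_mid(fit2, s2)
  expect_equal(em2$ant_index, 2L)  # 4% of a 25-rib axis
  expect_lt(em2$d_ant_mid, 1e-8)
})

test_that("interspecies disparity matches the hand value for equidistant shapes", {
  tri <- ribregions:::center_scale(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                         c(1, 1, 1)))
  same <- interspecies_disparity(lapply(1:3, function(i) {
    landmark_config(tri, rib_index = i)
  }))
  expect_equal(same$variance, 0, tolerance = 1e-12)

  # two nearby shapes sit at half their pairwise distance from the
  # consensus, so the variance is (d/2)^2 (exact in the small-shape-
  # difference limit where sphere curvature is negligible)
  set.seed(44)
  base <- matrix(rnorm(24), 8, 3)
  dir <- matrix(rnorm(24), 8, 3) * 0.005
  fit <- gpa(list(landmark_config(base + dir, rib_index = 1L),
                  landmark_config(base - dir, rib_index = 2L)))
  d <- procrustes_distance(fit$coords[, , 1L], fit$coords[, , 2L])
  v <- mean(vapply(1:2, function(i) {
    procrustes_distance(fit$consensus, fit$coords[, , i])^2
  }, numeric(1)))
  expect_equal(v, (d / 2)^2, tolerance = 1e-4)

  # and the exported disparity equals the mean squared distance to the
  # interval consensus for a larger random sample
  set.seed(45)
  cfgs <- random_config_list(4L, p = 7L)
  disp <- interspecies_disparity(cfgs)
  direct <- mean(vapply(1:4, function(i) {
    procrustes_distance(disp$fit$consensus, disp$fit$coords[, , i])^2
  }, numeric(1)))
  expect_equal(disp$variance, direct, tolerance = 1e-12)
  expect_error(interspecies_disparity(cfgs[1:2]), "3 species")
})

test_that("Procrustes ANOVA separates shifted groups and is seed-deterministic", {
  set.seed(45)
  p <- 6L
  base <- matrix(rnorm(3 * p), p, 3)
  shiftdir <- matrix(rnorm(3 * p), p, 3) * 0.2
  cfgs <- c(
    lapply(1:5, function(i) landmark_config(base + matrix(rnorm(3 * p, sd = 0.01), p, 3), rib_index = i)),
    lapply(6:10, function(i) landmark_config(base + shiftdir + matrix(rnorm(3 * p, sd = 0.01), p, 3), rib_index = i))
  )
  fit <- gpa(cfgs)
  groups <- rep(c("a", "b"), each = 5L)
  res <- procrustes_anova_groups(fit, groups, n_perm = 99, seed = 9)
  expect_equal(res$p, 1 / 100)
  expect_gt(res$F, 10)
  res2 <- procrustes_anova_groups(fit, groups, n_perm = 99, seed = 9)
  expect_identical(res2$p, res$p)
  expect_error(procrustes_anova_groups(fit, rep("a", 10L)), "two non-empty")
})

test_that("Welch contrasts match the hand formula and are antisymmetric", {
  ct <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(ct$t, -3.6742, tolerance = 1e-4)
  expect_equal(ct$df, 4, tolerance = 1e-10)
  expect_equal(ct$p, 0.0213, tolerance = 1e-3)
  rev <- welch_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rev$t, -ct$t)
  expect_equal(rev$p, ct$p)

  set.seed(46)
  a <- rnorm(8); b <- rnorm(11)
  w <- welch_t(a, b)
  expect_gte(w$df, min(8, 11) - 1)
  expect_lte(w$df, 8 + 11 - 2)
  same <- welch_t(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welch_t(c(1, 1), c(1, 1)), "undefined")
})
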