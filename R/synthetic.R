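#' Specification for a synthetic rib series
#'
#' Parameters of the generative model used by [generate_rib_series()]: a
#' smooth rib-like template curve whose shape varies along the axis as a
#' piecewise-linear trajectory in landmark space. Region boundaries come in
#' two kinds. Size-coupled (allometric) boundaries are growth-regime
#' changes: the log centroid size profile is a continuous piecewise-linear
#' hump (ribs lengthen toward the mid-axis and shorten again) whose slope
#' changes, and optionally jumps by `size_step`, exactly at the allometric
#' boundaries; shape tracks size through a single global allometric
#' direction with sensitivity `allometry_strength`. Size-independent
#' boundaries are mean shape shifts of magnitude `shift` in their own
#' random directions. Isotropic Gaussian landmark noise is added last.
#'
#' Allometric boundaries are exactly size-predicted by construction: their
#' entire shape signal is linear in log centroid size, so regressing shape
#' on size removes them while size-independent shifts survive as
#' non-allometric boundaries.
#'
#' @param n_ribs Total free dorsal ribs (default 101, an elongate series).
#' @param n_fixed,n_semi Fixed and semilandmark counts (defaults 12 and 18).
#' @param true_boundaries Strictly increasing rib indices (last rib of each
#'   region but the final one); default `c(7, 50, 89)` of 101, echoing the
#'   anterior-near-cranium / middle / posterior boundary geography of
#'   elongate squamates.
#' @param allometric_boundaries Subset of `true_boundaries` whose shift is
#'   size-coupled (default all of them, the snake-like condition).
#' @param shift Mean shape shift at each size-independent boundary,
#'   Procrustes units (default 0.04).
#' @param slope Within-segment linear shape drift per unit axis
#'   (default 0.01).
#' @param size_gradient Scale of the piecewise-linear log centroid size
#'   hump (default 0.8, about a two-fold size range; with no allometric
#'   boundaries, a plain linear gradient of this slope).
#' @param size_step Log centroid size jump at each allometric boundary
#'   (default 0.4).
#' @param allometry_strength Allometric sensitivity of shape: displacement
#'   along the allometric direction per unit log centroid size
#'   (default 0.1, so a default size jump carries a shape step of 0.04).
#' @param noise_sd Per-coordinate Gaussian landmark noise, in units of the
#'   unit-size template (default 0.002).
#' @param base_cs Centroid size of the mid-axis rib in scan units
#'   (default 10 mm).
#' @param template_torsion Torsion of the template curve; differs between
#'   body-type templates (default 0.15).
#' @param seed Integer seed; generation is bit-reproducible given the spec.
#' @return Object of class `synthetic_rib_spec`.
#' @export
synthetic_rib_spec <- function(n_ribs = 101L, n_fixed = 12L, n_semi = 18L,
                               true_boundaries = c(7L, 50L, 89L),
                               allometric_boundaries = true_boundaries,
                               shift = 0.04, slope = 0.01,
                               size_gradient = 0.8, size_step = 0.4,
                               allometry_strength = 0.1,
                               noise_sd = 0.002, base_cs = 10,
                               template_torsion = 0.15, seed = 1L) {
  true_boundaries <- as.integer(true_boundaries)
  allometric_boundaries <- as.integer(allometric_boundaries)
  if (length(true_boundaries)) {
    if (any(diff(true_boundaries) <= 0L)) stop("true_boundaries must be strictly increasing")
    if (min(true_boundaries) <= 1L || max(true_boundaries) >= n_ribs) {
      stop("true_boundaries must lie strictly inside (1, n_ribs)")
    }
  }
  if (!all(allometric_boundaries %in% true_boundaries)) {
    stop("allometric_boundaries must be a subset of true_boundaries")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_ribs = as.integer(n_ribs), n_fixed = as.integer(n_fixed),
                 n_semi = as.integer(n_semi),
                 true_k = length(true_boundaries) + 1L,
                 true_boundaries = true_boundaries,
                 allometric_boundaries = allometric_boundaries,
                 shift = shift, slope = slope,
                 size_gradient = size_gradient, size_step = size_step,
                 allometry_strength = allometry_strength,
                 noise_sd = noise_sd, base_cs = base_cs,
                 template_torsion = template_torsion, seed = as.integer(seed)),
            class = "synthetic_rib_spec")
}

# Rib-like template: half-ellipse with torsion, centered, unit centroid size.
rib_template <- function(n_points, torsion = 0.15) {
  t <- seq(0, pi, length.out = n_points)
  m <- cbind(cos(t), 0.6 * sin(t), torsion * sin(2 * t))
  center_scale(m)
}

random_unit_direction <- function(p) {
  v <- matrix(stats::rnorm(3L * p), p, 3L)
  v / sqrt(sum(v^2))
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

#' Generate a synthetic rib series with known ground truth
#'
#' Draws one specimen under a [synthetic_rib_spec()]: rib `j` has landmarks
#' `template + allometry_strength * (logCS_j - mean logCS) * allometric_dir
#'  + sum of size-independent boundary shifts + segment drift + noise`,
#' then is scaled to its centroid size, randomly rotated and translated
#' (so superimposition has real work to do). `logCS` is a continuous
#' piecewise-linear hump whose slope changes (and, if `size_step > 0`,
#' jumps) at the allometric boundaries only.
#'
#' @param spec A `synthetic_rib_spec`.
#' @param body_type Passed to the resulting series; defaults by the
#'   >50-ribs rule.
#' @param species Species name.
#' @return List: `series` (a [rib_series] of all `n_ribs` ribs) and
#'   `truth` (true region count, boundaries, allometric boundaries,
#'   per-rib log sizes, directions, and the spec).
#' @export
generate_rib_series <- function(spec, body_type = NULL, species = "synthetic_sp") {
  stopifnot(inherits(spec, "synthetic_rib_spec"))
  set.seed(spec$seed)
  n <- spec$n_ribs
  p <- spec$n_fixed + spec$n_semi
  k <- spec$true_k
  template <- rib_template(p, spec$template_torsion)

  alloc_dir <- random_unit_direction(p)
  step_dirs <- lapply(seq_len(max(k - 1L, 1L)), function(i) random_unit_direction(p))
  drift_dirs <- lapply(seq_len(k), function(i) random_unit_direction(p))

  u <- (seq_len(n) - 1) / (n - 1)
  is_allo <- spec$true_boundaries %in% spec$allometric_boundaries
  # size profile: a piecewise-linear hump over the partition defined by the
  # allometric boundaries only -- ribs lengthen toward the mid-axis and
  # shorten again, the growth rate changing (and size jumping by size_step)
  # exactly at the size-coupled boundaries
  ab <- spec$allometric_boundaries
  ka <- length(ab) + 1L
  seg_of_allo <- findInterval(seq_len(n), ab + 0.5) + 1L
  allo_u0 <- c(0, ab / (n - 1))
  size_slope <- if (ka == 1L) spec$size_gradient else {
    3 * spec$size_gradient * (ka + 1 - 2 * seq_len(ka)) / ka
  }
  log_cs <- numeric(n)
  acc_s <- 0
  for (j in seq_len(n)) {
    s <- seg_of_allo[j]
    if (j > 1L && s != seg_of_allo[j - 1L]) {
      acc_s <- acc_s + size_slope[s - 1L] * (allo_u0[s] - allo_u0[s - 1L]) +
        spec$size_step
    }
    log_cs[j] <- acc_s + size_slope[s] * (u[j] - allo_u0[s])
  }
  log_cs <- log(spec$base_cs) + log_cs - mean(log_cs)
  alloc_coef <- spec$allometry_strength

  # continuous piecewise-linear size-independent drift; its direction
  # changes only at non-allometric boundaries (a size-independent trend
  # change is itself a non-allometric boundary feature) and the path does
  # not jump (jumps are carried by the boundary shifts)
  nab <- setdiff(spec$true_boundaries, spec$allometric_boundaries)
  seg_of <- findInterval(seq_len(n), nab + 0.5) + 1L
  seg_start_u <- c(0, nab / (n - 1))
  drift <- vector("list", n)
  acc <- matrix(0, p, 3L)
  for (j in seq_len(n)) {
    s <- seg_of[j]
    if (j > 1L && s != seg_of[j - 1L]) {
      acc <- acc + spec$slope * (seg_start_u[s] - seg_start_u[s - 1L]) * drift_dirs[[s - 1L]]
    }
    drift[[j]] <- acc + spec$slope * (u[j] - seg_start_u[s]) * drift_dirs[[s]]
  }

  # assemble the size-independent displacement field (boundary shifts +
  # drift) and make it size-independent in the exact sample sense: project
  # out its component along centered log size, so a size regression leaves
  # it fully intact and removes only the allometric component
  z <- log_cs - mean(log_cs)
  indep <- matrix(0, n, 3L * p)
  for (j in seq_len(n)) {
    d <- drift[[j]]
    if (k > 1L) {
      for (m in seq_len(k - 1L)) {
        if (!is_allo[m] && j > spec$true_boundaries[m]) {
          d <- d + spec$shift * step_dirs[[m]]
        }
      }
    }
    indep[j, ] <- as.vector(d)
  }
  if (sum(z^2) > 0) {
    indep <- indep - outer(z, as.vector(crossprod(z, indep)) / sum(z^2))
  }

  configs <- vector("list", n)
  for (j in seq_len(n)) {
    shape <- template + alloc_coef * z[j] * alloc_dir +
      matrix(indep[j, ], p, 3L)
    if (spec$noise_sd > 0) {
      shape <- shape + matrix(stats::rnorm(3L * p, sd = spec$noise_sd), p, 3L)
    }
    shape <- center_scale(shape) * exp(log_cs[j])
    shape <- shape %*% random_rotation()
    shape <- sweep(shape, 2L, stats::runif(3L, -50, 50), `+`)
    configs[[j]] <- landmark_config(shape, n_fixed = spec$n_fixed,
                                    n_semi = spec$n_semi, rib_index = j,
                                    specimen_id = sprintf("%s_rib%03d", species, j))
  }
  if (is.null(body_type)) body_type <- if (n > 50L) "snake-like" else "limbed"
  series <- rib_series(configs, n_ribs_total = n, body_type = body_type,
                       species = species, specimen_id = species)
  list(series = series,
       truth = list(true_k = k, true_boundaries = spec$true_boundaries,
                    allometric_boundaries = spec$allometric_boundaries,
                    log_cs = log_cs, spec = spec))
}

#' Specification for a two-body-type synthetic cohort
#'
#' Defaults emulate the contrast structure of a limbed vs snake-like
#' squamate sample. Snake-like species have more than 50 ribs and all
#' boundaries size-coupled (growth-regime changes plus size jumps), with a
#' small allometric sensitivity, so their anterior and posterior shapes
#' deviate only mildly from the mid-axis template. Limbed species have 50
#' or fewer ribs, size-coupled anterior and posterior boundaries but a
#' size-independent mid-axis boundary, and all shape amplitudes scaled up
#' by `amplitude_ratio` -- giving them higher axial heterogeneity and
#' larger extreme-versus-mid shape distances. At `amplitude_ratio = 1` the
#' two groups have comparable shape amplitudes (the calibrated null for
#' the heterogeneity contrast).
#'
#' @param n_limbed,n_snakelike Species per body type (defaults 12 and 12).
#' @param base_shift Base boundary-shift unit, Procrustes units (default
#'   0.04): the snake-like allometric size jumps carry shape steps of this
#'   size, and the limbed size-independent shift is
#'   `base_shift * amplitude_ratio`.
#' @param amplitude_ratio Scale of all limbed shape amplitudes
#'   (allometric sensitivity, boundary shift, drift) relative to the
#'   snake-like base values (default 3).
#' @param noise_sd Landmark noise SD (default 0.002).
#' @param limbed_allometric Number of each limbed species' 3 boundaries
#'   that are size-coupled, assigned outermost first (default 2: anterior
#'   and posterior coupled, the mid-axis boundary size-independent).
#' @param seed Cohort seed; species `i` draws from `seed + i` so cohorts
#'   are stable under species addition.
#' @return Object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_limbed = 12L, n_snakelike = 12L,
                                  base_shift = 0.04, amplitude_ratio = 3,
                                  noise_sd = 0.002, limbed_allometric = 2L,
                                  seed = 1L) {
  structure(list(n_limbed = as.integer(n_limbed),
                 n_snakelike = as.integer(n_snakelike),
                 base_shift = base_shift, amplitude_ratio = amplitude_ratio,
                 noise_sd = noise_sd,
                 limbed_allometric = as.integer(limbed_allometric),
                 seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

#' Generate a synthetic cohort of rib series
#'
#' One [generate_rib_series()] draw per species. Limbed species have
#' 24-44 ribs with boundaries near 18%, 48% and 77% of the axis; by
#' default the anterior and posterior boundaries are size-coupled and the
#' mid-axis boundary is size-independent. Snake-like species have 61-141
#' ribs with boundaries near 7%, 50% and 88%, all size-coupled. Rib
#' counts vary deterministically across species within each group.
#'
#' @param cohort A `synthetic_cohort_spec`.
#' @return List of per-species records, each `list(series, truth)`, with
#'   species named `limbed_01`, ..., `snakelike_01`, ...
#' @export
generate_cohort <- function(cohort = synthetic_cohort_spec()) {
  stopifnot(inherits(cohort, "synthetic_cohort_spec"))
  out <- list()
  idx <- 0L
  r <- cohort$amplitude_ratio
  place <- function(n, frac) pmin(pmax(2L, as.integer(round(frac * n))), n - 1L)
  for (i in seq_len(cohort$n_limbed)) {
    idx <- idx + 1L
    n <- 24L + 4L * ((i - 1L) %% 6L)
    b <- place(n, c(0.18, 0.48, 0.77))
    m <- min(cohort$limbed_allometric, length(b))
    allo <- sort(b[c(1L, 3L, 2L)[seq_len(m)]])
    sp <- synthetic_rib_spec(
      n_ribs = n, true_boundaries = b, allometric_boundaries = allo,
      shift = cohort$base_shift * r,
      slope = 0.01 * r,
      size_gradient = 0.8, size_step = 0,
      allometry_strength = 0.1 * r,
      noise_sd = cohort$noise_sd, template_torsion = 0.25,
      seed = cohort$seed + idx)
    name <- sprintf("limbed_%02d", i)
    out[[name]] <- generate_rib_series(sp, body_type = "limbed", species = name)
  }
  for (i in seq_len(cohort$n_snakelike)) {
    idx <- idx + 1L
    n <- 61L + 16L * ((i - 1L) %% 6L)
    b <- place(n, c(0.07, 0.50, 0.88))
    sp <- synthetic_rib_spec(
      n_ribs = n, true_boundaries = b, allometric_boundaries = b,
      shift = cohort$base_shift, slope = 0.01,
      size_gradient = 0.8, size_step = 10 * cohort$base_shift,
      allometry_strength = 0.1,
      noise_sd = cohort$noise_sd, template_torsion = 0.15,
      seed = cohort$seed + idx)
    name <- sprintf("snakelike_%02d", i)
    out[[name]] <- generate_rib_series(sp, body_type = "snake-like", species = name)
  }
  out
}

#' Simulate a pure-birth tree with a Brownian trait
#'
#' A Yule topology with `n_tips` tips, branch lengths in Myr, and a
#' continuous trait evolved along branches under Brownian motion with
#' rate `sigma2` from `root_state` — the recovery target for
#' [bm_ancestral_states()].
#'
#' @param n_tips Number of tips (>= 3).
#' @param birth Speciation rate (default 1).
#' @param sigma2 BM rate (trait^2 per Myr; default 0.01).
#' @param root_state Trait value at the root (default 0.15).
#' @param seed Integer seed.
#' @return List: `tree` (ultrametric `phylo`), `traits` (named tip
#'   vector), `node_states` (true internal-node states), `truth`
#'   (`root_state`, `sigma2`).
#' @export
generate_bm_tree <- function(n_tips, birth = 1, sigma2 = 0.01,
                             root_state = 0.15, seed = 1L) {
  if (n_tips < 3L) stop("n_tips must be >= 3")
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth, death = 0)
  n <- n_tips
  state <- numeric(n + tree$Nnode)
  state[n + 1L] <- root_state
  cw <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(cw$edge))) {
    par <- cw$edge[e, 1L]; child <- cw$edge[e, 2L]
    state[child] <- state[par] +
      stats::rnorm(1L, sd = sqrt(sigma2 * cw$edge.length[e]))
  }
  list(tree = tree,
       traits = stats::setNames(state[seq_len(n)], tree$tip.label),
       node_states = state[n + seq_len(tree$Nnode)],
       truth = list(root_state = root_state, sigma2 = sigma2))
}
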