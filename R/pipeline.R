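#' Analysis configuration
#'
#' Bundles the tunable settings of the full pipeline. Defaults follow the
#' standard protocol for squamate rib regionalization: 4% axial sampling,
#' six retained PCs, up to six regions, minimum segment of three sampled
#' ribs, 999 permutations, and 1 Myr minimum branch length.
#'
#' @param interval_percent Axial subsampling interval (default 4).
#' @param n_retained_pcs PCs retained for segmented regression (default 6).
#' @param max_regions Maximum region count tested (default 6).
#' @param min_seg Minimum sampled ribs per segment (default 3).
#' @param n_perm Permutations for significance tests (default 999).
#' @param seed Base random seed (default 1).
#' @param mbl Minimum branch length, Myr (default 1).
#' @param heterogeneity One of `"max_pairwise"` (default) or
#'   `"consensus_range"` — which reading of the range of Procrustes
#'   distances is reported as `H`.
#' @param slide Slide semilandmarks during superimposition (default FALSE).
#' @return Object of class `run_config`.
#' @export
run_config <- function(interval_percent = 4, n_retained_pcs = 6L,
                       max_regions = 6L, min_seg = 3L, n_perm = 999L,
                       seed = 1L, mbl = 1.0,
                       heterogeneity = c("max_pairwise", "consensus_range"),
                       slide = FALSE) {
  heterogeneity <- match.arg(heterogeneity)
  structure(list(interval_percent = interval_percent,
                 n_retained_pcs = as.integer(n_retained_pcs),
                 max_regions = as.integer(max_regions),
                 min_seg = as.integer(min_seg),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 mbl = mbl, heterogeneity = heterogeneity, slide = slide),
            class = "run_config")
}

#' Full per-species analysis
#'
#' Runs the complete single-specimen pipeline: axial subsampling (for
#' elongate specimens), generalized Procrustes superimposition, PCA,
#' segmented regression with AICc selection, boundary percentages and
#' region score, allometric decomposition (size regression, residual
#' regionalization, allometric boundary count), axial heterogeneity and
#' extreme-versus-mid shape distances.
#'
#' @param series A [rib_series] (complete; subsampling is applied here),
#'   or a path to a TPS file together with `metadata`.
#' @param config A [run_config()].
#' @param metadata Optional one-row data frame (as from
#'   [read_specimen_table()]) used when `series` is a TPS path.
#' @param fit_perm Permutations for the allometric regression (defaults
#'   to `config$n_perm`; set to 0 to skip the permutation test).
#' @return Object of class `species_analysis` with elements `species`,
#'   `body_type`, `series` (subsampled), `gpa`, `space`, `full`
#'   (regionalization), `allometry`, `residual` (regionalization),
#'   `decomposition`, `heterogeneity`, `extremes`, `config`, and a
#'   one-row `summary` data frame.
#' @export
analyze_species <- function(series, config = run_config(), metadata = NULL,
                            fit_perm = NULL) {
  if (is.character(series)) {
    if (is.null(metadata) || nrow(metadata) != 1L) {
      stop("reading from TPS requires a one-row metadata entry naming the specimen")
    }
    configs <- read_tps(series)
    series <- rib_series(configs, n_ribs_total = metadata$n_ribs_total,
                         body_type = metadata$body_type,
                         species = metadata$species,
                         specimen_id = metadata$specimen_id)
  }
  stopifnot(inherits(series, "rib_series"), inherits(config, "run_config"))
  if (is.null(fit_perm)) fit_perm <- config$n_perm

  sub <- subsample_axis(series, config$interval_percent)
  fit <- gpa(sub, slide = config$slide)
  space <- shape_pca(fit, n_retained = config$n_retained_pcs)
  full <- slra(space, max_regions = config$max_regions,
               min_seg = config$min_seg, series = sub)
  allom <- fit_allometry(fit, n_perm = max(fit_perm, 1L), seed = config$seed)
  resid <- nonallometric_regionalization(allom, n_retained = config$n_retained_pcs,
                                         series = sub,
                                         max_regions = config$max_regions,
                                         min_seg = config$min_seg)
  decomp <- allometric_boundary_count(full, resid)
  het <- axial_heterogeneity(fit)
  ext <- extreme_vs_mid(fit, sub)

  H <- if (config$heterogeneity == "max_pairwise") het$H else het$H_consensus_range
  summary <- data.frame(
    species = series$species, body_type = series$body_type,
    n_ribs_total = series$n_ribs_total, n_sampled = n_ribs(sub),
    k_best = full$best_overall$k, region_score = full$region_score,
    accepted = full$accepted,
    boundaries_pct = paste(sprintf("%.2f", full$boundary_percent), collapse = ";"),
    anterior_boundary_pct = if (length(full$boundary_percent)) {
      min(full$boundary_percent)
    } else NA_real_,
    posterior_boundary_pct = if (length(full$boundary_percent)) {
      max(full$boundary_percent)
    } else NA_real_,
    r_squared = allom$r_squared, perm_p = allom$perm_p,
    k_residual = resid$best_overall$k,
    residual_score = resid$region_score,
    allometric_boundaries = decomp$allometric_boundaries,
    region_score_drop = decomp$region_score_drop,
    H = H, H_max_pairwise = het$H, H_consensus_range = het$H_consensus_range,
    d_ant_mid = ext$d_ant_mid, d_post_mid = ext$d_post_mid,
    stringsAsFactors = FALSE)

  structure(list(species = series$species, body_type = series$body_type,
                 series = sub, gpa = fit, space = space, full = full,
                 allometry = allom, residual = resid, decomposition = decomp,
                 heterogeneity = het, extremes = ext, config = config,
                 summary = summary),
            class = "species_analysis")
}

#' @export
print.species_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%s (%s): k = %d (score %.2f), non-allometric k = %d, A = %d, H = %.4f\n",
              s$species, s$body_type, s$k_best, s$region_score, s$k_residual,
              s$allometric_boundaries, s$H))
  invisible(x)
}

#' Cohort-level analysis and group contrasts
#'
#' Aggregates per-species analyses into the cohort report: Welch contrasts
#' between body types for region score, anterior/posterior boundary
#' position, axial heterogeneity, non-allometric region score and
#' region-score drop; inter-species disparity per axial interval and body
#' type; and, when a tree is supplied, minimum-branch-length time-scaling
#' followed by Brownian-motion ancestral-state reconstruction of axial
#' heterogeneity.
#'
#' @param analyses List of `species_analysis` objects (species names must
#'   be unique).
#' @param tree Optional rooted `phylo` over the species names.
#' @param fads Optional named FAD vector (Ma) for [mbl_timescale()];
#'   defaults to 0 for every tip (extant-only cohort).
#' @param config A [run_config()].
#' @param disparity_intervals Axial fractions at which between-species
#'   disparity and shape ANOVA are computed (default `seq(0, 1, 0.04)`).
#' @return Object of class `cohort_analysis`: `table` (per-species summary
#'   rows), `contrasts` (list of `group_contrast`), `disparity` (per
#'   interval and body type), `anova` (per-interval Procrustes ANOVA
#'   between body types), `dated_tree`, `asr`, `config`.
#' @export
analyze_cohort <- function(analyses, tree = NULL, fads = NULL,
                           config = run_config(),
                           disparity_intervals = seq(0, 1, by = 0.04)) {
  tab <- do.call(rbind, lapply(analyses, `[[`, "summary"))
  rownames(tab) <- NULL
  if (anyDuplicated(tab$species)) stop("duplicate species in cohort")
  grp <- split(tab, tab$body_type)
  two_groups <- length(grp) == 2L && all(vapply(grp, nrow, integer(1)) >= 2L)

  contrasts <- list()
  if (two_groups) {
    a <- grp[["limbed"]]; b <- grp[["snake-like"]]
    lab <- c("limbed", "snake-like")
    cvars <- c(region_score = "region_score",
               anterior_boundary_pct = "anterior_boundary_pct",
               posterior_boundary_pct = "posterior_boundary_pct",
               heterogeneity = "H",
               residual_score = "residual_score",
               region_score_drop = "region_score_drop")
    for (nm in names(cvars)) {
      va <- a[[cvars[nm]]]; vb <- b[[cvars[nm]]]
      va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
      if (length(va) >= 2L && length(vb) >= 2L) {
        contrasts[[nm]] <- welch_t(va, vb, labels = lab)
      }
    }
  } else {
    message("fewer than two body types with >= 2 species: contrasts skipped")
  }

  # per-interval inter-species disparity (fresh joint GPA per interval)
  disparity <- list(); anova <- list()
  for (f in disparity_intervals) {
    for (bt in names(grp)) {
      shapes <- interval_shapes(analyses[tab$body_type == bt], f)
      key <- sprintf("%s@%.0f%%", bt, 100 * f)
      disparity[[key]] <- if (dim(shapes)[3L] >= 3L) {
        d <- interspecies_disparity(shapes)
        data.frame(body_type = bt, interval = 100 * f,
                   variance = d$variance, n = d$n)
      } else NULL
    }
    if (two_groups) {
      all_shapes <- interval_shapes(analyses, f)
      labels <- tab$body_type
      if (dim(all_shapes)[3L] == nrow(tab) && all(table(labels) >= 3L)) {
        jf <- gpa(all_shapes)
        res <- procrustes_anova_groups(jf, labels, n_perm = config$n_perm,
                                       seed = config$seed)
        anova[[sprintf("%.0f%%", 100 * f)]] <-
          data.frame(interval = 100 * f, F = res$F, p = res$p)
      }
    }
  }
  disparity <- do.call(rbind, disparity)
  if (!is.null(disparity)) rownames(disparity) <- NULL
  anova <- do.call(rbind, anova)
  if (!is.null(anova)) rownames(anova) <- NULL

  dated <- NULL; asr <- NULL
  if (!is.null(tree)) {
    missing_tips <- setdiff(tree$tip.label, tab$species)
    missing_sp <- setdiff(tab$species, tree$tip.label)
    if (length(missing_tips) || length(missing_sp)) {
      stop("tree/cohort taxon mismatch; in tree only: ",
           paste(missing_tips, collapse = ", "), "; in cohort only: ",
           paste(missing_sp, collapse = ", "))
    }
    if (is.null(fads)) fads <- stats::setNames(rep(0, nrow(tab)), tab$species)
    dated <- mbl_timescale(tree, fads, mbl = config$mbl)
    asr <- bm_ancestral_states(dated, stats::setNames(tab$H, tab$species))
  }

  structure(list(table = tab, contrasts = contrasts, disparity = disparity,
                 anova = anova, dated_tree = dated, asr = asr,
                 config = config),
            class = "cohort_analysis")
}

# One rib per species at the axial fraction nearest `frac`, as a p x 3 x n
# array of raw (pre-superimposition) coordinates.
interval_shapes <- function(analyses, frac) {
  picks <- lapply(analyses, function(an) {
    i <- which.min(abs(an$series$axial_fraction - frac))
    an$series$coords[, , i]
  })
  p <- nrow(picks[[1L]])
  arr <- array(NA_real_, c(p, 3L, length(picks)))
  for (i in seq_along(picks)) arr[, , i] <- picks[[i]]
  arr
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("Cohort analysis:", nrow(x$table), "species (",
      paste(names(table(x$table$body_type)), table(x$table$body_type),
            collapse = ", "), ")\n")
  for (nm in names(x$contrasts)) {
    cat(" ", nm, ": ")
    print(x$contrasts[[nm]])
  }
  if (!is.null(x$asr)) {
    cat(sprintf("  ancestral heterogeneity at root: %.4f (95%% CI %.4f-%.4f)\n",
                x$asr$root_estimate, x$asr$ci_lower[1L], x$asr$ci_upper[1L]))
  }
  invisible(x)
}

#' Write cohort results as CSV tables
#'
#' Writes the per-species summary, the contrast table, the per-interval
#' disparity table and, when present, ancestral states to `dir`.
#'
#' @param cohort A `cohort_analysis`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$table, file.path(dir, "species_summary.csv"),
                   row.names = FALSE)
  if (length(cohort$contrasts)) {
    ct <- do.call(rbind, lapply(names(cohort$contrasts), function(nm) {
      cc <- cohort$contrasts[[nm]]
      data.frame(contrast = nm, t = cc$t, df = cc$df, p = cc$p,
                 mean_limbed = cc$mean_a, mean_snakelike = cc$mean_b)
    }))
    utils::write.csv(ct, file.path(dir, "contrasts.csv"), row.names = FALSE)
  }
  if (!is.null(cohort$disparity)) {
    utils::write.csv(cohort$disparity, file.path(dir, "disparity.csv"),
                     row.names = FALSE)
  }
  if (!is.null(cohort$asr)) {
    st <- data.frame(node = names(cohort$asr$estimates),
                     estimate = unname(cohort$asr$estimates),
                     var = unname(cohort$asr$variances),
                     ci_low = unname(cohort$asr$ci_lower),
                     ci_high = unname(cohort$asr$ci_upper))
    utils::write.csv(st, file.path(dir, "ancestral_states.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
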