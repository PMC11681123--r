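#' A single rib landmark configuration
#'
#' Container for one rib's 3D landmarks: `n_fixed` anatomical landmarks
#' followed by `n_semi` semilandmarks forming one ordered curve along the
#' visceral face. Coordinates are in scan units (typically mm).
#'
#' @param points Numeric matrix, (`n_fixed + n_semi`) x 3, finite.
#' @param n_fixed Number of fixed landmarks.
#' @param n_semi Number of semilandmarks (default 0).
#' @param rib_index 1-based axial position of this rib, counted from the
#'   cranial end.
#' @param specimen_id Identifier string.
#' @return An object of class `landmark_config`.
#' @export
landmark_config <- function(points, n_fixed = nrow(points), n_semi = 0L,
                            rib_index = 1L, specimen_id = "specimen") {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  if (any(!is.finite(points))) stop("coordinates must be finite")
  n_fixed <- as.integer(n_fixed); n_semi <- as.integer(n_semi)
  if (n_fixed + n_semi != nrow(points)) {
    stop("n_fixed + n_semi (", n_fixed + n_semi, ") != point count (", nrow(points), ")")
  }
  rib_index <- as.integer(rib_index)
  if (rib_index < 1L) stop("rib_index must be >= 1")
  structure(list(points = points, n_fixed = n_fixed, n_semi = n_semi,
                 rib_index = rib_index, specimen_id = as.character(specimen_id)),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("Landmark configuration:", x$specimen_id, "rib", x$rib_index, "-",
      x$n_fixed, "fixed +", x$n_semi, "semilandmarks\n")
  invisible(x)
}

#' An ordered series of rib configurations for one specimen
#'
#' Assembles per-rib landmark configurations into a single ordered series.
#' Axial position of rib `i` is expressed as the fraction
#' `(rib_index - 1) / (n_ribs_total - 1)` of the cranial-to-caudal axis.
#' Specimens with more than 50 pairs of free dorsal ribs are classed as
#' snake-like; the constructor enforces consistency between `body_type`
#' and `n_ribs_total` under that rule.
#'
#' @param configs List of [landmark_config] objects with strictly increasing
#'   `rib_index` and a common point count.
#' @param n_ribs_total Total free dorsal rib count of the specimen (the
#'   terminal forked rib of snakes is assumed excluded upstream).
#' @param body_type `"limbed"` or `"snake-like"`.
#' @param species Species name.
#' @param specimen_id Specimen identifier; defaults to the first config's id.
#' @return An object of class `rib_series` with elements `coords`
#'   (p x 3 x n array), `rib_index`, `axial_fraction`, `n_fixed`, `n_semi`,
#'   `n_ribs_total`, `body_type`, `species`, `specimen_id`.
#' @export
rib_series <- function(configs, n_ribs_total, body_type = c("limbed", "snake-like"),
                       species = "sp", specimen_id = NULL) {
  body_type <- match.arg(body_type)
  if (!length(configs)) stop("empty configuration list")
  idx <- vapply(configs, `[[`, integer(1), "rib_index")
  if (any(diff(idx) <= 0L)) stop("rib_index must be strictly increasing")
  np <- vapply(configs, function(cf) nrow(cf$points), integer(1))
  if (length(unique(np)) != 1L) stop("all ribs must have the same point count")
  n_ribs_total <- as.integer(n_ribs_total)
  if (max(idx) > n_ribs_total) stop("rib_index exceeds n_ribs_total")
  if (body_type == "snake-like" && n_ribs_total <= 50L) {
    stop("snake-like specimens must have more than 50 free dorsal ribs (got ",
         n_ribs_total, ")")
  }
  p <- np[1L]
  coords <- array(NA_real_, c(p, 3L, length(configs)))
  for (i in seq_along(configs)) coords[, , i] <- configs[[i]]$points
  af <- if (n_ribs_total > 1L) (idx - 1) / (n_ribs_total - 1) else rep(0, length(idx))
  structure(list(
    coords = coords, rib_index = idx, axial_fraction = af,
    n_fixed = configs[[1L]]$n_fixed, n_semi = configs[[1L]]$n_semi,
    n_ribs_total = n_ribs_total, body_type = body_type,
    species = species,
    specimen_id = if (is.null(specimen_id)) configs[[1L]]$specimen_id else specimen_id
  ), class = "rib_series")
}

#' @export
print.rib_series <- function(x, ...) {
  cat("Rib series:", x$species, "(", x$body_type, ")\n")
  cat(" ", dim(x$coords)[3L], "ribs sampled of", x$n_ribs_total, "total;",
      dim(x$coords)[1L], "landmarks per rib (", x$n_fixed, "fixed +",
      x$n_semi, "semi )\n")
  invisible(x)
}

#' Number of ribs held in a series
#' @param series A [rib_series].
#' @return Integer count of sampled ribs.
#' @export
n_ribs <- function(series) dim(series$coords)[3L]

#' Subsample an elongate rib series at fixed axial intervals
#'
#' Elongate specimens (more than 50 free dorsal ribs) are reduced to ribs
#' nearest the axial positions 0%, `interval_percent`, ..., 100%, so a 4%
#' interval yields 26 ribs spanning both axial extremes. The target rib index
#' for percentage `p` is `round(p/100 * (n_ribs_total - 1)) + 1` with
#' round-half-up; duplicate indices arising from rounding are dropped,
#' keeping the first occurrence. Specimens with 50 or fewer ribs are
#' returned unchanged, as is a series already shorter than the target count.
#'
#' @param series A [rib_series] whose configurations cover the selected
#'   indices (typically a complete series).
#' @param interval_percent Sampling interval as a percentage of the axis
#'   (default 4); must divide 100.
#' @return A [rib_series] restricted to the sampled ribs. The original rib
#'   indices are retained so boundary positions can be mapped back.
#' @export
subsample_axis <- function(series, interval_percent = 4) {
  if (interval_percent <= 0 || interval_percent > 100) {
    stop("interval_percent must be in (0, 100]")
  }
  steps <- 100 / interval_percent
  if (abs(steps - round(steps)) > 1e-8) stop("100 must be divisible by interval_percent")
  if (series$n_ribs_total < 2L) stop("series must have n_ribs_total >= 2")
  if (series$n_ribs_total <= 50L) return(series)

  pct <- seq(0, 100, by = interval_percent)
  # round half up: floor(x + 0.5) rather than banker's rounding
  target <- floor(pct / 100 * (series$n_ribs_total - 1) + 0.5) + 1
  target <- target[!duplicated(target)]

  pos <- match(target, series$rib_index)
  if (anyNA(pos)) {
    stop("series does not contain ribs at required indices: ",
         paste(target[is.na(pos)], collapse = ", "))
  }
  out <- series
  out$coords <- series$coords[, , pos, drop = FALSE]
  out$rib_index <- series$rib_index[pos]
  out$axial_fraction <- series$axial_fraction[pos]
  out
}

#' Read a specimen metadata table
#'
#' Reads a CSV with columns `specimen_id`, `species`, `body_type`,
#' `n_ribs_total` and optional `girdle_first`, `girdle_last`,
#' `sternal_first` (1-based rib indices of abaxial markers, descriptive
#' only). `specimen_id` must be unique and `body_type` must be `limbed`
#' or `snake-like`.
#'
#' @param path CSV path with a header row.
#' @return A data frame of specimen metadata.
#' @export
read_specimen_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "species", "body_type", "n_ribs_total")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$specimen_id)) stop("specimen_id values must be unique")
  bad <- setdiff(unique(tab$body_type), c("limbed", "snake-like"))
  if (length(bad)) stop("unknown body_type values: ", paste(bad, collapse = ", "))
  tab
}
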