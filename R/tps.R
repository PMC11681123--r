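#' Read a TPS landmark file
#'
#' Parses a TPS file into a list of landmark configurations. Each record must
#' declare its fixed landmarks with an `LM3=` line (three-dimensional data;
#' 2D `LM=` records are rejected) followed by that many whitespace-separated
#' coordinate rows. An optional `CURVES=`/`POINTS=` block supplies one ordered
#' curve of semilandmarks, which is appended to the point list in file order.
#' An `ID=` (or `IMAGE=`) line names the record.
#'
#' @param path Path to a TPS file.
#' @return A list of [landmark_config] objects, one per record, in file order.
#'   `rib_index` is assigned 1..n in file order unless the record ID ends in
#'   an integer, in which case that integer is used.
#' @seealso [write_tps()], [rib_series()]
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  starts <- grep("^LM3?=", lines)
  if (length(starts) == 0L) stop("no LM=/LM3= records found in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))

  configs <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    rec <- lines[starts[r]:ends[r]]
    head_line <- rec[1L]
    if (grepl("^LM=", head_line)) {
      stop("record ", r, " is two-dimensional (LM=); only LM3= records are supported")
    }
    n_fixed <- as.integer(sub("^LM3=", "", head_line))
    body <- rec[-1L]

    id_i <- grep("^(ID|IMAGE)=", body)
    id <- if (length(id_i)) sub("^(ID|IMAGE)=", "", body[id_i[1L]]) else paste0("record_", r)

    curve_i <- grep("^CURVES=", body)
    pts_i <- grep("^POINTS=", body)
    n_semi <- 0L
    if (length(curve_i)) {
      n_curves <- as.integer(sub("^CURVES=", "", body[curve_i[1L]]))
      if (n_curves > 1L) stop("record ", r, ": only a single semilandmark curve is supported")
      if (!length(pts_i)) stop("record ", r, ": CURVES= without POINTS=")
      n_semi <- as.integer(sub("^POINTS=", "", body[pts_i[1L]]))
    }

    coord_lines <- body[grepl("^[-+0-9.]", body)]
    n_expect <- n_fixed + n_semi
    if (length(coord_lines) != n_expect) {
      stop("record ", r, " (", id, "): declared ", n_expect,
           " points but found ", length(coord_lines), " coordinate rows")
    }
    fields <- strsplit(coord_lines, "[[:space:]]+")
    if (any(lengths(fields) != 3L)) {
      stop("record ", r, " (", id, "): coordinate rows must have exactly 3 values")
    }
    pts <- matrix(as.numeric(unlist(fields)), ncol = 3L, byrow = TRUE)
    if (any(!is.finite(pts))) stop("record ", r, " (", id, "): non-finite coordinates")

    idx <- suppressWarnings(as.integer(sub(".*?([0-9]+)$", "\\1", id)))
    if (is.na(idx) || !grepl("[0-9]$", id)) idx <- r
    configs[[r]] <- landmark_config(pts, n_fixed = n_fixed, n_semi = n_semi,
                                    rib_index = idx, specimen_id = id)
  }
  configs
}

#' Write landmark configurations to a TPS file
#'
#' Inverse of [read_tps()]: coordinates round-trip to at least six
#' significant digits. Records are written in list order with `LM3=`,
#' optional `CURVES=1`/`POINTS=` blocks, and `ID=` lines.
#'
#' @param configs Non-empty list of [landmark_config] objects with a common
#'   total point count.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path) {
  if (!length(configs)) stop("cannot write an empty configuration list")
  np <- vapply(configs, function(cf) nrow(cf$points), integer(1))
  if (length(unique(np)) != 1L) {
    stop("heterogeneous point counts across records: ", paste(unique(np), collapse = ", "))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cf in configs) {
    writeLines(sprintf("LM3=%d", cf$n_fixed), con)
    fmt <- function(m) apply(m, 1L, function(row) paste(sprintf("%.10g", row), collapse = " "))
    if (cf$n_fixed > 0L) writeLines(fmt(cf$points[seq_len(cf$n_fixed), , drop = FALSE]), con)
    if (cf$n_semi > 0L) {
      writeLines("CURVES=1", con)
      writeLines(sprintf("POINTS=%d", cf$n_semi), con)
      writeLines(fmt(cf$points[cf$n_fixed + seq_len(cf$n_semi), , drop = FALSE]), con)
    }
    writeLines(sprintf("ID=%s", cf$specimen_id), con)
  }
  invisible(path)
}
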