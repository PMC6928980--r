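# Collapse multi-day hourly IR values into per-site hour-of-day medians
# (robust to outlier days) and assemble the sites x 24 matrix that feeds
# the clustering stage.

#' Hour-of-day median and MAD over days for one site
#'
#' @param profile_hours data frame with at least columns `hour` (0-23) and
#'   `ir_percent` (one row per monitored hour; NA = missing hour); rows
#'   from several days are pooled by hour of day.
#' @return data frame with 24 rows: `hour`, `median_ir`, `mad_ir`
#'   (unscaled median absolute deviation, no 1.4826 consistency factor),
#'   `n_days`. Hours with no valid day get NA (a missing-cell marker).
#' @export
median_mad_by_hour <- function(profile_hours) {
  stopifnot(all(c("hour", "ir_percent") %in% names(profile_hours)))
  out <- data.frame(hour = 0:23, median_ir = NA_real_, mad_ir = NA_real_,
                    n_days = 0L)
  for (h in 0:23) {
    v <- profile_hours$ir_percent[profile_hours$hour == h]
    v <- v[!is.na(v)]
    out$n_days[h + 1] <- length(v)
    if (length(v) > 0) {
      m <- median(v)
      out$median_ir[h + 1] <- m
      out$mad_ir[h + 1] <- median(abs(v - m))
    }
  }
  out
}

#' Build the sites x 24 matrix of median hourly IR
#'
#' Sites with any empty hour-of-day cell are excluded (listed in the
#' rejection report) rather than imputed, so the clustering distance never
#' mixes observed and invented values.
#'
#' @param site_profiles named list (names = site ids) of
#'   [median_mad_by_hour()] tables.
#' @param road_classes optional named character vector of road classes,
#'   aligned by site id.
#' @return An object of class `site_hour_matrix`: list with `site_ids`,
#'   `road_classes`, `values` (sites x 24 matrix of medians, %), `mad`
#'   (same shape), `rejected` (character vector of excluded site ids).
#' @export
build_site_hour_matrix <- function(site_profiles, road_classes = NULL) {
  stopifnot(length(site_profiles) > 0, !is.null(names(site_profiles)))
  ids <- names(site_profiles)
  med <- t(vapply(site_profiles, function(p) p$median_ir, numeric(24)))
  madm <- t(vapply(site_profiles, function(p) p$mad_ir, numeric(24)))
  complete <- apply(med, 1, function(r) all(!is.na(r)))
  if (!any(complete)) stop("no site has 24 complete hour-of-day cells")
  values <- med[complete, , drop = FALSE]
  stopifnot(all(values >= 0 & values <= 100))
  colnames(values) <- colnames(madm) <- sprintf("hour_%02d", 0:23)
  rownames(values) <- ids[complete]
  structure(
    list(site_ids = ids[complete],
         road_classes = if (!is.null(road_classes))
           unname(road_classes[ids[complete]]) else NULL,
         values = values,
         mad = madm[complete, , drop = FALSE],
         rejected = ids[!complete]),
    class = "site_hour_matrix"
  )
}

#' Column-standardize a site x hour matrix
#'
#' Each hour column is centred to mean 0 and scaled to sample standard
#' deviation 1 (n - 1 denominator). The means and sds are stored as
#' attributes `center` and `scale` so the transform is invertible.
#'
#' @param matrix a `site_hour_matrix` or plain numeric matrix.
#' @return a numeric matrix of class `scaled_matrix` with attributes
#'   `center` and `scale`.
#' @export
scale_columns <- function(matrix) {
  m <- if (inherits(matrix, "site_hour_matrix")) matrix$values else matrix
  stopifnot(is.matrix(m), nrow(m) >= 2)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  }
  centers <- colMeans(m)
  z <- sweep(sweep(m, 2, centers), 2, sds, "/")
  structure(z, center = centers, scale = sds,
            class = c("scaled_matrix", "matrix", "array"))
}

#' Invert [scale_columns()]
#' @param scaled a `scaled_matrix`.
#' @return the original matrix.
#' @export
unscale_columns <- function(scaled) {
  stopifnot(inherits(scaled, "scaled_matrix"))
  out <- sweep(sweep(unclass(scaled), 2, attr(scaled, "scale"), "*"),
               2, attr(scaled, "center"), "+")
  attr(out, "center") <- NULL
  attr(out, "scale") <- NULL
  out
}

#' Export the aggregation products as CSV
#'
#' Writes `<prefix>_median.csv`, `<prefix>_mad.csv`, `<prefix>_scaled.csv`
#' (sites as rows, `hour_00` .. `hour_23` columns).
#'
#' @param shm a [build_site_hour_matrix()] result.
#' @param scaled the matching [scale_columns()] result.
#' @param out_prefix path prefix.
#' @return the paths, invisibly.
#' @export
write_matrix_csv <- function(shm, scaled, out_prefix) {
  paths <- paste0(out_prefix, c("_median.csv", "_mad.csv", "_scaled.csv"))
  wr <- function(m, p) {
    df <- data.frame(site_id = shm$site_ids, m, check.names = FALSE)
    write.csv(df, p, row.names = FALSE)
  }
  wr(shm$values, paths[1])
  wr(shm$mad, paths[2])
  wr(unclass(scaled), paths[3])
  invisible(paths)
}
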