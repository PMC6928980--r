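# Monitoring text format: four delimited columns per row —
# date (YYYY-MM-DD), time (HH:MM:SS), 1-s A-weighted level in dB with one
# decimal, and a source code ("T" = road traffic, anything else = masked).

SOURCE_TRAFFIC <- "T"
SOURCE_MASKED <- "M"
ROAD_CLASSES <- c("A", "D", "E", "F")

#' One site-day (or longer) series of 1-s A-weighted SPL samples
#'
#' Constructor and validator for the package's core container: an ordered
#' 1-s SPL series with per-sample source tags. Timestamps must be strictly
#' increasing with whole-second resolution; gaps are allowed and are never
#' interpolated. Levels must be finite and inside (0, 140) dB.
#'
#' @param site_id opaque site identifier.
#' @param road_class one of `"A"`, `"D"`, `"E"`, `"F"` (Italian functional
#'   classes: motorway, thoroughfare, urban district, urban local).
#' @param timestamp `POSIXct` vector (stored in UTC; interpreted as local
#'   civil clock time, no DST handling).
#' @param level numeric vector of 1-s equivalent levels, dB(A).
#' @param masked logical vector; `TRUE` marks samples attributed to a
#'   non-road source, which are excluded from all energy computations.
#' @return An object of class `spl_series`: a list with `site_id`,
#'   `road_class` and a data frame `samples`.
#' @export
spl_series <- function(site_id, road_class, timestamp, level,
                       masked = logical(length(level))) {
  road_class <- match.arg(road_class, ROAD_CLASSES)
  n <- length(timestamp)
  stopifnot(n > 0, length(level) == n, length(masked) == n,
            inherits(timestamp, "POSIXct"))
  secs <- as.numeric(timestamp)
  if (any(secs != round(secs)))
    stop("timestamps must have whole-second resolution")
  d <- diff(secs)
  if (any(d == 0)) stop("duplicate timestamps in series")
  if (any(d < 0)) stop("timestamps must be strictly increasing")
  if (any(!is.finite(level)) || any(level <= 0) || any(level >= 140))
    stop("levels must be finite and in (0, 140) dB")
  structure(
    list(site_id = as.character(site_id), road_class = road_class,
         samples = data.frame(timestamp = timestamp, level = level,
                              masked = as.logical(masked))),
    class = "spl_series"
  )
}

#' @export
print.spl_series <- function(x, ...) {
  cat(sprintf("<spl_series> site %s (class %s): %d samples, %s .. %s, %d masked\n",
              x$site_id, x$road_class, nrow(x$samples),
              format(min(x$samples$timestamp)), format(max(x$samples$timestamp)),
              sum(x$samples$masked)))
  invisible(x)
}

#' Read a 4-column SPL monitoring text file
#'
#' Accepts any run of whitespace or a single comma as delimiter. Rows whose
#' source code is not `"T"` are tagged as masked. Malformed rows,
#' non-monotone or duplicate timestamps abort with an informative error.
#'
#' @param path file path.
#' @param road_class road class of the site (see [spl_series()]).
#' @param site_id site identifier; defaults to the file name without
#'   extension.
#' @return An [spl_series()] object.
#' @export
read_spl_file <- function(path, road_class,
                          site_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no data rows in ", path)
  parts <- strsplit(trimws(lines), "[[:space:]]*,[[:space:]]*|[[:space:]]+")
  nf <- lengths(parts)
  if (any(nf != 4)) {
    bad <- which(nf != 4)[1]
    stop(sprintf("malformed row at line %d of %s: expected 4 fields, got %d",
                 bad, path, nf[bad]))
  }
  m <- matrix(unlist(parts), ncol = 4, byrow = TRUE)
  ts <- as.POSIXct(paste(m[, 1], m[, 2]), tz = "UTC",
                   format = "%Y-%m-%d %H:%M:%S")
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop(sprintf("malformed timestamp at line %d of %s", bad, path))
  }
  level <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(level)) {
    bad <- which(is.na(level))[1]
    stop(sprintf("malformed level at line %d of %s", bad, path))
  }
  spl_series(site_id, road_class, ts, level, masked = m[, 4] != SOURCE_TRAFFIC)
}

#' Write an SPL series in the 4-column monitoring format
#'
#' Levels are written with one decimal; fields are tab-separated; the
#' source code is `"T"` for road traffic and `"M"` for masked samples.
#' `read_spl_file(write_spl_file(x))` reproduces `x` up to the one-decimal
#' level format.
#'
#' @param series an [spl_series()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spl_file <- function(series, path) {
  stopifnot(inherits(series, "spl_series"), nrow(series$samples) > 0)
  s <- series$samples
  lines <- sprintf("%s\t%s\t%.1f\t%s",
                   format(s$timestamp, "%Y-%m-%d", tz = "UTC"),
                   format(s$timestamp, "%H:%M:%S", tz = "UTC"),
                   s$level,
                   ifelse(s$masked, SOURCE_MASKED, SOURCE_TRAFFIC))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Segment an SPL series into clock-aligned hour windows
#'
#' One window per clock hour intersecting the series. Each window holds a
#' 3600-slot level vector (NA where no sample is present), a parallel
#' masked flag, and `valid_fraction` = present-and-road-traffic seconds /
#' 3600. Empty hours yield windows with `valid_fraction` 0.
#'
#' @param series an [spl_series()] object.
#' @return list of `hour_window` objects, in time order.
#' @export
segment_hours <- function(series) {
  stopifnot(inherits(series, "spl_series"))
  s <- series$samples
  secs <- as.numeric(s$timestamp)
  hour_key <- floor(secs / 3600)
  keys <- seq(min(hour_key), max(hour_key))
  # timestamps are strictly increasing, so samples of one hour are a
  # contiguous block; tabulate is much cheaper than split/factor here
  counts <- tabulate(hour_key - keys[1] + 1L, nbins = length(keys))
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  lapply(seq_along(keys), function(i) {
    key <- keys[i]
    idx <- if (counts[i] > 0) starts[i]:ends[i] else integer(0)
    level <- rep(NA_real_, 3600L)
    masked <- rep(FALSE, 3600L)
    if (length(idx)) {
      slot <- as.integer(secs[idx] - key * 3600) + 1L
      level[slot] <- s$level[idx]
      masked[slot] <- s$masked[idx]
    }
    origin <- as.POSIXct(key * 3600, origin = "1970-01-01", tz = "UTC")
    hour_window(series$site_id, as.Date(origin, tz = "UTC"),
                as.integer(format(origin, "%H", tz = "UTC")), level, masked)
  })
}

#' Construct an hour window
#'
#' @param site_id site identifier.
#' @param date calendar date of the window start.
#' @param hour hour of day (0-23) labelling the interval starting then.
#' @param level numeric length-3600 vector, NA for absent seconds.
#' @param masked logical length-3600; TRUE = present but non-road source.
#' @return An object of class `hour_window`.
#' @export
hour_window <- function(site_id, date, hour, level,
                        masked = rep(FALSE, 3600L)) {
  stopifnot(length(level) == 3600L, length(masked) == 3600L,
            hour %in% 0:23)
  valid <- !is.na(level) & !masked
  structure(
    list(site_id = as.character(site_id), date = as.Date(date),
         hour = as.integer(hour), level = level, masked = masked,
         valid_fraction = sum(valid) / 3600),
    class = "hour_window"
  )
}

# present-and-traffic mask of a window
window_valid <- function(window) !is.na(window$level) & !window$masked
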