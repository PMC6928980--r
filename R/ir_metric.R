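# Intermittency ratio: share of an hour's acoustic energy carried by
# seconds whose level exceeds K = Leq + C. All energy arithmetic is done
# in linear power units (10^(L/10)); dB only at the boundary.

db_to_power <- function(db) 10^(db / 10)
power_to_db <- function(p) 10 * log10(p)

#' Energy-equivalent mean level (Leq)
#'
#' The constant level carrying the same energy as the input samples:
#' `10*log10(mean(10^(L/10)))`. Order-invariant.
#'
#' @param levels non-empty numeric vector of dB values.
#' @return Leq in dB.
#' @export
energy_mean_level <- function(levels) {
  if (length(levels) == 0) stop("Leq is undefined for an empty collection")
  if (any(!is.finite(levels))) stop("levels must be finite")
  power_to_db(mean(db_to_power(levels)))
}

#' Event detection threshold K = Leq + C
#'
#' @param leq_tot overall equivalent level of the window, dB.
#' @param offset_c offset C in dB; values outside \[0, 10\] trigger a
#'   warning (low C makes almost everything an event, high C almost
#'   nothing).
#' @return K in dB.
#' @export
event_threshold <- function(leq_tot, offset_c) {
  stopifnot(is.finite(leq_tot), is.finite(offset_c))
  if (offset_c < 0 || offset_c > 10)
    warning("offset C = ", offset_c, " dB is outside the advisory [0, 10] dB range")
  leq_tot + offset_c
}

#' Detect noise events in an hour window
#'
#' An event is a maximal run of consecutive valid seconds (present and
#' road-traffic) with level strictly above `threshold_k`; a masked or
#' missing second terminates a run. Each event carries its start time,
#' duration in seconds, and sound exposure level
#' `SEL = 10*log10(sum(10^(L/10)))` (energy referenced to 1 s).
#'
#' @param window an [hour_window()].
#' @param threshold_k detection threshold K, dB.
#' @return data frame with columns `start_time`, `duration_s`, `sel_db`
#'   (zero rows when nothing exceeds K).
#' @export
detect_events <- function(window, threshold_k) {
  stopifnot(inherits(window, "hour_window"))
  valid <- window_valid(window)
  if (!any(valid)) stop("window has no valid samples")
  above <- valid & !is.na(window$level) & window$level > threshold_k
  above[is.na(above)] <- FALSE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  origin <- as.POSIXct(paste(window$date, sprintf("%02d:00:00", window$hour)),
                       tz = "UTC")
  if (length(keep) == 0) {
    return(data.frame(start_time = origin[0], duration_s = integer(0),
                      sel_db = numeric(0)))
  }
  pw <- db_to_power(window$level)
  pw[!above] <- 0
  cs <- c(0, cumsum(pw))
  sel <- power_to_db(cs[ends[keep] + 1L] - cs[starts[keep]])
  data.frame(start_time = origin + (starts[keep] - 1L),
             duration_s = r$lengths[keep], sel_db = sel)
}

#' Intermittency ratio of an hour window
#'
#' Computes the overall equivalent level over valid seconds, the threshold
#' K = Leq + C, the event-only equivalent level (event energy normalized by
#' the same number of valid seconds as Leq), and
#' IR = 100 * 10^(0.1*Leq_events) / 10^(0.1*Leq_tot), i.e. the percentage
#' of total energy contributed by seconds above K. With no sample above K,
#' IR is exactly 0 and the event level is NA.
#'
#' @param window an [hour_window()].
#' @param offset_c event-emergence offset C, dB (default 3, the value
#'   established by traffic simulations in the metric's source work).
#' @param min_valid_fraction minimum fraction of the 3600 s that must be
#'   valid; below it an `noisir_insufficient_data` error is thrown.
#' @return An object of class `ir_result`: list with `leq_tot`,
#'   `leq_events`, `threshold_k`, `offset_c`, `ir_percent`, `n_events`,
#'   `events` (data frame from [detect_events()]), `window_duration`,
#'   `valid_seconds`, `valid_fraction`, `site_id`, `date`, `hour`.
#' @export
intermittency_ratio <- function(window, offset_c = 3, min_valid_fraction = 0.5) {
  stopifnot(inherits(window, "hour_window"))
  if (window$valid_fraction < min_valid_fraction) {
    stop(structure(
      class = c("noisir_insufficient_data", "error", "condition"),
      list(message = sprintf(
             "window %s %s h%02d: valid fraction %.3f below minimum %.3f",
             window$site_id, window$date, window$hour,
             window$valid_fraction, min_valid_fraction),
           call = sys.call(-1), valid_fraction = window$valid_fraction)))
  }
  valid <- window_valid(window)
  levels <- window$level[valid]
  n_valid <- length(levels)
  pow <- db_to_power(levels)
  total_energy <- sum(pow)
  leq_tot <- power_to_db(total_energy / n_valid)
  k <- event_threshold(leq_tot, offset_c)
  events <- detect_events(window, k)
  event_energy <- sum(pow[levels > k])
  leq_events <- if (event_energy > 0) power_to_db(event_energy / n_valid) else NA_real_
  ir <- 100 * event_energy / total_energy
  structure(
    list(site_id = window$site_id, date = window$date, hour = window$hour,
         leq_tot = leq_tot, leq_events = leq_events, threshold_k = k,
         offset_c = offset_c, ir_percent = ir, n_events = nrow(events),
         events = events, window_duration = 3600L, valid_seconds = n_valid,
         valid_fraction = window$valid_fraction),
    class = "ir_result"
  )
}

#' @export
print.ir_result <- function(x, ...) {
  cat(sprintf("<ir_result> %s %s h%02d: Leq %.1f dB, K %.1f dB, IR %.1f%%, %d events\n",
              x$site_id, x$date, x$hour, x$leq_tot, x$threshold_k,
              x$ir_percent, x$n_events))
  invisible(x)
}

#' IR directly from the two equivalent levels
#'
#' Evaluates `100 * 10^(0.1*leq_events) / 10^(0.1*leq_tot)`; useful to
#' reproduce worked examples where only the levels are reported.
#'
#' @param leq_events event-only equivalent level, dB.
#' @param leq_tot overall equivalent level, dB.
#' @return IR in percent.
#' @export
ir_from_levels <- function(leq_events, leq_tot) {
  stopifnot(is.finite(leq_events), is.finite(leq_tot))
  100 * db_to_power(leq_events) / db_to_power(leq_tot)
}

#' 24-hour IR profile of an SPL series
#'
#' Applies [intermittency_ratio()] to every clock-hour window from
#' [segment_hours()]. Hours failing the validity minimum are kept as rows
#' with NA metrics (a missing marker, not 0).
#'
#' @inheritParams intermittency_ratio
#' @param series an [spl_series()].
#' @return An object of class `ir_profile`: list with `hours` (one row per
#'   window: site_id, date, hour, leq_tot_db, leq_events_db, threshold_k_db,
#'   ir_percent, n_events, valid_seconds, valid_fraction) and `events`
#'   (site_id + the [detect_events()] columns).
#' @export
ir_profile_24h <- function(series, offset_c = 3, min_valid_fraction = 0.5) {
  windows <- segment_hours(series)
  n <- length(windows)
  date <- as.Date(vapply(windows, function(w) as.character(w$date), ""))
  hour <- vapply(windows, `[[`, 0L, "hour")
  leq_tot <- leq_ev <- k <- ir <- rep(NA_real_, n)
  n_events <- rep(NA_integer_, n)
  valid_sec <- integer(n)
  valid_frac <- vapply(windows, `[[`, 0, "valid_fraction")
  evs <- vector("list", n)
  for (i in seq_len(n)) {
    w <- windows[[i]]
    valid_sec[i] <- sum(window_valid(w))
    res <- tryCatch(
      intermittency_ratio(w, offset_c, min_valid_fraction),
      noisir_insufficient_data = function(e) NULL)
    if (!is.null(res)) {
      leq_tot[i] <- res$leq_tot
      leq_ev[i] <- res$leq_events
      k[i] <- res$threshold_k
      ir[i] <- res$ir_percent
      n_events[i] <- res$n_events
      if (nrow(res$events) > 0)
        evs[[i]] <- cbind(site_id = res$site_id, res$events)
    }
  }
  events <- do.call(rbind, evs[!vapply(evs, is.null, logical(1))])
  if (is.null(events))
    events <- data.frame(site_id = character(0),
                         start_time = as.POSIXct(character(0), tz = "UTC"),
                         duration_s = integer(0), sel_db = numeric(0))
  hours <- data.frame(site_id = series$site_id, date = date, hour = hour,
                      leq_tot_db = leq_tot, leq_events_db = leq_ev,
                      threshold_k_db = k, ir_percent = ir,
                      n_events = n_events, valid_seconds = valid_sec,
                      valid_fraction = valid_frac)
  structure(list(hours = hours, events = events), class = "ir_profile")
}

#' Write the hourly-IR and event tables of a profile as CSV
#'
#' @param profile an [ir_profile_24h()] result.
#' @param out_prefix path prefix; writes `<prefix>_hours.csv` and
#'   `<prefix>_events.csv`.
#' @return the two paths, invisibly.
#' @export
write_ir_csv <- function(profile, out_prefix) {
  stopifnot(inherits(profile, "ir_profile"))
  hp <- paste0(out_prefix, "_hours.csv")
  ep <- paste0(out_prefix, "_events.csv")
  write.csv(profile$hours, hp, row.names = FALSE)
  ev <- profile$events
  ev$start_time <- format(ev$start_time, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  write.csv(ev, ep, row.names = FALSE)
  invisible(c(hours = hp, events = ep))
}
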