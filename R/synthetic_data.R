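# Synthetic road-traffic SPL generator: Poisson pass-by arrivals driven
# by a diurnal flow profile, moving-point-source level pulses over an
# energetic ambient background, Gaussian measurement noise. Produces
# cohorts with known regime labels and matching traffic-flow tables, in
# the same containers the analysis consumes.

# fixed diurnal flow shape (fraction of the daily peak): morning and
# evening peaks at hours 8 and 18, night trough at hours 2-4
FLOW_SHAPE <- c(0.04, 0.025, 0.02, 0.02, 0.02, 0.05, 0.10, 0.55,
                1.00, 0.85, 0.75, 0.72, 0.70, 0.72, 0.72, 0.75,
                0.82, 0.92, 1.00, 0.85, 0.50, 0.20, 0.07, 0.05)

# ambient (non-simulated-road) background schedule: day level for hours
# 8-19, night level for hours 22-5, linear shoulders in between
diurnal_background <- function(day_db, night_db) {
  bg <- rep(day_db, 24)
  bg[c(23, 24, 1:6)] <- night_db
  mid <- (day_db + night_db) / 2
  bg[c(7, 8, 21, 22)] <- c(mid, (day_db + mid) / 2, (day_db + mid) / 2, mid)
  bg
}

#' Road-class emission/geometry profile for the simulator
#'
#' Defaults follow the Italian functional classes: motorways ("A") are
#' fast, distant, high-emission and high-flow; urban local roads ("F")
#' slow, close, low-emission and low-flow. All values are configurable.
#'
#' @param road_class `"A"`, `"D"`, `"E"` or `"F"`.
#' @param peak_flow daily peak traffic flow, veh/h (scaled by the fixed
#'   bimodal diurnal shape, peaks at hours 8 and 18, trough at 2-4).
#' @param hourly_flow explicit 24-vector of flows, veh/h (overrides
#'   `peak_flow`).
#' @param speed travelling speed, km/h.
#' @param distance source-receiver distance, m.
#' @param emission_level mean maximum pass-by level at the receiver, dB.
#' @param emission_spread between-vehicle sd of the maximum level, dB.
#' @param heavy_fraction share of heavy vehicles.
#' @param heavy_offset emission offset of heavy vehicles, dB.
#' @param background_day,background_night ambient background SPL, dB
#'   (sources other than the simulated road).
#' @param background_level explicit 24-vector of ambient background, dB.
#' @param night_speed_boost relative speed increase when the flow is at
#'   its diurnal trough (free-flowing traffic at night is faster, which
#'   sharpens pass-by pulses and makes night events more prominent).
#' @return An object of class `road_class_profile`.
#' @export
road_class_profile <- function(road_class = c("A", "D", "E", "F"),
                               peak_flow = NULL, hourly_flow = NULL,
                               speed = NULL, distance = NULL,
                               emission_level = NULL, emission_spread = NULL,
                               heavy_fraction = NULL, heavy_offset = 6,
                               background_day = NULL, background_night = NULL,
                               background_level = NULL,
                               night_speed_boost = 0.35) {
  road_class <- match.arg(road_class)
  def <- switch(road_class,
    A = list(peak_flow = 2500, speed = 85, distance = 18,
             emission_level = 78, emission_spread = 3, heavy_fraction = 0.15,
             background_day = 52, background_night = 46),
    D = list(peak_flow = 1500, speed = 60, distance = 12,
             emission_level = 76, emission_spread = 3, heavy_fraction = 0.08,
             background_day = 52, background_night = 45),
    E = list(peak_flow = 600, speed = 50, distance = 8,
             emission_level = 74, emission_spread = 3.5, heavy_fraction = 0.05,
             background_day = 47, background_night = 41),
    F = list(peak_flow = 200, speed = 30, distance = 9,
             emission_level = 72, emission_spread = 4, heavy_fraction = 0.02,
             background_day = 45, background_night = 40))
  pick <- function(v, d) if (is.null(v)) d else v
  peak_flow <- pick(peak_flow, def$peak_flow)
  if (is.null(hourly_flow)) hourly_flow <- peak_flow * FLOW_SHAPE
  if (is.null(background_level))
    background_level <- diurnal_background(
      pick(background_day, def$background_day),
      pick(background_night, def$background_night))
  p <- list(road_class = road_class,
            hourly_flow = hourly_flow,
            speed = pick(speed, def$speed),
            distance = pick(distance, def$distance),
            emission_level = pick(emission_level, def$emission_level),
            emission_spread = pick(emission_spread, def$emission_spread),
            heavy_fraction = pick(heavy_fraction, def$heavy_fraction),
            heavy_offset = heavy_offset,
            background_level = background_level,
            night_speed_boost = night_speed_boost)
  stopifnot(length(p$hourly_flow) == 24, all(p$hourly_flow >= 0),
            p$speed > 0, p$distance > 0, p$emission_spread >= 0,
            length(p$background_level) == 24,
            p$heavy_fraction >= 0, p$heavy_fraction <= 1,
            p$night_speed_boost >= 0)
  structure(p, class = "road_class_profile")
}

#' Level pulse of a single vehicle pass-by (moving point source)
#'
#' `L(t) = l_max - 10*log10(1 + (v*(t - t0)/d)^2)` with v in m/s: peak
#' `l_max` when the vehicle passes the receiver at `t0`, symmetric
#' geometric decay, half-power (-3.01 dB) at `|t - t0| = d/v`.
#'
#' @param l_max maximum pass-by level at the receiver, dB.
#' @param speed vehicle speed, km/h.
#' @param distance source-receiver distance, m.
#' @param t0 pass-by time, s.
#' @param t evaluation time(s), s.
#' @return level(s) in dB.
#' @export
passby_pulse <- function(l_max, speed, distance, t0, t) {
  stopifnot(speed > 0, distance > 0)
  v <- speed / 3.6
  l_max - 10 * log10(1 + (v * (t - t0) / distance)^2)
}

#' Simulate one hour of 1-s SPL at a road-traffic site
#'
#' Pass-by count ~ Poisson(hourly flow), arrival times uniform in the
#' hour, per-vehicle maximum level ~ Normal(emission, spread) plus a heavy
#' offset with probability `heavy_fraction`. Per second, the total level
#' is the energetic sum of the ambient background and all active pulses,
#' plus Gaussian measurement noise. Uses the current RNG stream (seed the
#' caller).
#'
#' @param profile a [road_class_profile()].
#' @param hour hour of day, 0-23.
#' @param noise_sd measurement noise sd, dB (default 0.5).
#' @return numeric vector of 3600 levels, dB.
#' @export
simulate_hour <- function(profile, hour, noise_sd = 0.5) {
  stopifnot(inherits(profile, "road_class_profile"), hour %in% 0:23)
  bg_pow <- db_to_power(profile$background_level[hour + 1])
  pow <- rep(bg_pow, 3600L)
  n <- rpois(1, profile$hourly_flow[hour + 1])
  if (n > 0) {
    t0 <- runif(n, 0, 3600)
    lmax <- rnorm(n, profile$emission_level, profile$emission_spread) +
      profile$heavy_offset * rbinom(n, 1, profile$heavy_fraction)
    # lower flow lets traffic move faster (night speed-up)
    v <- profile$speed / 3.6 *
      (1 + profile$night_speed_boost * (1 - FLOW_SHAPE[hour + 1]))
    # truncate each pulse where it has fallen 25 dB below its peak
    w <- ceiling(sqrt(10^2.5 - 1) * profile$distance / v)
    off <- -w:w
    L <- length(off)
    idx <- rep(as.integer(round(t0)), each = L) + rep(off, times = n)
    dt <- idx - rep(t0, each = L)
    contrib <- rep(db_to_power(lmax), each = L) /
      (1 + (v * dt / profile$distance)^2)
    keep <- idx >= 1 & idx <= 3600
    if (any(keep)) {
      # accumulate by slot: sort, then sum runs of equal indices
      o <- order(idx[keep])
      si <- idx[keep][o]
      cs <- cumsum(contrib[keep][o])
      last <- c(which(diff(si) != 0), length(si))
      pow[si[last]] <- pow[si[last]] + cs[last] - c(0, cs[head(last, -1)])
    }
  }
  power_to_db(pow) + rnorm(3600L, 0, noise_sd)
}

#' Simulate a full site-day as an SPL series
#'
#' @param profile a [road_class_profile()].
#' @param site_id site identifier.
#' @param date calendar date of the simulated day.
#' @param noise_sd measurement noise sd, dB.
#' @return an [spl_series()] of 86400 samples (none masked).
#' @export
simulate_site_day <- function(profile, site_id, date = as.Date("2019-03-04"),
                              noise_sd = 0.5) {
  levels <- unlist(lapply(0:23, function(h)
    simulate_hour(profile, h, noise_sd)), use.names = FALSE)
  ts <- as.POSIXct(paste(as.Date(date), "00:00:00"), tz = "UTC") + 0:86399
  spl_series(site_id, profile$road_class, ts,
             pmin(pmax(levels, 0.1), 139.9))
}

#' Cohort simulation configuration
#'
#' The default cohort has two regimes mirroring the qualitative contrast
#' between busy arterial corridors and quiet local streets: 20 "arterial"
#' sites (thoroughfare class "D", daytime peak flows drawn uniformly in
#' 800-2000 veh/h, high ambient background) and 20 "local" sites (class
#' "F", peak flows 30-300 veh/h, low background), 3 weekdays each,
#' measurement noise sd 0.5 dB.
#'
#' @param sites_per_regime sites per regime (recycled over regimes).
#' @param regimes named list; each entry is a list with `road_class` and
#'   `peak_flow_range` plus any [road_class_profile()] override.
#' @param days_per_site monitored days per site.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param noise_sd measurement noise sd, dB.
#' @param flow_jitter relative perturbation of the reported flow table
#'   around the generating flows (0 = report exactly; 0.1 = +/-10%).
#' @param confounder if TRUE, the first `confounder_sites` sites of the
#'   last regime get a nearby-busy-street background added
#'   ([confound_with_busy_road()], daytime schedule `confounder_boost`).
#' @param confounder_sites number of confounded sites.
#' @param confounder_boost 24-vector: absolute SPL of the added busy-road
#'   background (dB); non-positive entries mean no addition.
#' @param site_bg_sd sd of the persistent per-site ambient-background
#'   offset, dB (monitoring positions differ in surrounding sources).
#' @param site_emission_sd sd of the persistent per-site emission offset,
#'   dB (pavement, facade reflections).
#' @param site_distance_range,site_speed_range multiplicative per-site
#'   ranges for receiver distance and travelling speed (microphone
#'   placement and road geometry vary between sites).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(sites_per_regime = 20,
                       regimes = list(
                         arterial = list(road_class = "D",
                                         peak_flow_range = c(800, 2000)),
                         local = list(road_class = "F",
                                      peak_flow_range = c(30, 300))),
                       days_per_site = 3, seed = 1, noise_sd = 0.5,
                       flow_jitter = 0, confounder = FALSE,
                       confounder_sites = 2,
                       confounder_boost = diurnal_background(57, 0),
                       site_bg_sd = 5, site_emission_sd = 1.5,
                       site_distance_range = c(0.8, 1.25),
                       site_speed_range = c(0.85, 1.15)) {
  stopifnot(length(regimes) >= 1, days_per_site >= 1, noise_sd >= 0,
            flow_jitter >= 0, flow_jitter < 1, site_bg_sd >= 0,
            site_emission_sd >= 0)
  structure(list(sites_per_regime = rep(sites_per_regime,
                                        length.out = length(regimes)),
                 regimes = regimes, days_per_site = days_per_site,
                 seed = seed, noise_sd = noise_sd, flow_jitter = flow_jitter,
                 confounder = confounder, confounder_sites = confounder_sites,
                 confounder_boost = confounder_boost,
                 site_bg_sd = site_bg_sd, site_emission_sd = site_emission_sd,
                 site_distance_range = site_distance_range,
                 site_speed_range = site_speed_range),
            class = "sim_config")
}

#' Simulate a labelled cohort of monitoring sites
#'
#' @param config a [sim_config()].
#' @return list with `series` (list of [spl_series()], one per site-day),
#'   `flows` (data frame site_id, hour, veh_per_h), `truth` (data frame
#'   site_id, regime, road_class), `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    series <- list()
    flows <- list()
    truth <- list()
    dates <- as.Date("2019-03-04") + seq_len(config$days_per_site) - 1
    site_no <- 0
    for (r in seq_along(config$regimes)) {
      rg <- config$regimes[[r]]
      rname <- names(config$regimes)[r]
      for (s in seq_len(config$sites_per_regime[r])) {
        site_no <- site_no + 1
        site_id <- sprintf("S%02d", site_no)
        peak <- runif(1, rg$peak_flow_range[1], rg$peak_flow_range[2])
        args <- rg[setdiff(names(rg), "peak_flow_range")]
        args$peak_flow <- peak
        profile <- do.call(road_class_profile, args)
        # persistent site idiosyncrasies: microphone placement, geometry,
        # pavement and surrounding sources differ between real sites
        profile$distance <- profile$distance *
          runif(1, config$site_distance_range[1], config$site_distance_range[2])
        profile$speed <- profile$speed *
          runif(1, config$site_speed_range[1], config$site_speed_range[2])
        profile$emission_level <- profile$emission_level +
          rnorm(1, 0, config$site_emission_sd)
        profile$background_level <- profile$background_level +
          rnorm(1, 0, config$site_bg_sd)
        confound <- config$confounder && r == length(config$regimes) &&
          s <= config$confounder_sites
        for (d in seq_along(dates)) {
          sd_series <- simulate_site_day(profile, site_id, dates[d],
                                         config$noise_sd)
          if (confound)
            sd_series <- confound_with_busy_road(sd_series,
                                                 config$confounder_boost)
          series[[paste0(site_id, "_", dates[d])]] <- sd_series
        }
        flow <- profile$hourly_flow
        if (config$flow_jitter > 0)
          flow <- flow * runif(24, 1 - config$flow_jitter,
                               1 + config$flow_jitter)
        flows[[site_id]] <- data.frame(site_id = site_id, hour = 0:23,
                                       veh_per_h = round(flow, 1))
        truth[[site_id]] <- data.frame(site_id = site_id, regime = rname,
                                       road_class = profile$road_class,
                                       confounded = confound)
      }
    }
    list(series = series, flows = do.call(rbind, c(flows, make.row.names = FALSE)),
         truth = do.call(rbind, c(truth, make.row.names = FALSE)),
         config = config)
  })
}

#' Energetically add a nearby-busy-street background to a series
#'
#' Every sample level becomes the energetic sum of itself and the
#' schedule's background for its hour of day:
#' `10*log10(10^(L/10) + 10^(B_h/10))`. Schedule entries that are not
#' positive switch the addition off for that hour, so an all-zero
#' schedule leaves the series unchanged. The boosted series is never
#' below the original.
#'
#' @param series an [spl_series()].
#' @param boost scalar or 24-vector of absolute background SPL, dB.
#' @return a new [spl_series()].
#' @export
confound_with_busy_road <- function(series, boost) {
  stopifnot(inherits(series, "spl_series"))
  boost <- rep(boost, length.out = 24)
  s <- series$samples
  hour <- as.integer(format(s$timestamp, "%H", tz = "UTC"))
  b <- boost[hour + 1]
  on <- b > 0
  level <- s$level
  level[on] <- power_to_db(db_to_power(level[on]) + db_to_power(b[on]))
  spl_series(series$site_id, series$road_class, s$timestamp,
             pmin(level, 139.9), s$masked)
}

#' Write a simulated cohort to disk in the monitoring formats
#'
#' One 4-column SPL file per site-day (`<site>_<date>.txt`), plus
#' `flows.csv` and `truth.csv`.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(cohort$series))
    write_spl_file(cohort$series[[nm]], file.path(dir, paste0(nm, ".txt")))
  write.csv(cohort$flows, file.path(dir, "flows.csv"), row.names = FALSE)
  write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
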