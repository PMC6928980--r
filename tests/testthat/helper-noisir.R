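# Shared fixture builders. Everything is generated in code; no files.

# a series of `n` seconds starting at date 00:00:00
make_series <- function(levels, masked = logical(length(levels)),
                        site_id = "S01", road_class = "F",
                        start = "2019-03-04 00:00:00") {
  ts <- as.POSIXct(start, tz = "UTC") + seq_along(levels) - 1
  spl_series(site_id, road_class, ts, levels, masked)
}

# a single hour window from a full 3600-vector of levels
make_window <- function(levels, masked = rep(FALSE, 3600L), hour = 10,
                        site_id = "S01") {
  stopifnot(length(levels) == 3600L)
  hour_window(site_id, as.Date("2019-03-04"), hour, levels, masked)
}

# random plausible SPL window: background + a few rectangular bursts
random_window <- function() {
  lv <- runif(3600, 35, 55)
  n_burst <- sample(0:6, 1)
  for (b in seq_len(n_burst)) {
    at <- sample(3500, 1)
    len <- sample(3:20, 1)
    lv[at:(at + len)] <- runif(1, 60, 85)
  }
  make_window(lv)
}

# independent one-pass energy-ratio oracle for IR
oracle_ir <- function(levels, offset_c = 3) {
  pw <- 10^(levels / 10)
  leq <- 10 * log10(mean(pw))
  100 * sum(pw[levels > leq + offset_c]) / sum(pw)
}

# brute-force exact two-sided Mann-Whitney p by enumerating assignments
oracle_mw_exact_p <- function(x, y) {
  n1 <- length(x)
  pool <- c(x, y)
  r <- rank(pool)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * length(y) / 2
  combs <- utils::combn(length(pool), n1)
  us <- apply(combs, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# small two-regime cohort for fast end-to-end tests
tiny_cohort_config <- function(seed = 1, sites = 4, days = 1) {
  sim_config(sites_per_regime = sites, days_per_site = days, seed = seed)
}
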