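test_that("passby_pulse has the closed-form peak, -3 dB point and width", {
  expect_equal(passby_pulse(80, 50, 10, 100, 100), 80)
  # v*|t - t0| = d -> 10*log10(2) = 3.01 dB below peak
  v <- 50 / 3.6
  t3 <- 100 + 10 / v
  expect_equal(passby_pulse(80, 50, 10, 100, t3), 80 - 10 * log10(2),
               tolerance = 1e-12)
  # half-width d/v shrinks as speed rises
  lv_slow <- passby_pulse(80, 30, 10, 0, 2)
  lv_fast <- passby_pulse(80, 90, 10, 0, 2)
  expect_gt(lv_slow, lv_fast)
  # symmetric decay
  expect_equal(passby_pulse(80, 50, 10, 100, 95),
               passby_pulse(80, 50, 10, 100, 105))
})

test_that("simulate_hour reflects flow, background and Poisson arrivals", {
  # zero flow: all samples near the background, no events above Leq + 3
  p0 <- road_class_profile("F", hourly_flow = rep(0, 24),
                           background_level = rep(45, 24))
  lv <- with_seed(1, simulate_hour(p0, 12))
  expect_length(lv, 3600)
  expect_lt(max(abs(lv - 45)), 4)      # within a few noise sd
  r <- intermittency_ratio(make_window(lv))
  expect_equal(r$n_events, 0)
  expect_equal(r$ir_percent, 0)

  # sparse loud pass-bys over quiet background: events dominate energy
  p10 <- road_class_profile("F", hourly_flow = rep(10, 24),
                            emission_level = 75, emission_spread = 1,
                            background_level = rep(40, 24))
  with_seed(7, {
    lv10 <- simulate_hour(p10, 12)
    r10 <- intermittency_ratio(make_window(lv10))
    expect_gt(r10$ir_percent, 80)
    expect_equal(r10$ir_percent, oracle_ir(lv10), tolerance = 1e-9)
  })

  # realized pass-by counts follow the Poisson mean over 200 seeded
  # hours at flow 30/h: count runs above a threshold 2 dB under the
  # (spread-free) peak, which isolates the ~1.5 s summit of each pulse
  # so near-simultaneous arrivals almost never merge
  with_seed(11, {
    flow <- 30
    p30 <- road_class_profile("F", hourly_flow = rep(flow, 24),
                              emission_level = 75, emission_spread = 0,
                              heavy_fraction = 0,
                              background_level = rep(30, 24))
    counts <- replicate(200, {
      lv <- simulate_hour(p30, 12, noise_sd = 0)
      nrow(detect_events(make_window(lv), 73))
    })
    expect_lt(abs(mean(counts) - flow), 3 * sqrt(flow / 200) + 0.5)
  })
})

test_that("cohorts are reproducible and correctly shaped", {
  cfg <- tiny_cohort_config(seed = 9, sites = 2, days = 1)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_equal(length(c1$series), 4)    # 2 regimes x 2 sites x 1 day
  expect_equal(nrow(c1$series[[1]]$samples), 86400)
  expect_identical(c1$series[["S01_2019-03-04"]]$samples,
                   c2$series[["S01_2019-03-04"]]$samples)
  expect_identical(c1$flows, c2$flows)
  expect_equal(nrow(c1$flows), 4 * 24)
  expect_equal(unique(c1$truth$regime), c("arterial", "local"))
  # flows table equals the generating profile (no jitter by default)
  expect_true(all(c1$flows$veh_per_h >= 0))
})

test_that("confound_with_busy_road adds energy only where scheduled", {
  s <- with_seed(5, simulate_site_day(road_class_profile("F", peak_flow = 80),
                                      "S01"))
  # all-zero schedule: unchanged
  expect_identical(confound_with_busy_road(s, 0)$samples$level,
                   s$samples$level)
  # daytime boost: level never decreases, and strictly rises in boosted hours
  sched <- rep(0, 24)
  sched[9:19] <- 55
  sb <- confound_with_busy_road(s, sched)
  expect_true(all(sb$samples$level >= s$samples$level - 1e-12))
  boosted <- as.integer(format(s$samples$timestamp, "%H")) %in% 8:18
  expect_true(all(sb$samples$level[boosted] > s$samples$level[boosted]))

  # confounding suppresses daytime IR relative to the unconfounded copy
  ir0 <- ir_profile_24h(s)$hours
  ir1 <- ir_profile_24h(sb)$hours
  day <- ir0$hour %in% 8:18
  expect_lt(mean(ir1$ir_percent[day]), mean(ir0$ir_percent[day]))
})

test_that("regime-level IR orderings match the intended sonic environments", {
  cfg <- sim_config(sites_per_regime = 3, days_per_site = 1, seed = 31)
  co <- simulate_cohort(cfg)
  hours <- do.call(rbind, lapply(co$series, function(s)
    ir_profile_24h(s)$hours))
  reg <- co$truth$regime[match(hours$site_id, co$truth$site_id)]
  day <- hours$hour %in% 8:19
  night <- hours$hour %in% c(22, 23, 0:5)
  # arterial daytime IR strictly below local daytime IR
  expect_lt(median(hours$ir_percent[day & reg == "arterial"]),
            median(hours$ir_percent[day & reg == "local"]))
  # night IR >= day IR on average for both regimes
  for (r in c("arterial", "local")) {
    expect_gte(mean(hours$ir_percent[night & reg == r]),
               mean(hours$ir_percent[day & reg == r]))
  }
})

test_that("IR falls with rising flow at fixed geometry (trend over seeds)", {
  flows <- c(50, 200, 800, 2000)
  mean_ir <- sapply(seq_along(flows), function(i) {
    f <- flows[i]
    p <- road_class_profile("D", hourly_flow = rep(f, 24))
    mean(sapply(1:20, function(s) with_seed(1000 + s * 7 + i, {
      intermittency_ratio(make_window(simulate_hour(p, 12)))$ir_percent
    })))
  })
  expect_true(all(diff(mean_ir) < 0))
})
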