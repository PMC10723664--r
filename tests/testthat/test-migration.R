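test_that("3-position straightness matches plane geometry", {
  east <- cbind(c(0, 0.1, 0.2, 0.3), rep(0, 4))
  expect_equal(straightness_3pt(east), 1, tolerance = 1e-9)

  # right-angle triple with equal ~10-km legs: sqrt(2)/2
  ctr <- c(-64.9, 32.3)
  tri <- aeqd_inverse(rbind(c(0, 0), c(10000, 0), c(10000, 10000)), ctr)
  expect_equal(straightness_3pt(tri), sqrt(2) / 2, tolerance = 1e-3)

  # zero-length steps are dropped before evaluation
  dup <- rbind(east[1, ], east)
  expect_equal(straightness_3pt(dup), 1, tolerance = 1e-9)
  expect_error(straightness_3pt(east[1:2, ]), "at least 3")
})

test_that("path metrics on a constant westward path recover rate, bearing, straightness", {
  t0 <- as.POSIXct("2015-09-01 00:00:00", tz = "UTC")
  n <- 60
  lat <- 30
  km_per_deg <- haversine_km(c(-60, lat), c(-59, lat))
  step_deg <- 2 * 2 / km_per_deg # 2 km/h for 2 h
  fx <- data.frame(timestamp = t0 + (0:(n - 1)) * 7200,
                   lon = -60 - (0:(n - 1)) * step_deg, lat = lat)
  pm <- path_metrics(fx)
  expect_equal(pm$rate_mean_kmh, 2, tolerance = 0.01)
  expect_lt(min(abs(pm$bearing_mean_deg - 270), 360 - abs(pm$bearing_mean_deg - 270)), 1)
  expect_gt(pm$straightness, 0.999)
  # path length bounds the end-to-end great-circle distance
  expect_gte(pm$total_path_km,
             haversine_km(c(fx$lon[1], fx$lat[1]), c(fx$lon[n], fx$lat[n])) - 1e-6)
})

test_that("steps across long transmission gaps are excluded from rate statistics", {
  t0 <- as.POSIXct("2015-09-01 00:00:00", tz = "UTC")
  fx <- data.frame(timestamp = t0 + c(0, 2, 4, 30, 32) * 3600,
                   lon = -60 - c(0, 0.04, 0.08, 0.60, 0.64), lat = 30)
  pm <- path_metrics(fx)
  expect_equal(sum(pm$steps$rate_ok), 3)
  expect_equal(nrow(pm$steps), 4)
})

test_that("current speed is averaged from per-fix velocity components", {
  fx <- line_fixes(5)
  fx$current_u <- c(0.3, 0.4, 0.5, 0.3, 0.4)
  fx$current_v <- c(0.4, 0.3, 0.0, 0.4, 0.3)
  pm <- path_metrics(fx)
  expect_equal(pm$current_mean_ms, mean(sqrt(fx$current_u^2 + fx$current_v^2)))
})

test_that("day and night travel rates are compared with a Welch test", {
  t0 <- as.POSIXct("2015-09-01 00:00:00", tz = "UTC")
  hit <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 200
    hrs <- (0:(n - 1)) * 2
    ts <- t0 + hrs * 3600
    ph <- photoperiod(ts + 3600, -60, 30)
    speed <- ifelse(ph == "day", 2.4, 2.0) + rnorm(n, 0, 0.3)
    steps <- data.frame(rate_kmh = speed, photoperiod = ph, rate_ok = TRUE)
    r <- day_night_rate_test(steps)
    if (r$rate_day > r$rate_night && r$p_value < 0.05) hit <- hit + 1
  }
  expect_gte(hit, 9)
  one_side <- data.frame(rate_kmh = rnorm(20, 2), photoperiod = "day", rate_ok = TRUE)
  expect_error(day_night_rate_test(one_side), "each photoperiod")
})

test_that("departures are detected and forays are not mistaken for them", {
  cfg <- sim_config(seed = 41, retention_prob = 0.6,
                    migration_start = as.POSIXct("2016-09-10", tz = "UTC"))
  ring <- make_platform_ring(cfg)
  tr <- simulate_track(cfg, 55)
  fx <- qc_pipeline(observe_fixes(tr, cfg))$fixes
  dep <- detect_departure(fx, ring)
  expect_false(is.null(dep))
  expect_lt(abs(as.numeric(difftime(dep$time, tr$truth$departure_time, units = "hours"))),
            24)

  # resident-only track: no departure
  cfg_res <- sim_config(seed = 42, retention_prob = 0.6)
  fx_res <- qc_pipeline(observe_fixes(simulate_track(cfg_res, 40), cfg_res))$fixes
  expect_null(detect_departure(fx_res, ring))

  # a 2-day outside loop with return is not a departure
  t0 <- as.POSIXct("2016-08-05", tz = "UTC")
  inside <- cfg$centers$release
  outside <- aeqd_inverse(cbind(15000, 0), inside)
  loop <- data.frame(tag_id = "t",
                     timestamp = t0 + c(0, 1, 2, 3, 4, 5, 6) * 86400,
                     lon = c(rep(inside[1], 2), rep(outside[1], 2), rep(inside[1], 3)),
                     lat = c(rep(inside[2], 2), rep(outside[2], 2), rep(inside[2], 3)))
  expect_null(detect_departure(loop, ring))
})

test_that("pre-departure forays of qualifying duration are recovered", {
  t0 <- as.POSIXct("2016-08-01", tz = "UTC")
  home <- c(-64.87, 32.27)
  away <- aeqd_inverse(cbind(5000, 0), home)
  # residence ring ~1 km around home
  th <- seq(0, 2 * pi, length.out = 33)[-1]
  ring95 <- aeqd_inverse(cbind(1000 * cos(th), 1000 * sin(th)), home)
  dep_time <- t0 + 25 * 86400
  days <- 0:24
  lon <- rep(home[1], 25); lat <- rep(home[2], 25)
  foray_days <- 10:16 # 6-day excursion, returns afterwards
  lon[foray_days] <- away[1]; lat[foray_days] <- away[2]
  fx <- data.frame(tag_id = "t", timestamp = t0 + days * 86400, lon = lon, lat = lat)
  fo <- detect_forays(fx, ring95, dep_time, window_days = 30)
  expect_length(fo, 1)
  expect_true(fo[[1]]$returned)
  expect_gte(fo[[1]]$duration_days, 4)
  expect_gt(fo[[1]]$max_displacement_m, 4000)

  # 2-day excursion is below the duration floor
  lon2 <- rep(home[1], 25); lat2 <- rep(home[2], 25)
  lon2[12:14] <- away[1]; lat2[12:14] <- away[2]
  fx2 <- data.frame(tag_id = "t", timestamp = t0 + days * 86400, lon = lon2, lat = lat2)
  expect_length(detect_forays(fx2, ring95, dep_time, window_days = 30), 0)

  # no excursions at all
  fx3 <- data.frame(tag_id = "t", timestamp = t0 + days * 86400,
                    lon = home[1], lat = home[2])
  expect_length(detect_forays(fx3, ring95, dep_time), 0)
})
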