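test_that("fix labelling applies the season, photoperiod, and habitat rules", {
  cfg <- sim_config(seed = 1)
  hab <- make_seagrass_habitat(cfg)
  fx <- data.frame(
    tag_id = "t",
    timestamp = as.POSIXct(c("2017-01-10 16:00:00", "2017-06-10 16:00:00",
                             "2017-06-10 04:00:00"), tz = "UTC"),
    lon = c(cfg$centers$foraging[1], cfg$centers$foraging[1], cfg$centers$refuge[1]),
    lat = c(cfg$centers$foraging[2], cfg$centers$foraging[2], cfg$centers$refuge[2]))
  lb <- label_fixes(fx, hab, make_bathymetry(cfg))
  expect_equal(lb$season, c("cool", "warm", "warm"))
  expect_equal(lb$photoperiod[2], "day") # local noon in June
  expect_equal(lb$photoperiod[3], "night")
  expect_true(lb$in_seagrass[1])
  expect_false(lb$in_seagrass[3])
  expect_gt(lb$bathymetric_depth[3], lb$bathymetric_depth[1])
})

test_that("distinct use areas are discovered and classified from a simulated track", {
  cfg <- sim_config(seed = 31, retention_prob = 0.6, outlier_prob = 0)
  tr <- simulate_track(cfg, 40)
  fx <- qc_pipeline(observe_fixes(tr, cfg))$fixes
  lb <- label_fixes(fx, make_seagrass_habitat(cfg), make_bathymetry(cfg))
  ua <- find_use_areas(lb, eps = 100, min_count = 10)
  kinds <- vapply(ua, function(a) a$kind, character(1))
  expect_setequal(kinds, c("foraging_f", "rest_day_r", "rest_night_r"))
  # every fix belongs to at most one area
  members <- unlist(lapply(ua, function(a) a$members))
  expect_equal(anyDuplicated(members), 0)
  # permuting input order leaves areas unchanged
  perm <- sample(nrow(lb))
  ua2 <- find_use_areas(lb[perm, ], eps = 100, min_count = 10)
  expect_setequal(vapply(ua2, function(a) a$kind, character(1)), kinds)
  sizes1 <- sort(vapply(ua, function(a) a$size_km2, numeric(1)))
  sizes2 <- sort(vapply(ua2, function(a) a$size_km2, numeric(1)))
  expect_equal(sizes1, sizes2, tolerance = 1e-9)
})

test_that("a deep winter-only cluster is overridden to a cool-weather refuge", {
  cfg <- sim_config(seed = 32, retention_prob = 0.8, outlier_prob = 0,
                    temp_amplitude = 7.75)
  tr <- simulate_track(cfg, 240) # spans warm season into winter
  fx <- qc_pipeline(observe_fixes(tr, cfg))$fixes
  lb <- label_fixes(fx, make_seagrass_habitat(cfg), make_bathymetry(cfg))
  ua <- find_use_areas(lb, eps = 100, min_count = 10)
  kinds <- vapply(ua, function(a) a$kind, character(1))
  expect_true("cool_refuge_c" %in% kinds)
  ref <- ua[[which(kinds == "cool_refuge_c")[1]]]
  expect_gte(ref$frac_cool, 0.8)
  expect_gte(ref$mean_depth_m, 1.5 * 2.5)
  d_truth <- haversine_km(ref$mean_center, cfg$centers$refuge) * 1000
  expect_lt(d_truth, 200)
})

test_that("mean-centre distances follow the haversine closed form", {
  ua <- structure(list(
    list(mean_center = c(lon = -64.9, lat = 32.30)),
    list(mean_center = c(lon = -64.9, lat = 32.31))), class = "use_area_list")
  d <- area_center_distances(ua)
  expect_equal(d[1, 2], 1111.9, tolerance = 0.5)
  expect_equal(d[1, 2], d[2, 1])
  expect_equal(d[1, 1], 0)
})

test_that("occupancy histograms bound proportions and detect the bimodal pattern", {
  cfg <- sim_config(seed = 33, retention_prob = 0.9, outlier_prob = 0)
  tr <- simulate_track(cfg, 40)
  fx <- qc_pipeline(observe_fixes(tr, cfg))$fixes
  lb <- label_fixes(fx, make_seagrass_habitat(cfg), make_bathymetry(cfg))
  oh <- occupancy_histogram(lb, season = "warm")
  p <- oh$proportion[!is.na(oh$proportion)]
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(oh$bimodality, 1)

  all_on <- lb; all_on$in_seagrass <- TRUE
  expect_true(all(occupancy_histogram(all_on, season = "warm")$proportion == 1,
                  na.rm = TRUE))
  none_on <- lb; none_on$in_seagrass <- FALSE
  expect_true(all(occupancy_histogram(none_on, season = "warm")$proportion == 0,
                  na.rm = TRUE))
})

test_that("weighted bin means use midpoints and the open-bin convention", {
  h1 <- list(bin_edges = c(1, 2, 3, 4, 5), proportions = c(0, 0, 1, 0, 0, 0))
  expect_equal(weighted_mean_bins(h1), 2.5)
  h2 <- list(bin_edges = c(1, 2, 3, 4), proportions = c(0, 0.5, 0, 0.5, 0))
  expect_equal(weighted_mean_bins(h2), 2.5)
  # open bin above 29 with preceding bin (24, 29]: midpoint 31.5
  h3 <- list(bin_edges = c(24, 29), proportions = c(0, 0, 1))
  expect_equal(weighted_mean_bins(h3), 31.5)
  expect_error(weighted_mean_bins(list(bin_edges = c(2, 2), proportions = c(0, 1, 0))),
               "zero-width")
})

test_that("distance-temperature correlation recovers exact linear dependence", {
  t0 <- as.POSIXct("2017-01-01", tz = "UTC")
  n <- 60
  temps <- 20 + 5 * sin(seq(0, 3 * pi, length.out = n))
  # fixes placed so displacement is exactly linear in (matched) temperature
  ctr <- c(-64.9, 32.3)
  d_m <- 5000 - 200 * temps
  ll <- aeqd_inverse(cbind(d_m, 0), ctr)
  fx <- data.frame(timestamp = t0 + (0:(n - 1)) * 86400, lon = ll[, 1], lat = ll[, 2])
  buoy <- data.frame(time = t0 + (0:(n - 1)) * 86400, temp_c = temps)
  res <- distance_temperature_correlation(fx, ctr, buoy)
  expect_equal(res$r, -1, tolerance = 1e-6)
  expect_equal(res$n, n)
  expect_lt(res$p_value, 1e-10)

  const <- buoy; const$temp_c <- 20
  expect_error(distance_temperature_correlation(fx, ctr, const), "constant")
})

test_that("independent displacement and temperature give near-zero correlation", {
  t0 <- as.POSIXct("2017-01-01", tz = "UTC")
  ok <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 200
    ll <- aeqd_inverse(cbind(rnorm(n, 2000, 500), rnorm(n, 0, 500)), c(-64.9, 32.3))
    fx <- data.frame(timestamp = t0 + (0:(n - 1)) * 86400, lon = ll[, 1], lat = ll[, 2])
    buoy <- data.frame(time = t0 + (0:(n - 1)) * 86400, temp_c = rnorm(n, 22, 3))
    if (abs(distance_temperature_correlation(fx, c(-64.9, 32.3), buoy)$r) < 0.2)
      ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("seasonal occupancy shift reports off-meadow use by photoperiod and season", {
  cfg <- sim_config(seed = 34, retention_prob = 0.8, temp_amplitude = 7.75)
  tr <- simulate_track(cfg, 240)
  fx <- qc_pipeline(observe_fixes(tr, cfg))$fixes
  lb <- label_fixes(fx, make_seagrass_habitat(cfg), make_bathymetry(cfg))
  tab <- seasonal_occupancy_shift(lb)
  expect_true(all(tab$prop_off_seagrass >= 0 & tab$prop_off_seagrass <= 1, na.rm = TRUE))
  day_warm <- tab$prop_off_seagrass[tab$photoperiod == "day" & tab$season == "warm"]
  day_cool <- tab$prop_off_seagrass[tab$photoperiod == "day" & tab$season == "cool"]
  # refuge use in winter pulls daytime fixes off the meadow
  expect_gt(day_cool, day_warm)

  all_on <- lb; all_on$in_seagrass <- TRUE
  expect_true(all(seasonal_occupancy_shift(all_on)$prop_off_seagrass == 0, na.rm = TRUE))
})
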