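#' Configuration for the central-place forager simulator
#'
#' Builds the parameter set for [simulate_track()] and [observe_fixes()]. The
#' movement model is a discrete-time biased random walk (Ornstein-Uhlenbeck
#' style attraction toward the active behavioural centre) stepped every 30
#' simulated minutes. The active centre follows a diel schedule in local time
#' (fixed UTC-4, Atlantic Standard Time), is overridden to a cool-weather
#' refuge while simulated water temperature is below `refuge_threshold`, and
#' switches to directed migratory travel after `migration_start`.
#'
#' Defaults emulate an immature green turtle resident on a shallow carbonate
#' platform: foraging on a seagrass meadow at dawn and dusk, resting off the
#' meadow by day and night at centres several hundred metres away, a deeper
#' refuge ~3 km away used during cold snaps, water temperature a seasonal
#' sinusoid (mean 23.9 degC, amplitude 7.75, summer maximum), and snapshot-GPS
#' observation at 2-h even-hour (GMT) epochs with satellite-count-dependent
#' position error.
#'
#' @param centers Named list of (lon, lat) centres for roles
#'   `foraging`, `day_rest`, `night_rest`, `refuge`, `release`.
#' @param attraction Named per-role pull strength (1/h).
#' @param step_sd Isotropic step noise, metres per 30-min step.
#' @param diel_schedule Integer vector of length 24 mapping local hour (0-23)
#'   to a role name.
#' @param temp_mean,temp_amplitude,temp_phase Water temperature sinusoid:
#'   mean degC, amplitude degC, and day-of-year of the maximum.
#' @param temp_ar_sd,temp_ar_phi Optional AR(1) noise on daily temperature.
#' @param refuge_threshold degC below which the refuge role overrides the
#'   schedule (default 20).
#' @param migration_start POSIXct (UTC) start of directed migration, or `NULL`.
#' @param migration_bearing Degrees true for migratory travel.
#' @param migration_speed km/h during migration.
#' @param persistence Directional concentration of migration steps; heading
#'   noise has circular sd `1/sqrt(persistence)` radians.
#' @param fix_interval Hours between scheduled fixes (even hours GMT).
#' @param retention_prob Probability a scheduled fix is actually obtained.
#' @param error_sd_good,error_sd_bad Position error sd (m) for fixes with >= 6
#'   and < 6 satellites respectively.
#' @param p_good_fix Probability a retained fix uses >= 6 satellites.
#' @param outlier_prob,outlier_km Probability and displacement of planted
#'   gross outliers.
#' @param role_depths Named per-role dive depth (m) used by
#'   [make_dive_histograms()].
#' @param depth_sd Within-role dive depth noise sd (m).
#' @param start POSIXct (UTC) start of the simulation.
#' @param seed Integer seed; identical configs and seeds give identical tracks.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(centers = NULL,
                       attraction = c(foraging = 1, day_rest = 1, night_rest = 1,
                                      refuge = 1, release = 1),
                       step_sd = 30,
                       diel_schedule = NULL,
                       temp_mean = 23.9, temp_amplitude = 7.75, temp_phase = 227,
                       temp_ar_sd = 0, temp_ar_phi = 0.8,
                       refuge_threshold = 20,
                       migration_start = NULL, migration_bearing = 230,
                       migration_speed = 2.27, persistence = 20,
                       fix_interval = 2, retention_prob = 0.3,
                       error_sd_good = 25, error_sd_bad = 250,
                       p_good_fix = 0.85,
                       outlier_prob = 0.02, outlier_km = 5,
                       role_depths = c(foraging = 2.5, day_rest = 8, night_rest = 7,
                                       refuge = 10.5, release = 2.5, migrating = 5),
                       depth_sd = 0.3,
                       start = as.POSIXct("2016-08-01 00:00:00", tz = "UTC"),
                       seed = 1L) {
  if (is.null(centers)) {
    # release on the meadow; rest sites a few hundred m off; refuge ~3 km away
    centers <- list(
      foraging   = c(-64.870, 32.270),
      day_rest   = c(-64.862, 32.270),
      night_rest = c(-64.870, 32.2762),
      refuge     = c(-64.845, 32.250),
      release    = c(-64.870, 32.270)
    )
  }
  if (is.null(diel_schedule)) {
    sched <- rep("night_rest", 24)
    sched[(6:9) + 1] <- "foraging"
    sched[(10:16) + 1] <- "day_rest"
    sched[(17:20) + 1] <- "foraging"
    diel_schedule <- sched
  }
  stopifnot(length(diel_schedule) == 24)
  probs <- c(retention_prob, p_good_fix, outlier_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (step_sd < 0 || error_sd_good < 0 || error_sd_bad < 0)
    stop("step_sd and error sds must be >= 0")
  cfg <- list(centers = centers, attraction = attraction, step_sd = step_sd,
              diel_schedule = diel_schedule,
              temp_mean = temp_mean, temp_amplitude = temp_amplitude,
              temp_phase = temp_phase, temp_ar_sd = temp_ar_sd,
              temp_ar_phi = temp_ar_phi,
              refuge_threshold = refuge_threshold,
              migration_start = migration_start,
              migration_bearing = migration_bearing,
              migration_speed = migration_speed, persistence = persistence,
              fix_interval = fix_interval, retention_prob = retention_prob,
              error_sd_good = error_sd_good, error_sd_bad = error_sd_bad,
              p_good_fix = p_good_fix,
              outlier_prob = outlier_prob, outlier_km = outlier_km,
              role_depths = role_depths, depth_sd = depth_sd,
              start = start, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulated daily water temperature
#'
#' Sinusoid of day-of-year with optional AR(1) noise (noise drawn under the
#' config seed so tracks are reproducible).
#'
#' @param config A [sim_config()].
#' @param dates Date vector.
#' @return degC per date.
#' @export
sim_water_temperature <- function(config, dates) {
  doy <- as.integer(format(dates, "%j"))
  base <- config$temp_mean +
    config$temp_amplitude * cos(2 * pi * (doy - config$temp_phase) / 365.25)
  if (config$temp_ar_sd > 0) {
    n <- length(dates)
    e <- numeric(n)
    innov <- stats::rnorm(n, 0, config$temp_ar_sd)
    e[1] <- innov[1]
    for (i in seq_len(n)[-1]) e[i] <- config$temp_ar_phi * e[i - 1] + innov[i]
    base <- base + e
  }
  base
}

#' Simulate a ground-truthed track
#'
#' Biased random walk at 30-min steps. Each step pulls the animal toward the
#' centre of the active role (diel schedule in AST, refuge override below the
#' temperature threshold, directed migration after `migration_start`) and adds
#' isotropic Gaussian noise. Truth labels record the active role per step.
#'
#' @param config A [sim_config()].
#' @param n_days Number of simulated days (>= 1).
#' @return List of class `sim_track` with elements `true_positions`
#'   (data.frame: time, lon, lat, state), `temperature` (per-day degC),
#'   `truth` (states, regime breakpoints, departure time), `config`,
#'   and the projection centre used internally.
#' @export
simulate_track <- function(config, n_days) {
  stopifnot(inherits(config, "sim_config"), n_days >= 1)
  roles_used <- unique(config$diel_schedule)
  unknown <- setdiff(roles_used, names(config$centers))
  if (length(unknown))
    stop("diel_schedule references unknown role(s): ", paste(unknown, collapse = ", "))
  if (!is.null(config$migration_start) && config$migration_start < config$start)
    stop("migration_start precedes the track start")

  set.seed(config$seed)
  dt_h <- 0.5
  n_steps <- as.integer(n_days * 24 / dt_h)
  times <- config$start + seq(0, by = dt_h * 3600, length.out = n_steps)

  dates <- unique(as.Date(times, tz = "UTC"))
  temp_by_day <- sim_water_temperature(config, dates)
  temp_step <- temp_by_day[match(as.Date(times, tz = "UTC"), dates)]

  local_hour <- (as.POSIXlt(times, tz = "UTC")$hour - 4) %% 24
  role <- config$diel_schedule[local_hour + 1]
  role[temp_step < config$refuge_threshold] <- "refuge"
  migrating <- if (is.null(config$migration_start)) rep(FALSE, n_steps)
               else times >= config$migration_start
  role[migrating] <- "migrating"

  proj_center <- config$centers$release
  centers_xy <- lapply(config$centers, function(c_)
    aeqd_project(matrix(c_, ncol = 2), center = proj_center)$xy[1, ])

  xy <- matrix(0, n_steps, 2)
  xy[1, ] <- centers_xy$release
  noise <- matrix(stats::rnorm(2 * n_steps, 0, config$step_sd), ncol = 2)
  head_noise <- stats::rnorm(n_steps, 0, 1 / sqrt(max(config$persistence, 1e-8)))
  for (i in seq_len(n_steps)[-1]) {
    p <- xy[i - 1, ]
    if (role[i] == "migrating") {
      theta <- (config$migration_bearing * pi / 180) + head_noise[i]
      step_m <- config$migration_speed * 1000 * dt_h
      p <- p + step_m * c(sin(theta), cos(theta)) + noise[i, ]
    } else {
      ctr <- centers_xy[[role[i]]]
      a <- config$attraction[[role[i]]]
      alpha <- 1 - exp(-a * dt_h)
      p <- p + alpha * (ctr - p) + noise[i, ]
    }
    xy[i, ] <- p
  }
  lonlat <- aeqd_inverse(xy, proj_center)

  regime <- ifelse(role == "migrating", "migrating",
                   ifelse(role == "refuge", "refuge", "resident"))
  bk <- which(diff(as.integer(factor(regime))) != 0) + 1L
  departure <- if (any(migrating)) times[which(migrating)[1]] else NULL

  out <- list(
    true_positions = data.frame(time = times, lon = lonlat[, 1],
                                lat = lonlat[, 2], state = role,
                                stringsAsFactors = FALSE),
    temperature = data.frame(date = dates, temp_c = temp_by_day),
    truth = list(states = role, breakpoints = times[bk], departure_time = departure),
    config = config, proj_center = proj_center, xy = xy
  )
  class(out) <- "sim_track"
  out
}

#' Observe a simulated track through the tag's duty cycle
#'
#' One candidate fix per scheduled even-hour (GMT) epoch, retained with
#' `retention_prob`. Retained fixes get Gaussian position error whose sd
#' depends on a drawn satellite count (>= 6 with probability `p_good_fix`),
#' plus occasional planted gross outliers. Residual-error scores are drawn so
#' that poor-quality fixes (few satellites or planted outliers) exceed the
#' conventional screening threshold of 30 with probability >= 0.9 while clean
#' fixes stay below it; the generator therefore has known quality-control
#' truth (columns `true_lon`, `true_lat`, `outlier`, `bad`).
#'
#' @param track A `sim_track`.
#' @param config The [sim_config()] used to build it.
#' @param tag_id Tag identifier stored on each fix.
#' @return data.frame of fixes: tag_id, timestamp, lon, lat, n_satellites,
#'   residual, source, plus truth columns.
#' @export
observe_fixes <- function(track, config = track$config, tag_id = "sim1") {
  stopifnot(inherits(track, "sim_track"))
  set.seed(config$seed + 1L)
  tp <- track$true_positions
  lt <- as.POSIXlt(tp$time, tz = "UTC")
  sched <- lt$min == 0 & lt$sec == 0 & (lt$hour %% config$fix_interval == 0)
  cand <- which(sched)
  keep <- cand[stats::runif(length(cand)) < config$retention_prob]
  n <- length(keep)
  if (n == 0) {
    return(data.frame(tag_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                      lon = numeric(), lat = numeric(), n_satellites = integer(),
                      residual = numeric(), source = character(),
                      true_lon = numeric(), true_lat = numeric(),
                      outlier = logical(), bad = logical()))
  }
  good <- stats::runif(n) < config$p_good_fix
  nsat <- ifelse(good, sample(6:10, n, replace = TRUE), sample(4:5, n, replace = TRUE))
  err_sd <- ifelse(good, config$error_sd_good, config$error_sd_bad)
  exy <- cbind(stats::rnorm(n, 0, 1), stats::rnorm(n, 0, 1)) * err_sd
  outlier <- stats::runif(n) < config$outlier_prob
  ang <- stats::runif(n, 0, 2 * pi)
  exy[outlier, 1] <- exy[outlier, 1] + config$outlier_km * 1000 * sin(ang[outlier])
  exy[outlier, 2] <- exy[outlier, 2] + config$outlier_km * 1000 * cos(ang[outlier])
  obs_xy <- track$xy[keep, , drop = FALSE] + exy
  lonlat <- aeqd_inverse(obs_xy, track$proj_center)
  bad <- !good | outlier
  # residuals: bad fixes exceed 30 w.p. 0.95; clean fixes never do
  residual <- ifelse(bad,
                     ifelse(stats::runif(n) < 0.95,
                            30 + stats::rexp(n, rate = 1 / 20),
                            stats::runif(n, 0, 30)),
                     stats::runif(n, 0, 25))
  data.frame(tag_id = tag_id, timestamp = tp$time[keep],
             lon = lonlat[, 1], lat = lonlat[, 2],
             n_satellites = as.integer(nsat), residual = residual,
             source = "fastloc",
             true_lon = tp$lon[keep], true_lat = tp$lat[keep],
             outlier = outlier, bad = bad,
             stringsAsFactors = FALSE)
}

#' Summarise simulated diving as time-at-depth histograms
#'
#' Each 30-min step contributes its role's configured depth plus noise; per
#' reporting period the proportions of time in each depth bin are returned.
#' Bins follow tag-archive convention: (0, e1], (e1, e2], ..., (em, Inf) for
#' strictly increasing upper edges e.
#'
#' @param track A `sim_track`.
#' @param bin_edges Strictly increasing numeric upper bin edges (m).
#' @param period_h Reporting period in hours (default 24).
#' @param variable Histogram variable label.
#' @param tag_id Tag identifier.
#' @return List of class `dive_histogram` elements: tag_id, period_start,
#'   period_end, variable, bin_edges, proportions (summing to 1).
#' @export
make_dive_histograms <- function(track, bin_edges, period_h = 24,
                                 variable = "depth_m", tag_id = "sim1") {
  stopifnot(inherits(track, "sim_track"))
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  config <- track$config
  set.seed(config$seed + 2L)
  tp <- track$true_positions
  depth <- config$role_depths[tp$state] +
    stats::rnorm(nrow(tp), 0, config$depth_sd)
  depth <- pmax(depth, 0.01)
  period_id <- floor(as.numeric(difftime(tp$time, tp$time[1], units = "hours")) / period_h)
  breaks <- c(0, bin_edges, Inf)
  out <- list()
  for (p in unique(period_id)) {
    idx <- period_id == p
    if (!any(idx)) next
    counts <- table(cut(depth[idx], breaks = breaks, right = TRUE))
    props <- as.numeric(counts) / sum(counts)
    out[[length(out) + 1]] <- list(
      tag_id = tag_id,
      period_start = min(tp$time[idx]),
      period_end = max(tp$time[idx]),
      variable = variable,
      bin_edges = bin_edges,
      proportions = props)
  }
  class(out) <- "dive_histogram_list"
  out
}
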