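#' Detect a departure from the platform
#'
#' The departure fix is the first fix outside the platform boundary that is
#' not followed by any inside fix within `no_return_days`. Brief outside
#' loops with a return (forays) are therefore not departures.
#'
#' @param fixes data.frame of QC-filtered fixes, sorted by time.
#' @param platform_ring Two-column lon/lat ring of the platform boundary.
#' @param no_return_days Return window, days (default 5).
#' @return List of class `departure` (`time`, `fix`, `nighttime`), or NULL
#'   when the animal never departs.
#' @export
detect_departure <- function(fixes, platform_ring, no_return_days = 5) {
  inside <- points_in_polygon(cbind(fixes$lon, fixes$lat), platform_ring)
  out_idx <- which(!inside)
  for (i in out_idx) {
    t0 <- fixes$timestamp[i]
    later_inside <- inside & fixes$timestamp > t0 &
      fixes$timestamp <= t0 + no_return_days * 86400
    if (!any(later_inside)) {
      night <- photoperiod(t0, fixes$lon[i], fixes$lat[i]) == "night"
      return(structure(list(time = t0, fix = fixes[i, , drop = FALSE],
                            nighttime = night, index = i),
                       class = "departure"))
    }
  }
  NULL
}

#' Detect pre-departure forays
#'
#' Maximal runs of fixes outside the residency 95% isopleth during the
#' `window_days` before departure, lasting between `min_d` and `max_d` days,
#' after which the animal either returns inside or proceeds directly to
#' departure.
#'
#' @param fixes data.frame of fixes sorted by time.
#' @param isopleth95_ring Two-column lon/lat ring of the residency 95%
#'   isopleth (e.g. the largest polygon from [isopleth()], back-projected).
#' @param departure_time POSIXct departure time from [detect_departure()].
#' @param window_days Pre-departure window examined (default 30).
#' @param min_d,max_d Duration bounds in days (default 4-15).
#' @return List of `foray` records: `start`, `end`, `duration_days`,
#'   `max_displacement_m` (from the isopleth centroid), `returned`.
#' @export
detect_forays <- function(fixes, isopleth95_ring, departure_time,
                          window_days = 30, min_d = 4, max_d = 15) {
  win <- fixes$timestamp >= departure_time - window_days * 86400 &
    fixes$timestamp < departure_time
  fx <- fixes[win, , drop = FALSE]
  if (nrow(fx) == 0) return(list())
  inside <- points_in_polygon(cbind(fx$lon, fx$lat), isopleth95_ring)
  runs <- rle(!inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ctr <- colMeans(isopleth95_ring)
  out <- list()
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    i0 <- starts[k]; i1 <- ends[k]
    dur <- as.numeric(difftime(fx$timestamp[i1], fx$timestamp[i0], units = "days"))
    if (dur < min_d || dur > max_d) next
    disp <- max(haversine_km(cbind(fx$lon[i0:i1], fx$lat[i0:i1]),
                             matrix(ctr, nrow = i1 - i0 + 1, ncol = 2,
                                    byrow = TRUE))) * 1000
    out[[length(out) + 1]] <- list(start = fx$timestamp[i0], end = fx$timestamp[i1],
                                   duration_days = dur,
                                   max_displacement_m = disp,
                                   returned = i1 < nrow(fx))
  }
  out
}

#' 3-position straightness index
#'
#' For each consecutive triple of positions (A, B, C) the ratio of the
#' straight-line distance d(A, C) to the travelled distance
#' d(A, B) + d(B, C); the overall index is the mean over triples.
#' Zero-length steps are dropped first. Equals 1 on a collinear forward path
#' and decreases with tortuosity.
#'
#' @param lonlat Two-column lon/lat matrix or data.frame with lon/lat.
#' @return Straightness in (0, 1].
#' @export
straightness_3pt <- function(lonlat) {
  if (is.data.frame(lonlat)) lonlat <- cbind(lonlat$lon, lonlat$lat)
  lonlat <- matrix(as.numeric(unlist(lonlat)), ncol = 2)
  n0 <- nrow(lonlat)
  if (n0 >= 2) {
    d <- haversine_km(lonlat[-n0, , drop = FALSE], lonlat[-1, , drop = FALSE])
    lonlat <- lonlat[c(TRUE, d > 1e-9), , drop = FALSE]
  }
  n <- nrow(lonlat)
  if (n < 3) stop("straightness needs at least 3 distinct positions")
  s <- vapply(seq_len(n - 2), function(i) {
    ab <- haversine_km(lonlat[i, ], lonlat[i + 1, ])
    bc <- haversine_km(lonlat[i + 1, ], lonlat[i + 2, ])
    ac <- haversine_km(lonlat[i, ], lonlat[i + 2, ])
    ac / (ab + bc)
  }, numeric(1))
  mean(s)
}

#' Metrics of a migration path
#'
#' Retains the pelagic portion of the track (bathymetric depth > 200 m when
#' depths are available, otherwise fixes outside the platform boundary, or
#' everything when neither is supplied) and computes step-wise metrics
#' between consecutive retained fixes: total path distance, circular mean
#' and SD of step initial bearings, 3-position straightness, and travel
#' rates. Steps longer than `dt_max_h` are excluded from rate statistics to
#' avoid biasing rates across transmission gaps. Day/night rates use the
#' photoperiod at each step's midpoint. When `current_u`/`current_v`
#' columns are present the mean current speed sqrt(u^2 + v^2) is reported.
#'
#' @param fixes data.frame of fixes sorted by time (`timestamp`, `lon`,
#'   `lat`, optional `depth`, `current_u`, `current_v`).
#' @param platform_ring Optional lon/lat ring for the pelagic mask.
#' @param depth_m Optional per-fix bathymetric depth (positive down).
#' @param dt_max_h Step-duration cutoff for rate statistics (default 12).
#' @return List of class `path_metrics`: `n_fixes`, `total_path_km`,
#'   `bearing_mean_deg`, `bearing_sd_deg`, `straightness`, `rate_mean_kmh`,
#'   `rate_sd_kmh`, `rate_day_kmh`, `rate_night_kmh`, `current_mean_ms`,
#'   and the per-step table `steps`.
#' @export
path_metrics <- function(fixes, platform_ring = NULL, depth_m = NULL,
                         dt_max_h = 12) {
  keep <- rep(TRUE, nrow(fixes))
  if (!is.null(depth_m)) keep <- !is.na(depth_m) & depth_m > 200
  else if (!is.null(platform_ring))
    keep <- !points_in_polygon(cbind(fixes$lon, fixes$lat), platform_ring)
  fx <- fixes[keep, , drop = FALSE]
  if (nrow(fx) < 2) stop("need at least 2 pelagic fixes")
  n <- nrow(fx)
  a <- cbind(fx$lon[-n], fx$lat[-n])
  b <- cbind(fx$lon[-1], fx$lat[-1])
  dist_km <- haversine_km(a, b)
  dt_h <- as.numeric(difftime(fx$timestamp[-1], fx$timestamp[-n], units = "hours"))
  brg <- bearing_deg(a, b)
  mid_t <- fx$timestamp[-n] + dt_h * 1800
  mid_lon <- (fx$lon[-n] + fx$lon[-1]) / 2
  mid_lat <- (fx$lat[-n] + fx$lat[-1]) / 2
  photo <- photoperiod(mid_t, mid_lon, mid_lat)
  rate <- dist_km / pmax(dt_h, 1e-9)
  rate_ok <- dt_h <= dt_max_h & dt_h > 0
  if (!any(rate_ok)) warning("all steps exceed the rate duration cutoff; rates undefined")
  cb <- circular_mean_deg(brg)
  current <- NA_real_
  if (!is.null(fx$current_u) && !is.null(fx$current_v)) {
    spd <- sqrt(fx$current_u^2 + fx$current_v^2)
    current <- mean(spd, na.rm = TRUE)
  }
  steps <- data.frame(dist_km = dist_km, dt_h = dt_h, rate_kmh = rate,
                      bearing = brg, photoperiod = photo, rate_ok = rate_ok)
  structure(list(
    n_fixes = n,
    total_path_km = sum(dist_km),
    bearing_mean_deg = cb$mean, bearing_sd_deg = cb$sd,
    straightness = if (n >= 3) straightness_3pt(cbind(fx$lon, fx$lat)) else NA,
    rate_mean_kmh = if (any(rate_ok)) mean(rate[rate_ok]) else NA,
    rate_sd_kmh = if (sum(rate_ok) > 1) stats::sd(rate[rate_ok]) else NA,
    rate_day_kmh = if (any(rate_ok & photo == "day")) mean(rate[rate_ok & photo == "day"]) else NA,
    rate_night_kmh = if (any(rate_ok & photo == "night")) mean(rate[rate_ok & photo == "night"]) else NA,
    current_mean_ms = current,
    steps = steps),
    class = "path_metrics")
}

#' Compare day and night travel rates
#'
#' Two-sided Welch two-sample t test of step travel rates by photoperiod.
#'
#' @param pm A `path_metrics` result (or a data.frame of steps with
#'   `rate_kmh`, `photoperiod`, `rate_ok`).
#' @param min_steps Minimum steps required per photoperiod (default 5).
#' @return List: `rate_day`, `rate_night`, `p_value`, `n_day`, `n_night`.
#' @export
day_night_rate_test <- function(pm, min_steps = 5) {
  steps <- if (inherits(pm, "path_metrics")) pm$steps else pm
  steps <- steps[steps$rate_ok, , drop = FALSE]
  rd <- steps$rate_kmh[steps$photoperiod == "day"]
  rn <- steps$rate_kmh[steps$photoperiod == "night"]
  if (length(rd) < min_steps || length(rn) < min_steps)
    stop("need at least ", min_steps, " steps in each photoperiod")
  tt <- stats::t.test(rd, rn)
  list(rate_day = mean(rd), rate_night = mean(rn), p_value = tt$p.value,
       n_day = length(rd), n_night = length(rn))
}
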