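#' Label fixes with photoperiod, season, habitat, and depth
#'
#' Photoperiod comes from solar elevation at the fix position and time
#' (day = centre of the sun above the horizon). Season follows the month
#' rule for a high-latitude platform: warm = May-Nov, cool = Dec-April
#' (months taken in local time, fixed UTC-4). Seagrass membership is a
#' point-in-polygon test against the habitat map; bathymetric depth is
#' sampled from the supplied bathymetry.
#'
#' @param fixes data.frame of fixes with `timestamp`, `lon`, `lat`.
#' @param habitat A [habitat_map()] (or NULL: `in_seagrass` all FALSE).
#' @param bathymetry Either a function(lon, lat) returning depth in metres
#'   (positive down), or a list with vectors `x` (lon), `y` (lat) and matrix
#'   `z` for bilinear lookup, or NULL.
#' @return The input with columns `photoperiod`, `season`, `in_seagrass`,
#'   `bathymetric_depth` (NA and flagged when outside the bathymetry extent).
#' @export
label_fixes <- function(fixes, habitat = NULL, bathymetry = NULL) {
  out <- fixes
  out$photoperiod <- photoperiod(fixes$timestamp, fixes$lon, fixes$lat)
  mo <- as.integer(format(fixes$timestamp - 4 * 3600, "%m", tz = "UTC"))
  out$season <- ifelse(mo %in% 5:11, "warm", "cool")
  out$in_seagrass <- FALSE
  if (!is.null(habitat)) {
    pts <- cbind(fixes$lon, fixes$lat)
    for (ring in habitat_rings(habitat, "seagrass"))
      out$in_seagrass <- out$in_seagrass | points_in_polygon(pts, ring)
  }
  out$bathymetric_depth <- NA_real_
  if (!is.null(bathymetry)) {
    if (is.function(bathymetry)) {
      out$bathymetric_depth <- bathymetry(fixes$lon, fixes$lat)
    } else {
      out$bathymetric_depth <- .bilinear(bathymetry, fixes$lon, fixes$lat)
    }
    if (anyNA(out$bathymetric_depth))
      out$depth_missing <- is.na(out$bathymetric_depth)
  }
  out
}

.bilinear <- function(grid, lon, lat) {
  ix <- findInterval(lon, grid$x)
  iy <- findInterval(lat, grid$y)
  out <- rep(NA_real_, length(lon))
  ok <- ix >= 1 & ix < length(grid$x) & iy >= 1 & iy < length(grid$y)
  if (!any(ok)) return(out)
  x1 <- grid$x[ix[ok]]; x2 <- grid$x[ix[ok] + 1]
  y1 <- grid$y[iy[ok]]; y2 <- grid$y[iy[ok] + 1]
  tx <- (lon[ok] - x1) / (x2 - x1)
  ty <- (lat[ok] - y1) / (y2 - y1)
  z11 <- grid$z[cbind(ix[ok], iy[ok])]
  z21 <- grid$z[cbind(ix[ok] + 1, iy[ok])]
  z12 <- grid$z[cbind(ix[ok], iy[ok] + 1)]
  z22 <- grid$z[cbind(ix[ok] + 1, iy[ok] + 1)]
  out[ok] <- z11 * (1 - tx) * (1 - ty) + z21 * tx * (1 - ty) +
    z12 * (1 - tx) * ty + z22 * tx * ty
  out
}

## density-connected clustering (DBSCAN-style) in projected metres
.density_cluster <- function(xy, eps, min_count) {
  n <- nrow(xy)
  d2 <- as.matrix(stats::dist(xy))^2
  eps2 <- eps^2
  nbr <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps2))
  core <- vapply(nbr, length, integer(1)) >= min_count
  cluster <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || cluster[i] != 0L) next
    cur <- cur + 1L
    frontier <- i
    cluster[i] <- cur
    while (length(frontier)) {
      nxt <- unique(unlist(nbr[frontier]))
      nxt <- nxt[cluster[nxt] == 0L]
      cluster[nxt] <- cur
      frontier <- nxt[core[nxt]]
    }
  }
  cluster
}

## convex buffer of a point set: hull of circles of radius r around hull points
.buffered_hull <- function(xy, r, n_arc = 24) {
  hi <- grDevices::chull(xy)
  hp <- xy[hi, , drop = FALSE]
  th <- seq(0, 2 * pi, length.out = n_arc + 1)[-1]
  ring <- do.call(rbind, lapply(seq_len(nrow(hp)), function(i)
    cbind(hp[i, 1] + r * cos(th), hp[i, 2] + r * sin(th))))
  ring[grDevices::chull(ring), , drop = FALSE]
}

#' Discover and classify distinct use areas
#'
#' Density-connected clustering of labelled fixes in projected coordinates
#' (neighbourhood radius `eps`, minimum neighbourhood size `min_count`)
#' replaces manual digitisation of location clusters. Each cluster becomes a
#' use area whose polygon is the convex hull buffered by `eps / 2`.
#' Classification: clusters whose fixes are mostly on seagrass are foraging
#' (on-meadow foraging and resting cannot be separated and are reported as
#' the combined f/r class); off-meadow clusters are day or night resting
#' areas by photoperiod majority; any cluster with at least
#' `refuge_cool_frac` of fixes in the cool season and mean depth at least
#' `refuge_depth_ratio` times the animal's foraging-area depth is overridden
#' to a cool-weather refuge.
#'
#' @param labeled data.frame from [label_fixes()].
#' @param eps Neighbourhood radius, m (default 100, the scale of Fastloc
#'   positional accuracy for >= 6-satellite solutions).
#' @param min_count Minimum neighbours for a core point (default 15).
#' @param refuge_cool_frac Cool-season fraction triggering the refuge
#'   override (default 0.8).
#' @param refuge_depth_ratio Depth ratio (vs foraging areas) for the
#'   override (default 1.5).
#' @return List of class `use_area_list`; each element has `kind`
#'   (foraging_f, rest_day_r, rest_night_r, cool_refuge_c), `polygon`
#'   (lon/lat ring), `size_km2`, `mean_depth_m`, `mean_center`, `n`,
#'   `usage_timing` (proportions by photoperiod x season), and the member
#'   row indices.
#' @export
find_use_areas <- function(labeled, eps = 100, min_count = 15,
                           refuge_cool_frac = 0.8, refuge_depth_ratio = 1.5) {
  stopifnot(nrow(labeled) >= min_count)
  pr <- aeqd_project(cbind(labeled$lon, labeled$lat))
  xy <- pr$xy
  cl <- .density_cluster(xy, eps, min_count)
  ids <- setdiff(sort(unique(cl)), 0L)
  if (!length(ids)) {
    message("no density-connected clusters found")
    return(structure(list(), class = "use_area_list"))
  }
  areas <- lapply(ids, function(k) {
    idx <- which(cl == k)
    sg <- mean(labeled$in_seagrass[idx])
    day <- mean(labeled$photoperiod[idx] == "day")
    cool <- mean(labeled$season[idx] == "cool")
    depth <- mean(labeled$bathymetric_depth[idx], na.rm = TRUE)
    kind <- if (sg >= 0.5) "foraging_f"
            else if (day >= 0.5) "rest_day_r"
            else "rest_night_r"
    ring_xy <- .buffered_hull(xy[idx, , drop = FALSE], eps / 2)
    ring_ll <- aeqd_inverse(ring_xy, pr$center)
    timing <- prop.table(table(factor(labeled$photoperiod[idx], c("day", "night")),
                               factor(labeled$season[idx], c("warm", "cool"))))
    list(kind = kind, polygon = ring_ll,
         size_km2 = polygon_area_m2(ring_xy) / 1e6,
         mean_depth_m = depth, frac_seagrass = sg, frac_day = day,
         frac_cool = cool,
         mean_center = c(lon = mean(labeled$lon[idx]), lat = mean(labeled$lat[idx])),
         n = length(idx), usage_timing = timing, members = idx)
  })
  forage_depth <- mean(vapply(
    Filter(function(a) a$kind == "foraging_f", areas),
    function(a) a$mean_depth_m, numeric(1)))
  if (is.finite(forage_depth)) {
    areas <- lapply(areas, function(a) {
      if (!is.na(a$mean_depth_m) && a$frac_cool >= refuge_cool_frac &&
          a$mean_depth_m >= refuge_depth_ratio * forage_depth)
        a$kind <- "cool_refuge_c"
      a
    })
  }
  structure(areas, class = "use_area_list")
}

#' Pairwise distances between use-area mean centres
#'
#' @param use_areas A `use_area_list`.
#' @return Symmetric matrix of great-circle distances in metres.
#' @export
area_center_distances <- function(use_areas) {
  stopifnot(length(use_areas) >= 2)
  ctr <- do.call(rbind, lapply(use_areas, function(a) a$mean_center))
  n <- nrow(ctr)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    m[i, j] <- haversine_km(ctr[i, ], ctr[j, ]) * 1000
  m
}

#' Diel seagrass-occupancy histogram
#'
#' For each even local hour (AST, fixed UTC-4) the fraction of that hour's
#' fixes lying on seagrass. A bimodality statistic compares mean occupancy in
#' the morning/evening foraging bins (06, 08, 18, 20 h) to the mid-day bins
#' (10, 12, 14 h); values above 1 indicate the twice-daily foraging pattern.
#'
#' @param labeled data.frame from [label_fixes()].
#' @param season Restrict to a season ("warm", "cool", or NULL for all).
#' @return List of class `occupancy_histogram`: `hour` (even hours 0-22),
#'   `proportion`, `n`, `bimodality`.
#' @export
occupancy_histogram <- function(labeled, season = "warm") {
  if (!is.null(season)) labeled <- labeled[labeled$season == season, , drop = FALSE]
  hr <- (as.integer(format(labeled$timestamp, "%H", tz = "UTC")) - 4) %% 24
  hours <- seq(0, 22, by = 2)
  prop <- rep(NA_real_, length(hours))
  n <- integer(length(hours))
  for (i in seq_along(hours)) {
    idx <- hr == hours[i]
    n[i] <- sum(idx)
    if (n[i] > 0) prop[i] <- mean(labeled$in_seagrass[idx])
  }
  am_pm <- prop[hours %in% c(6, 8, 18, 20)]
  mid <- prop[hours %in% c(10, 12, 14)]
  bim <- if (all(is.na(mid)) || mean(mid, na.rm = TRUE) == 0) NA_real_
         else mean(am_pm, na.rm = TRUE) / mean(mid, na.rm = TRUE)
  structure(list(hour = hours, proportion = prop, n = n, bimodality = bim),
            class = "occupancy_histogram")
}

#' Weighted mean of a binned histogram
#'
#' Bin midpoints weighted by the proportion of time in each bin. With upper
#' edges e1 < ... < em the bins are (0, e1], (e1, e2], ..., (em, Inf); the
#' open top bin's midpoint is em plus half the width of the preceding bin.
#'
#' @param hist A single histogram element from [make_dive_histograms()], or a
#'   list with `bin_edges` and `proportions`.
#' @return Weighted mean on the histogram's scale.
#' @export
weighted_mean_bins <- function(hist) {
  e <- hist$bin_edges
  p <- hist$proportions
  if (any(diff(e) <= 0)) stop("zero-width or decreasing bin")
  stopifnot(length(p) == length(e) + 1)
  m <- length(e)
  lower <- c(0, e)
  upper <- c(e, NA)
  mid <- (lower + upper) / 2
  prev_w <- if (m >= 2) e[m] - e[m - 1] else e[1]
  mid[m + 1] <- e[m] + prev_w / 2
  sum(mid * p)
}

#' Correlation of displacement from the core area with water temperature
#'
#' Each fix's great-circle distance to the core-area (25% UD) mean centre is
#' paired with the buoy temperature nearest in time (within `max_match_h`),
#' aggregated to daily means, and tested with Pearson's product-moment
#' correlation.
#'
#' @param labeled data.frame of fixes (needs `timestamp`, `lon`, `lat`).
#' @param center (lon, lat) of the 25% UD mean centre.
#' @param buoy A `temperature_series`.
#' @param max_match_h Maximum time offset for temperature matching, hours.
#' @return List of class `correlation_result`: `r`, `n`, `p_value`.
#' @export
distance_temperature_correlation <- function(labeled, center, buoy,
                                             max_match_h = 24) {
  d_m <- haversine_km(cbind(labeled$lon, labeled$lat),
                      matrix(center, nrow = nrow(labeled), ncol = 2, byrow = TRUE)) * 1000
  bt <- as.numeric(buoy$time)
  ft <- as.numeric(labeled$timestamp)
  idx <- findInterval(ft, bt, all.inside = TRUE)
  idx2 <- pmin(idx + 1, length(bt))
  use_hi <- abs(bt[idx2] - ft) < abs(bt[idx] - ft)
  near <- ifelse(use_hi, idx2, idx)
  dt_h <- abs(bt[near] - ft) / 3600
  ok <- dt_h <= max_match_h
  day <- as.Date(labeled$timestamp[ok], tz = "UTC")
  dd <- tapply(d_m[ok], day, mean)
  tt <- tapply(buoy$temp_c[near][ok], day, mean)
  if (length(dd) < 3) stop("fewer than 3 matched days; correlation undefined")
  if (stats::sd(tt) == 0 || stats::sd(dd) == 0)
    stop("constant series; correlation undefined")
  ct <- stats::cor.test(dd, tt, method = "pearson")
  structure(list(r = unname(ct$estimate), n = length(dd),
                 p_value = ct$p.value),
            class = "correlation_result")
}

#' Off-seagrass occupancy by photoperiod and season
#'
#' @param labeled data.frame from [label_fixes()].
#' @return data.frame: photoperiod, season, prop_off_seagrass, n. Missing
#'   season/photoperiod cells are reported with a message.
#' @export
seasonal_occupancy_shift <- function(labeled) {
  combos <- expand.grid(photoperiod = c("day", "night"),
                        season = c("warm", "cool"), stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    idx <- labeled$photoperiod == combos$photoperiod[i] &
      labeled$season == combos$season[i]
    data.frame(photoperiod = combos$photoperiod[i], season = combos$season[i],
               prop_off_seagrass = if (any(idx)) mean(!labeled$in_seagrass[idx]) else NA,
               n = sum(idx))
  }))
  if (anyNA(out$prop_off_seagrass))
    message("some photoperiod x season cells have no fixes")
  out
}
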