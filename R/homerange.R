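## Kernel utilization distributions, isopleths, smoothing-parameter selection,
## and minimum convex polygons. All computation happens on a local planar
## projection in metres; areas are reported in km^2.

.make_grid <- function(xy, h, cell_size, pad_factor = 3) {
  pad <- pad_factor * h
  gx <- seq(min(xy[, 1]) - pad, max(xy[, 1]) + pad + cell_size, by = cell_size)
  gy <- seq(min(xy[, 2]) - pad, max(xy[, 2]) + pad + cell_size, by = cell_size)
  list(x = gx, y = gy)
}

.kde_on_grid <- function(xy, h, grid) {
  # separable bivariate Gaussian kernel: density[i, j] at (x_i, y_j)
  gx <- grid$x; gy <- grid$y
  Kx <- stats::dnorm(outer(gx, xy[, 1], "-") / h) # nx x n
  Ky <- stats::dnorm(outer(gy, xy[, 2], "-") / h) # ny x n
  z <- (Kx %*% t(Ky)) / (nrow(xy) * h^2)
  z
}

#' Kernel utilization distribution on a regular grid
#'
#' Bivariate Gaussian kernel density of projected fixes, normalised so that
#' density times cell area sums to one. The grid extends at least
#' `pad_factor * h` beyond the data bounding box.
#'
#' @param xy Two-column matrix of projected coordinates (m), or a data.frame
#'   of fixes with lon/lat (projected internally; the projection centre is
#'   stored on the result).
#' @param h Gaussian kernel smoothing parameter, metres.
#' @param cell_size Grid cell edge, metres (default 50).
#' @param pad_factor Grid padding in units of `h` (default 3).
#' @return List of class `ud_grid`: `x`, `y` (cell centres, m), `z` (density
#'   matrix, x by y), `cell_size`, `h`, and `proj_center` when projected here.
#' @export
kde_ud <- function(xy, h, cell_size = 50, pad_factor = 3) {
  proj_center <- NULL
  if (is.data.frame(xy)) {
    pr <- aeqd_project(cbind(xy$lon, xy$lat))
    proj_center <- pr$center
    xy <- pr$xy
  }
  xy <- matrix(as.numeric(unlist(xy)), ncol = 2)
  if (nrow(xy) < 5) stop("kernel UD needs at least 5 points")
  if (h <= 0) stop("smoothing parameter h must be positive")
  if (all(apply(xy, 2, stats::var) < 1e-12))
    stop("degenerate points (all identical); supply a minimum h and jitter or more data")
  grid <- .make_grid(xy, h, cell_size, pad_factor)
  z <- .kde_on_grid(xy, h, grid)
  mass <- sum(z) * cell_size^2
  z <- z / mass
  structure(list(x = grid$x, y = grid$y, z = z, cell_size = cell_size, h = h,
                 proj_center = proj_center),
            class = "ud_grid")
}

## connected components of a logical matrix, 8-connectivity
.label_components <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  labels <- matrix(0L, nx, ny)
  cur <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    frontier <- start
    labels[start] <- cur
    while (length(frontier)) {
      i <- (frontier - 1L) %% nx + 1L
      j <- (frontier - 1L) %/% nx + 1L
      nbr <- integer(0)
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- i + di; jj <- j + dj
        ok <- ii >= 1 & ii <= nx & jj >= 1 & jj <= ny
        nbr <- c(nbr, (jj[ok] - 1L) * nx + ii[ok])
      }
      nbr <- unique(nbr)
      nbr <- nbr[mask[nbr] & labels[nbr] == 0L]
      labels[nbr] <- cur
      frontier <- nbr
    }
  }
  list(labels = labels, n = cur)
}

#' Isopleth of a utilization distribution
#'
#' The smallest-area region containing `level` of the total mass: cells are
#' ranked by density, the cumulative-mass cutoff defines the level set, and
#' the set is polygonised by contouring at the cutoff density. Contiguity is
#' the 8-connectivity of the level-set cells.
#'
#' @param ud A `ud_grid` from [kde_ud()].
#' @param level Mass level in (0, 1), e.g. 0.50 or 0.95.
#' @return List of class `isopleth`: `level`, `area_km2` (level-set cell
#'   count times cell area), `threshold` (density cutoff), `n_parts`,
#'   `contiguous`, `mask`, and `polygons` (list of x/y contour data.frames).
#' @export
isopleth <- function(ud, level) {
  stopifnot(inherits(ud, "ud_grid"), level > 0, level < 1)
  cell_area <- ud$cell_size^2
  dens <- as.numeric(ud$z)
  ord <- order(dens, decreasing = TRUE)
  cum_mass <- cumsum(dens[ord]) * cell_area
  k <- which(cum_mass >= level)[1]
  if (is.na(k)) stop("requested mass level unreachable on this grid; increase padding")
  threshold <- dens[ord][k]
  mask <- ud$z >= threshold
  comp <- .label_components(mask)
  polys <- grDevices::contourLines(ud$x, ud$y, ud$z, levels = threshold)
  structure(list(level = level,
                 area_km2 = sum(mask) * cell_area / 1e6,
                 threshold = threshold,
                 n_parts = comp$n,
                 contiguous = comp$n == 1L,
                 mask = mask,
                 polygons = polys),
            class = "isopleth")
}

#' Contiguity-based ad hoc smoothing-parameter selection
#'
#' Starts from the reference smoothing h0 = sigma * n^(-1/6) with
#' sigma = sqrt((var_x + var_y) / 2), then repeatedly shrinks h by `shrink`
#' while the `level` isopleth remains a single connected region; returns the
#' smallest h whose isopleth is still contiguous. If h0 itself yields a
#' non-contiguous isopleth the rule cannot be satisfied and h0 is returned
#' with `satisfied = FALSE`.
#'
#' @param xy Projected coordinates (m) or data.frame with lon/lat.
#' @param level Isopleth level checked for contiguity (default 0.95).
#' @param shrink Multiplicative shrink factor per iteration (default 0.95).
#' @param cell_size Grid cell edge, m.
#' @param max_iter Iteration cap.
#' @return List: `h`, `h0`, `satisfied`, `iterations`.
#' @export
select_h_adhoc <- function(xy, level = 0.95, shrink = 0.95, cell_size = 50,
                           max_iter = 200) {
  if (is.data.frame(xy)) xy <- aeqd_project(cbind(xy$lon, xy$lat))$xy
  xy <- matrix(as.numeric(unlist(xy)), ncol = 2)
  if (nrow(xy) < 30) warning("fewer than 30 points; h selection may be unstable")
  sigma <- sqrt((stats::var(xy[, 1]) + stats::var(xy[, 2])) / 2)
  h0 <- sigma * nrow(xy)^(-1 / 6)
  contiguous_at <- function(h) {
    ud <- kde_ud(xy, h, cell_size = cell_size)
    isopleth(ud, level)$contiguous
  }
  if (!contiguous_at(h0))
    return(list(h = h0, h0 = h0, satisfied = FALSE, iterations = 0L))
  if (shrink >= 1)
    return(list(h = h0, h0 = h0, satisfied = TRUE, iterations = 0L))
  h <- h0
  it <- 0L
  while (it < max_iter) {
    h_next <- h * shrink
    if (h_next < cell_size / 2) break # below grid resolution; stop shrinking
    if (!contiguous_at(h_next)) break
    h <- h_next
    it <- it + 1L
  }
  list(h = h, h0 = h0, satisfied = TRUE, iterations = it)
}

#' Minimum convex polygon (total residence area)
#'
#' Convex hull of the fixes, optionally after trimming to the central
#' `percent` of points by distance from the centroid. When fix times are
#' supplied, the cumulative hull area by tracking day is computed and the
#' asymptote check reports whether the final 10% of tracking days added less
#' than 5% of cumulative area.
#'
#' @param points Two-column lon/lat matrix or data.frame of fixes with
#'   `lon`/`lat` (and optionally `timestamp`).
#' @param percent Central percentage of points to keep (default 100).
#' @param times Optional POSIXct per point (taken from `points$timestamp` if
#'   present).
#' @return List of class `mcp_result`: `hull` (lon/lat ring), `hull_xy`,
#'   `area_km2`, `asymptote_reached`, `cumulative` (day, area_km2).
#' @export
mcp <- function(points, percent = 100, times = NULL) {
  if (is.data.frame(points)) {
    if (is.null(times) && "timestamp" %in% names(points)) times <- points$timestamp
    lonlat <- cbind(points$lon, points$lat)
  } else lonlat <- matrix(as.numeric(unlist(points)), ncol = 2)
  pr <- aeqd_project(lonlat)
  xy <- pr$xy
  if (percent < 100) {
    ctr <- colMeans(xy)
    d <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
    keep <- d <= stats::quantile(d, percent / 100)
    xy <- xy[keep, , drop = FALSE]
    lonlat <- lonlat[keep, , drop = FALSE]
    if (!is.null(times)) times <- times[keep]
  }
  if (nrow(xy) < 3) stop("MCP needs at least 3 points")
  hull_area <- function(m) {
    hi <- grDevices::chull(m)
    polygon_area_m2(m[hi, , drop = FALSE]) / 1e6
  }
  hi <- grDevices::chull(xy)
  area <- polygon_area_m2(xy[hi, , drop = FALSE]) / 1e6
  if (area == 0) warning("collinear points: zero-area hull")
  cumulative <- NULL
  asymptote <- NA
  if (!is.null(times)) {
    day <- as.numeric(difftime(times, min(times), units = "days"))
    days <- sort(unique(ceiling(day)))
    areas <- vapply(days, function(d) {
      m <- xy[day <= d, , drop = FALSE]
      if (nrow(m) < 3) 0 else hull_area(m)
    }, numeric(1))
    areas <- cummax(areas)
    cumulative <- data.frame(day = days, area_km2 = areas)
    total_days <- max(days)
    cut_day <- total_days * 0.9
    a90 <- max(areas[days <= cut_day], 0)
    asymptote <- if (area > 0) (area - a90) / area < 0.05 else TRUE
  }
  structure(list(hull = lonlat[hi, , drop = FALSE],
                 hull_xy = xy[hi, , drop = FALSE],
                 area_km2 = area,
                 asymptote_reached = asymptote,
                 cumulative = cumulative,
                 proj_center = pr$center),
            class = "mcp_result")
}

#' Per-animal home-range summary table
#'
#' Binds per-animal 25/50/90% UD and MCP areas and appends column means.
#' Rows flagged `exclude` (e.g. a residence established after a developmental
#' migration) appear in the table but are left out of the means.
#'
#' @param results data.frame with columns `id`, `ud25`, `ud50`, `ud90`, `mcp`
#'   and optionally logical `exclude`.
#' @return List: `table` (per-animal rows), `means` (named vector computed
#'   over non-excluded rows).
#' @export
summarize_home_ranges <- function(results) {
  stopifnot(nrow(results) >= 1)
  if (is.null(results$exclude)) results$exclude <- FALSE
  use <- !results$exclude
  means <- c(ud25 = mean(results$ud25[use]), ud50 = mean(results$ud50[use]),
             ud90 = mean(results$ud90[use]), mcp = mean(results$mcp[use]))
  list(table = results, means = means)
}
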