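#' Read a delimited Fastloc-GPS fix table
#'
#' Column-name-driven reader: the file's columns are matched to the canonical
#' schema (`tag_id`, `timestamp`, `lon`, `lat`, `n_satellites`, `residual`)
#' either directly or through `mapping`. Timestamps may be ISO-8601 strings or
#' numeric epoch seconds. Rows are sorted by (tag, time); duplicate
#' (tag, time) rows collapse to the one with more satellites (ties keep the
#' first). Unknown columns are carried through untouched.
#'
#' @param path File path.
#' @param mapping Optional named character vector, canonical name -> file
#'   column name.
#' @param sep Field separator (default comma).
#' @return data.frame of fixes sorted by (tag_id, timestamp).
#' @export
read_fix_table <- function(path, mapping = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  canonical <- c("tag_id", "timestamp", "lon", "lat", "n_satellites", "residual")
  for (cn in canonical) {
    src <- if (!is.null(mapping) && cn %in% names(mapping)) mapping[[cn]] else cn
    if (!src %in% names(df)) {
      if (cn %in% c("tag_id", "timestamp", "lon", "lat"))
        stop("fix table is missing mandatory column: ", src)
      df[[src]] <- NA
    }
    if (src != cn) names(df)[names(df) == src] <- cn
  }
  if (nrow(df) == 0) {
    df$timestamp <- as.POSIXct(character(), tz = "UTC")
    return(df)
  }
  ts_raw <- df$timestamp
  if (is.numeric(ts_raw)) {
    ts <- as.POSIXct(ts_raw, origin = "1970-01-01", tz = "UTC")
  } else {
    ts <- as.POSIXct(rep(NA_real_, length(ts_raw)), origin = "1970-01-01", tz = "UTC")
    for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                  "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
      idx <- which(is.na(ts))
      if (!length(idx)) break
      ts[idx] <- as.POSIXct(strptime(ts_raw[idx], fmt, tz = "UTC"))
    }
    idx <- which(is.na(ts))
    if (length(idx)) suppressWarnings({
      num <- as.numeric(ts_raw[idx])
      ts[idx[!is.na(num)]] <- as.POSIXct(num[!is.na(num)],
                                         origin = "1970-01-01", tz = "UTC")
    })
  }
  bad <- is.na(ts) | is.na(suppressWarnings(as.numeric(df$lon))) |
    is.na(suppressWarnings(as.numeric(df$lat)))
  if (any(bad)) {
    warning(sum(bad), " unparseable row(s) skipped")
    df <- df[!bad, , drop = FALSE]
    ts <- ts[!bad]
  }
  df$timestamp <- ts
  df$lon <- as.numeric(df$lon)
  df$lat <- as.numeric(df$lat)
  if (any(df$lon < -180 | df$lon > 180 | df$lat < -90 | df$lat > 90))
    stop("coordinates outside valid lon/lat range")
  ord <- order(df$tag_id, df$timestamp,
               -ifelse(is.na(df$n_satellites), -1, df$n_satellites))
  df <- df[ord, , drop = FALSE]
  dup <- duplicated(df[, c("tag_id", "timestamp")])
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write fixes to a delimited table
#'
#' @param fixes data.frame of fixes.
#' @param path Output path.
#' @param sep Separator.
#' @export
write_fix_table <- function(fixes, path, sep = ",") {
  out <- fixes
  if (inherits(out$timestamp, "POSIXct"))
    out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an NDBC-style buoy water-temperature series
#'
#' Whitespace-delimited text with year/month/day/hour/minute columns and a
#' water-temperature column (WTMP). Values >= 999 are treated as the NDBC
#' missing sentinel and dropped.
#'
#' @param path File path.
#' @return data.frame of class `temperature_series` with columns `time`
#'   (POSIXct UTC) and `temp_c`, sorted by time.
#' @export
read_buoy_series <- function(path) {
  lines <- readLines(path)
  # header is the first line (NDBC convention: "#YY MM DD hh mm ... WTMP");
  # any further '#' lines (units) are skipped
  cols <- strsplit(trimws(sub("^#", "", lines[1])), "\\s+")[[1]]
  body <- lines[-1]
  body <- body[!grepl("^#", body)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) {
    warning("buoy file contains no data rows")
    out <- data.frame(time = as.POSIXct(character(), tz = "UTC"), temp_c = numeric())
    class(out) <- c("temperature_series", "data.frame")
    return(out)
  }
  mat <- utils::read.table(text = body, stringsAsFactors = FALSE)
  names(mat) <- cols[seq_len(ncol(mat))]
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(mat)) return(mat[[nm]])
    stop("buoy file missing column: ", paste(c(...), collapse = "/"))
  }
  yy <- pick("YY", "YYYY"); mm <- pick("MM"); dd <- pick("DD")
  hh <- pick("hh"); mi <- pick("mm", "min")
  wt <- pick("WTMP", "wtmp", "temp_c")
  yy <- ifelse(yy < 100, yy + 2000, yy)
  time <- as.POSIXct(sprintf("%04d-%02d-%02d %02d:%02d:00", yy, mm, dd, hh, mi),
                     tz = "UTC")
  ok <- !is.na(time) & wt < 999 & wt > -5 & wt < 45
  if (!any(ok)) warning("all buoy temperature values missing")
  out <- data.frame(time = time[ok], temp_c = wt[ok])
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("temperature_series", "data.frame")
  out
}

#' Monthly summary of a temperature series
#'
#' One row per calendar month present; records pooled over all years.
#'
#' @param series A `temperature_series` (or data.frame with `time`, `temp_c`).
#' @return data.frame with month (1-12), mean, sd, n.
#' @export
monthly_summary <- function(series) {
  stopifnot(nrow(series) > 0)
  mo <- as.integer(format(series$time, "%m"))
  agg <- do.call(rbind, lapply(sort(unique(mo)), function(m) {
    v <- series$temp_c[mo == m]
    data.frame(month = m, mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0, n = length(v))
  }))
  rownames(agg) <- NULL
  agg
}

## GeoJSON ----------------------------------------------------------------------

.ring_is_simple <- function(ring) {
  # O(n^2) segment-intersection check on one ring; adequate for habitat-scale
  # polygons. Shared endpoints between adjacent segments are not intersections.
  ring <- matrix(as.numeric(unlist(ring)), ncol = 2)
  if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
  n <- nrow(ring)
  if (n < 3) return(FALSE)
  seg <- cbind(ring, ring[c(2:n, 1), , drop = FALSE])
  inter <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next
      if (inter(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4])) return(FALSE)
    }
  }
  TRUE
}

#' Build a GeoJSON-style feature
#'
#' @param geometry_type "Point" or "Polygon".
#' @param coordinates For a point, c(lon, lat); for a polygon, a two-column
#'   matrix for the outer ring (closed automatically).
#' @param properties Named list of properties.
#' @return Feature list.
#' @export
geo_feature <- function(geometry_type, coordinates, properties = list()) {
  if (geometry_type == "Polygon") {
    ring <- matrix(as.numeric(unlist(coordinates)), ncol = 2)
    if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    coordinates <- list(ring)
  }
  list(type = "Feature",
       geometry = list(type = geometry_type, coordinates = coordinates),
       properties = properties)
}

#' Write features as a GeoJSON FeatureCollection
#'
#' Polygon rings are checked for self-intersection before writing; invalid
#' geometry is an error. Coordinates are written at full precision.
#'
#' @param features List of features from [geo_feature()].
#' @param path Output path.
#' @export
write_geojson <- function(features, path) {
  for (f in features) {
    if (identical(f$geometry$type, "Polygon")) {
      for (ring in f$geometry$coordinates)
        if (!.ring_is_simple(ring)) stop("invalid (self-intersecting) polygon ring")
    }
  }
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a GeoJSON FeatureCollection
#'
#' @param path File path.
#' @return List of features; polygon outer rings as two-column matrices.
#' @export
read_geojson <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  stopifnot(identical(fc$type, "FeatureCollection"))
  lapply(fc$features, function(f) {
    g <- f$geometry
    if (identical(g$type, "Polygon")) {
      rings <- lapply(g$coordinates, function(r)
        do.call(rbind, lapply(r, function(p) c(p[[1]], p[[2]]))))
      g$coordinates <- rings
    } else if (identical(g$type, "Point")) {
      g$coordinates <- c(g$coordinates[[1]], g$coordinates[[2]])
    }
    list(type = "Feature", geometry = g,
         properties = if (is.null(f$properties)) list() else f$properties)
  })
}

#' Assemble a habitat map from class-labelled polygons
#'
#' @param polygons List of lists with `class` (one of seagrass, reef, channel,
#'   platform_boundary), `name`, and `ring` (two-column lon/lat matrix).
#' @return List of class `habitat_map`.
#' @export
habitat_map <- function(polygons) {
  classes <- c("seagrass", "reef", "channel", "platform_boundary")
  for (p in polygons) {
    if (!p$class %in% classes) stop("unknown habitat class: ", p$class)
    if (!.ring_is_simple(p$ring)) stop("invalid habitat polygon: ", p$name)
  }
  structure(polygons, class = "habitat_map")
}

#' Extract rings of a habitat class
#'
#' @param map A `habitat_map`.
#' @param class Habitat class to extract.
#' @return List of two-column lon/lat matrices.
#' @export
habitat_rings <- function(map, class) {
  lapply(Filter(function(p) p$class == class, map), function(p) p$ring)
}
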