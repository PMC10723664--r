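# Shared fixtures, all built in code.

# circular seagrass meadow around the configured foraging centre
make_seagrass_habitat <- function(cfg, radius_m = 350) {
  th <- seq(0, 2 * pi, length.out = 33)[-1]
  ring <- aeqd_inverse(cbind(radius_m * cos(th), radius_m * sin(th)),
                       cfg$centers$foraging)
  habitat_map(list(list(class = "seagrass", name = "meadow", ring = ring)))
}

# smooth synthetic bathymetry: depth interpolated among the behavioural
# centres so each simulated cluster sits at its nominal depth
make_bathymetry <- function(cfg,
                            depths = c(foraging = 2.5, day_rest = 8,
                                       night_rest = 7, refuge = 10.5)) {
  ctrs <- do.call(rbind, cfg$centers[names(depths)])
  function(lon, lat) {
    d <- sapply(seq_len(nrow(ctrs)), function(i)
      haversine_km(cbind(lon, lat),
                   matrix(ctrs[i, ], nrow = length(lon), ncol = 2, byrow = TRUE)) * 1000)
    if (is.null(dim(d))) d <- matrix(d, nrow = 1)
    w <- exp(-d / 200)
    rowSums(w * matrix(depths, nrow(d), length(depths), byrow = TRUE)) /
      (rowSums(w) + 1e-9)
  }
}

# circular platform boundary of given radius around the release site
make_platform_ring <- function(cfg, radius_m = 10000) {
  th <- seq(0, 2 * pi, length.out = 65)[-1]
  aeqd_inverse(cbind(radius_m * cos(th), radius_m * sin(th)),
               cfg$centers$release)
}

# fixes marching along a parallel at constant speed
line_fixes <- function(n = 10, speed_kmh = 2, dt_h = 2, lat = 32.3,
                       lon0 = -64.9, start = as.POSIXct("2016-08-02 00:00:00", tz = "UTC"),
                       tag = "t1") {
  km_per_deg <- haversine_km(c(lon0, lat), c(lon0 + 1, lat))
  step_deg <- speed_kmh * dt_h / km_per_deg
  data.frame(tag_id = tag,
             timestamp = start + (0:(n - 1)) * dt_h * 3600,
             lon = lon0 + (0:(n - 1)) * step_deg,
             lat = lat,
             n_satellites = 8L, residual = 5,
             stringsAsFactors = FALSE)
}
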