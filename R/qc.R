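#' Quality-control configuration
#'
#' Thresholds for plausibility screening of Fastloc-GPS fixes. A fix is
#' flagged potentially errant when its satellite count is *fewer than*
#' `min_satellites` or its residual error *exceeds* `max_residual` (both
#' boundaries inclusive for retention). The two clauses are combined with OR
#' by default; the conjunctive reading is available via `rule = "and"`.
#' `vmax` bounds plausible sustained travel speed: 10 km/h is roughly four
#' times typical migratory rates for immature green turtles, generous for
#' within-platform residency movements.
#'
#' @param min_satellites Minimum satellites in the position solution (default 6).
#' @param max_residual Maximum Fastloc residual error (default 30).
#' @param vmax Speed-filter threshold, km/h (default 10).
#' @param exclude_initial_h Post-release settling window to drop, hours.
#' @param max_gap_days Gap length that splits a track into bursts, days.
#' @param rule "or" (either failing clause removes the fix) or "and".
#' @return List of class `qc_config`.
#' @export
qc_config <- function(min_satellites = 6, max_residual = 30, vmax = 10,
                      exclude_initial_h = 24, max_gap_days = 3,
                      rule = c("or", "and")) {
  rule <- match.arg(rule)
  stopifnot(min_satellites > 0, max_residual > 0, vmax > 0,
            exclude_initial_h >= 0, max_gap_days > 0)
  structure(list(min_satellites = min_satellites, max_residual = max_residual,
                 vmax = vmax, exclude_initial_h = exclude_initial_h,
                 max_gap_days = max_gap_days, rule = rule),
            class = "qc_config")
}

#' Satellite-count / residual plausibility screen
#'
#' @param fixes data.frame of fixes sorted by timestamp within tag.
#' @param qc A [qc_config()].
#' @return List with `fixes` (retained rows) and `report` (counts and per-tag
#'   breakdown; input = retained + removed).
#' @export
flag_implausible <- function(fixes, qc = qc_config()) {
  low_sat <- fixes$n_satellites < qc$min_satellites
  high_res <- fixes$residual > qc$max_residual
  low_sat[is.na(low_sat)] <- FALSE
  high_res[is.na(high_res)] <- FALSE
  bad <- if (qc$rule == "or") low_sat | high_res else low_sat & high_res
  report <- list(input = nrow(fixes), retained = sum(!bad),
                 removed = sum(bad),
                 removed_low_satellites = sum(low_sat),
                 removed_high_residual = sum(high_res),
                 per_tag = table(fixes$tag_id[bad]))
  list(fixes = fixes[!bad, , drop = FALSE], report = report)
}

.speeds_kmh <- function(fixes) {
  n <- nrow(fixes)
  if (n < 2) return(numeric(0))
  d <- haversine_km(cbind(fixes$lon[-n], fixes$lat[-n]),
                    cbind(fixes$lon[-1], fixes$lat[-1]))
  dt <- as.numeric(difftime(fixes$timestamp[-1], fixes$timestamp[-n], units = "hours"))
  d / pmax(dt, 1e-9)
}

#' Iterative speed filter
#'
#' Re-implementation of data-driven speed screening: on each pass, every
#' interior fix whose required inbound AND outbound great-circle speeds both
#' exceed `vmax` is removed, and an endpoint is removed when its single
#' adjacent speed exceeds `3 * vmax`; passes repeat until no fix is removed.
#' Applied per tag.
#'
#' @param fixes data.frame of fixes.
#' @param vmax Speed threshold, km/h.
#' @return Retained fixes.
#' @export
speed_filter <- function(fixes, vmax = 10) {
  out <- lapply(split(fixes, fixes$tag_id), function(fx) {
    fx <- fx[order(fx$timestamp), , drop = FALSE]
    if (nrow(fx) < 3) {
      warning("fewer than 3 fixes; speed filter not applied")
      return(fx)
    }
    repeat {
      n <- nrow(fx)
      if (n < 2) break
      v <- .speeds_kmh(fx)
      drop <- rep(FALSE, n)
      if (n >= 3) {
        interior <- 2:(n - 1)
        drop[interior] <- v[interior - 1] > vmax & v[interior] > vmax
      }
      drop[1] <- drop[1] | v[1] > 3 * vmax
      drop[n] <- drop[n] | v[n - 1] > 3 * vmax
      if (!any(drop)) break
      fx <- fx[!drop, , drop = FALSE]
    }
    fx
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Exclude the post-release settling window
#'
#' Drops fixes within `hours` of the deployment time, when behaviour after
#' capture and tagging is not representative.
#'
#' @param fixes data.frame of fixes.
#' @param deployment_time POSIXct deployment/release time (<= first fix).
#' @param hours Window length (default 24).
#' @return Remaining fixes.
#' @export
exclude_initial_window <- function(fixes, deployment_time, hours = 24) {
  keep <- fixes$timestamp >= deployment_time + hours * 3600
  if (!any(keep) && nrow(fixes) > 0)
    warning("all fixes fall inside the initial exclusion window")
  fixes[keep, , drop = FALSE]
}

#' Split a track into contiguous bursts at long gaps
#'
#' @param fixes data.frame of fixes sorted by timestamp (single tag).
#' @param max_gap_days Gap threshold in days (default 3).
#' @return List of data.frames; their concatenation equals the input.
#' @export
split_on_gaps <- function(fixes, max_gap_days = 3) {
  n <- nrow(fixes)
  if (n == 0) return(list())
  gaps <- as.numeric(difftime(fixes$timestamp[-1], fixes$timestamp[-n], units = "days"))
  burst <- cumsum(c(0, gaps > max_gap_days))
  unname(split(fixes, burst))
}

#' Full quality-control pipeline
#'
#' Satellite/residual screen, then iterative speed filter, then initial-window
#' exclusion; returns retained fixes and an accounting report.
#'
#' @param fixes data.frame of fixes.
#' @param qc A [qc_config()].
#' @param deployment_time POSIXct; defaults to the first fix time.
#' @return List with `fixes` and `report` (input = retained + sum(removed)).
#' @export
qc_pipeline <- function(fixes, qc = qc_config(), deployment_time = NULL) {
  if (is.null(deployment_time)) deployment_time <- min(fixes$timestamp)
  n0 <- nrow(fixes)
  s1 <- flag_implausible(fixes, qc)
  n1 <- nrow(s1$fixes)
  f2 <- suppressWarnings(speed_filter(s1$fixes, qc$vmax))
  n2 <- nrow(f2)
  f3 <- suppressWarnings(exclude_initial_window(f2, deployment_time, qc$exclude_initial_h))
  n3 <- nrow(f3)
  report <- list(input = n0, retained = n3,
                 removed_satellite_residual = n0 - n1,
                 removed_speed = n1 - n2,
                 removed_initial_window = n2 - n3)
  list(fixes = f3, report = report)
}
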