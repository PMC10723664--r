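#' Net-capture detection rate for one resident animal
#'
#' Detectability of the entrapment-net sampling method: the number of net
#' captures divided by the number of net sets made within the animal's
#' presumed foraging area during its residency, as a percentage. The
#' estimate is considered eligible for study-level summaries only when the
#' animal was resident for at least a year and at a single sampling site.
#'
#' @param n_captures Net captures during the residency period.
#' @param n_sets Net sets within the foraging area during residency (>= 1).
#' @param residency_months Total known residency, months.
#' @param single_site Logical: residency attributable to one sampling site.
#' @param turtle_id Identifier carried through.
#' @return List of class `detectability_estimate`: `turtle_id`,
#'   `rate_percent` (full precision), `rate_reported` (1 d.p., half-up),
#'   `eligible`.
#' @export
detection_rate <- function(n_captures, n_sets, residency_months = NA,
                           single_site = TRUE, turtle_id = NA) {
  if (is.na(n_sets) || n_sets < 1) {
    warning("no net sets recorded; detection rate undefined")
    return(structure(list(turtle_id = turtle_id, rate_percent = NA_real_,
                          rate_reported = NA_real_, eligible = FALSE),
                     class = "detectability_estimate"))
  }
  rate <- 100 * n_captures / n_sets
  eligible <- isTRUE(single_site) && (is.na(residency_months) || residency_months >= 12)
  structure(list(turtle_id = turtle_id, rate_percent = rate,
                 rate_reported = .round_half_up(rate, 1),
                 eligible = eligible),
            class = "detectability_estimate")
}

# round half away from zero, the convention of the printed report tables
.round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Study-level detectability summary
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of per-animal detection
#' rates, over animals with a computable rate. Full-precision ratios are
#' summarised; rounding to reporting precision happens only on display.
#'
#' @param estimates List of `detectability_estimate`s, or a data.frame with
#'   `rate_percent`.
#' @return List: `mean`, `sd`, `n`.
#' @export
detectability_summary <- function(estimates) {
  rates <- if (is.data.frame(estimates)) {
    estimates$rate_percent
  } else {
    vapply(estimates, function(e) e$rate_percent, numeric(1))
  }
  rates <- rates[!is.na(rates)]
  stopifnot(length(rates) >= 2)
  list(mean = mean(rates), sd = stats::sd(rates), n = length(rates))
}

## Packaged published-table fixtures --------------------------------------------

#' Published per-animal summary tables for the Bermuda green turtle study
#'
#' Loads the per-animal values printed in the source study's report tables,
#' packaged as plain-text fixtures: deployments with home-range areas
#' (`deployments`), distinct use areas (`use_areas`), residency and
#' net-capture detectability (`detectability`), and developmental migration
#' metrics (`migrations`). These serve as reference inputs for aggregate
#' recomputation; raw fix data were not deposited.
#'
#' @return Named list of data.frames.
#' @export
bermuda_tables <- function() {
  rd <- function(f) utils::read.csv(
    system.file("extdata", f, package = "fastloctrack", mustWork = TRUE),
    stringsAsFactors = FALSE)
  list(deployments = rd("table1_deployments.csv"),
       use_areas = rd("table2_use_areas.csv"),
       detectability = rd("table4_detectability.csv"),
       migrations = rd("table5_migrations.csv"))
}

#' Assemble the study report tables
#'
#' Recomputes every aggregate from per-row values: the home-range table with
#' column means (excluding post-migration residences), the use-area size and
#' depth means by class, the detectability estimates and their summary, and
#' the migration metric means. Re-running on unchanged inputs is
#' byte-identical; nothing is cached.
#'
#' @param tables A list shaped like [bermuda_tables()].
#' @param out_dir Optional directory; when given, each table is written as a
#'   CSV.
#' @return List of class `study_report`: `home_range` (table + means),
#'   `use_area_means` (per-class mean size and depth), `detectability`
#'   (per-animal estimates + summary), `migration_means` (straightness,
#'   travel rate, current speed, departing SCL), `deployment_means`.
#' @export
build_report <- function(tables = bermuda_tables(), out_dir = NULL) {
  t1 <- tables$deployments
  hr_in <- data.frame(id = t1$ptt, ud25 = t1$ud25, ud50 = t1$ud50,
                      ud90 = t1$ud90, mcp = t1$mcp, exclude = t1$post_migration)
  hr <- summarize_home_ranges(hr_in)
  keep <- !t1$post_migration
  deployment_means <- c(days_deployed = mean(t1$days_deployed[keep], na.rm = TRUE),
                        n_fixes = mean(t1$n_fixes[keep], na.rm = TRUE),
                        scl_cm = mean(t1$scl_cm[keep], na.rm = TRUE))

  t2 <- tables$use_areas
  colmean <- function(v) mean(v[!is.na(v)])
  use_area_means <- data.frame(
    kind = c("foraging_f", "rest_day_r", "rest_night_r", "cool_refuge_c"),
    mean_size_km2 = c(colmean(t2$f_size_km2), colmean(t2$rday_size_km2),
                      colmean(t2$rnight_size_km2), colmean(t2$c_size_km2)),
    mean_depth_m = c(colmean(t2$f_depth_m), colmean(t2$rday_depth_m),
                     colmean(t2$rnight_depth_m), colmean(t2$c_depth_m)),
    n = c(sum(!is.na(t2$f_size_km2)), sum(!is.na(t2$rday_size_km2)),
          sum(!is.na(t2$rnight_size_km2)), sum(!is.na(t2$c_size_km2))))

  t4 <- tables$detectability
  est <- lapply(seq_len(nrow(t4)), function(i) {
    if (is.na(t4$n_sets[i])) return(NULL)
    detection_rate(t4$n_captures[i], t4$n_sets[i], t4$residency_months[i],
                   t4$single_site[i] %in% c("yes", "lt1yr"), t4$ptt[i])
  })
  est <- Filter(Negate(is.null), est)
  det_summary <- detectability_summary(est)

  t5 <- tables$migrations
  migration_means <- c(
    straightness = mean(t5$straightness),
    rate_kmh = mean(t5$rate_kmh),
    current_ms = mean(t5$current_ms),
    path_km = mean(t5$path_km),
    departing_scl_cm = mean(t5$scl_cm[t5$study_cohort]))

  report <- structure(list(home_range = hr,
                           deployment_means = deployment_means,
                           use_area_means = use_area_means,
                           detectability = list(estimates = est, summary = det_summary),
                           migration_means = migration_means),
                      class = "study_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(hr$table, file.path(out_dir, "home_range.csv"), row.names = FALSE)
    utils::write.csv(use_area_means, file.path(out_dir, "use_area_means.csv"),
                     row.names = FALSE)
    det_df <- do.call(rbind, lapply(est, function(e)
      data.frame(turtle_id = e$turtle_id, rate_percent = e$rate_reported)))
    utils::write.csv(det_df, file.path(out_dir, "detectability.csv"), row.names = FALSE)
    utils::write.csv(t5, file.path(out_dir, "migrations.csv"), row.names = FALSE)
  }
  report
}
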