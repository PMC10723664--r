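#' Re-discretize a track to a regular time step
#'
#' Positions are linearly interpolated along the straight chord between the
#' bracketing fixes at each epoch of a fixed 12-h grid anchored at the first
#' fix of each burst. Bursts are delimited by positional gaps longer than
#' `max_gap_days`; no epochs are emitted inside such gaps. An epoch is marked
#' `interpolated` when no observed fix lies within one hour of it.
#'
#' @param fixes data.frame of fixes for one tag, sorted by timestamp.
#' @param dt_h Epoch spacing in hours (default 12).
#' @param max_gap_days Gap threshold splitting bursts (default 3).
#' @return data.frame of class `reg_track`: tag_id, epoch, lon, lat, x, y
#'   (local azimuthal-equidistant metres), interpolated, burst. The projection
#'   centre is stored as attribute `proj_center`.
#' @export
rediscretize <- function(fixes, dt_h = 12, max_gap_days = 3) {
  stopifnot(nrow(fixes) >= 2)
  fixes <- fixes[order(fixes$timestamp), , drop = FALSE]
  bursts <- split_on_gaps(fixes, max_gap_days)
  proj_center <- colMeans(cbind(fixes$lon, fixes$lat))
  rows <- list()
  for (b in seq_along(bursts)) {
    fx <- bursts[[b]]
    span_h <- as.numeric(difftime(max(fx$timestamp), min(fx$timestamp), units = "hours"))
    if (nrow(fx) < 2 || span_h < dt_h) {
      warning("burst shorter than one epoch interval skipped")
      next
    }
    epochs <- seq(min(fx$timestamp), max(fx$timestamp), by = dt_h * 3600)
    tt <- as.numeric(fx$timestamp)
    te <- as.numeric(epochs)
    lon <- stats::approx(tt, fx$lon, xout = te, ties = "ordered")$y
    lat <- stats::approx(tt, fx$lat, xout = te, ties = "ordered")$y
    nearest <- vapply(te, function(e) min(abs(tt - e)), numeric(1))
    rows[[length(rows) + 1]] <- data.frame(
      tag_id = fx$tag_id[1], epoch = epochs, lon = lon, lat = lat,
      interpolated = nearest > 3600, burst = b, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no burst long enough to re-discretize")
  out <- do.call(rbind, rows)
  xy <- aeqd_project(cbind(out$lon, out$lat), center = proj_center)$xy
  out$x <- xy[, 1]
  out$y <- xy[, 2]
  attr(out, "proj_center") <- proj_center
  class(out) <- c("reg_track", "data.frame")
  out
}

## per-segment Gaussian cost matrix (independent coordinates, per-segment
## mean and variance, ML); cost[i, j] = -2 x log-likelihood up to constants
.segment_cost <- function(x, y, lmin, min_var = 1e-8) {
  n <- length(x)
  cs <- function(v) cumsum(c(0, v))
  Sx <- cs(x); Sx2 <- cs(x^2); Sy <- cs(y); Sy2 <- cs(y^2)
  cost <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    j <- i:n
    len <- j - i + 1
    vx <- (Sx2[j + 1] - Sx2[i]) / len - ((Sx[j + 1] - Sx[i]) / len)^2
    vy <- (Sy2[j + 1] - Sy2[i]) / len - ((Sy[j + 1] - Sy[i]) / len)^2
    vx <- pmax(vx, min_var); vy <- pmax(vy, min_var)
    val <- 0.5 * len * (log(2 * pi * vx) + 1) + 0.5 * len * (log(2 * pi * vy) + 1)
    val[len < lmin] <- Inf
    cost[i, j] <- val
  }
  cost
}

## exact dynamic program: optimal K-segmentations for K = 1..Kmax
.segment_dp <- function(cost, Kmax, lmin) {
  n <- ncol(cost)
  C <- matrix(Inf, Kmax, n)
  B <- matrix(NA_integer_, Kmax, n)
  C[1, ] <- cost[1, ]
  if (Kmax >= 2) {
    for (k in 2:Kmax) {
      for (j in seq_len(n)) {
        if (j < k * lmin) next
        ts <- seq((k - 1) * lmin, j - lmin)
        vals <- C[k - 1, ts] + cost[ts + 1, j]
        m <- which.min(vals)
        if (length(m) && is.finite(vals[m])) {
          C[k, j] <- vals[m]
          B[k, j] <- ts[m]
        }
      }
    }
  }
  list(C = C, B = B)
}

.backtrack <- function(B, K, n) {
  ends <- integer(K)
  ends[K] <- n
  if (K >= 2) for (k in K:2) ends[k - 1] <- B[k, ends[k]]
  ends
}

#' Segment a regularized track into stationary phases
#'
#' Exact dynamic-programming segmentation of the projected coordinates under
#' an independent-Gaussian model with per-segment mean and variance, subject
#' to a minimum segment length. The number of phases K is chosen by the
#' normalized-contrast threshold rule (threshold `S`, default 0.75), with a
#' guard requiring each added segment to lower the raw contrast by at least
#' `guard * log(n)` (BIC-scale); without the guard the threshold rule selects
#' spurious phases on structureless series.
#'
#' @param track A `reg_track` from [rediscretize()], or any data.frame with
#'   `x`, `y` columns in metres.
#' @param lmin Minimum segment length in epochs (default 40 epochs = 20 days
#'   at 12-h spacing).
#' @param Kmax Maximum number of phases; default `min(10, floor(n / lmin))`.
#' @param S Normalized-contrast decrease threshold (default 0.75).
#' @param guard Raw-contrast guard multiplier on log(n) (default 3; 0 disables).
#' @param min_var Variance floor, m^2.
#' @return List of class `phase_model`: `K`, `breakpoints` (epoch indices of
#'   segment ends), `segments` (start, end, n, mean_x, mean_y, duration_days,
#'   valid flag), `J` (optimal contrast per K), `D` (normalized decreases).
#' @export
segment_track <- function(track, lmin = 40, Kmax = NULL, S = 0.75,
                          guard = 3, min_var = 1e-8) {
  x <- track$x
  y <- track$y
  n <- length(x)
  if (is.null(Kmax)) Kmax <- max(1L, min(10L, floor(n / lmin)))
  single <- function(note) {
    seg <- .segments_df(track, n, ends = n)
    structure(list(K = 1L, breakpoints = n, segments = seg,
                   J = NA_real_, D = NA_real_, note = note),
              class = "phase_model")
  }
  if (n < 2 * lmin || Kmax < 2) return(single("series too short for K >= 2"))
  cost <- .segment_cost(x, y, lmin, min_var)
  dp <- .segment_dp(cost, Kmax, lmin)
  J <- dp$C[, n]
  feasible <- which(is.finite(J))
  Kmax_f <- max(feasible)
  J <- J[seq_len(Kmax_f)]
  K <- 1L
  D <- NA_real_
  if (Kmax_f >= 2 && J[Kmax_f] < J[1]) {
    Jt <- (J[Kmax_f] - J) / (J[Kmax_f] - J[1]) * (Kmax_f - 1) + 1
    D <- -diff(Jt) # normalized decrease going K-1 -> K, indexed by K = 2..
    raw <- -diff(J)
    ok <- D > S & raw > guard * log(n)
    if (any(ok)) K <- max(which(ok)) + 1L
  }
  ends <- .backtrack(dp$B, K, n)
  seg <- .segments_df(track, n, ends)
  structure(list(K = K, breakpoints = ends, segments = seg, J = J, D = D),
            class = "phase_model")
}

.segments_df <- function(track, n, ends) {
  starts <- c(1L, utils::head(ends, -1) + 1L)
  has_time <- "epoch" %in% names(track)
  has_burst <- "burst" %in% names(track)
  do.call(rbind, lapply(seq_along(ends), function(k) {
    i <- starts[k]:ends[k]
    dur <- if (has_time)
      as.numeric(difftime(track$epoch[ends[k]], track$epoch[starts[k]], units = "days"))
    else NA_real_
    data.frame(segment = k, start = starts[k], end = ends[k], n = length(i),
               mean_x = mean(track$x[i]), mean_y = mean(track$y[i]),
               var_x = stats::var(track$x[i]), var_y = stats::var(track$y[i]),
               duration_days = dur,
               spans_gap = if (has_burst) length(unique(track$burst[i])) > 1 else FALSE,
               valid = if (has_burst)
                 length(unique(track$burst[i])) == 1 && (!has_time || dur >= 20)
               else TRUE)
  }))
}

#' Bhattacharyya coefficient of two gridded distributions
#'
#' BC = sum over cells of sqrt(p_a * p_b) for per-cell probability masses;
#' lies in [0, 1], is symmetric, and equals 1 for identical distributions.
#'
#' @param pa,pb Matrices (or vectors) of per-cell masses on a shared grid;
#'   renormalised to sum to 1.
#' @return Numeric BC.
#' @export
bhattacharyya_coef <- function(pa, pb) {
  pa <- as.numeric(pa); pb <- as.numeric(pb)
  stopifnot(length(pa) == length(pb))
  pa <- pa / sum(pa)
  pb <- pb / sum(pb)
  min(1, sum(sqrt(pa * pb)))
}

#' Utilization-overlap test of two phases
#'
#' Kernel UDs of both phases are computed on one shared grid; each is masked
#' to its own `mask_level` isopleth (the convention used when comparing
#' residence phases) and renormalised; the Bhattacharyya coefficient of the
#' masked distributions is returned. Phases with BC below `distinct_below`
#' are considered distinct periods of habitat use.
#'
#' @param fixes_a,fixes_b data.frames with lon/lat (or two-column matrices of
#'   projected metres).
#' @param h Kernel smoothing parameter, m.
#' @param cell_size Grid cell edge, m.
#' @param mask_level Isopleth used to mask each UD (default 0.95); `NULL`
#'   compares the full, unmasked UDs.
#' @param distinct_below BC threshold for distinctness (default 0.5).
#' @param min_fixes Floor on per-phase fix count (default 30).
#' @return List of class `phase_pair`: `bc`, `distinct`, `h`, `n_a`, `n_b`.
#' @export
phase_ud_overlap <- function(fixes_a, fixes_b, h, cell_size = 50,
                             mask_level = 0.95, distinct_below = 0.5,
                             min_fixes = 30) {
  get_xy <- function(f) {
    if (is.data.frame(f)) cbind(f$lon, f$lat) else matrix(as.numeric(unlist(f)), ncol = 2)
  }
  a_ll <- get_xy(fixes_a)
  b_ll <- get_xy(fixes_b)
  if (nrow(a_ll) < min_fixes || nrow(b_ll) < min_fixes)
    warning("phase has fewer than ", min_fixes, " fixes; BC may be unstable")
  if (is.data.frame(fixes_a)) {
    ctr <- colMeans(rbind(a_ll, b_ll))
    xa <- aeqd_project(a_ll, center = ctr)$xy
    xb <- aeqd_project(b_ll, center = ctr)$xy
  } else {
    xa <- a_ll; xb <- b_ll
  }
  degen <- function(m) all(apply(m, 2, stats::var) < 1e-12)
  if (degen(xa) || degen(xb)) {
    warning("degenerate phase (all fixes identical); using minimum smoothing")
    jit <- cell_size / 10
    if (degen(xa)) xa <- xa + matrix(stats::rnorm(length(xa), 0, jit), ncol = 2)
    if (degen(xb)) xb <- xb + matrix(stats::rnorm(length(xb), 0, jit), ncol = 2)
  }
  both <- rbind(xa, xb)
  grid <- .make_grid(both, h, cell_size)
  za <- .kde_on_grid(xa, h, grid)
  zb <- .kde_on_grid(xb, h, grid)
  mass <- function(z) z / sum(z)
  ma <- mass(za); mb <- mass(zb)
  if (!is.null(mask_level)) {
    mask_to <- function(m) {
      ord <- order(m, decreasing = TRUE)
      cum <- cumsum(m[ord])
      thr <- m[ord][which(cum >= mask_level)[1]]
      m[m < thr] <- 0
      m / sum(m)
    }
    ma <- mask_to(ma)
    mb <- mask_to(mb)
  }
  bc <- bhattacharyya_coef(ma, mb)
  structure(list(bc = bc, distinct = bc < distinct_below, h = h,
                 n_a = nrow(xa), n_b = nrow(xb)),
            class = "phase_pair")
}
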