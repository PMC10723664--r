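test_that("kernel UD conserves mass, stays nonnegative, and shifts with the data", {
  set.seed(200)
  pts <- cbind(rnorm(500, 0, 200), rnorm(500, 0, 200))
  ud <- kde_ud(pts, h = 80, cell_size = 50)
  expect_true(all(ud$z >= 0))
  expect_equal(sum(ud$z) * ud$cell_size^2, 1, tolerance = 1e-6)
  ud2 <- kde_ud(pts + matrix(c(1000, -500), 500, 2, byrow = TRUE), h = 80, cell_size = 50)
  expect_equal(ud2$z, ud$z, tolerance = 1e-9)
  expect_equal(ud2$x, ud$x + 1000)
  expect_error(kde_ud(matrix(1, 10, 2), h = 50), "degenerate")
  expect_error(kde_ud(pts[1:3, ], h = 50), "at least 5")
})

test_that("Gaussian UD mass inside a circle matches the convolution closed form", {
  set.seed(201)
  s <- 300; h <- 60
  pts <- cbind(rnorm(10000, 0, s), rnorm(10000, 0, s))
  ud <- kde_ud(pts, h = h, cell_size = 50)
  v <- s^2 + h^2
  gx <- outer(ud$x, rep(1, length(ud$y)))
  gy <- outer(rep(1, length(ud$x)), ud$y)
  mu <- colMeans(pts)
  for (r in c(300, 500, 800)) {
    inside <- (gx - mu[1])^2 + (gy - mu[2])^2 <= r^2
    mass <- sum(ud$z[inside]) * ud$cell_size^2
    expect_lt(abs(mass - (1 - exp(-r^2 / (2 * v)))), 0.02)
  }
})

test_that("isopleth areas match the Gaussian quantile form and nest by level", {
  set.seed(202)
  s <- 300; h <- 60
  pts <- cbind(rnorm(10000, 0, s), rnorm(10000, 0, s))
  ud <- kde_ud(pts, h = h, cell_size = 50)
  v <- s^2 + h^2
  i50 <- isopleth(ud, 0.50)
  expect_equal(i50$area_km2, pi * v * 2 * log(2) / 1e6, tolerance = 0.05)
  i25 <- isopleth(ud, 0.25); i90 <- isopleth(ud, 0.90)
  expect_lte(i25$area_km2, i50$area_km2)
  expect_lte(i50$area_km2, i90$area_km2)
  expect_true(i50$contiguous)
})

test_that("well-separated clusters yield a multi-part 95% isopleth", {
  set.seed(203)
  a <- cbind(rnorm(300, 0, 100), rnorm(300, 0, 100))
  b <- cbind(rnorm(300, 50000, 100), rnorm(300, 0, 100))
  ud <- kde_ud(rbind(a, b), h = 200, cell_size = 200)
  iso <- isopleth(ud, 0.95)
  expect_equal(iso$n_parts, 2)
  expect_false(iso$contiguous)
})

test_that("ad hoc smoothing shrinks h while the 95% isopleth stays contiguous", {
  set.seed(204)
  # single tight cluster: shrinking proceeds at least once
  one <- cbind(rnorm(300, 0, 150), rnorm(300, 0, 150))
  sel1 <- select_h_adhoc(one, cell_size = 50)
  expect_true(sel1$satisfied)
  expect_lt(sel1$h, sel1$h0)

  # shrink = 1 returns the reference h unchanged
  sel_ref <- select_h_adhoc(one, shrink = 1)
  expect_equal(sel_ref$h, sel_ref$h0)

  # two nearby clusters: the returned h is contiguous, one more shrink is not
  two <- rbind(cbind(rnorm(300, 0, 100), rnorm(300, 0, 100)),
               cbind(rnorm(300, 700, 100), rnorm(300, 0, 100)))
  sel2 <- select_h_adhoc(two, cell_size = 50)
  expect_true(sel2$satisfied)
  contig <- function(h) isopleth(kde_ud(two, h, cell_size = 50), 0.95)$contiguous
  expect_true(contig(sel2$h))
  if (sel2$h * 0.95 >= 25) expect_false(contig(sel2$h * 0.95))
})

test_that("MCP area, containment, and asymptote behave as expected", {
  # 1-km square constructed in projected metres
  ctr <- c(-64.9, 32.3)
  sq <- aeqd_inverse(rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000)), ctr)
  m <- mcp(sq)
  expect_equal(m$area_km2, 1, tolerance = 0.001)

  # an interior point never changes the hull
  sq5 <- rbind(sq, aeqd_inverse(cbind(500, 500), ctr))
  expect_equal(mcp(sq5)$area_km2, m$area_km2, tolerance = 1e-9)

  # hull contains every input point
  set.seed(205)
  pts <- aeqd_inverse(cbind(rnorm(100, 0, 300), rnorm(100, 0, 300)), ctr)
  mh <- mcp(pts)
  xy <- aeqd_project(pts, center = mh$proj_center)$xy
  hull_grown <- mh$hull_xy * 1.0000001 +
    matrix(colMeans(mh$hull_xy) * -1e-7, nrow(mh$hull_xy), 2, byrow = TRUE)
  expect_true(all(points_in_polygon(xy, hull_grown)))

  # positions fixed after day 10 of 100: asymptote reached
  t0 <- as.POSIXct("2016-08-01", tz = "UTC")
  wander <- aeqd_inverse(cbind(c(seq(0, 900, length.out = 10), rep(900, 90)) +
                                 rnorm(100, 0, 20),
                               rnorm(100, 0, 20)), ctr)
  df <- data.frame(lon = wander[, 1], lat = wander[, 2],
                   timestamp = t0 + (0:99) * 86400)
  expect_true(mcp(df)$asymptote_reached)
})

test_that("the 50% UD recovers the planted foraging centre on resident tracks", {
  hits <- 0
  for (seed in 1:10) {
    cfg <- sim_config(seed = seed, retention_prob = 0.6, outlier_prob = 0)
    tr <- simulate_track(cfg, 30)
    fx <- qc_pipeline(observe_fixes(tr, cfg))$fixes
    pr <- aeqd_project(cbind(fx$lon, fx$lat))
    ud <- kde_ud(pr$xy, h = 100, cell_size = 50)
    i50 <- isopleth(ud, 0.50)
    ctr_xy <- aeqd_project(matrix(cfg$centers$foraging, ncol = 2),
                           center = pr$center)$xy
    ix <- which.min(abs(ud$x - ctr_xy[1]))
    iy <- which.min(abs(ud$y - ctr_xy[2]))
    if (i50$mask[ix, iy]) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("home-range summaries exclude flagged rows from the means", {
  df <- data.frame(id = c("a", "b", "c"), ud25 = c(0.1, 0.2, 9),
                   ud50 = c(0.3, 0.5, 9), ud90 = c(1, 2, 9),
                   mcp = c(2, 4, 9), exclude = c(FALSE, FALSE, TRUE))
  s <- summarize_home_ranges(df)
  expect_equal(unname(s$means["ud90"]), 1.5)
  single <- summarize_home_ranges(df[1, ])
  expect_equal(unname(single$means["ud25"]), 0.1)
})
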