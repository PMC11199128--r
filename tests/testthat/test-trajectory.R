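# Backward-trajectory integrator against the constant-wind analytic oracle,
# conservation and convergence properties.

test_that("zero wind leaves the parcel at the arrival point", {
  w <- make_constant_winds(0, 0)
  tr <- backtrack(w, 45, 145, arrival_time = utc("2004-12-10"), hours = 72)
  expect_true(all(tr$positions$lat == 45))
  expect_true(all(tr$positions$lon == 145))
  expect_false(tr$left_domain)
  feats <- trajectory_features(tr)
  expect_equal(feats$lat24, 45)
  expect_equal(feats$lat72, 45)
  expect_equal(feats$deg24, 0)  # degenerate bearing convention
})

test_that("constant meridional winds reproduce the closed-form displacement", {
  for (v in c(-10, 10)) {
    w <- make_constant_winds(0, v)
    tr <- backtrack(w, 45, 145, arrival_time = utc("2004-12-10"), hours = 24)
    want <- oracle_constant_backtrack(45, 145, 0, v, 24)
    got <- tr$positions[tr$positions$lag_hours == 24, ]
    expect_equal(got$lat, want[["lat"]], tolerance = 1e-9)
    expect_equal(got$lon, 145)
  }
  # northerly wind (v < 0) must RAISE lat24: the parcel came from the north
  w <- make_constant_winds(0, -10)
  tr <- backtrack(w, 45, 145, arrival_time = utc("2004-12-10"), hours = 24)
  expect_equal(tr$positions$lat[tr$positions$lag_hours == 24],
               52.77014, tolerance = 1e-4)
})

test_that("constant zonal wind matches the analytic zonal branch", {
  w <- make_constant_winds(10, 0)
  tr <- backtrack(w, 45, 145, arrival_time = utc("2004-12-10"), hours = 24)
  want <- oracle_constant_backtrack(45, 145, 10, 0, 24)
  got <- tr$positions[tr$positions$lag_hours == 24, ]
  expect_equal(got$lat, 45)
  expect_equal(got$lon, want[["lon"]], tolerance = 1e-9)
  expect_equal(got$lon, 134.0114, tolerance = 1e-3)
})

test_that("forward integration from the backward endpoint returns to arrival (constant winds)", {
  w <- make_constant_winds(7, -4)
  tr <- backtrack(w, 45, 145, arrival_time = utc("2004-12-10"), hours = 24)
  end <- tr$positions[tr$positions$lag_hours == 24, ]
  # forward Euler with the same constant wind, reversed in time
  lat <- end$lat; lon <- end$lon
  for (s in 1:24) {
    lat_next <- lat + (-4) * 3600 / (6371000 * pi / 180)
    lon <- lon + 7 * 3600 / (6371000 * pi / 180 * cos(lat * pi / 180))
    lat <- lat_next
  }
  expect_equal(lat, 45, tolerance = 1e-9)
  # longitude uses cos(lat at the current point); with varying lat the
  # forward path is not the exact mirror, so allow first-order slack there
  expect_equal(lon, 145, tolerance = 1e-3)
})

test_that("bearing_from_arrival covers the cardinal directions and wraps to [0, 360)", {
  expect_equal(bearing_from_arrival(45, 145, 50, 145), 0)
  expect_equal(bearing_from_arrival(45, 145, 45, 150), 90)
  expect_equal(bearing_from_arrival(45, 145, 45, 140), 270)
  expect_equal(bearing_from_arrival(45, 145, 40, 145), 180)
  b <- bearing_from_arrival(45, 145, 46, 144)
  expect_true(b >= 270 && b < 360)
})

test_that("features read the lagged positions and the analytic northerly case", {
  w <- make_constant_winds(0, -10, lats = seq(20, 80, 1.25))
  tr <- backtrack(w, 45, 145, arrival_time = utc("2004-12-10"), hours = 72)
  feats <- trajectory_features(tr)
  expect_equal(feats$lat24, 52.77014, tolerance = 1e-4)
  expect_equal(feats$lat48, 60.54028, tolerance = 1e-4)
  expect_equal(feats$deg24, 0, tolerance = 1e-9)
  expect_false(feats$left_domain)
})

test_that("a parcel exiting the grid is frozen at the boundary with the exit lag recorded", {
  w <- make_constant_winds(0, 30, lats = seq(40, 50, 1.25),
                           lons = seq(140, 150, 1.25))
  tr <- backtrack(w, 45, 145, arrival_time = utc("2004-12-10"), hours = 24)
  expect_true(tr$left_domain)
  expect_true(is.finite(tr$exit_lag_hours))
  expect_equal(min(tr$positions$lat), 40)  # frozen at the southern edge
  feats <- trajectory_features(tr)
  expect_true(feats$left_domain)
  expect_equal(feats$lat24, 40)
})

test_that("halving the step shows first-order convergence on a smooth rotating wind", {
  # smooth spatially varying wind from a synthetic low
  cy <- cyclone_spec(50, 150, -35, 700)
  day_idx <- seq(-1.25, 0.25, by = 0.25)
  slp <- gen_slp_field(day_idx, list(cy), noise_sd = 0, seed = 3,
                       origin = "2004-12-10",
                       domain = list(latitudes = seq(30, 70, 1.25),
                                     longitudes = seq(120, 180, 1.25)))
  w <- gen_wind_from_slp(slp)
  t0 <- utc("2004-12-10")
  ref <- backtrack(w, 45, 145, arrival_time = t0, hours = 24,
                   step_hours = 1 / 60)
  end <- function(tr) unlist(tr$positions[tr$positions$lag_hours == 24, c("lat", "lon")])
  e1 <- sqrt(sum((end(backtrack(w, 45, 145, arrival_time = t0, hours = 24,
                                step_hours = 1)) - end(ref))^2))
  e05 <- sqrt(sum((end(backtrack(w, 45, 145, arrival_time = t0, hours = 24,
                                 step_hours = 0.5)) - end(ref))^2))
  expect_gt(e1 / e05, 1.8)
})

test_that("solid-body rotation conserves the parcel's distance from the centre within 1%", {
  # circular streamlines about (50N, 150E), one revolution per 12 days (a
  # slow synoptic eddy); the zonal component carries a cos(lat) factor so
  # the lat-lon integrator sees exact planar rotation in the projected
  # coordinates x = lon * cos(50), y = lat
  lats <- seq(40, 60, 0.5); lons <- seq(135, 165, 0.5)
  times <- utc("2004-12-10") + seq(-26, 1) * 3600
  m_per_deg <- 6371000 * pi / 180
  omega <- 2 * pi / (12 * 86400)
  c_lat <- 50; c_lon <- 150
  cosc <- cos(c_lat * pi / 180)
  u <- array(0, c(length(times), length(lats), length(lons)))
  v <- array(0, c(length(times), length(lats), length(lons)))
  for (i in seq_along(lats)) for (j in seq_along(lons)) {
    dy <- (lats[i] - c_lat) * m_per_deg
    dx <- (lons[j] - c_lon) * m_per_deg * cosc
    u[, i, j] <- -omega * dy * cos(lats[i] * pi / 180) / cosc
    v[, i, j] <- omega * dx
  }
  w <- wind_pair(grid_field("u10", "m s-1", lats, lons, times, u),
                 grid_field("v10", "m s-1", lats, lons, times, v))
  tr <- backtrack(w, 52, 150, arrival_time = utc("2004-12-10"), hours = 24)
  radius <- function(lat, lon) {
    sqrt(((lat - c_lat) * m_per_deg)^2 + ((lon - c_lon) * m_per_deg * cosc)^2)
  }
  r0 <- radius(52, 150)
  r_end <- radius(tr$positions$lat[25], tr$positions$lon[25])
  expect_false(tr$left_domain)
  expect_lt(abs(r_end - r0) / r0, 0.01)
})

test_that("insufficient wind coverage or an arrival outside the grid errors", {
  w <- make_constant_winds(0, 0, hours = 10)
  expect_error(backtrack(w, 45, 145, arrival_time = utc("2004-12-10"), hours = 72),
               "coverage")
  w2 <- make_constant_winds(0, 0)
  expect_error(backtrack(w2, 10, 145, arrival_time = utc("2004-12-10"), hours = 24),
               "outside the wind grid")
})
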