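# Small field constructors shared across tests.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# uniform single-variable field over an arbitrary box
make_uniform_field <- function(value, times = utc("2004-12-10"),
                               lats = seq(35, 65, 1.25),
                               lons = seq(135, 165, 1.25),
                               variable = "slp", units = "hPa") {
  grid_field(variable, units, lats, lons, times,
             array(value, dim = c(length(times), length(lats), length(lons))))
}

# constant-wind pair covering [t0 - hours, t0 + 2h]
make_constant_winds <- function(u, v, t0 = utc("2004-12-10"), hours = 80,
                                lats = seq(20, 70, 1.25),
                                lons = seq(100, 180, 1.25)) {
  times <- t0 + seq(-hours, 2) * 3600
  wind_pair(
    make_uniform_field(u, times, lats, lons, "u10", "m s-1"),
    make_uniform_field(v, times, lats, lons, "v10", "m s-1"))
}

# closed-form endpoint of a constant-wind backtrack (the analytic oracle;
# longitude branch is exact because latitude never changes when v = 0)
oracle_constant_backtrack <- function(lat0, lon0, u, v, hours) {
  m_per_deg <- 6371 * 1000 * pi / 180
  lat <- lat0 - v * hours * 3600 / m_per_deg
  lon <- lon0 - u * hours * 3600 / (m_per_deg * cos(lat0 * pi / 180))
  c(lat = lat, lon = lon)
}

# cached one-winter synthetic weather (shared by several test files)
cached_weather <- local({
  cache <- list()
  function(n_winters = 1L, seed = 7L) {
    key <- sprintf("w%d_s%d", n_winters, seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- gen_weather_series(n_winters = n_winters, seed = seed)
    }
    cache[[key]]
  }
})
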