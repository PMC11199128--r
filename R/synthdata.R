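# Synthetic winter weather and sighting generator.
#
# Purpose: give every other module a dynamically coherent, fully known test
# bed — migrating Gaussian low-pressure systems over the Sea-of-Okhotsk
# domain, geostrophically balanced winds (so pressure patterns and winds
# covary the way composites do), smooth sea-ice fraction fields, and
# presence/absence records drawn from a known logistic truth on
# trajectory-derived covariates.  Geostrophy is deliberately the whole
# dynamics: the package needs pattern-wind covariance, not forecast skill.

#' Specify a synthetic migrating cyclone
#'
#' A Gaussian pressure anomaly whose centre is advected by a constant drift
#' velocity; optional birth/death days with 1-day amplitude ramps.
#'
#' @param center_lat,center_lon centre at `day = 0`, degrees.
#' @param amplitude pressure anomaly at the centre, hPa (negative = low;
#'   `|amplitude| <= 60`).
#' @param radius_sigma Gaussian radius, km (> 0).
#' @param drift_east,drift_north drift velocity, km/day.
#' @param birth_day,death_day days between which the system exists
#'   (amplitude ramps linearly over the first/last day); default always-on.
#' @return list of class `cyclone_spec`.
#' @export
cyclone_spec <- function(center_lat, center_lon, amplitude, radius_sigma,
                         drift_east = 0, drift_north = 0,
                         birth_day = -Inf, death_day = Inf) {
  stopifnot(radius_sigma > 0, abs(amplitude) <= 60)
  structure(list(center_lat = center_lat, center_lon = center_lon,
                 amplitude = amplitude, radius_sigma = radius_sigma,
                 drift_east = drift_east, drift_north = drift_north,
                 birth_day = birth_day, death_day = death_day),
            class = "cyclone_spec")
}

#' Default synthetic domain: the Sea-of-Okhotsk analysis box
#'
#' @param res grid spacing in degrees (default 1.25).
#' @return list `latitudes`, `longitudes` spanning 35-65N, 135-165E.
#' @export
default_domain <- function(res = 1.25) {
  list(latitudes = seq(35, 65, by = res), longitudes = seq(135, 165, by = res))
}

#' @noRd
haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  dlat <- (lat2 - lat1) * r
  dlon <- (lon2 - lon1) * r
  a <- sin(dlat / 2)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

# Smoothing kernel for the noise fields.  The default correlation length of
# 4 cells (~5 deg, ~500 km) keeps the noise synoptic-scale: sharper noise of
# the same amplitude would carry pressure gradients whose geostrophic winds
# rival the cyclones themselves, which no reanalysis residual does.
#' @noRd
gauss_smoother <- function(n, sigma_cells = 4) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  K <- exp(-d^2 / (2 * sigma_cells^2))
  K / rowSums(K)
}

#' Generate synthetic sea-level-pressure fields
#'
#' `p(x, day) = base + sum_i A_i(day) * exp(-d_i^2 / (2 sigma_i^2)) + noise`,
#' where `d_i` is the great-circle distance to cyclone `i`'s centre advected
#' by its drift times `day`, and the noise is spatially smooth with AR(1)
#' day-to-day persistence (`phi` per day; fractional steps use
#' `phi^delta`).  Deterministic for a fixed seed.
#'
#' @param day_index numeric vector of days (fractions allowed, e.g. 0.25 for
#'   06 UTC); one output time per element.
#' @param cyclones list of [cyclone_spec()]s.
#' @param base_pressure background pressure, hPa (default 1012).
#' @param noise_sd marginal sd of the smooth noise, hPa (default 3).
#' @param seed integer seed.
#' @param origin date of `day_index = 0` (default `"2004-11-01"`, i.e. a
#'   season start).
#' @param domain from [default_domain()].
#' @param phi AR(1) persistence per day (default 0.7).
#' @return an SLP [grid_field] (hPa) with one time per `day_index`.
#' @export
gen_slp_field <- function(day_index, cyclones = list(), base_pressure = 1012,
                          noise_sd = 3, seed = 1L, origin = "2004-11-01",
                          domain = default_domain(), phi = 0.7) {
  day_index <- sort(as.numeric(day_index))
  lats <- domain$latitudes
  lons <- domain$longitudes
  nlat <- length(lats); nlon <- length(lons)
  grid_lat <- matrix(lats, nlat, nlon)
  grid_lon <- matrix(lons, nlat, nlon, byrow = TRUE)
  Slat <- gauss_smoother(nlat)
  Slon <- gauss_smoother(nlon)
  vals <- array(0, dim = c(length(day_index), nlat, nlon))
  withr::with_seed(seed, {
    state <- matrix(0, nlat, nlon)
    if (noise_sd > 0) {
      z <- Slat %*% matrix(stats::rnorm(nlat * nlon), nlat, nlon) %*% Slon
      state <- z / stats::sd(z) * noise_sd
    }
    prev_day <- day_index[1]
    for (k in seq_along(day_index)) {
      d <- day_index[k]
      if (k > 1 && noise_sd > 0) {
        a <- phi^(d - prev_day)
        z <- Slat %*% matrix(stats::rnorm(nlat * nlon), nlat, nlon) %*% Slon
        z <- z / stats::sd(z) * noise_sd
        state <- a * state + sqrt(max(1 - a^2, 0)) * z
      }
      slice <- matrix(base_pressure, nlat, nlon) + state
      for (cy in cyclones) {
        amp <- cyclone_amplitude(cy, d)
        if (amp == 0) next
        c_lat <- cy$center_lat + cy$drift_north * d / (M_PER_DEG / 1000)
        c_lon <- cy$center_lon + cy$drift_east * d /
          ((M_PER_DEG / 1000) * cos(c_lat * pi / 180))
        dist <- haversine_km(grid_lat, grid_lon, c_lat, c_lon)
        slice <- slice + amp * exp(-dist^2 / (2 * cy$radius_sigma^2))
      }
      vals[k, , ] <- slice
      prev_day <- d
    }
  })
  times <- as_utc(as.Date(origin)) + day_index * 86400
  grid_field("slp", "hPa", lats, lons, times, vals)
}

#' @noRd
cyclone_amplitude <- function(cy, day) {
  if (day < cy$birth_day || day > cy$death_day) return(0)
  ramp_in <- min(1, day - cy$birth_day)
  ramp_out <- min(1, cy$death_day - day)
  cy$amplitude * max(0, min(ramp_in, ramp_out, 1))
}

#' Geostrophic winds from an SLP field
#'
#' `u = -(1 / (rho f)) dp/dy`, `v = (1 / (rho f)) dp/dx`, with
#' `f = 2 Omega sin(lat)`, centred finite differences (one-sided at edges),
#' and wind speed capped at `wind_cap` (the geostrophic approximation blows
#' up in tight gradients).  Refuses latitudes within 5 degrees of the
#' equator where `f` vanishes.
#'
#' @param slp an SLP [grid_field] (any number of times).
#' @param rho air density, kg/m^3 (default 1.25).
#' @param wind_cap maximum wind speed, m/s (default 40).
#' @return a [wind_pair()] of `u10`, `v10` fields (m/s).
#' @export
gen_wind_from_slp <- function(slp, rho = 1.25, wind_cap = 40) {
  lats <- slp$latitudes
  if (any(abs(lats) < 5)) stopf("geostrophic wind undefined within 5 deg of the equator")
  lons <- slp$longitudes
  nlat <- length(lats); nlon <- length(lons)
  f <- 2 * OMEGA_EARTH * sin(lats * pi / 180)
  dy <- M_PER_DEG * c(diff(lats)[1], diff(lats))          # m between rows
  dx <- M_PER_DEG * cos(lats * pi / 180) * diff(lons)[1]  # m between cols, per row
  u_arr <- v_arr <- array(0, dim = dim(slp$values))
  ddy <- function(M) {
    out <- M
    n <- nrow(M)
    out[2:(n - 1), ] <- (M[3:n, ] - M[1:(n - 2), ]) / (2 * dy[2])
    out[1, ] <- (M[2, ] - M[1, ]) / dy[2]
    out[n, ] <- (M[n, ] - M[n - 1, ]) / dy[2]
    out
  }
  ddx <- function(M) {
    out <- M
    n <- ncol(M)
    step <- matrix(dx, nrow(M), n)
    out[, 2:(n - 1)] <- (M[, 3:n] - M[, 1:(n - 2)]) / (2 * step[, 2:(n - 1)])
    out[, 1] <- (M[, 2] - M[, 1]) / step[, 1]
    out[, n] <- (M[, n] - M[, n - 1]) / step[, n]
    out
  }
  for (k in seq_along(slp$times)) {
    p <- matrix(slp$values[k, , ], nlat, nlon) * 100  # hPa -> Pa
    inv_rf <- 1 / (rho * f)
    u <- -inv_rf * ddy(p)
    v <- inv_rf * ddx(p)
    spd <- sqrt(u^2 + v^2)
    over <- spd > wind_cap
    if (any(over)) {
      sc <- wind_cap / spd[over]
      u[over] <- u[over] * sc
      v[over] <- v[over] * sc
    }
    u_arr[k, , ] <- u
    v_arr[k, , ] <- v
  }
  wind_pair(
    grid_field("u10", "m s-1", lats, lons, slp$times, u_arr),
    grid_field("v10", "m s-1", lats, lons, slp$times, v_arr)
  )
}

#' Synthetic sea-ice fraction fields
#'
#' Smooth fractions in \[0, 1\] with a north-south gradient (heavier ice in
#' the north of the basin, growing as the season advances) plus smooth AR(1)
#' noise.  Ice dynamics are deliberately absent.
#'
#' @param day_index numeric vector of days.
#' @param seed integer seed.
#' @param origin,domain,phi as in [gen_slp_field()].
#' @param noise_sd sd of the (logit-scale) noise (default 0.6).
#' @return an ice-fraction [grid_field].
#' @export
gen_ice_field <- function(day_index, seed = 1L, origin = "2004-11-01",
                          domain = default_domain(), phi = 0.95,
                          noise_sd = 0.6) {
  day_index <- sort(as.numeric(day_index))
  lats <- domain$latitudes
  lons <- domain$longitudes
  nlat <- length(lats); nlon <- length(lons)
  Slat <- gauss_smoother(nlat, 3)
  Slon <- gauss_smoother(nlon, 3)
  vals <- array(0, dim = c(length(day_index), nlat, nlon))
  base_lat <- matrix(lats, nlat, nlon)
  withr::with_seed(seed + 1L, {
    z <- Slat %*% matrix(stats::rnorm(nlat * nlon), nlat, nlon) %*% Slon
    state <- z / stats::sd(z) * noise_sd
    prev <- day_index[1]
    for (k in seq_along(day_index)) {
      d <- day_index[k]
      if (k > 1) {
        a <- phi^(d - prev)
        z <- Slat %*% matrix(stats::rnorm(nlat * nlon), nlat, nlon) %*% Slon
        z <- z / stats::sd(z) * noise_sd
        state <- a * state + sqrt(max(1 - a^2, 0)) * z
      }
      edge_lat <- 58 - 6 * min(d / 90, 1.5)  # ice edge advances south with season
      vals[k, , ] <- stats::plogis((base_lat - edge_lat) / 2 + state)
      prev <- d
    }
  })
  times <- as_utc(as.Date(origin)) + day_index * 86400
  grid_field("ice", "fraction", lats, lons, times, vals)
}

#' Known logistic truth for synthetic sightings
#'
#' Coefficients act on within-sample scaled covariates.  Defaults mirror the
#' fitted best model for the real study site (intercept -2.38, ordinal date
#' 0.48, parcel latitude 24 h before arrival 1.74, observation duration
#' 0.59), so parameter-recovery tests target those values.
#'
#' @param beta0 intercept.
#' @param beta_lat24,beta_date,beta_duration slopes on scaled covariates.
#' @return list of class `truth_model`.
#' @export
truth_model <- function(beta0 = -2.38, beta_lat24 = 1.74, beta_date = 0.48,
                        beta_duration = 0.59) {
  stopifnot(is.finite(c(beta0, beta_lat24, beta_date, beta_duration)))
  structure(list(beta0 = beta0, beta_lat24 = beta_lat24,
                 beta_date = beta_date, beta_duration = beta_duration),
            class = "truth_model")
}

#' Generate a multi-winter synthetic weather archive
#'
#' For each winter (Nov 1 - Feb 28, with a 3-day spin-up so the first day
#' has trajectory history), draws a schedule of migrating lows (born every
#' ~4 days near the western edge, drifting east-northeast, living 4-8 days)
#' and produces 6-hourly SLP, geostrophic winds, and daily ice fields.
#'
#' @param n_winters number of winters (default 1).
#' @param seed integer seed.
#' @param start_year first season's year (default 2004: winter 2004/05).
#' @param step_hours SLP/wind time step (default 6).
#' @param days_per_winter days from Nov 1 (default 120, through Feb).
#' @param noise_sd SLP noise sd, hPa.
#' @param domain from [default_domain()].
#' @return list: `slp` (grid_field), `winds` ([wind_pair()]), `ice`
#'   (grid_field, daily), `dates` (Date vector of the n_winters x
#'   days_per_winter study days).
#' @export
gen_weather_series <- function(n_winters = 1L, seed = 1L, start_year = 2004L,
                               step_hours = 6, days_per_winter = 120L,
                               noise_sd = 3, domain = default_domain()) {
  spinup <- 3
  slp_parts <- list()
  ice_parts <- list()
  dates <- as.Date(character())
  for (w in seq_len(n_winters)) {
    origin <- as.Date(sprintf("%d-11-01", start_year + w - 1L))
    wseed <- seed + 1000L * w
    cyclones <- withr::with_seed(wseed, {
      cys <- list()
      d <- -spinup + stats::runif(1, 0, 2)
      while (d < days_per_winter) {
        cys[[length(cys) + 1L]] <- cyclone_spec(
          center_lat = stats::runif(1, 38, 52),
          center_lon = stats::runif(1, 130, 142),
          amplitude = -stats::runif(1, 15, 45),
          radius_sigma = stats::runif(1, 500, 900),
          drift_east = stats::runif(1, 500, 1100),
          drift_north = stats::runif(1, -100, 400),
          birth_day = d,
          death_day = d + stats::runif(1, 4, 8))
        d <- d + stats::runif(1, 2.5, 5.5)
      }
      cys
    })
    day_idx <- seq(-spinup, days_per_winter - 1 + 18 / 24, by = step_hours / 24)
    slp_parts[[w]] <- gen_slp_field(day_idx, cyclones, noise_sd = noise_sd,
                                    seed = wseed, origin = origin,
                                    domain = domain)
    ice_parts[[w]] <- gen_ice_field(seq(-spinup, days_per_winter - 1),
                                    seed = wseed, origin = origin,
                                    domain = domain)
    dates <- c(dates, origin + 0:(days_per_winter - 1L))
  }
  bind_fields <- function(parts) {
    times <- do.call(c, lapply(parts, function(p) p$times))
    vals <- array(0, dim = c(length(times), dim(parts[[1]]$values)[2],
                             dim(parts[[1]]$values)[3]))
    k <- 0L
    for (p in parts) {
      n <- length(p$times)
      vals[k + seq_len(n), , ] <- p$values
      k <- k + n
    }
    grid_field(parts[[1]]$variable, parts[[1]]$units,
               parts[[1]]$latitudes, parts[[1]]$longitudes, times, vals)
  }
  slp <- bind_fields(slp_parts)
  list(slp = slp, winds = gen_wind_from_slp(slp), ice = bind_fields(ice_parts),
       dates = dates)
}

#' @noRd
wind_covers <- function(winds, t0, t1, max_gap_hours = 12) {
  tn <- as.numeric(winds$u$times)
  a <- as.numeric(as_utc(t0)); b <- as.numeric(as_utc(t1))
  if (a < tn[1] - 1 || b > tn[length(tn)] + 1) return(FALSE)
  sel <- tn[tn >= a - max_gap_hours * 3600 & tn <= b + max_gap_hours * 3600]
  length(sel) >= 2 && max(diff(sel)) <= max_gap_hours * 3600
}

#' Generate synthetic sighting records from a known logistic truth
#'
#' For each candidate day (00 UTC arrival with at least 24 h of wind
#' history), computes the parcel latitude 24 h before arrival via
#' [backtrack()], scales the covariates (lat24, season ordinal date,
#' observation duration) within the sample, draws presence from
#' `Bernoulli(plogis(truth %*% x))`, and gives presence days a
#' zero-truncated negative-binomial count (mean 35, dispersion matched to
#' the observed sd of ~64; counts are cosmetic — presence drives all
#' downstream fitting).
#'
#' @param n_days number of records to generate.
#' @param winds a [wind_pair()] archive (see [gen_weather_series()]).
#' @param truth a [truth_model()].
#' @param duration_dist `c(mean, sd)` minutes of the truncated-normal
#'   observation duration (default `c(77.47, 65.83)`, the study-site
#'   protocol; minimum 15 min).
#' @param seed integer seed.
#' @param arrival_lat,arrival_lon trajectory arrival point.
#' @param site site label.
#' @return a [sighting_records] table with an attached `"covariates"`
#'   attribute (data.frame: `date`, `lat24`, `date_ordinal`,
#'   `duration_min`, `presence`, `left_domain`) for direct model fitting.
#' @export
gen_sightings <- function(n_days, winds, truth = truth_model(),
                          duration_dist = c(77.47, 65.83), seed = 1L,
                          arrival_lat = 45.0, arrival_lon = 145.0,
                          site = "site1") {
  all_days <- unique(as.Date(winds$u$times, tz = "UTC"))
  all_days <- all_days[as.integer(format(all_days, "%m")) %in% c(11L, 12L, 1L, 2L, 3L)]
  cand <- all_days[vapply(all_days, function(d) {
    t1 <- as_utc(d)
    wind_covers(winds, t1 - 24 * 3600, t1)
  }, TRUE)]
  if (length(cand) < n_days) {
    stopf("only %d days have 24 h of wind history; %d requested",
          length(cand), n_days)
  }
  days <- cand[seq_len(n_days)]
  lat24 <- numeric(n_days)
  left <- logical(n_days)
  for (i in seq_len(n_days)) {
    tr <- backtrack(winds, arrival_lat, arrival_lon,
                    arrival_time = as_utc(days[i]), hours = 24)
    lat24[i] <- tr$positions$lat[tr$positions$lag_hours == 24]
    left[i] <- tr$left_domain
  }
  ords <- vapply(days, date_ordinal, 1)
  withr::with_seed(seed, {
    dur <- pmax(15, round(stats::rnorm(n_days, duration_dist[1], duration_dist[2])))
    zs <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
    eta <- truth$beta0 + truth$beta_lat24 * zs(lat24) +
      truth$beta_date * zs(ords) + truth$beta_duration * zs(dur)
    presence <- stats::runif(n_days) < stats::plogis(eta)
    counts <- integer(n_days)
    # zero-truncated NB: mean 35, size tuned so sd ~ 64
    for (i in which(presence)) {
      x <- 0L
      while (x == 0L) x <- stats::rnbinom(1, mu = 35, size = 0.298)
      counts[i] <- x
    }
  })
  rec <- sighting_records(days, site, dur, counts)
  attr(rec, "covariates") <- data.frame(
    date = days, lat24 = lat24, date_ordinal = ords, duration_min = dur,
    presence = presence, left_domain = left)
  rec
}
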