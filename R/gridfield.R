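# Gridded meteorological fields: the container every other module consumes.

#' Construct a gridded meteorological field
#'
#' A `grid_field` is a time-stamped stack of 2-D lat-lon rasters of a single
#' meteorological variable (sea-level pressure in hPa, a wind component in
#' m/s, or sea-ice fraction in \[0, 1\]).  Axes are stored ascending;
#' longitudes are degrees east normalised to \[0, 360); values are indexed
#' `[time, lat, lon]` with grid-cell-centre registration.
#'
#' @param variable short variable name, e.g. `"slp"`, `"u10"`, `"v10"`,
#'   `"ice"`.
#' @param units unit string: `"hPa"`, `"m s-1"` or `"fraction"`.
#' @param latitudes strictly monotone vector of degrees north (stored
#'   ascending).
#' @param longitudes strictly monotone vector of degrees east (normalised to
#'   \[0, 360) and stored ascending).
#' @param times vector of UTC timestamps (`POSIXct`, `Date`, or anything
#'   `as.POSIXct` accepts), strictly increasing.
#' @param values numeric array of dim `c(length(times), nlat, nlon)`.  A
#'   matrix is accepted for a single time.
#' @return an object of class `grid_field`.
#' @details Sea-level pressure values are validated against the physical
#'   range \[870, 1090\] hPa; ice fractions against \[0, 1\].
#' @export
grid_field <- function(variable, units, latitudes, longitudes, times, values) {
  if (is.matrix(values)) {
    values <- array(values, dim = c(1L, nrow(values), ncol(values)))
  }
  times <- as_utc(times)
  lat_ord <- order(latitudes)
  lon_raw <- longitudes %% 360
  lon_ord <- order(lon_raw)
  t_ord <- order(times)
  values <- values[t_ord, lat_ord, lon_ord, drop = FALSE]
  f <- structure(
    list(
      variable = as.character(variable),
      units = as.character(units),
      latitudes = as.numeric(latitudes[lat_ord]),
      longitudes = as.numeric(lon_raw[lon_ord]),
      times = times[t_ord],
      values = values
    ),
    class = "grid_field"
  )
  validate_grid_field(f)
  f
}

#' @noRd
validate_grid_field <- function(f) {
  if (any(diff(f$latitudes) <= 0)) stopf("latitudes must be strictly monotone")
  if (any(diff(f$longitudes) <= 0)) stopf("longitudes must be strictly monotone")
  if (length(f$times) > 1 && any(diff(as.numeric(f$times)) <= 0)) {
    stopf("times must be strictly increasing")
  }
  dv <- dim(f$values)
  if (length(dv) != 3 ||
      dv[1] != length(f$times) ||
      dv[2] != length(f$latitudes) ||
      dv[3] != length(f$longitudes)) {
    stopf("values dimensions (%s) inconsistent with axes (%d, %d, %d)",
          paste(dv, collapse = ","),
          length(f$times), length(f$latitudes), length(f$longitudes))
  }
  if (identical(tolower(f$variable), "slp")) {
    if (any(!is.finite(f$values))) stopf("SLP values must be finite")
    rng <- range(f$values)
    if (rng[1] < 870 || rng[2] > 1090) {
      stopf("SLP values outside physical range [870, 1090] hPa: [%.1f, %.1f]",
            rng[1], rng[2])
    }
  }
  if (identical(tolower(f$variable), "ice")) {
    v <- f$values[is.finite(f$values)]
    if (length(v) && (min(v) < 0 || max(v) > 1)) {
      stopf("ice fraction outside [0, 1]")
    }
  }
  invisible(f)
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<grid_field> %s [%s]\n", x$variable, x$units))
  cat(sprintf("  %d time(s) %s .. %s\n", length(x$times),
              format(x$times[1], "%Y-%m-%d %H:%M", tz = "UTC"),
              format(x$times[length(x$times)], "%Y-%m-%d %H:%M", tz = "UTC")))
  cat(sprintf("  lat %g..%g (n=%d)  lon %g..%g (n=%d)\n",
              min(x$latitudes), max(x$latitudes), length(x$latitudes),
              min(x$longitudes), max(x$longitudes), length(x$longitudes)))
  invisible(x)
}

#' Pair of wind-component fields
#'
#' Bundles the eastward (`u`) and northward (`v`) 10-m wind components on
#' identical axes.
#'
#' @param u,v `grid_field`s of the eastward / northward components (m/s).
#' @return an object of class `wind_pair`.
#' @export
wind_pair <- function(u, v) {
  stopifnot(inherits(u, "grid_field"), inherits(v, "grid_field"))
  if (!isTRUE(all.equal(u$latitudes, v$latitudes)) ||
      !isTRUE(all.equal(u$longitudes, v$longitudes)) ||
      !identical(as.numeric(u$times), as.numeric(v$times))) {
    stopf("u and v must share identical axes")
  }
  structure(list(u = u, v = v), class = "wind_pair")
}

#' Read one variable from a NetCDF file into a grid_field
#'
#' CF-style coordinate names (`lat`/`latitude`, `lon`/`longitude`, `time`)
#' are auto-detected; axes are sorted ascending and longitudes normalised to
#' \[0, 360).  Only regular lat-lon grids are supported.
#'
#' @param path NetCDF file path.
#' @param variable variable name to read.
#' @return a [grid_field].
#' @export
read_grid <- function(path, variable) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  if (!variable %in% names(nc$var)) {
    stopf("variable '%s' not found; available: %s", variable,
          paste(names(nc$var), collapse = ", "))
  }
  dims <- nc$var[[variable]]$dim
  dim_names <- vapply(dims, function(d) d$name, "")
  find_dim <- function(cands) {
    i <- which(tolower(dim_names) %in% cands)
    if (!length(i)) stopf("no %s coordinate among (%s)",
                          cands[1], paste(dim_names, collapse = ", "))
    i[1]
  }
  i_lat <- find_dim(c("lat", "latitude", "y"))
  i_lon <- find_dim(c("lon", "longitude", "x"))
  i_time <- find_dim(c("time", "t"))
  lats <- dims[[i_lat]]$vals
  lons <- dims[[i_lon]]$vals
  for (ax in list(lats, lons)) {
    if (length(ax) > 2 && max(abs(diff(diff(ax)))) > 1e-6 * max(abs(diff(ax)))) {
      stopf("non-regular grid spacing is not supported")
    }
  }
  tdim <- dims[[i_time]]
  t_units <- tdim$units %||% "seconds since 1970-01-01 00:00:00"
  origin <- sub("^.*since\\s+", "", t_units)
  mult <- switch(sub("\\s+since.*$", "", tolower(t_units)),
                 "seconds" = 1, "minutes" = 60, "hours" = 3600,
                 "days" = 86400,
                 stopf("unsupported time units '%s'", t_units))
  times <- as.POSIXct(origin, tz = "UTC") + tdim$vals * mult
  raw <- ncdf4::ncvar_get(nc, variable, collapse_degen = FALSE)
  # ncvar_get returns dims in file order; permute to (time, lat, lon)
  vals <- aperm(array(raw, dim = vapply(dims, function(d) d$len, 1L)),
                c(i_time, i_lat, i_lon))
  units <- ncdf4::ncatt_get(nc, variable, "units")
  units <- if (isTRUE(units$hasatt)) units$value else ""
  grid_field(variable, units, lats, lons, times, vals)
}

#' Write a grid_field to a CF-style NetCDF file
#'
#' @param field a [grid_field].
#' @param path output path (overwritten).
#' @return `path`, invisibly.
#' @export
write_grid <- function(field, path) {
  stopifnot(inherits(field, "grid_field"))
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", field$latitudes)
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", field$longitudes)
  dim_time <- ncdf4::ncdim_def(
    "time", "seconds since 1970-01-01 00:00:00",
    as.numeric(field$times), unlim = TRUE)
  # CF layout: lon fastest, time the record dimension
  var <- ncdf4::ncvar_def(field$variable, field$units,
                          list(dim_lon, dim_lat, dim_time),
                          missval = 1e30, prec = "double")
  nc <- ncdf4::nc_create(path, list(var))
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ncdf4::ncvar_put(nc, var, aperm(field$values, c(3, 2, 1)))
  invisible(path)
}

#' Bilinear space / linear time interpolation of a gridded field
#'
#' Interpolates bilinearly between the four surrounding grid-cell centres at
#' each bracketing snapshot, then linearly in time.  Exact on grid nodes at
#' snapshot times and for any field affine in (lat, lon, t).  No
#' extrapolation: a query outside the grid hull or the time range is a hard
#' error, so that trajectories leaving the domain are detected rather than
#' silently extended.
#'
#' @param field a [grid_field].
#' @param lat,lon query point, degrees.
#' @param t query time (UTC).
#' @return interpolated value (scalar).
#' @export
interp_space_time <- function(field, lat, lon, t) {
  lats <- field$latitudes
  lons <- field$longitudes
  lon <- lon %% 360
  if (lat < lats[1] || lat > lats[length(lats)] ||
      lon < lons[1] || lon > lons[length(lons)]) {
    stopf("point (%.3f, %.3f) outside grid hull [%g, %g] x [%g, %g]",
          lat, lon, lats[1], lats[length(lats)], lons[1], lons[length(lons)])
  }
  tn <- as.numeric(as_utc(t))
  ft <- as.numeric(field$times)
  nt <- length(ft)
  if (tn < ft[1] - 1e-6 || tn > ft[nt] + 1e-6) {
    stopf("time %s outside field range [%s, %s]",
          format(as_utc(t)), format(field$times[1]), format(field$times[nt]))
  }
  i <- min(max(findInterval(lat, lats), 1L), length(lats) - 1L)
  j <- min(max(findInterval(lon, lons), 1L), length(lons) - 1L)
  if (length(lats) == 1L) i <- 1L
  if (length(lons) == 1L) j <- 1L
  wy <- if (length(lats) == 1L) 0 else (lat - lats[i]) / (lats[i + 1] - lats[i])
  wx <- if (length(lons) == 1L) 0 else (lon - lons[j]) / (lons[j + 1] - lons[j])
  i2 <- if (length(lats) == 1L) 1L else i + 1L
  j2 <- if (length(lons) == 1L) 1L else j + 1L
  plane <- function(k) {
    v <- field$values
    (1 - wy) * ((1 - wx) * v[k, i, j] + wx * v[k, i, j2]) +
      wy * ((1 - wx) * v[k, i2, j] + wx * v[k, i2, j2])
  }
  k <- min(max(findInterval(tn, ft), 1L), max(nt - 1L, 1L))
  if (nt == 1L) return(plane(1L))
  wt <- (tn - ft[k]) / (ft[k + 1] - ft[k])
  wt <- min(max(wt, 0), 1)
  (1 - wt) * plane(k) + wt * plane(k + 1L)
}

#' Daily mean of sub-daily snapshots
#'
#' Reduces all snapshots falling within one UTC calendar day to their
#' arithmetic mean, the standard reanalysis convention for "daily" fields.
#' The output carries the day (00 UTC) as its timestamp.
#'
#' @param field a [grid_field].
#' @param day a `Date` (or string coercible to one).
#' @return a single-time [grid_field].
#' @export
daily_mean <- function(field, day) {
  day <- as.Date(day)
  d0 <- as.numeric(as_utc(day))
  tn <- as.numeric(field$times)
  sel <- which(tn >= d0 & tn < d0 + 86400)
  if (!length(sel)) stopf("no snapshots within UTC day %s", format(day))
  vals <- field$values[sel, , , drop = FALSE]
  m <- apply(vals, c(2, 3), mean)
  grid_field(field$variable, field$units, field$latitudes, field$longitudes,
             as_utc(day), m)
}

#' Subset a field to a lat-lon box
#'
#' Keeps grid cells whose centres lie inside the closed box.
#'
#' @param field a [grid_field].
#' @param lat_min,lat_max,lon_min,lon_max box bounds, degrees.
#' @return a [grid_field] on the reduced axes.
#' @export
subset_region <- function(field, lat_min, lat_max, lon_min, lon_max) {
  sel_lat <- which(field$latitudes >= lat_min & field$latitudes <= lat_max)
  sel_lon <- which(field$longitudes >= lon_min %% 360 &
                   field$longitudes <= lon_max %% 360)
  if (!length(sel_lat) || !length(sel_lon)) {
    stopf("subset box [%g, %g] x [%g, %g] does not intersect the grid",
          lat_min, lat_max, lon_min, lon_max)
  }
  grid_field(field$variable, field$units,
             field$latitudes[sel_lat], field$longitudes[sel_lon],
             field$times,
             field$values[, sel_lat, sel_lon, drop = FALSE])
}

#' Extract one time slice as a matrix
#'
#' @param field a [grid_field].
#' @param t time of the slice (must match a stored snapshot); default the
#'   first.
#' @return matrix `[lat, lon]`.
#' @export
field_slice <- function(field, t = NULL) {
  k <- 1L
  if (!is.null(t)) {
    k <- which(abs(as.numeric(field$times) - as.numeric(as_utc(t))) < 1e-3)
    if (length(k) != 1L) stopf("no snapshot at %s", format(as_utc(t)))
  }
  matrix(field$values[k, , ], nrow = length(field$latitudes),
         dimnames = list(NULL, NULL))
}

#' Flatten a single-time slice to a pattern vector
#'
#' Row-major over latitude rows: element `(i-1)*nlon + j` is the cell at
#' `latitudes[i]`, `longitudes[j]`.  The ordering is stable and inverted by
#' [unflatten_pattern()].
#'
#' @param slice matrix `[lat, lon]` (e.g. from [field_slice()]), or a
#'   single-time [grid_field].
#' @return numeric vector of length `nlat * nlon`.
#' @export
flatten_pattern <- function(slice) {
  if (inherits(slice, "grid_field")) {
    if (length(slice$times) != 1L) stopf("flatten_pattern needs a single time slice")
    slice <- field_slice(slice)
  }
  as.vector(t(slice))
}

#' Invert [flatten_pattern()]
#'
#' @param x pattern vector.
#' @param nlat,nlon grid dimensions.
#' @return matrix `[lat, lon]`.
#' @export
unflatten_pattern <- function(x, nlat, nlon) {
  if (length(x) != nlat * nlon) stopf("length %d != %d x %d", length(x), nlat, nlon)
  t(matrix(x, nrow = nlon, ncol = nlat))
}
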