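# Sea-ice extent covariates: area-weighted mean ice fraction over the
# Sea-of-Okhotsk mask and its halves north/south of 51N.

#' Default rectangular Sea-of-Okhotsk mask
#'
#' A rectangular proxy for the basin (44-62N, 135-157E) on the given axes.
#' Supply a bespoke mask (e.g. read from NetCDF) when basin fidelity
#' matters; cells that are `NA` in the ice field are excluded from the
#' weighting automatically, so land handled by the ice product's missing
#' values needs no extra flagging here.
#'
#' @param latitudes,longitudes grid axes.
#' @param lat_min,lat_max,lon_min,lon_max box bounds.
#' @return logical matrix `[lat, lon]`.
#' @export
okhotsk_mask <- function(latitudes, longitudes, lat_min = 44, lat_max = 62,
                         lon_min = 135, lon_max = 157) {
  outer(latitudes >= lat_min & latitudes <= lat_max,
        longitudes >= lon_min & longitudes <= lon_max, "&")
}

#' Area-weighted sea-ice extent of the basin and its halves
#'
#' Computes the cos-latitude-area-weighted mean ice fraction over the masked
#' cells (`extent_whole`), over masked cells north of `split_lat`
#' (`extent_north`, cells at exactly `split_lat` count as north), and south
#' of it (`extent_south`).  "Extent" here is mean concentration; set
#' `threshold = 0.15` for the conventional fraction-of-area-above-15%
#' definition instead.
#'
#' @param ice single-time ice-fraction [grid_field] (or matrix slice with
#'   axes supplied via `latitudes`).
#' @param mask logical matrix `[lat, lon]` (default [okhotsk_mask()]).
#' @param split_lat north/south split, degrees (default 51).
#' @param threshold if non-`NULL`, compute thresholded extent (weighted
#'   fraction of cells with concentration >= threshold) instead of mean
#'   concentration.
#' @return list of class `ice_extent`: `date`, `extent_whole`,
#'   `extent_north`, `extent_south`.
#' @export
compute_ice_extent <- function(ice, mask = NULL, split_lat = 51.0,
                               threshold = NULL) {
  stopifnot(inherits(ice, "grid_field"))
  if (length(ice$times) != 1L) stopf("compute_ice_extent needs a single time slice")
  lats <- ice$latitudes
  vals <- field_slice(ice)
  if (!is.null(threshold)) vals <- (vals >= threshold) * 1
  mask <- mask %||% okhotsk_mask(lats, ice$longitudes)
  if (!any(mask)) stopf("empty mask region")
  wlat <- matrix(cos(lats * pi / 180), length(lats), length(ice$longitudes))
  ok <- mask & is.finite(vals)
  wmean <- function(sel) {
    if (!any(sel)) return(NA_real_)
    sum(vals[sel] * wlat[sel]) / sum(wlat[sel])
  }
  north <- ok & matrix(lats >= split_lat, length(lats), length(ice$longitudes))
  structure(list(date = as.Date(ice$times[1], tz = "UTC"),
                 extent_whole = wmean(ok),
                 extent_north = wmean(north),
                 extent_south = wmean(ok & !north)),
            class = "ice_extent")
}

#' @export
print.ice_extent <- function(x, ...) {
  cat(sprintf("<ice_extent> %s  whole %.3f  north %.3f  south %.3f\n",
              format(x$date), x$extent_whole, x$extent_north, x$extent_south))
  invisible(x)
}
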