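# Shared physical constants and small helpers.

# Mean Earth radius used throughout for metre <-> degree conversion.
EARTH_RADIUS_KM <- 6371.0
# Metres per degree of latitude (and of longitude at the equator).
M_PER_DEG <- EARTH_RADIUS_KM * 1000 * pi / 180
# Earth's angular velocity, rad/s (Coriolis parameter f = 2*omega*sin(lat)).
OMEGA_EARTH <- 7.292115e-5

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
as_utc <- function(t) {
  if (inherits(t, "POSIXct")) {
    attr(t, "tzone") <- "UTC"
    return(t)
  }
  if (inherits(t, "Date")) {
    return(as.POSIXct(as.character(t), tz = "UTC"))
  }
  as.POSIXct(t, tz = "UTC")
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
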