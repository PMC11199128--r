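# Forecast driver: run both methods off predicted meteorological fields for
# 1-5-day leads and emit a joint report.  The two methods are reported side
# by side and never averaged.

#' Season ordinal date (November 1 = 1)
#'
#' Counts continuously from November 1 through the winter: Dec 1 = 31,
#' Feb 10 = 102, Mar 31 = 151.  Dates outside November-March are an error —
#' the vagrancy season and the pattern-training window end there.
#'
#' @param date a `Date` (or string).
#' @return integer ordinal.
#' @export
date_ordinal <- function(date) {
  date <- as.Date(date)
  m <- as.integer(format(date, "%m"))
  d <- as.integer(format(date, "%d"))
  offset <- c(`11` = 0L, `12` = 30L, `1` = 61L, `2` = 92L, `3` = 120L)
  if (!as.character(m) %in% names(offset)) {
    stopf("%s outside the November-March season window", format(date))
  }
  offset[[as.character(m)]] + d
}

#' One focal-day forecast through both methods
#'
#' Method A classifies the predicted SLP snapshot valid at `snapshot_hour`
#' UTC of the focal day to its best-matching node and reports that node's
#' empirical sighting probability.  Method B integrates a 24-h backward
#' trajectory arriving at 00 UTC of the focal day through the predicted
#' winds (6-hourly fields are linearly time-interpolated to the hourly
#' steps), and feeds the resulting parcel latitude, the season ordinal date,
#' and a fixed 60-min observation duration into the occurrence model.
#'
#' Missing input coverage makes the affected method's probability `NA` with
#' the reason recorded — never a silent 0.
#'
#' @param focal_date the day being forecast.
#' @param nwp_slp predicted SLP [grid_field] covering the focal snapshot (on
#'   the SOM training grid).
#' @param nwp_winds predicted [wind_pair()] covering `[focal - 24 h, focal]`.
#' @param som a [train_som()] model.
#' @param node_probs a [node_probabilities()] table.
#' @param occ an `occurrence_model` from [select_model()]/[fit_occurrence()].
#' @param duration_min fixed duration input, minutes (default 60).
#' @param snapshot_hour UTC hour of the Method A snapshot (default 0).
#' @param arrival_lat,arrival_lon Method B arrival point.
#' @return one-row data.frame: `focal_date`, `method_a_prob`, `node_id`,
#'   `bmu_distance`, `method_b_prob`, `lat24`, `left_domain`,
#'   `method_a_note`, `method_b_note`.
#' @export
forecast_day <- function(focal_date, nwp_slp, nwp_winds, som, node_probs, occ,
                         duration_min = 60, snapshot_hour = 0,
                         arrival_lat = 45.0, arrival_lon = 145.0) {
  focal_date <- as.Date(focal_date)
  a <- list(probability = NA_real_, node_id = NA_integer_, distance = NA_real_)
  a_note <- ""
  res_a <- tryCatch({
    t_snap <- as_utc(focal_date) + snapshot_hour * 3600
    k <- which(abs(as.numeric(nwp_slp$times) - as.numeric(t_snap)) < 1)
    if (!length(k)) stopf("no SLP snapshot at %s", format(t_snap))
    forecast_method_a(som, node_probs,
                      matrix(nwp_slp$values[k[1], , ],
                             length(nwp_slp$latitudes)))
  }, error = function(e) {
    a_note <<- conditionMessage(e)
    a
  })
  if (!is.na(res_a$node_id) && is.na(res_a$probability) && a_note == "") {
    a_note <- sprintf("node %d had no observation days", res_a$node_id)
  }
  b_prob <- NA_real_
  b_lat24 <- NA_real_
  b_left <- NA
  b_note <- ""
  tryCatch({
    tr <- backtrack(nwp_winds, arrival_lat, arrival_lon,
                    arrival_time = as_utc(focal_date), hours = 24)
    b_lat24 <- tr$positions$lat[tr$positions$lag_hours == 24]
    b_left <- tr$left_domain
    b_prob <- predict_occurrence(occ, lat24 = b_lat24,
                                 date_ordinal = date_ordinal(focal_date),
                                 duration_min = duration_min)
  }, error = function(e) b_note <<- conditionMessage(e))
  data.frame(focal_date = focal_date,
             method_a_prob = res_a$probability,
             node_id = res_a$node_id,
             bmu_distance = res_a$distance,
             method_b_prob = b_prob,
             lat24 = b_lat24,
             left_domain = b_left,
             method_a_note = a_note,
             method_b_note = b_note,
             stringsAsFactors = FALSE)
}

#' 1-5-day-lead forecasts from an initialization date
#'
#' Applies [forecast_day()] to each lead's focal day using the supplied
#' predicted-field archive.  Missing coverage at one lead leaves that lead's
#' method missing and the others intact.
#'
#' @param init_date forecast initialization date.
#' @param nwp_slp,nwp_winds predicted fields valid across the lead range.
#' @param som,node_probs,occ fitted model artifacts (see [forecast_day()]).
#' @param leads integer lead days (default `1:5`).
#' @param ... passed to [forecast_day()].
#' @return data.frame of class `forecast_report`, one row per lead, with
#'   `init_date` and `lead_days` columns prepended.
#' @export
forecast_range <- function(init_date, nwp_slp, nwp_winds, som, node_probs,
                           occ, leads = 1:5, ...) {
  init_date <- as.Date(init_date)
  rows <- lapply(sort(leads), function(ld) {
    row <- forecast_day(init_date + ld, nwp_slp, nwp_winds, som, node_probs,
                        occ, ...)
    cbind(data.frame(init_date = init_date, lead_days = ld), row)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("forecast_report", "data.frame")
  out
}

#' Write a forecast report as CSV or JSON
#'
#' @param report a [forecast_range()] report.
#' @param path output path; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_forecast_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(report), path, digits = NA, na = "null")
  } else {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  }
  invisible(path)
}
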