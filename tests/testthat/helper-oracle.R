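# Independent brute-force oracle for the record de-duplication rules.
#
# Deliberately different construction from the pipeline: presence periods
# are the connected components of the graph linking any two presence days
# <= max_gap apart (transitive closure by repeated label propagation), not a
# cumulative-gap scan.  Returns the row indices (into the input table) of
# the records an exhaustive application of the rules keeps.

dedup_oracle <- function(records, max_gap = 2, near = 2) {
  keep_rows <- integer()
  rows <- seq_len(nrow(records))
  for (s in unique(records$site)) {
    in_site <- rows[records$site == s]
    in_site <- in_site[order(records$date[in_site])]
    pres <- in_site[records$presence[in_site]]
    abse <- in_site[!records$presence[in_site]]
    if (length(pres)) {
      d <- as.numeric(records$date[pres])
      adj <- abs(outer(d, d, "-")) <= max_gap
      comp <- seq_along(pres)
      repeat {
        new_comp <- vapply(seq_along(pres), function(i) min(comp[adj[i, ]]), 1)
        if (all(new_comp == comp)) break
        comp <- new_comp
      }
      for (p in unique(comp)) {
        m <- which(comp == p)
        mx <- max(records$count[pres[m]])
        first_best <- m[records$count[pres[m]] == mx][1]  # ascending date
        keep_rows <- c(keep_rows, pres[first_best])
      }
    }
    if (length(abse)) {
      pd <- as.numeric(records$date[pres])
      ad <- as.numeric(records$date[abse])
      far <- vapply(ad, function(x) !length(pd) || min(abs(pd - x)) > near, TRUE)
      surv <- abse[far]
      sd_ <- ad[far]
      prev_date <- -Inf
      for (j in seq_along(surv)) {
        # first-of-chain: a new chain starts when the gap to the previous
        # surviving absence exceeds max_gap
        if (sd_[j] - prev_date > max_gap) keep_rows <- c(keep_rows, surv[j])
        prev_date <- sd_[j]
      }
    }
  }
  sort(keep_rows)
}

# random fixture for oracle comparison: one record per (site, date)
random_sighting_fixture <- function(n, seed) {
  withr::with_seed(seed, {
    dates <- as.Date("2010-12-01") + sample(0:40, n, replace = TRUE)
    site <- sample(c("shari", "oshinkoshin"), n, replace = TRUE)
    keep <- !duplicated(paste(site, dates))
    dates <- dates[keep]; site <- site[keep]
    count <- ifelse(stats::runif(length(dates)) < 0.4,
                    stats::rpois(length(dates), 4) + 1L, 0L)
    sighting_records(dates, site, stats::runif(length(dates), 20, 120), count)
  })
}

# run the package pipeline and return kept row indices into the input table
run_dedup_pipeline <- function(records, months = 1:12) {
  kept <- filter_sightings(records, months = months)$kept
  sort(match(paste(kept$site, kept$date),
             paste(records$site, records$date)))
}
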