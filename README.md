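# gullcast

Weather-driven daily observation forecasts for a vagrant Arctic seabird.

Ross's Gull (*Rhodostethia rosea*) is one of the most sought-after birds in
the northern hemisphere, and the coastline of the southern Sea of Okhotsk is
one of the few places it can be seen reliably — but only on the right days:
arrivals are driven by northerly winds over the basin and by the advance of
the winter season. `gullcast` implements, end to end, two coupled systems
that turn gridded meteorological fields into a daily observation
probability, for the birdwatchers, tour planners and ecologists who need to
decide *which day* to stand on the sea wall:

* **Method A — synoptic-pattern lookup.** Daily winter sea-level-pressure
  fields over 35–65°N, 135–165°E are classified by a 4×4 self-organizing
  map into 16 canonical patterns. Each node carries the empirical sighting
  probability of the monitoring days assigned to it
  (`probability = n_sighted / n_days`). A forecast assigns the predicted
  SLP snapshot to its best-matching unit (minimum Euclidean distance) and
  reports that node's probability.
* **Method B — trajectory regression.** A backward air-parcel trajectory is
  integrated hourly through the gridded winds from the arrival point
  (45°N, 145°E), `p(t−Δt) = p(t) − V(p(t),t)·Δt`. The parcel latitude 24 h
  before arrival (`lat24`), the season ordinal date (Nov 1 = 1), and the
  observation duration enter a binomial GLM on scaled covariates,
  `logit P(presence) = β₀ + β₁·z(lat24) + β₂·z(date) + β₃·z(duration)`,
  selected by a two-stage AIC search (family screening of the collinear
  ice/latitude/bearing triplets, then all 32 candidate subsets).

The package also ships the supporting machinery: NetCDF gridded-field I/O
with bilinear space / linear time interpolation, the monitoring-record
de-duplication and effort filters that define "independent" observation
days, sea-ice extent covariates, a synthetic weather-and-sightings generator
(migrating Gaussian lows, geostrophic winds, a known logistic truth) so the
whole system is testable offline, a 1–5-day-lead forecast driver, and a
`gullcast` command-line tool (`inst/exec/gullcast`).

## Worked example

Simulate a six-winter synthetic study, arrange the records, train both
systems, and forecast five lead days:

```r
library(gullcast)

wx  <- gen_weather_series(n_winters = 6, seed = 7)   # SLP, winds, ice, dates
rec <- gen_sightings(600, wx$winds, truth_model(), seed = 7)

rep <- filter_sightings(rec)                          # season + de-duplication
rep
#> <filter_report> 600 input -> 98 unique-day records (58 presence, 40 absence);
#>   removed 54 presence, 448 absence
analysis <- effort_filter(rep$kept)                   # >= 45 min effort

# Method A: SOM on the daily patterns + node probabilities
pats <- t(vapply(wx$dates, function(d) flatten_pattern(daily_mean(wx$slp, d)),
                 numeric(625)))
som <- train_som(pats, seed = 7)
som
#> <som_model> 4x4 lattice, 625-dim codebook, trained on 720 patterns (50 epochs)
#>   quantization error 74.03 -> 68.03
tab <- node_probabilities(som, pats[match(analysis$date, wx$dates), ],
                          analysis$presence)
head(tab, 4)
#>   node_id n_days n_sighted probability
#> 1       1      6         5   0.8333333
#> 2       2      3         0   0.0000000
#> 3       3      4         1   0.2500000
#> 4       4      4         2   0.5000000

# Method B: covariates -> scaling -> AIC selection -> forecast model
covs <- build_covariates(analysis, wx$winds, ice = wx$ice)
scd  <- scale_covariates(covs[setdiff(names(covs), c("date", "left_domain"))])
sel  <- select_model(scd$data, scaling = scd$scaling)   # ranked 32-model table
occ  <- fit_occurrence(scd$data, c("lat24", "date_ordinal", "duration_min"),
                       scaling = scd$scaling)           # operational inputs
occ
#> <occurrence_model> terms: lat24 + date_ordinal + duration_min
#>  (Intercept)        lat24 date_ordinal duration_min
#>       0.6627       1.5368       0.6281       0.4974
#>   logLik -35.634  k 4  AIC 79.268

fc <- forecast_range(as.Date("2005-01-10"), wx$slp, wx$winds, som, tab, occ)
fc[c("lead_days", "focal_date", "method_a_prob", "node_id",
     "method_b_prob", "lat24")]
#>   lead_days focal_date method_a_prob node_id method_b_prob lat24
#> 1         1 2005-01-11             1       7         0.709  47.4
#> 2         2 2005-01-12             0       2         0.743  47.7
#> 3         3 2005-01-13             0       2         0.485  45.2
#> 4         4 2005-01-14             0       2         0.399  44.4
#> 5         5 2005-01-15             1       7         0.526  45.5
```

Reading the output: the positive `lat24` coefficient is the vagrancy
mechanism — the farther north the air (and the birds it carries) was 24 h
ago, the likelier a sighting; the intercept reflects the *post-filter*
sample presence rate (de-duplication discards far more absence than presence
days), which is why forecasts are probabilities of an *independent arrival
day*, not of a raw calendar day. Method A's stepwise 0/1 jumps versus
Method B's smooth probabilities on the same days show why the two systems
are reported side by side and never averaged: with a small node table a
single node flip changes Method A discontinuously, while Method B moves with
`lat24`. The forecast model is fit on the three operationally available
inputs (trajectory latitude, date, fixed 60-min duration); the ranked
`sel$table` is the evidence that those terms carry the signal.

The same pipeline runs from the shell:

```sh
gullcast simulate --winters 1 --seed 4 --out-dir demo/
gullcast filter   --sightings demo/sightings.csv --out demo/kept.csv
gullcast backtrack --u demo/u10.nc --v demo/v10.nc \
                   --arrival-time "2004-11-20 00:00" --hours 24 --out demo/traj.csv
```

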