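# Covariate scaling, logistic ML fitting, AIC identity, two-stage selection.

# Directly constructed covariate table with a known signal structure (no
# trajectories needed): lat24 carries the signal, lat48/72 and deg/ice are
# correlated or pure-noise companions.
make_cov_fixture <- function(n, seed, beta = c(b0 = -1.2, lat24 = 1.5, date = 0.6),
                             duration_effect = 0) {
  withr::with_seed(seed, {
    lat24 <- rnorm(n, 46, 4)
    data <- data.frame(
      date_ordinal = sample(1:120, n, replace = TRUE),
      lat24 = lat24,
      lat48 = 0.8 * lat24 + rnorm(n, 9, 3),
      lat72 = 0.6 * lat24 + rnorm(n, 18, 4),
      deg24 = runif(n, 0, 360), deg48 = runif(n, 0, 360),
      deg72 = runif(n, 0, 360),
      ice_whole = runif(n, 0, 0.6), ice_north = runif(n, 0, 0.9),
      ice_south = runif(n, 0, 0.4),
      duration_min = pmax(15, rnorm(n, 77, 40)))
    z <- function(x) (x - mean(x)) / sd(x)
    eta <- beta["b0"] + beta["lat24"] * z(data$lat24) +
      beta["date"] * z(data$date_ordinal) +
      duration_effect * z(data$duration_min)
    data$presence <- runif(n) < plogis(eta)
    data
  })
}

test_that("scaling centres and standardizes, and frozen constants are reused", {
  data <- make_cov_fixture(200, 1)
  sc <- scale_covariates(data)
  expect_equal(mean(sc$data$lat24), 0, tolerance = 1e-12)
  expect_equal(sd(sc$data$lat24), 1, tolerance = 1e-12)
  again <- scale_covariates(data, scaling = sc$scaling)
  expect_equal(again$data$lat24, sc$data$lat24, tolerance = 1e-12)
  # a prediction input equal to the training mean scales to 0
  k <- match("lat24", sc$scaling$column)
  expect_equal((sc$scaling$mean[k] - sc$scaling$mean[k]) / sc$scaling$sd[k], 0)
  data$flat <- 1
  expect_error(scale_covariates(data, columns = "flat"), "zero sd")
})

test_that("the intercept-only fit equals the closed-form logit of the sample rate", {
  pres <- c(rep(TRUE, 33), rep(FALSE, 145))  # 33 presences in 178 records
  data <- data.frame(presence = pres)
  fit <- fit_occurrence(data, character())
  expect_equal(unname(fit$coefficients["(Intercept)"]),
               qlogis(33 / 178), tolerance = 1e-8)
  expect_equal(round(unname(fit$coefficients["(Intercept)"]), 3), -1.48)
  # mean fitted probability equals the sample rate (intercept score equation)
  expect_equal(plogis(fit$coefficients[["(Intercept)"]]), 33 / 178,
               tolerance = 1e-10)
})

test_that("AIC identity reproduces every printed AIC and delta-AIC within print rounding", {
  tab <- published_model_table()
  recomputed <- -2 * tab$logLik + 2 * tab$df
  expect_lte(max(abs(recomputed - tab$aic)), 0.06 + 1e-9)
  expect_lte(max(abs((recomputed - recomputed[1]) - tab$delta_aic)), 0.06 + 1e-9)
  # the identity holds exactly for the package's own fits
  data <- scale_covariates(make_cov_fixture(300, 3))$data
  fit <- fit_occurrence(data, c("lat24", "date_ordinal", "duration_min"))
  expect_equal(fit$aic, -2 * fit$log_likelihood + 2 * fit$k)
  expect_equal(fit$k, 4L)
})

test_that("IRLS coefficients agree with a brute-force likelihood maximization", {
  data <- scale_covariates(make_cov_fixture(30, 7))$data
  terms <- c("lat24", "date_ordinal")
  fit <- fit_occurrence(data, terms)
  nll <- function(b) {
    eta <- b[1] + as.matrix(data[terms]) %*% b[-1]
    -sum(ifelse(data$presence, plogis(eta, log.p = TRUE),
                plogis(-eta, log.p = TRUE)))
  }
  opt <- optim(c(0, 0, 0), nll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  expect_equal(unname(fit$coefficients), unname(opt$par), tolerance = 1e-4)
  expect_equal(fit$log_likelihood, -opt$value, tolerance = 1e-6)
})

test_that("fitted probabilities average to the sample presence rate", {
  data <- scale_covariates(make_cov_fixture(400, 9))$data
  fit <- fit_occurrence(data, c("lat24", "duration_min"))
  eta <- fit$coefficients[["(Intercept)"]] +
    as.matrix(data[fit$terms]) %*% fit$coefficients[fit$terms]
  expect_equal(mean(plogis(eta)), mean(data$presence), tolerance = 1e-8)
})

test_that("family screening finds the signal-bearing member and breaks ties by order", {
  data <- scale_covariates(make_cov_fixture(1000, 11))$data
  sc <- screen_categories(data)
  expect_equal(unname(sc$winners["lat"]), "lat24")
  expect_true(all(c("ice", "lat", "deg") %in% names(sc$winners)))
  # winner AIC is minimal within its family
  for (fam in unique(sc$table$family)) {
    rows <- sc$table[sc$table$family == fam, ]
    expect_equal(min(rows$aic), rows$aic[rows$term == sc$winners[fam]])
  }
  # identical columns tie -> first member in family order wins
  data2 <- data
  data2$ice_north <- data2$ice_whole
  data2$ice_south <- data2$ice_whole
  sc2 <- screen_categories(data2)
  expect_equal(unname(sc2$winners["ice"]), "ice_whole")
})

test_that("exhaustive selection ranks 32 models, best delta is zero, signals are found", {
  scd <- scale_covariates(make_cov_fixture(1000, 13))
  sel <- select_model(scd$data, scaling = scd$scaling)
  expect_equal(nrow(sel$table), 32)
  expect_equal(sel$table$delta_aic[1], 0)
  expect_true(!is.unsorted(sel$table$aic))
  expect_true(all(c("lat24", "date_ordinal") %in% sel$best$terms))
  expect_true("(intercept)" %in% sel$table$terms)
})

test_that("prediction applies frozen scaling and the logistic link", {
  # a hand-built model mirroring the published best fit
  model <- structure(list(
    terms = c("date_ordinal", "lat24", "duration_min"),
    coefficients = c(`(Intercept)` = -2.38, date_ordinal = 0.48,
                     lat24 = 1.74, duration_min = 0.59),
    scaling = data.frame(column = c("date_ordinal", "lat24", "duration_min"),
                         mean = c(60, 46, 77), sd = c(30, 4, 60)),
    log_likelihood = -52.98, k = 4, aic = 114.0, converged = TRUE, n = 178),
    class = "occurrence_model")
  # inputs at the training means -> all scaled covariates zero
  expect_equal(predict_occurrence(model, date_ordinal = 60, lat24 = 46,
                                  duration_min = 77),
               plogis(-2.38), tolerance = 1e-12)
  expect_equal(round(plogis(-2.38), 4), 0.0847)
  # zero slopes and intercept -> one half
  m0 <- model
  m0$coefficients[] <- 0
  expect_equal(predict_occurrence(m0, date_ordinal = 10, lat24 = 50,
                                  duration_min = 60), 0.5)
  # strictly increasing in lat24 when its coefficient is positive
  p <- predict_occurrence(model, lat24 = seq(38, 58, 2), date_ordinal = 45,
                          duration_min = 60)
  expect_true(all(diff(p) > 0))
  expect_error(predict_occurrence(model, lat24 = 50), "not supplied")
})

test_that("separation is flagged and singular designs error with the term named", {
  data <- data.frame(x = c(-2, -1, 1, 2, 3, 4), presence = c(F, F, T, T, T, T))
  expect_warning(fit <- fit_occurrence(data, "x"), "separation")
  expect_false(fit$converged)
  data2 <- scale_covariates(make_cov_fixture(100, 17))$data
  data2$lat24_copy <- data2$lat24
  expect_error(fit_occurrence(data2, c("lat24", "lat24_copy")),
               "lat24_copy")
})

test_that("model artifacts round-trip through JSON", {
  scd <- scale_covariates(make_cov_fixture(300, 19))
  fit <- fit_occurrence(scd$data, c("lat24", "date_ordinal"),
                        scaling = scd$scaling)
  path <- withr::local_tempfile(fileext = ".json")
  write_occurrence(fit, path)
  back <- read_occurrence(path)
  expect_equal(back$coefficients, fit$coefficients, tolerance = 1e-12)
  expect_equal(back$aic, fit$aic)
  p1 <- predict_occurrence(fit, lat24 = 50, date_ordinal = 40)
  p2 <- predict_occurrence(back, lat24 = 50, date_ordinal = 40)
  expect_equal(p2, p1, tolerance = 1e-12)
})

test_that("build_covariates assembles trajectory, ice, date and effort columns", {
  wx <- cached_weather(1, seed = 11)
  rec <- gen_sightings(25, wx$winds, truth_model(), seed = 2)
  covs <- build_covariates(rec, wx$winds, ice = wx$ice)
  expect_equal(nrow(covs), 25)
  expect_true(all(c("date_ordinal", "lat24", "lat48", "lat72", "deg24",
                    "deg48", "deg72", "duration_min", "presence",
                    "ice_whole", "ice_north", "ice_south") %in% names(covs)))
  expect_true(all(is.finite(covs$lat24)))
  expect_true(all(covs$deg72 >= 0 & covs$deg72 < 360))
  expect_true(all(covs$ice_whole >= 0 & covs$ice_whole <= 1))
  # the 24-h feature agrees with the generator's own lat24
  expect_equal(covs$lat24, attr(rec, "covariates")$lat24, tolerance = 1e-9)
})
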