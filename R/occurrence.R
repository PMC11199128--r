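# Method B statistical core: covariate scaling, binomial-GLM maximum
# likelihood, AIC, and the two-stage model selection (per-family screening,
# then exhaustive subset enumeration).

#' Assemble the Method B covariate table from records and gridded fields
#'
#' Per record: season ordinal date (November 1 = 1), the six lagged
#' trajectory covariates from a 72-h [backtrack()] arriving at 00 UTC of the
#' record date, the three sea-ice extents for the date, the observation
#' duration, and the presence response.
#'
#' @param records a [sighting_records] table.
#' @param winds a [wind_pair()] covering each record date minus 72 h.
#' @param ice optional ice-fraction [grid_field] with daily slices; if
#'   `NULL`, ice covariates are omitted.
#' @param arrival_lat,arrival_lon trajectory arrival point (default 45N,
#'   145E).
#' @param ice_mask optional mask for [compute_ice_extent()].
#' @return data.frame of covariates plus `presence`.
#' @export
build_covariates <- function(records, winds, ice = NULL,
                             arrival_lat = 45.0, arrival_lon = 145.0,
                             ice_mask = NULL) {
  n <- nrow(records)
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- backtrack(winds, arrival_lat, arrival_lon,
                    arrival_time = as_utc(records$date[i]), hours = 72)
    feats[[i]] <- trajectory_features(tr)
  }
  feats <- do.call(rbind, feats)
  out <- data.frame(
    date = records$date,
    date_ordinal = vapply(records$date, date_ordinal, 1),
    feats[c("lat24", "lat48", "lat72", "deg24", "deg48", "deg72")],
    duration_min = records$duration_min,
    presence = records$presence,
    left_domain = feats$left_domain
  )
  if (!is.null(ice)) {
    ex <- lapply(records$date, function(d) {
      compute_ice_extent(daily_mean(ice, d), mask = ice_mask)
    })
    out$ice_whole <- vapply(ex, `[[`, 1, "extent_whole")
    out$ice_north <- vapply(ex, `[[`, 1, "extent_north")
    out$ice_south <- vapply(ex, `[[`, 1, "extent_south")
  }
  out
}

#' Scale covariates to zero mean / unit sd
#'
#' Training call (no `scaling` given) fits and returns the constants;
#' prediction calls reuse them, so forecast inputs — including the fixed
#' 60-min duration — are placed on the training scale.
#'
#' @param data covariate data.frame.
#' @param columns columns to scale (default: every numeric column except
#'   `presence`/`left_domain`/`date`).
#' @param scaling optional previously fitted scaling (data.frame `column`,
#'   `mean`, `sd`).
#' @return list: `data` (scaled), `scaling`.
#' @export
scale_covariates <- function(data, columns = NULL, scaling = NULL) {
  if (is.null(columns)) {
    columns <- setdiff(names(data)[vapply(data, is.numeric, TRUE)],
                       c("presence", "left_domain"))
  }
  if (is.null(scaling)) {
    mu <- vapply(columns, function(cn) mean(data[[cn]]), 1)
    sd_ <- vapply(columns, function(cn) stats::sd(data[[cn]]), 1)
    if (any(sd_ == 0)) {
      stopf("degenerate covariate(s) with zero sd: %s",
            paste(columns[sd_ == 0], collapse = ", "))
    }
    scaling <- data.frame(column = columns, mean = mu, sd = sd_,
                          row.names = NULL)
  }
  for (k in seq_len(nrow(scaling))) {
    cn <- scaling$column[k]
    if (cn %in% names(data)) {
      data[[cn]] <- (data[[cn]] - scaling$mean[k]) / scaling$sd[k]
    }
  }
  list(data = data, scaling = scaling)
}

#' Fit a binomial (logistic) occurrence GLM on scaled covariates
#'
#' Maximum likelihood via IRLS (`stats::glm`, convergence when the deviance
#' change is below 1e-10).  AIC is computed as `-2 logLik + 2 k`, `k` the
#' number of estimated coefficients including the intercept.  Perfect
#' separation yields a warning and a model flagged `converged = FALSE`; a
#' rank-deficient design is an error naming the collinear terms.
#'
#' @param data scaled covariate data.frame containing `presence`.
#' @param terms character vector of covariate columns (may be empty for the
#'   intercept-only model).
#' @param scaling the scaling constants to freeze into the model (from
#'   [scale_covariates()]); optional but required for forecasting.
#' @return object of class `occurrence_model`: `terms`, `coefficients`,
#'   `log_likelihood`, `k`, `aic`, `scaling`, `converged`.
#' @export
fit_occurrence <- function(data, terms, scaling = NULL) {
  stopifnot(all(terms %in% names(data)), "presence" %in% names(data))
  if (!any(data$presence) || all(data$presence)) {
    stopf("need at least one record of each response class")
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, terms, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("singular design; collinear term(s): %s", paste(bad, collapse = ", "))
  }
  form <- if (length(terms)) {
    stats::reformulate(sprintf("`%s`", terms), response = "presence")
  } else {
    presence ~ 1
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = data,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep_warn) {
    warning("possible perfect separation; model flagged as non-converged",
            call. = FALSE)
  }
  ll <- as.numeric(stats::logLik(fit))
  k <- length(stats::coef(fit))
  cf <- stats::coef(fit)
  names(cf) <- sub("^`|`$", "", names(cf))
  structure(
    list(terms = terms, coefficients = cf, log_likelihood = ll, k = k,
         aic = -2 * ll + 2 * k, scaling = scaling,
         converged = fit$converged && !sep_warn,
         n = nrow(data)),
    class = "occurrence_model")
}

#' @export
print.occurrence_model <- function(x, ...) {
  cat(sprintf("<occurrence_model> terms: %s\n",
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "(intercept only)"))
  print(round(x$coefficients, 4))
  cat(sprintf("  logLik %.3f  k %d  AIC %.3f%s\n", x$log_likelihood, x$k,
              x$aic, if (!x$converged) "  [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Per-family screening of collinear covariate triplets
#'
#' The ice extents, lagged latitudes and lagged bearings come in families of
#' three near-collinear members; for each family present in the data, fits
#' `presence ~ member + duration_min` and keeps the member with the lowest
#' AIC (ties go to family order).
#'
#' @param data scaled covariate data.frame.
#' @param families named list of candidate columns per family.
#' @return list: `winners` (named character), `table` (data.frame of every
#'   screened fit: family, term, aic).
#' @export
screen_categories <- function(data,
                              families = list(
                                ice = c("ice_whole", "ice_north", "ice_south"),
                                lat = c("lat24", "lat48", "lat72"),
                                deg = c("deg24", "deg48", "deg72"))) {
  rows <- list()
  winners <- character()
  for (fam in names(families)) {
    members <- intersect(families[[fam]], names(data))
    if (!length(members)) next
    aics <- vapply(members, function(m) {
      fit_occurrence(data, c(m, "duration_min"))$aic
    }, 1)
    rows[[fam]] <- data.frame(family = fam, term = members, aic = aics,
                              row.names = NULL)
    winners[fam] <- members[which.min(aics)]  # first minimum = family order
  }
  list(winners = winners, table = do.call(rbind, rows))
}

#' Exhaustive AIC model selection over candidate terms
#'
#' Fits every subset of `candidates` (including the intercept-only model),
#' ranks by AIC, and returns the ranked table plus the best model with the
#' scaling constants attached.
#'
#' @param data scaled covariate data.frame.
#' @param candidates candidate term columns (default: ordinal date, the
#'   three family winners from [screen_categories()], and duration).
#' @param scaling scaling constants to freeze into the best model.
#' @return list: `table` (data.frame: `terms`, `df`, `log_lik`, `aic`,
#'   `delta_aic`, ranked), `best` (an `occurrence_model`), `models` (all
#'   fits, in table order).
#' @export
select_model <- function(data, candidates = NULL, scaling = NULL) {
  if (is.null(candidates)) {
    sc <- screen_categories(data)
    candidates <- c("date_ordinal", unname(sc$winners), "duration_min")
    candidates <- intersect(candidates, names(data))
  }
  n_cand <- length(candidates)
  subsets <- lapply(seq_len(2^n_cand) - 1L, function(m) {
    candidates[bitwAnd(m, 2^(seq_len(n_cand) - 1L)) > 0]
  })
  fits <- vector("list", length(subsets))
  ok <- logical(length(subsets))
  for (i in seq_along(subsets)) {
    fits[[i]] <- tryCatch(
      suppressWarnings(fit_occurrence(data, subsets[[i]], scaling = scaling)),
      error = function(e) NULL)
    ok[i] <- !is.null(fits[[i]])
  }
  fits <- fits[ok]
  tab <- data.frame(
    terms = vapply(fits, function(f) {
      if (length(f$terms)) paste(f$terms, collapse = "+") else "(intercept)"
    }, ""),
    df = vapply(fits, `[[`, 1L, "k"),
    log_lik = vapply(fits, `[[`, 1, "log_likelihood"),
    aic = vapply(fits, `[[`, 1, "aic"))
  ord <- order(tab$aic)
  tab <- tab[ord, , drop = FALSE]
  fits <- fits[ord]
  tab$delta_aic <- tab$aic - tab$aic[1]
  rownames(tab) <- NULL
  list(table = tab, best = fits[[1]], models = fits,
       n_unranked = sum(!ok))
}

#' Predict an occurrence probability
#'
#' Applies the model's frozen scaling to the supplied raw covariates and
#' returns `plogis` of the linear predictor.  Any model term not supplied is
#' an error.
#'
#' @param model an `occurrence_model` (with scaling).
#' @param ... named raw covariate values (scalars or equal-length vectors),
#'   e.g. `lat24 = 52.8, date_ordinal = 45, duration_min = 60`.
#' @return probability vector in \[0, 1\].
#' @export
predict_occurrence <- function(model, ...) {
  vals <- list(...)
  missing_terms <- setdiff(model$terms, names(vals))
  if (length(missing_terms)) {
    stopf("model term(s) not supplied: %s", paste(missing_terms, collapse = ", "))
  }
  n <- max(c(1L, lengths(vals)))
  eta <- rep(model$coefficients[["(Intercept)"]], n)
  for (term in model$terms) {
    x <- vals[[term]]
    if (!is.null(model$scaling) && term %in% model$scaling$column) {
      k <- match(term, model$scaling$column)
      x <- (x - model$scaling$mean[k]) / model$scaling$sd[k]
    }
    eta <- eta + model$coefficients[[term]] * x
  }
  stats::plogis(eta)
}

#' Published top-10 model-selection table for the study site
#'
#' The printed model-ranking table from the original Ross's Gull analysis
#' (coefficients on scaled covariates, df, log-likelihood, AIC, delta-AIC to
#' two-ish printed digits).  Shipped as reference data: the AIC identity
#' `aic = -2 logLik + 2 df` must reproduce every printed AIC within its
#' print rounding.
#'
#' @return data.frame with columns `model`, `intercept`, `date`, `deg72`,
#'   `ice_north`, `lat24`, `duration`, `df`, `logLik`, `aic`, `delta_aic`.
#' @export
published_model_table <- function() {
  utils::read.csv(system.file("extdata", "model_selection_table.csv",
                              package = "gullcast"))
}

#' Write / read an occurrence model artifact as JSON
#'
#' @param model an `occurrence_model`.
#' @param path JSON path.
#' @return `path` (write) or the model (read).
#' @export
write_occurrence <- function(model, path) {
  obj <- list(terms = model$terms,
              coefficients = as.list(model$coefficients),
              log_likelihood = model$log_likelihood,
              k = model$k, aic = model$aic,
              converged = model$converged, n = model$n,
              scaling = model$scaling)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_occurrence
#' @export
read_occurrence <- function(path) {
  obj <- jsonlite::fromJSON(path)
  cf <- unlist(obj$coefficients)
  structure(
    list(terms = as.character(obj$terms %||% character()),
         coefficients = cf,
         log_likelihood = obj$log_likelihood, k = obj$k, aic = obj$aic,
         scaling = if (!is.null(obj$scaling)) as.data.frame(obj$scaling),
         converged = obj$converged, n = obj$n),
    class = "occurrence_model")
}
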