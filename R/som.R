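# Method A: a 4x4 self-organizing map over daily sea-level-pressure pattern
# vectors, with empirical per-node sighting probabilities and Euclidean
# best-matching-unit forecast lookup.
#
# Training is the Kohonen batch algorithm with deterministic PCA
# initialization, so the same inputs always give the same codebook — a
# property an operational forecast product needs.

#' Train a self-organizing map on pattern vectors
#'
#' Batch Kohonen algorithm.  The codebook is initialized on a regular grid
#' spanning the first two principal directions of the inputs (signs fixed
#' deterministically).  Each epoch assigns every input to its Euclidean
#' best-matching unit (BMU) and replaces each codebook vector by the
#' neighborhood-weighted mean of all inputs, with a Gaussian neighborhood on
#' the 2-D lattice whose radius shrinks linearly from `max(rows, cols)/2`
#' to 0.5.  Training stops after `iterations` epochs or when the mean
#' quantization error changes by less than `tol`.
#'
#' @param patterns numeric matrix, one row per input pattern (e.g. flattened
#'   daily SLP grids in hPa; raw values, no anomaly step, per
#'   `standardize`).
#' @param rows,cols lattice size (default 4 x 4 = 16 nodes).
#' @param iterations maximum epochs (default 50).
#' @param seed integer; training is deterministic, the seed only resolves
#'   principal-direction sign ambiguity reproducibly.
#' @param standardize standardize each column (grid cell) before training?
#'   Default `FALSE`: raw SLP fields are used, so deeper systems weigh more.
#' @param cos_lat_weights optional vector of per-element distance weights
#'   (e.g. `sqrt(cos(lat))` per cell); default none.
#' @param tol quantization-error convergence tolerance (default 1e-6).
#' @return object of class `som_model`: `codebook` (nodes x pattern length),
#'   `grid_rows`, `grid_cols`, `node_frequency`, `quantization_error`,
#'   `training_meta`.
#' @details Node numbering is row-major `#001 .. #016` over the lattice.
#' @export
train_som <- function(patterns, rows = 4L, cols = 4L, iterations = 50L,
                      seed = 1L, standardize = FALSE,
                      cos_lat_weights = NULL, tol = 1e-6) {
  patterns <- as.matrix(patterns)
  n_nodes <- rows * cols
  if (nrow(patterns) < n_nodes) {
    stopf("need at least %d patterns to train a %dx%d map, got %d",
          n_nodes, rows, cols, nrow(patterns))
  }
  if (any(!is.finite(patterns))) stopf("patterns contain non-finite values")
  scale_center <- rep(0, ncol(patterns))
  scale_sd <- rep(1, ncol(patterns))
  if (standardize) {
    scale_center <- colMeans(patterns)
    scale_sd <- apply(patterns, 2, stats::sd)
    scale_sd[scale_sd == 0] <- 1
    patterns <- sweep(sweep(patterns, 2, scale_center), 2, scale_sd, "/")
  }
  w <- cos_lat_weights %||% rep(1, ncol(patterns))
  if (length(w) != ncol(patterns)) stopf("cos_lat_weights length mismatch")
  X <- sweep(patterns, 2, sqrt(w), "*")

  # deterministic PCA (linear) initialization
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = 0, nv = 2)
  fix_sign <- function(v) if (v[which.max(abs(v))] < 0) -v else v
  pc1 <- fix_sign(sv$v[, 1])
  sd1 <- sv$d[1] / sqrt(max(nrow(X) - 1, 1))
  if (ncol(sv$v) >= 2 && length(sv$d) >= 2) {
    pc2 <- fix_sign(sv$v[, 2])
    sd2 <- sv$d[2] / sqrt(max(nrow(X) - 1, 1))
  } else {
    pc2 <- rep(0, ncol(X)); sd2 <- 0
  }
  a <- if (cols > 1) seq(-1.5, 1.5, length.out = cols) else 0
  b <- if (rows > 1) seq(-1.5, 1.5, length.out = rows) else 0
  codebook <- matrix(0, n_nodes, ncol(X))
  lattice <- node_lattice(rows, cols)
  for (k in seq_len(n_nodes)) {
    codebook[k, ] <- ctr + a[lattice$col[k]] * sd1 * pc1 +
      b[lattice$row[k]] * sd2 * pc2
  }

  lat_d2 <- as.matrix(stats::dist(cbind(lattice$row, lattice$col)))^2
  qe <- function(cb) {
    d2 <- bmu_dist2(X, cb)
    mean(sqrt(pmax(d2$dist2, 0)))
  }
  qe0 <- qe(codebook)
  sigma_max <- max(rows, cols) / 2
  prev_qe <- qe0
  n_iter_run <- 0L
  for (e in seq_len(iterations)) {
    sigma <- sigma_max + (0.5 - sigma_max) * (e - 1) / max(iterations - 1, 1)
    d2 <- bmu_dist2(X, codebook)
    H <- exp(-lat_d2 / (2 * sigma^2))        # n_nodes x n_nodes
    A <- H[, d2$bmu, drop = FALSE]           # n_nodes x n_inputs
    denom <- rowSums(A)
    codebook <- (A %*% X) / denom
    n_iter_run <- e
    cur_qe <- qe(codebook)
    if (abs(prev_qe - cur_qe) < tol) break
    prev_qe <- cur_qe
  }
  final <- bmu_dist2(X, codebook)
  dimnames(codebook) <- NULL
  freq <- tabulate(final$bmu, nbins = n_nodes) / nrow(X)
  structure(
    list(
      codebook = codebook,
      grid_rows = rows, grid_cols = cols,
      node_frequency = freq,
      quantization_error = c(initial = qe0, final = mean(sqrt(pmax(final$dist2, 0)))),
      standardize = standardize,
      scale_center = scale_center, scale_sd = scale_sd,
      weights = w,
      training_meta = list(n_inputs = nrow(X), iterations = n_iter_run,
                           seed = seed, sigma_max = sigma_max, sigma_min = 0.5)
    ),
    class = "som_model"
  )
}

#' @noRd
node_lattice <- function(rows, cols) {
  # row-major node numbering: node k sits at (row, col)
  k <- seq_len(rows * cols)
  list(row = (k - 1L) %/% cols + 1L, col = (k - 1L) %% cols + 1L)
}

#' @noRd
bmu_dist2 <- function(X, codebook) {
  # squared Euclidean distances X (n x d) vs codebook (m x d), arg-min per row
  cross <- X %*% t(codebook)
  d2 <- outer(rowSums(X^2), rep(1, nrow(codebook))) +
    outer(rep(1, nrow(X)), rowSums(codebook^2)) - 2 * cross
  bmu <- max.col(-d2, ties.method = "first")  # lowest node id on ties
  list(bmu = bmu, dist2 = d2[cbind(seq_len(nrow(X)), bmu)])
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("<som_model> %dx%d lattice, %d-dim codebook, trained on %d patterns (%d epochs)\n",
              x$grid_rows, x$grid_cols, ncol(x$codebook),
              x$training_meta$n_inputs, x$training_meta$iterations))
  cat(sprintf("  quantization error %.4g -> %.4g\n",
              x$quantization_error["initial"], x$quantization_error["final"]))
  invisible(x)
}

#' Best-matching unit of a pattern
#'
#' Resemblance between a pattern and each node is the Euclidean distance
#' between pattern vectors; ties go to the lowest node id.
#'
#' @param model a [train_som()] model.
#' @param pattern numeric vector of the codebook's length (raw scale; any
#'   training standardization/weighting is applied internally).
#' @return list `node_id`, `distance`.
#' @export
assign_node <- function(model, pattern) {
  if (length(pattern) != ncol(model$codebook)) {
    stopf("pattern length %d != codebook length %d",
          length(pattern), ncol(model$codebook))
  }
  if (model$standardize) {
    pattern <- (pattern - model$scale_center) / model$scale_sd
  }
  x <- pattern * sqrt(model$weights)
  d2 <- colSums((t(model$codebook) - x)^2)
  k <- which.min(d2)  # first minimum = lowest node id
  list(node_id = as.integer(k), distance = sqrt(max(d2[k], 0)))
}

#' Per-node sighting counts and probabilities
#'
#' Classifies each observation day's SLP pattern to its BMU and tabulates,
#' per node, the number of classified days (`n_days`), sighted days
#' (`n_sighted`) and the empirical probability `n_sighted / n_days`.  Nodes
#' with no observation days carry `NA` probability — 0/0 is no evidence of
#' absence, and forecasts landing there report missing, never 0.
#'
#' @param model a [train_som()] model.
#' @param patterns matrix of observation-day patterns (rows), pre-filtered
#'   for survey effort (see [effort_filter()]).
#' @param sighted logical vector, one per row of `patterns`.
#' @return data.frame of class `node_prob_table`: `node_id`, `n_days`,
#'   `n_sighted`, `probability`.
#' @export
node_probabilities <- function(model, patterns, sighted) {
  patterns <- as.matrix(patterns)
  stopifnot(nrow(patterns) == length(sighted))
  n_nodes <- model$grid_rows * model$grid_cols
  bmu <- vapply(seq_len(nrow(patterns)),
                function(i) assign_node(model, patterns[i, ])$node_id, 1L)
  n_days <- tabulate(bmu, nbins = n_nodes)
  n_sighted <- tabulate(bmu[sighted], nbins = n_nodes)
  prob <- ifelse(n_days > 0, n_sighted / n_days, NA_real_)
  structure(data.frame(node_id = seq_len(n_nodes), n_days = n_days,
                       n_sighted = n_sighted, probability = prob),
            class = c("node_prob_table", "data.frame"))
}

#' Method A forecast from an SLP snapshot
#'
#' Flattens the forecast SLP slice, finds its BMU, and returns that node's
#' empirical sighting probability.  If the node had no observation days the
#' probability is `NA` (missing) with the node id still reported.
#'
#' @param model a [train_som()] model.
#' @param table a [node_probabilities()] table.
#' @param slp_snapshot single-time [grid_field] (or matrix slice, or an
#'   already-flattened vector) on the training grid.
#' @return list `probability`, `node_id`, `distance`.
#' @export
forecast_method_a <- function(model, table, slp_snapshot) {
  pattern <- if (inherits(slp_snapshot, "grid_field") || is.matrix(slp_snapshot)) {
    flatten_pattern(slp_snapshot)
  } else {
    as.numeric(slp_snapshot)
  }
  hit <- assign_node(model, pattern)
  row <- table[table$node_id == hit$node_id, ]
  list(probability = row$probability[1], node_id = hit$node_id,
       distance = hit$distance)
}

#' Persist an SOM model as NetCDF (+ axes as attributes)
#'
#' The codebook is written as a `(node, lat, lon)` variable so each node can
#' be mapped back to its SLP pattern; lattice shape and training metadata go
#' into global attributes.
#'
#' @param model a [train_som()] model.
#' @param path output NetCDF path.
#' @param latitudes,longitudes grid axes whose product matches the codebook
#'   length.
#' @return `path`, invisibly.
#' @export
write_som <- function(model, path, latitudes, longitudes) {
  nlat <- length(latitudes); nlon <- length(longitudes)
  if (nlat * nlon != ncol(model$codebook)) stopf("axes do not match codebook length")
  d_node <- ncdf4::ncdim_def("node", "", seq_len(nrow(model$codebook)))
  d_lat <- ncdf4::ncdim_def("lat", "degrees_north", latitudes)
  d_lon <- ncdf4::ncdim_def("lon", "degrees_east", longitudes)
  v_cb <- ncdf4::ncvar_def("codebook", "hPa", list(d_node, d_lat, d_lon),
                           prec = "double")
  v_fr <- ncdf4::ncvar_def("node_frequency", "1", list(d_node), prec = "double")
  nc <- ncdf4::nc_create(path, list(v_cb, v_fr))
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  arr <- array(0, dim = c(nrow(model$codebook), nlat, nlon))
  for (k in seq_len(nrow(model$codebook))) {
    arr[k, , ] <- unflatten_pattern(model$codebook[k, ], nlat, nlon)
  }
  ncdf4::ncvar_put(nc, v_cb, arr)
  ncdf4::ncvar_put(nc, v_fr, model$node_frequency)
  ncdf4::ncatt_put(nc, 0, "grid_rows", model$grid_rows)
  ncdf4::ncatt_put(nc, 0, "grid_cols", model$grid_cols)
  ncdf4::ncatt_put(nc, 0, "n_inputs", model$training_meta$n_inputs)
  ncdf4::ncatt_put(nc, 0, "iterations", model$training_meta$iterations)
  ncdf4::ncatt_put(nc, 0, "seed", model$training_meta$seed)
  invisible(path)
}

#' Load an SOM model written by [write_som()]
#'
#' @param path NetCDF path.
#' @return a `som_model` (training-only diagnostics absent).
#' @export
read_som <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  arr <- ncdf4::ncvar_get(nc, "codebook", collapse_degen = FALSE)
  freq <- as.numeric(ncdf4::ncvar_get(nc, "node_frequency"))
  rows <- ncdf4::ncatt_get(nc, 0, "grid_rows")$value
  cols <- ncdf4::ncatt_get(nc, 0, "grid_cols")$value
  n_nodes <- dim(arr)[1]
  cb <- t(vapply(seq_len(n_nodes),
                 function(k) as.vector(t(arr[k, , ])),
                 numeric(dim(arr)[2] * dim(arr)[3])))
  structure(
    list(codebook = cb, grid_rows = rows, grid_cols = cols,
         node_frequency = freq,
         quantization_error = c(initial = NA_real_, final = NA_real_),
         standardize = FALSE,
         scale_center = rep(0, ncol(cb)), scale_sd = rep(1, ncol(cb)),
         weights = rep(1, ncol(cb)),
         training_meta = list(
           n_inputs = ncdf4::ncatt_get(nc, 0, "n_inputs")$value,
           iterations = ncdf4::ncatt_get(nc, 0, "iterations")$value,
           seed = ncdf4::ncatt_get(nc, 0, "seed")$value,
           sigma_max = NA_real_, sigma_min = 0.5)),
    class = "som_model")
}

#' Write / read a node-probability table as JSON
#'
#' @param table a [node_probabilities()] table.
#' @param path JSON path.
#' @return `path` (write) or the table (read).
#' @export
write_node_probs <- function(table, path) {
  jsonlite::write_json(as.data.frame(table), path, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_node_probs
#' @export
read_node_probs <- function(path) {
  df <- jsonlite::fromJSON(path)
  df$probability <- as.numeric(df$probability)
  structure(df, class = c("node_prob_table", "data.frame"))
}
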