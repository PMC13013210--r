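#' Station records for surface interpolation
#'
#' Validates and normalises a station table: planar coordinates in the
#' working CRS, an elevation covariate in metres, and the observed value
#' (air temperature in degrees C or relative humidity in percent).
#' Coordinates must be planar — geographic (degree) inputs must be projected
#' before use, since kriging distances are Euclidean in the working CRS.
#' Duplicate coordinates are averaged into one record with a warning,
#' because they make the kriging system singular.
#'
#' @param x,y Numeric coordinates (CRS units).
#' @param elevation Elevation in metres.
#' @param value Observed value.
#' @return A data frame of class `ssi_stations` with columns
#'   `x, y, elev, value`.
#' @export
stations <- function(x, y, elevation, value) {
  n <- length(x)
  if (length(y) != n || length(elevation) != n || length(value) != n) {
    stop("station columns must have equal length", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("station coordinates must be finite", call. = FALSE)
  }
  df <- data.frame(x = as.numeric(x), y = as.numeric(y),
                   elev = as.numeric(elevation), value = as.numeric(value))
  key <- paste(df$x, df$y)
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate station coordinate(s) ",
            "averaged into single records", call. = FALSE)
    df <- stats::aggregate(df[c("elev", "value")],
                           by = list(x = df$x, y = df$y), FUN = mean)
    df <- df[c("x", "y", "elev", "value")]
  }
  structure(df, class = c("ssi_stations", "data.frame"))
}

as_stations <- function(df) {
  stopifnot(all(c("x", "y", "elev", "value") %in% names(df)))
  stations(df$x, df$y, df$elev, df$value)
}

#' Read / write stations as CSV
#'
#' Column layout `x,y,elev,value`.
#'
#' @param path CSV path.
#' @return An `ssi_stations` data frame.
#' @export
read_stations <- function(path) {
  if (!file.exists(path)) stop("station file not found: ", path, call. = FALSE)
  as_stations(utils::read.csv(path))
}

#' @param stn An `ssi_stations` data frame.
#' @rdname read_stations
#' @export
write_stations <- function(stn, path) {
  # 17 significant digits so a write/read round trip preserves doubles
  # exactly (the CSV is part of the reproducible file pipeline)
  df <- as.data.frame(stn)
  df[] <- lapply(df, function(col) sprintf("%.17g", col))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Drift (lapse-rate) model

#' Fit the elevation drift (lapse-rate) model
#'
#' Ordinary least squares of `value ~ elevation` over the stations: the
#' deterministic part of the regression-kriging decomposition. For air
#' temperature the slope is the empirical lapse rate (degrees C per metre,
#' typically about -0.0065).
#'
#' @param stn An `ssi_stations` data frame (>= 3 stations, non-constant
#'   elevation).
#' @return A list of class `ssi_drift` with `intercept`, `elevation_coef`,
#'   and `residuals` (stations with the drift removed).
#' @export
fit_drift <- function(stn) {
  stn <- as_stations(stn)
  if (nrow(stn) < 3L) {
    stop("drift fit needs at least 3 stations", call. = FALSE)
  }
  if (stats::var(stn$elev) <= 0) {
    stop("degenerate design: station elevations are constant", call. = FALSE)
  }
  fit <- stats::lm(value ~ elev, data = stn)
  res <- stn
  res$value <- stats::residuals(fit)
  structure(
    list(intercept = unname(stats::coef(fit)[1]),
         elevation_coef = unname(stats::coef(fit)[2]),
         residuals = as_stations(res)),
    class = "ssi_drift"
  )
}

predict_drift <- function(drift, elevation) {
  stopifnot(inherits(drift, "ssi_drift"))
  drift$intercept + drift$elevation_coef * elevation
}

# ---------------------------------------------------------------------------
# Variogram estimation and models

#' Empirical semivariogram (Matheron estimator)
#'
#' Bins all station pairs by separation distance and computes
#' \eqn{\gamma(h) = \frac{1}{2 N(h)} \sum (z_i - z_j)^2} per bin. Empty bins
#' are retained with pair count 0 and `NA` semivariance.
#'
#' @param stn An `ssi_stations` data frame (residuals, typically).
#' @param n_lags Number of distance bins (default 12).
#' @param max_dist Largest pair distance considered; default half the
#'   bounding-box diagonal of the stations.
#' @return A list of class `ssi_variogram_est` with `lag_centers`,
#'   `semivariances`, `pair_counts`, `max_dist`.
#' @export
empirical_variogram <- function(stn, n_lags = 12, max_dist = NULL) {
  stn <- as_stations(stn)
  n <- nrow(stn)
  if (n < 2L) stop("variogram needs at least 2 stations", call. = FALSE)
  d <- as.matrix(stats::dist(cbind(stn$x, stn$y)))
  if (is.null(max_dist)) {
    max_dist <- sqrt(diff(range(stn$x))^2 + diff(range(stn$y))^2) / 2
  }
  iu <- upper.tri(d)
  h <- d[iu]
  dz2 <- (outer(stn$value, stn$value, "-")^2)[iu]
  keep <- h > 0 & h <= max_dist
  if (!any(keep)) {
    stop("no station pairs within max_dist = ", max_dist, call. = FALSE)
  }
  h <- h[keep]; dz2 <- dz2[keep]
  breaks <- seq(0, max_dist, length.out = n_lags + 1L)
  bin <- findInterval(h, breaks, rightmost.closed = TRUE, left.open = TRUE)
  counts <- tabulate(bin, nbins = n_lags)
  gamma <- rep(NA_real_, n_lags)
  nz <- which(counts > 0L)
  gamma[nz] <- vapply(nz, function(k) sum(dz2[bin == k]) / (2 * counts[k]),
                      numeric(1))
  structure(
    list(lag_centers = (breaks[-1L] + breaks[-(n_lags + 1L)]) / 2,
         semivariances = gamma,
         pair_counts = as.integer(counts),
         max_dist = max_dist),
    class = "ssi_variogram_est"
  )
}

#' Parametric variogram model
#'
#' Semivariance as a function of separation distance `h`, with
#' `gamma(0) = 0` by convention:
#' * spherical: nugget + psill * (1.5 h/r - 0.5 (h/r)^3) for h < r, sill
#'   beyond;
#' * exponential: nugget + psill * (1 - exp(-h/r)) (r is the effective
#'   range / 3);
#' * gaussian: nugget + psill * (1 - exp(-(h/r)^2)).
#'
#' @param kind `"spherical"`, `"exponential"` or `"gaussian"`.
#' @param nugget Nugget variance (>= 0).
#' @param psill Partial sill (>= 0).
#' @param range_param Range parameter (> 0), in distance units.
#' @return A list of class `ssi_variogram_model`.
#' @export
variogram_model <- function(kind = c("exponential", "spherical", "gaussian"),
                            nugget, psill, range_param) {
  kind <- match.arg(kind)
  if (nugget < 0 || psill < 0 || range_param <= 0) {
    stop("variogram parameters must satisfy nugget >= 0, psill >= 0, ",
         "range > 0", call. = FALSE)
  }
  structure(list(kind = kind, nugget = nugget, psill = psill,
                 range_param = range_param),
            class = "ssi_variogram_model")
}

#' Evaluate a variogram model at distances `h`
#'
#' @param model An `ssi_variogram_model`.
#' @param h Numeric vector of distances (>= 0).
#' @return Semivariances; exactly 0 at `h = 0`.
#' @export
variogram_gamma <- function(model, h) {
  stopifnot(inherits(model, "ssi_variogram_model"))
  r <- model$range_param
  structural <- switch(model$kind,
    spherical = ifelse(h >= r, 1, 1.5 * h / r - 0.5 * (h / r)^3),
    exponential = 1 - exp(-h / r),
    gaussian = 1 - exp(-(h / r)^2)
  )
  out <- model$nugget + model$psill * structural
  out[h == 0] <- 0
  out
}

#' Fit a variogram model to an empirical variogram
#'
#' Weighted least squares over (nugget, partial sill, range) with weights
#' equal to the pair counts, box-constrained to nonnegative variances and a
#' positive range (L-BFGS-B, multiple starts over the range axis). An
#' all-zero empirical variogram short-circuits to the pure-drift model
#' (nugget 0, partial sill 0).
#'
#' @param est An [empirical_variogram()] result.
#' @param kind Model family (default `"exponential"`).
#' @return An `ssi_variogram_model`.
#' @export
fit_variogram <- function(est, kind = c("exponential", "spherical",
                                        "gaussian")) {
  stopifnot(inherits(est, "ssi_variogram_est"))
  kind <- match.arg(kind)
  ok <- est$pair_counts > 0L & !is.na(est$semivariances)
  if (sum(ok) < 3L) {
    stop("variogram fit needs at least 3 non-empty bins (have ", sum(ok), ")",
         call. = FALSE)
  }
  h <- est$lag_centers[ok]
  g <- est$semivariances[ok]
  w <- est$pair_counts[ok]
  if (all(g == 0)) {
    return(variogram_model(kind, nugget = 0, psill = 0,
                           range_param = max(h)))
  }
  obj <- function(p) {
    m <- variogram_model(kind, p[1], p[2], p[3])
    sum(w * (variogram_gamma(m, h) - g)^2)
  }
  s2 <- max(g)
  starts <- lapply(c(1 / 4, 1 / 2, 1) * max(h), function(r0) {
    c(nugget = 0, psill = s2, range = r0)
  })
  best <- NULL
  for (p0 in starts) {
    res <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B",
                   lower = c(0, 0, 1e-8 * max(h)),
                   upper = c(Inf, Inf, 100 * max(h)),
                   control = list(maxit = 500,
                                  parscale = c(s2 + 1e-12, s2 + 1e-12,
                                               max(h)))),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) {
    stop("variogram optimisation failed for all starts", call. = FALSE)
  }
  variogram_model(kind, unname(best$par[1]), unname(best$par[2]),
                  unname(best$par[3]))
}

# ---------------------------------------------------------------------------
# Ordinary kriging

# Bordered OK matrix for a set of stations: [Gamma 1; 1' 0]
.ok_matrix <- function(model, sx, sy) {
  n <- length(sx)
  dm <- as.matrix(stats::dist(cbind(sx, sy)))
  G <- matrix(variogram_gamma(model, dm), n, n)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  A
}

#' Ordinary-kriging prediction at one point
#'
#' Solves the ordinary-kriging system (n + 1 equations with a Lagrange
#' multiplier enforcing unit-sum weights) over the `neighborhood` nearest
#' stations. With a zero nugget the predictor is exact at station
#' locations (prediction equals the station value, variance 0).
#'
#' @param x,y Target coordinates.
#' @param stn An `ssi_stations` data frame (typically drift residuals).
#' @param model An `ssi_variogram_model`.
#' @param neighborhood Number of nearest stations used (default 16; all
#'   stations when fewer are available).
#' @return A list of class `ssi_kriging_result` with `prediction`,
#'   `variance`, `weights` and `neighbors` (row indices used).
#' @export
krige_point <- function(x, y, stn, model, neighborhood = 16L) {
  stn <- as_stations(stn)
  n <- nrow(stn)
  if (n < 2L) stop("kriging needs at least 2 stations", call. = FALSE)
  d <- sqrt((stn$x - x)^2 + (stn$y - y)^2)
  k <- min(neighborhood, n)
  idx <- sort.int(order(d)[seq_len(k)])  # station order, deterministic
  A <- .ok_matrix(model, stn$x[idx], stn$y[idx])
  b <- c(variogram_gamma(model, d[idx]), 1)
  sol <- tryCatch(solve(A, b), error = function(e) {
    stop("singular kriging system (duplicate or collinear degenerate ",
         "station coordinates among neighbors ",
         paste(idx, collapse = ","), ")", call. = FALSE)
  })
  wgt <- sol[seq_len(k)]
  mu <- sol[k + 1L]
  pred <- sum(wgt * stn$value[idx])
  var <- sum(wgt * b[seq_len(k)]) + mu
  structure(
    list(prediction = pred, variance = max(var, 0),
         weights = wgt, neighbors = idx),
    class = "ssi_kriging_result"
  )
}

# Kriged residual values at many target points. Vectorised over targets;
# when the neighborhood covers all stations, one factorisation serves every
# target.
.krige_many <- function(tx, ty, stn, model, neighborhood = 16L) {
  n <- nrow(stn)
  k <- min(neighborhood, n)
  m <- length(tx)
  out <- numeric(m)
  if (k == n) {
    A <- .ok_matrix(model, stn$x, stn$y)
    Adec <- tryCatch(qr(A), error = function(e) {
      stop("singular kriging system (duplicate station coordinates)",
           call. = FALSE)
    })
    # distances stations x targets
    D <- sqrt(outer(stn$x, tx, "-")^2 + outer(stn$y, ty, "-")^2)
    B <- rbind(matrix(variogram_gamma(model, D), n, m), rep(1, m))
    W <- solve.qr(Adec, B)
    out <- colSums(W[seq_len(n), , drop = FALSE] * stn$value)
  } else {
    # moving-neighborhood solve; neighbor sets repeat across nearby cells,
    # so cache the inverted bordered matrix per distinct set
    dm <- as.matrix(stats::dist(cbind(stn$x, stn$y)))
    G <- matrix(variogram_gamma(model, dm), n, n)
    inv_cache <- new.env(parent = emptyenv())
    for (i in seq_len(m)) {
      d <- sqrt((stn$x - tx[i])^2 + (stn$y - ty[i])^2)
      idx <- sort.int(order(d)[seq_len(k)])
      key <- paste(idx, collapse = ",")
      Ainv <- inv_cache[[key]]
      if (is.null(Ainv)) {
        A <- rbind(cbind(G[idx, idx], 1), c(rep(1, k), 0))
        Ainv <- tryCatch(solve(A), error = function(e) {
          stop("singular kriging system (duplicate station coordinates ",
               "among neighbors ", key, ")", call. = FALSE)
        })
        inv_cache[[key]] <- Ainv
      }
      b <- c(variogram_gamma(model, d[idx]), 1)
      out[i] <- sum((Ainv %*% b)[seq_len(k)] * stn$value[idx])
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Surface interpolation (regression-kriging)

#' Interpolation configuration
#'
#' @param use_elevation_drift Use the elevation covariate as a linear drift
#'   (default `TRUE`); when `FALSE`, ordinary kriging of the raw values.
#' @param variogram_kind Model family (default `"exponential"`).
#' @param n_lags,max_dist Passed to [empirical_variogram()].
#' @param neighborhood Nearest-station count for the kriging solve
#'   (default 16).
#' @return A list of class `ssi_interp_config`.
#' @export
interp_config <- function(use_elevation_drift = TRUE,
                          variogram_kind = "exponential",
                          n_lags = 12, max_dist = NULL,
                          neighborhood = 16L) {
  structure(
    list(use_elevation_drift = isTRUE(use_elevation_drift),
         variogram_kind = variogram_kind,
         n_lags = n_lags, max_dist = max_dist,
         neighborhood = as.integer(neighborhood)),
    class = "ssi_interp_config"
  )
}

# DEM elevation at station coordinates (cell-center lookup)
.dem_lookup <- function(dem, x, y) {
  gt <- dem$geotransform
  col <- floor((x - gt[1]) / gt[2]) + 1L
  row <- floor((y - gt[4]) / gt[6]) + 1L
  inside <- col >= 1L & col <= ncol(dem$values) &
    row >= 1L & row <= nrow(dem$values)
  elev <- rep(NA_real_, length(x))
  v <- grid_values_na(dem)
  elev[inside] <- v[cbind(row[inside], col[inside])]
  elev
}

#' Interpolate station observations to a continuous surface
#'
#' Regression-kriging on the DEM's grid: a linear drift on elevation
#' (the lapse rate, for temperature) is fitted by least squares, its
#' residuals are kriged with an ordinary-kriging system under a fitted
#' variogram, and the surface is the drift evaluated on the DEM plus the
#' kriged residual field. With `use_elevation_drift = FALSE` the same
#' machinery performs plain ordinary kriging of the raw values (the
#' comparison baseline). Output is nodata wherever the DEM is nodata.
#'
#' @param stn An `ssi_stations` data frame; all stations must fall inside
#'   the DEM bounds.
#' @param dem An `ssi_grid` of elevations (metres).
#' @param config An [interp_config()].
#' @return An `ssi_grid` on the DEM's georeferencing, with attributes
#'   `drift` (the fitted `ssi_drift`, or `NULL`) and `variogram` (the fitted
#'   model).
#' @export
interpolate_surface <- function(stn, dem, config = interp_config()) {
  stn <- as_stations(stn)
  stopifnot(is_grid(dem), inherits(config, "ssi_interp_config"))
  dem_elev <- .dem_lookup(dem, stn$x, stn$y)
  if (all(is.na(dem_elev))) {
    stop("all stations fall outside the DEM", call. = FALSE)
  }
  drift <- NULL
  resid_stn <- stn
  if (config$use_elevation_drift) {
    drift <- fit_drift(stn)
    resid_stn <- drift$residuals
  }
  est <- empirical_variogram(resid_stn, n_lags = config$n_lags,
                             max_dist = config$max_dist)
  model <- fit_variogram(est, kind = config$variogram_kind)

  ctr <- grid_cell_centers(dem)
  nr <- nrow(dem$values); nc <- ncol(dem$values)
  dem_na <- grid_values_na(dem)
  valid <- !is.na(dem_na)
  # cell-center coordinates of valid cells (column-major like the matrix)
  X <- matrix(rep(ctr$x, each = nr), nr, nc)
  Y <- matrix(rep(ctr$y, times = nc), nr, nc)
  tx <- X[valid]; ty <- Y[valid]

  out <- matrix(NA_real_, nr, nc)
  if (model$psill < 1e-12 && model$nugget < 1e-12) {
    # numerically zero semivariance (e.g. noiseless drift residuals):
    # the kriging system is singular and the surface is pure drift
    resid_surface <- numeric(length(tx))
  } else {
    resid_surface <- .krige_many(tx, ty, resid_stn, model,
                                 neighborhood = config$neighborhood)
  }
  base <- if (is.null(drift)) 0 else predict_drift(drift, dem_na[valid])
  out[valid] <- base + resid_surface
  g <- new_grid(out, dem$geotransform, crs = dem$crs, nodata = -9999)
  attr(g, "drift") <- drift
  attr(g, "variogram") <- model
  g
}

#' Leave-one-out cross-validation of the interpolation
#'
#' Refits drift and variogram without each station in turn and predicts it;
#' intended for diagnostics and tests, not as a user-facing model selector.
#'
#' @inheritParams interpolate_surface
#' @return Data frame with `observed`, `predicted`, `error` per station.
#' @export
loo_cv <- function(stn, dem, config = interp_config()) {
  stn <- as_stations(stn)
  n <- nrow(stn)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    train <- as_stations(stn[-i, , drop = FALSE])
    drift <- NULL
    resid_stn <- train
    if (config$use_elevation_drift) {
      drift <- fit_drift(train)
      resid_stn <- drift$residuals
    }
    est <- empirical_variogram(resid_stn, n_lags = config$n_lags,
                               max_dist = config$max_dist)
    model <- fit_variogram(est, kind = config$variogram_kind)
    r <- .krige_many(stn$x[i], stn$y[i], resid_stn, model,
                     neighborhood = config$neighborhood)
    base <- if (is.null(drift)) 0 else {
      elev_i <- .dem_lookup(dem, stn$x[i], stn$y[i])
      predict_drift(drift, elev_i)
    }
    pred[i] <- base + r
  }
  data.frame(observed = stn$value, predicted = pred,
             error = pred - stn$value)
}
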