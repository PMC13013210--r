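#' Synthetic-scenario configuration
#'
#' Parameters of the miniature Mediterranean-like world used for recovery
#' and conservation tests: a coastal plain rising to inland mountains,
#' temperature decreasing with elevation at a fixed lapse rate plus a
#' spatially correlated residual, humidity decreasing with elevation, and
#' population concentrated in the low-elevation zones. Defaults give a
#' 120 x 120 grid at 250 m pixels so the full pipeline runs in seconds; the
#' 30 m resolution typical of DEM-driven city studies is available by
#' setting `cellsize = 30`.
#'
#' @param seed Integer RNG seed; the whole bundle is a pure function of the
#'   config.
#' @param nrow,ncol Grid shape in cells.
#' @param cellsize Square pixel size in metres.
#' @param relief Total elevation relief (m) from the southern plain to the
#'   northern mountains (default 1500, a plain-to-Taurus-like contrast).
#' @param base_temp Sea-level summer air temperature (degrees C,
#'   default 30).
#' @param lapse_rate Temperature change per metre of elevation (degrees
#'   C/m, default -0.0065, the standard environmental lapse rate).
#' @param rh_base Sea-level relative humidity (percent, default 75: humid
#'   coastal plain).
#' @param rh_elev_coef Humidity change per metre (percent/m, default -0.025,
#'   giving a roughly 75 to 37 percent coastal-to-highland contrast over the
#'   default relief).
#' @param residual_sd Standard deviation of the spatially correlated
#'   temperature residual (degrees C, default 0.5).
#' @param rh_residual_sd Same for humidity (percent, default 2).
#' @param residual_range Correlation range of the residual fields (m,
#'   default 15000: mesoscale structure, half the default domain width,
#'   calibrated so the residual field is resolvable by the default station
#'   network — see the methods vignette).
#' @param n_stations Stations sampled from the truth surfaces (default 60).
#' @param n_zones Number of rectangular population zones; must be a perfect
#'   square (default 16).
#' @param total_population Total residents across zones (default 1,000,000).
#' @param crs CRS identifier attached to all layers (default
#'   `"EPSG:32636"`, a UTM zone; planar metres).
#' @return A list of class `ssi_scenario_config`.
#' @export
scenario_config <- function(seed = 1L, nrow = 120L, ncol = 120L,
                            cellsize = 250, relief = 1500,
                            base_temp = 30, lapse_rate = -0.0065,
                            rh_base = 75, rh_elev_coef = -0.025,
                            residual_sd = 0.5, rh_residual_sd = 2,
                            residual_range = 15000,
                            n_stations = 60L, n_zones = 16L,
                            total_population = 1000000L,
                            crs = "EPSG:32636") {
  stopifnot(nrow >= 2, ncol >= 2, cellsize > 0, relief >= 0,
            residual_sd >= 0, rh_residual_sd >= 0, residual_range > 0,
            n_stations >= 3, n_zones >= 1, total_population >= 0)
  if (round(sqrt(n_zones))^2 != n_zones) {
    stop("n_zones must be a perfect square (rectangular tessellation)",
         call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), nrow = as.integer(nrow),
         ncol = as.integer(ncol), cellsize = cellsize, relief = relief,
         base_temp = base_temp, lapse_rate = lapse_rate,
         rh_base = rh_base, rh_elev_coef = rh_elev_coef,
         residual_sd = residual_sd, rh_residual_sd = rh_residual_sd,
         residual_range = residual_range,
         n_stations = as.integer(n_stations),
         n_zones = as.integer(n_zones),
         total_population = as.integer(total_population),
         crs = as.character(crs)),
    class = "ssi_scenario_config"
  )
}

# Gaussian random field with exponential correlogram, unit variance,
# via FFT spectral synthesis on a doubled (circulant-embedded) grid.
# Slightly approximate when the embedding is not positive definite
# (negative eigenvalues are clipped), the standard practical recipe.
.gaussian_field <- function(nr, nc, cellsize, range) {
  m1 <- 2L * nr; m2 <- 2L * nc
  dx <- c(0:(m2 %/% 2), (m2 %/% 2 - 1):1) * cellsize
  dy <- c(0:(m1 %/% 2), (m1 %/% 2 - 1):1) * cellsize
  h <- sqrt(outer(dy[seq_len(m1)]^2, dx[seq_len(m2)]^2, "+"))
  C <- exp(-h / range)
  lambda <- Re(stats::fft(C))
  lambda[lambda < 0] <- 0
  z <- matrix(stats::rnorm(m1 * m2), m1, m2) +
    1i * matrix(stats::rnorm(m1 * m2), m1, m2)
  f <- stats::fft(sqrt(lambda) * z, inverse = TRUE)
  field <- Re(f)[seq_len(nr), seq_len(nc)]
  # normalise to zero mean / unit variance empirically (eigenvalue clipping
  # and subgrid extraction perturb the nominal scaling)
  field <- field / stats::sd(field)
  field - mean(field)
}

#' Generate the synthetic truth bundle
#'
#' Builds, deterministically from the config seed: a DEM (south-to-north
#' ramp with band-limited spatially correlated relief noise), truth
#' temperature and humidity surfaces that are linear in elevation plus a
#' correlated Gaussian residual, stations sampled without replacement at
#' valid cells (values read off the truth surfaces), and a rectangular
#' tessellation of population zones with residents concentrated at low
#' elevation.
#'
#' @param config A [scenario_config()].
#' @return A list of class `ssi_truth_bundle` with elements `dem`,
#'   `temp_truth` (degrees C), `rh_truth` (percent), `temp_stations`,
#'   `rh_stations`, `zones`, and `config`.
#' @export
make_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "ssi_scenario_config"))
  cfg <- config
  nr <- cfg$nrow; nc <- cfg$ncol; cs <- cfg$cellsize
  if (cfg$n_stations > nr * nc) {
    stop("n_stations exceeds the number of grid cells", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)

  # DEM: ramp rising northwards (row 1 is the north edge) + correlated
  # relief noise at 10% of the relief; clipped at sea level
  ramp <- matrix(rep((nr:1 - 1) / (nr - 1), times = nc), nr, nc)
  dem_noise <- .gaussian_field(nr, nc, cs, cfg$residual_range * 2)
  elev <- cfg$relief * ramp + 0.1 * cfg$relief * dem_noise
  elev <- pmax(elev, 0)
  gt <- c(500000, cs, 0, 4100000 + nr * cs, 0, -cs)
  dem <- new_grid(elev, gt, crs = cfg$crs, nodata = -9999)

  resid_t <- if (cfg$residual_sd > 0) {
    cfg$residual_sd * .gaussian_field(nr, nc, cs, cfg$residual_range)
  } else matrix(0, nr, nc)
  resid_rh <- if (cfg$rh_residual_sd > 0) {
    cfg$rh_residual_sd * .gaussian_field(nr, nc, cs, cfg$residual_range)
  } else matrix(0, nr, nc)

  temp <- cfg$base_temp + cfg$lapse_rate * elev + resid_t
  rh <- pmin(pmax(cfg$rh_base + cfg$rh_elev_coef * elev + resid_rh, 0), 100)
  temp_truth <- new_grid(temp, gt, crs = cfg$crs, nodata = -9999)
  rh_truth <- new_grid(rh, gt, crs = cfg$crs, nodata = -9999)

  # stations: cells sampled without replacement, values from the truth
  cells <- sample.int(nr * nc, cfg$n_stations, replace = FALSE)
  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  ctr <- grid_cell_centers(dem)
  sx <- ctr$x[col]; sy <- ctr$y[row]
  selev <- elev[cbind(row, col)]
  temp_stations <- stations(sx, sy, selev, temp[cbind(row, col)])
  rh_stations <- stations(sx, sy, selev, rh[cbind(row, col)])

  zones <- .make_zones(dem, cfg)

  structure(
    list(dem = dem, temp_truth = temp_truth, rh_truth = rh_truth,
         temp_stations = temp_stations, rh_stations = rh_stations,
         zones = zones, config = cfg),
    class = "ssi_truth_bundle"
  )
}

# k x k rectangular tessellation; population ~ exp(-mean elevation / 300 m)
# (a density scale height concentrating residents on the plain), rounded by
# largest remainder to hit the configured total exactly.
.make_zones <- function(dem, cfg) {
  k <- as.integer(round(sqrt(cfg$n_zones)))
  nr <- nrow(dem$values); nc <- ncol(dem$values)
  gt <- dem$geotransform
  row_edges <- round(seq(0, nr, length.out = k + 1L))
  col_edges <- round(seq(0, nc, length.out = k + 1L))
  zones <- list(); mean_elev <- numeric(0)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    r0 <- row_edges[i] + 1L; r1 <- row_edges[i + 1L]
    c0 <- col_edges[j] + 1L; c1 <- col_edges[j + 1L]
    # map-coordinate rectangle spanning those cells exactly
    x0 <- gt[1] + (c0 - 1L) * gt[2]; x1 <- gt[1] + c1 * gt[2]
    ytop <- gt[4] + (r0 - 1L) * gt[6]; ybot <- gt[4] + r1 * gt[6]
    ring <- rbind(c(x0, ybot), c(x1, ybot), c(x1, ytop), c(x0, ytop))
    zones[[length(zones) + 1L]] <- zone_polygon(
      sprintf("Z%02d", length(zones) + 1L), ring, 0, crs = dem$crs)
    mean_elev <- c(mean_elev, mean(dem$values[r0:r1, c0:c1]))
  }
  wt <- exp(-mean_elev / 300)
  shares <- wt / sum(wt)
  names(shares) <- as.character(seq_along(shares))
  pops <- apportion_population(shares, cfg$total_population)
  for (i in seq_along(zones)) zones[[i]]$population <- as.integer(pops[i])
  zones
}

#' Run the full pipeline on a synthetic scenario
#'
#' Generates the truth bundle, interpolates temperature and humidity from
#' the station samples by regression-kriging on the DEM, computes the SSI
#' surface (Celsius inputs, Fahrenheit index), classifies it, and aggregates
#' population exposure over the zones. Diagnostics compare the pipeline
#' against the withheld truth surfaces.
#'
#' @param config A [scenario_config()].
#' @param scheme Classification scheme (default [ssi_scheme()]).
#' @param interp An [interp_config()].
#' @return A list of class `ssi_e2e` with `bundle`, `temp_surface`,
#'   `rh_surface`, `ssi`, `classified`, `exposure`, and `diagnostics`
#'   (`temp_rmse`, `rh_rmse`, `class_agreement` in \[0, 1\], and the
#'   truth-derived exposure table).
#' @export
run_end_to_end <- function(config = scenario_config(),
                           scheme = ssi_scheme(),
                           interp = interp_config()) {
  bundle <- make_scenario(config)
  temp_surface <- interpolate_surface(bundle$temp_stations, bundle$dem,
                                      interp)
  rh_surface <- interpolate_surface(bundle$rh_stations, bundle$dem, interp)
  # interpolated humidity can stray slightly outside [0,100]; clip as the
  # truth field is clipped
  rh_surface$values <- pmin(pmax(rh_surface$values, 0), 100)
  ssi <- ssi_grid_map(temp_surface, rh_surface, in_unit = "C",
                      out_unit = "F")
  classified <- classify_grid(ssi, scheme)
  exposure <- aggregate_exposure(classified, bundle$zones)

  truth_ssi <- ssi_grid_map(bundle$temp_truth, bundle$rh_truth,
                            in_unit = "C", out_unit = "F")
  truth_classes <- classify_grid(truth_ssi, scheme)
  tm <- grid_values_na(bundle$temp_truth); ts <- grid_values_na(temp_surface)
  rm_ <- grid_values_na(bundle$rh_truth); rs <- grid_values_na(rh_surface)
  agree <- mean(classified$codes == truth_classes$codes)
  diagnostics <- list(
    temp_rmse = sqrt(mean((ts - tm)^2, na.rm = TRUE)),
    rh_rmse = sqrt(mean((rs - rm_)^2, na.rm = TRUE)),
    class_agreement = agree,
    truth_exposure = aggregate_exposure(truth_classes, bundle$zones)
  )
  structure(
    list(bundle = bundle, temp_surface = temp_surface,
         rh_surface = rh_surface, ssi = ssi, classified = classified,
         exposure = exposure, diagnostics = diagnostics),
    class = "ssi_e2e"
  )
}

#' Write a truth bundle to a directory
#'
#' Writes `dem.asc`, `temp_truth.asc`, `rh_truth.asc`, the two station CSVs,
#' `zones.geojson`, and `truth.json` (the echoed config) into `dir`.
#'
#' @param bundle A [make_scenario()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ssi_truth_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_grid(bundle$dem, file.path(dir, "dem.asc"))
  write_grid(bundle$temp_truth, file.path(dir, "temp_truth.asc"))
  write_grid(bundle$rh_truth, file.path(dir, "rh_truth.asc"))
  write_stations(bundle$temp_stations, file.path(dir, "temp_stations.csv"))
  write_stations(bundle$rh_stations, file.path(dir, "rh_stations.csv"))
  write_zones(bundle$zones, file.path(dir, "zones.geojson"))
  jsonlite::write_json(unclass(bundle$config),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
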