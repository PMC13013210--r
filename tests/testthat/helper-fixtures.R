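# Shared fixture builders: everything is generated in code at test time.

# random co-registered temperature/humidity grid pair (Celsius, percent)
random_grid_pair <- function(nr, nc, crs = "EPSG:32636",
                             nodata_frac = 0.05) {
  gt <- c(300000, 100, 0, 4200000, 0, -100)
  temp <- matrix(runif(nr * nc, 10, 45), nr, nc)
  rh <- matrix(runif(nr * nc, 0, 100), nr, nc)
  if (nodata_frac > 0) {
    hole <- sample(nr * nc, ceiling(nodata_frac * nr * nc))
    temp[hole] <- NA
    rh[sample(nr * nc, ceiling(nodata_frac * nr * nc))] <- NA
  }
  list(temp = ssimap::new_grid(temp, gt, crs = crs),
       rh = ssimap::new_grid(rh, gt, crs = crs))
}

# stations exactly linear in elevation (value = a + b * elev), scattered
# uniformly over a square domain
linear_stations <- function(n, a = 30, b = -0.0065, elev_max = 2000,
                            noise_sd = 0, domain = 10000) {
  x <- runif(n, 0, domain)
  y <- runif(n, 0, domain)
  elev <- runif(n, 0, elev_max)
  value <- a + b * elev + rnorm(n, 0, noise_sd)
  ssimap::stations(x, y, elev, value)
}

# small square zone as a closed ring
square_zone <- function(id, x0, y0, side, population,
                        crs = "EPSG:32636") {
  ring <- rbind(c(x0, y0), c(x0 + side, y0),
                c(x0 + side, y0 + side), c(x0, y0 + side))
  ssimap::zone_polygon(id, ring, population, crs = crs)
}

# run the installed CLI script in a subprocess; returns list(status, stdout)
run_cli <- function(args) {
  script <- system.file("cli", "ssi.R", package = "ssimap")
  stopifnot(nzchar(script))
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, c(shQuote(script), shQuote(args)),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
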