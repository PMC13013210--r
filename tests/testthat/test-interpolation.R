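test_that("drift fit recovers an exact lapse rate and flags bad designs", {
  set.seed(101)
  stn <- linear_stations(20, a = 30, b = -0.0065, noise_sd = 0)
  d <- fit_drift(stn)
  expect_equal(d$elevation_coef, -0.0065, tolerance = 1e-12)
  expect_equal(d$intercept, 30, tolerance = 1e-9)
  expect_lt(max(abs(d$residuals$value)), 1e-9)

  expect_error(fit_drift(stn[1:2, ]), "at least 3")
  flat <- stations(1:5, 5:1, rep(100, 5), rnorm(5))
  expect_error(fit_drift(flat), "degenerate design")
})

test_that("noisy lapse-rate estimate lands within 10% of truth", {
  set.seed(102)
  stn <- linear_stations(60, a = 30, b = -0.0065, noise_sd = 0.5)
  d <- fit_drift(stn)
  expect_lt(abs(d$elevation_coef - (-0.0065)) / 0.0065, 0.1)
})

test_that("empirical variogram matches closed forms on tiny inputs", {
  # constant residual field: all semivariances zero
  set.seed(111)
  stn <- stations(runif(10), runif(10), runif(10), rep(3.3, 10))
  ev <- empirical_variogram(stn, n_lags = 4)
  expect_true(all(ev$semivariances[ev$pair_counts > 0] == 0))

  # two points, one bin: gamma = (z1 - z2)^2 / 2
  two <- stations(c(0, 1), c(0, 0), c(0, 0), c(1, 4))
  ev2 <- empirical_variogram(two, n_lags = 1, max_dist = 2)
  expect_equal(ev2$semivariances[1], (4 - 1)^2 / 2)
  expect_equal(ev2$pair_counts[1], 1L)

  # empty bins retained with count 0 and NA semivariance
  ev3 <- empirical_variogram(two, n_lags = 5, max_dist = 5)
  expect_equal(sum(ev3$pair_counts), 1L)
  expect_true(all(is.na(ev3$semivariances[ev3$pair_counts == 0])))
})

test_that("variogram fit recovers parameters from noise-free semivariances", {
  truth <- variogram_model("spherical", nugget = 0.2, psill = 1.5,
                           range_param = 800)
  h <- seq(50, 1400, length.out = 12)
  est <- structure(
    list(lag_centers = h, semivariances = variogram_gamma(truth, h),
         pair_counts = rep(20L, 12), max_dist = 1400),
    class = "ssi_variogram_est")
  fit <- fit_variogram(est, "spherical")
  expect_equal(fit$nugget, truth$nugget, tolerance = 1e-3)
  expect_equal(fit$psill, truth$psill, tolerance = 1e-3)
  expect_equal(fit$range_param, truth$range_param, tolerance = 1e-3)

  # all-zero variogram collapses to the pure-drift model
  zero <- structure(
    list(lag_centers = h, semivariances = rep(0, 12),
         pair_counts = rep(5L, 12), max_dist = 1400),
    class = "ssi_variogram_est")
  fz <- fit_variogram(zero)
  expect_equal(fz$nugget, 0)
  expect_equal(fz$psill, 0)

  # fewer than 3 usable bins is an error
  thin <- structure(
    list(lag_centers = h[1:2], semivariances = c(1, 2),
         pair_counts = c(3L, 3L), max_dist = 200),
    class = "ssi_variogram_est")
  expect_error(fit_variogram(thin), "at least 3 non-empty bins")
})

test_that("ordinary kriging weights sum to 1 and interpolate exactly", {
  set.seed(121)
  model <- variogram_model("exponential", nugget = 0, psill = 1,
                           range_param = 500)
  for (rep in 1:8) {
    n <- sample(5:30, 1)
    stn <- stations(runif(n, 0, 2000), runif(n, 0, 2000), runif(n),
                    rnorm(n))
    kr <- krige_point(runif(1, 0, 2000), runif(1, 0, 2000), stn, model,
                      neighborhood = sample(c(4L, 16L, 64L), 1))
    expect_lt(abs(sum(kr$weights) - 1), 1e-9)
  }
  # exactness at a station with zero nugget
  stn <- stations(c(0, 100, 200, 50), c(0, 100, 0, 150), runif(4),
                  c(2, -1, 4, 0.5))
  at <- krige_point(100, 100, stn, model)
  expect_equal(at$prediction, -1, tolerance = 1e-9)
  expect_equal(at$variance, 0, tolerance = 1e-9)
  # symmetry: two stations equidistant from the target get equal weight
  two <- stations(c(-100, 100), c(0, 0), c(0, 0), c(1, 3))
  sym <- krige_point(0, 0, two, model)
  expect_equal(sym$weights, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(sym$prediction, 2)
})

test_that("kriging solve agrees with an independent dense linear solve", {
  model <- variogram_model("spherical", nugget = 0.1, psill = 2,
                           range_param = 900)
  sx <- c(0, 500, 300); sy <- c(0, 100, 700); z <- c(1.2, -0.4, 2.5)
  stn <- stations(sx, sy, c(0, 0, 0), z)
  tx <- 250; ty <- 300
  kr <- krige_point(tx, ty, stn, model)

  # oracle: build and solve the bordered system directly
  gma <- function(h) {
    s <- ifelse(h >= 900, 1, 1.5 * h / 900 - 0.5 * (h / 900)^3)
    out <- 0.1 + 2 * s
    out[h == 0] <- 0
    out
  }
  A <- matrix(0, 4, 4)
  for (i in 1:3) for (j in 1:3) {
    A[i, j] <- gma(sqrt((sx[i] - sx[j])^2 + (sy[i] - sy[j])^2))
  }
  A[4, 1:3] <- A[1:3, 4] <- 1
  b <- c(gma(sqrt((sx - tx)^2 + (sy - ty)^2)), 1)
  sol <- solve(A, b)
  expect_equal(kr$weights, sol[1:3], tolerance = 1e-10)
  expect_equal(kr$prediction, sum(sol[1:3] * z), tolerance = 1e-10)
  expect_equal(kr$variance, sum(sol[1:3] * b[1:3]) + sol[4],
               tolerance = 1e-10)
})

test_that("duplicate station coordinates are merged with a warning", {
  expect_warning(
    stn <- stations(c(0, 0, 10), c(5, 5, 5), c(1, 3, 2), c(10, 12, 7)),
    "duplicate")
  expect_equal(nrow(stn), 2L)
  expect_equal(stn$value[stn$x == 0], 11)  # averaged
})

test_that("zero-noise stations reproduce the drift surface exactly", {
  set.seed(131)
  dem_vals <- matrix(runif(30 * 30, 0, 1500), 30, 30)
  dem <- make_grid(dem_vals, origin = c(0, 3000), cellsize = 100,
                   crs = "EPSG:32636")
  ctr <- grid_cell_centers(dem)
  idx <- sample(900, 25)
  row <- (idx - 1) %% 30 + 1; col <- (idx - 1) %/% 30 + 1
  stn <- stations(ctr$x[col], ctr$y[row], dem_vals[cbind(row, col)],
                  30 - 0.0065 * dem_vals[cbind(row, col)])
  surf <- interpolate_surface(stn, dem)
  expect_lt(max(abs(grid_values_na(surf) - (30 - 0.0065 * dem_vals))),
            1e-6)
  # drift attribute carries the recovered lapse rate
  expect_equal(attr(surf, "drift")$elevation_coef, -0.0065,
               tolerance = 1e-9)
})

test_that("interpolated surface honours DEM nodata and station bounds", {
  dem_vals <- matrix(500, 10, 10)
  dem_vals[1, ] <- NA
  dem <- make_grid(dem_vals, origin = c(0, 1000), cellsize = 100,
                   crs = "EPSG:32636")
  set.seed(141)
  stn <- stations(runif(10, 0, 1000), runif(10, 0, 900),
                  rep(500, 10) + rnorm(10), rnorm(10, 20))
  surf <- interpolate_surface(stn, dem)
  expect_true(all(is.na(grid_values_na(surf)[1, ])))
  far <- stations(c(-5000, -6000, -7000), c(-5000, -6000, -7000),
                  c(1, 2, 3), c(1, 2, 3))
  expect_error(interpolate_surface(far, dem), "outside the DEM")
})

test_that("elevation drift lowers RMSE versus drift-free kriging", {
  cfg <- scenario_config(seed = 7)
  bundle <- make_scenario(cfg)
  truth <- grid_values_na(bundle$temp_truth)
  rk <- interpolate_surface(bundle$temp_stations, bundle$dem,
                            interp_config(use_elevation_drift = TRUE))
  ok <- interpolate_surface(bundle$temp_stations, bundle$dem,
                            interp_config(use_elevation_drift = FALSE))
  rmse <- function(s) sqrt(mean((grid_values_na(s) - truth)^2,
                                na.rm = TRUE))
  expect_lte(rmse(rk), rmse(ok))
})
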