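test_that("raster write/read round trip preserves values and georeferencing", {
  set.seed(11)
  g <- make_grid(matrix(rnorm(12 * 7), 12, 7), origin = c(350000, 4201000),
                 cellsize = 30, crs = "EPSG:32636")
  g$values[3, 2] <- NA
  path <- withr::local_tempfile(fileext = ".asc")
  write_grid(g, path)
  back <- read_grid(path)
  expect_identical(back$geotransform, g$geotransform)
  expect_identical(back$crs, g$crs)
  expect_identical(back$nodata, g$nodata)
  # text storage at 17 significant digits reproduces doubles exactly
  expect_identical(grid_values_na(back), grid_values_na(g))
})

test_that("reading degenerate or broken rasters behaves as specified", {
  expect_error(read_grid("/nonexistent/raster.asc"), "not found")
  # all-nodata band loads as a grid with zero valid cells, not an error
  g <- make_grid(matrix(-9999, 4, 4), cellsize = 10)
  path <- withr::local_tempfile(fileext = ".asc")
  write_grid(g, path)
  back <- read_grid(path)
  expect_equal(sum(grid_valid_mask(back)), 0L)
  # missing sidecar: warning, CRS falls back to unspecified
  file.remove(paste0(path, ".aux.json"))
  expect_warning(back2 <- read_grid(path), "sidecar")
  expect_equal(back2$crs, "unspecified")
})

test_that("alignment predicate detects shape, CRS and geotransform drift", {
  g <- make_grid(matrix(1, 5, 5), origin = c(0, 500), cellsize = 100,
                 crs = "EPSG:32636")
  expect_true(assert_aligned(g, g))
  shifted <- g
  shifted$geotransform[1] <- shifted$geotransform[1] + 100  # one pixel east
  expect_false(assert_aligned(g, shifted))
  other_crs <- g
  other_crs$crs <- "EPSG:32637"
  expect_false(assert_aligned(g, other_crs))
  smaller <- make_grid(matrix(1, 4, 5), origin = c(0, 500), cellsize = 100,
                       crs = "EPSG:32636")
  expect_false(assert_aligned(g, smaller))
  # sub-tolerance jitter is accepted
  jittered <- g
  jittered$geotransform[1] <- jittered$geotransform[1] + 1e-9
  expect_true(assert_aligned(g, jittered))
})

test_that("gridded SSI equals the scalar oracle cell by cell", {
  # single cell worked example: Ta = 100 F, Ur = 50
  t1 <- make_grid(matrix(100, 1, 1), cellsize = 1)
  r1 <- make_grid(matrix(50, 1, 1), cellsize = 1)
  s1 <- ssi_grid_map(t1, r1, in_unit = "F", out_unit = "F")
  expect_equal(s1$values[1, 1], 118.301)

  set.seed(21)
  for (rep in 1:3) {
    p <- random_grid_pair(40, 35)
    out <- ssi_grid_map(p$temp, p$rh, in_unit = "C", out_unit = "F")
    tv <- grid_values_na(p$temp); rv <- grid_values_na(p$rh)
    oracle <- matrix(NA_real_, nrow(tv), ncol(tv))
    for (i in seq_len(nrow(tv))) for (j in seq_len(ncol(tv))) {
      if (!is.na(tv[i, j]) && !is.na(rv[i, j])) {
        oracle[i, j] <- compute_ssi_units(tv[i, j], "C", rv[i, j], "F")
      }
    }
    expect_lt(max(abs(grid_values_na(out) - oracle), na.rm = TRUE), 1e-9)
    # nodata propagation: output invalid exactly where either input is
    expect_identical(grid_valid_mask(out),
                     grid_valid_mask(p$temp) & grid_valid_mask(p$rh))
    # georeference preserved verbatim
    expect_identical(out$geotransform, p$temp$geotransform)
    expect_identical(out$crs, p$temp$crs)
  }
})

test_that("gridded SSI rejects misaligned inputs and bad humidity", {
  g <- make_grid(matrix(25, 3, 3), cellsize = 100, crs = "EPSG:32636")
  rh <- make_grid(matrix(50, 3, 3), cellsize = 100, crs = "EPSG:32636")
  moved <- rh
  moved$geotransform[1] <- moved$geotransform[1] + 100
  expect_error(ssi_grid_map(g, moved), "not aligned")
  rh_bad <- rh
  rh_bad$values[1, 1] <- 130
  rh_bad$values[2, 2] <- 150
  expect_error(ssi_grid_map(g, rh_bad), "2 cell\\(s\\)")
  clamped <- ssi_grid_map(g, rh_bad, clamp_rh = TRUE)
  expect_equal(clamped$values[1, 1],
               compute_ssi_units(25, "C", 100, "F"))
})

test_that("grid classification matches the scalar classifier", {
  sch <- ssi_scheme()
  uniform <- make_grid(matrix(105, 6, 6), cellsize = 10)
  cat1 <- classify_grid(uniform, sch)
  expect_true(all(cat1$codes == 5L))  # Sweltering
  boundary <- make_grid(matrix(91, 4, 4), cellsize = 10)
  expect_true(all(classify_grid(boundary, sch)$codes == 4L))  # Warm-Hot

  set.seed(31)
  vals <- matrix(runif(50 * 50, 40, 160), 50, 50)
  vals[sample(2500, 60)] <- NA
  g <- make_grid(vals, cellsize = 10)
  cg <- classify_grid(g, sch)
  oracle <- matrix(255L, 50, 50)
  for (i in 1:50) for (j in 1:50) {
    if (!is.na(vals[i, j])) oracle[i, j] <- classify_ssi(vals[i, j], sch)
  }
  expect_identical(cg$codes, oracle)
})

test_that("categorical grids survive a write/read round trip", {
  set.seed(41)
  g <- make_grid(matrix(runif(100, 60, 160), 10, 10), cellsize = 30,
                 crs = "EPSG:32636")
  g$values[4, 4] <- NA
  cg <- classify_grid(g, ssi_scheme())
  path <- withr::local_tempfile(fileext = ".asc")
  write_categorical(cg, path)
  back <- read_grid(path)
  expect_s3_class(back, "ssi_catgrid")
  expect_identical(back$codes, cg$codes)
  expect_identical(back$nodata_code, cg$nodata_code)
  expect_equal(back$scheme$code, cg$scheme$code)
  # idempotence under reload: classifying identical values changes no code
  expect_identical(classify_grid(g, ssi_scheme())$codes, cg$codes)
})

test_that("area fractions count valid cell area and sum to 100", {
  sch <- ssi_scheme()
  uniform <- classify_grid(make_grid(matrix(85, 8, 8), cellsize = 10,
                                     crs = "EPSG:32636"), sch)
  fr <- class_area_fractions(uniform)
  expect_equal(fr$area_pct[fr$code == 3L], 100)
  expect_equal(sum(fr$area_pct), 100, tolerance = 1e-6)

  # half/half checkerboard in a projected CRS
  v <- matrix(85, 10, 10)
  v[(row(v) + col(v)) %% 2 == 0] <- 105
  cb <- classify_grid(make_grid(v, cellsize = 10, crs = "EPSG:32636"), sch)
  fr2 <- class_area_fractions(cb)
  expect_equal(fr2$area_pct[fr2$code == 3L], 50)
  expect_equal(fr2$area_pct[fr2$code == 5L], 50)

  # known counts with nodata: fractions equal exact count ratios
  set.seed(51)
  vv <- matrix(sample(c(75, 95, 120), 400, replace = TRUE), 20, 20)
  vv[sample(400, 30)] <- NA
  cg <- classify_grid(make_grid(vv, cellsize = 30, crs = "EPSG:32636"), sch)
  fr3 <- class_area_fractions(cg)
  counts <- table(factor(cg$codes[cg$codes != 255L], levels = 0:8))
  expect_equal(fr3$area_pct, as.numeric(100 * counts / sum(counts)))
  expect_equal(sum(fr3$area_pct), 100, tolerance = 1e-6)
})

test_that("geographic grids use cos-latitude cell weighting", {
  sch <- ssi_scheme()
  # two rows at latitudes 0-1 (code 3) and 1-2 degrees (code 5)
  v <- matrix(c(105, 85), 2, 10)
  g <- new_grid(v, c(35, 1, 0, 2, 0, -1), crs = "EPSG:4326")
  fr <- class_area_fractions(classify_grid(g, sch))
  w_top <- cos(1.5 * pi / 180)  # row 1 center latitude
  w_bot <- cos(0.5 * pi / 180)
  expect_equal(fr$area_pct[fr$code == 5L], 100 * w_top / (w_top + w_bot))
  expect_equal(fr$area_pct[fr$code == 3L], 100 * w_bot / (w_top + w_bot))
})

test_that("rotated geotransforms and degenerate shapes are rejected", {
  expect_error(new_grid(matrix(1, 2, 2), c(0, 1, 0.1, 0, 0, -1)),
               "rotated")
  expect_error(new_grid(matrix(1, 2, 2), c(0, 0, 0, 0, 0, -1)), "nonzero")
  expect_error(new_grid(matrix(numeric(0), 0, 0), c(0, 1, 0, 0, 0, -1)),
               "1x1")
  all_nodata <- classify_grid(make_grid(matrix(NA_real_, 3, 3),
                                        cellsize = 1), ssi_scheme())
  expect_error(class_area_fractions(all_nodata), "empty domain")
})
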