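#' Georeferenced single-band raster grid
#'
#' The raster data model used throughout the package: a numeric matrix
#' (row 1 is the northernmost row, north-up, pixel-is-area) together with a
#' GDAL-style affine geotransform `(x0, dx, 0, y0, 0, -dy)`, a CRS
#' identifier string, and a nodata sentinel. Rotated geotransforms are not
#' supported; interpolation products are axis-aligned.
#'
#' @param values Numeric matrix of cell values, row 1 at the top.
#' @param geotransform Numeric vector of 6 affine coefficients
#'   `(x origin, pixel width, 0, y origin, 0, -pixel height)`. The origin is
#'   the outer corner of the top-left cell.
#' @param crs CRS identifier (e.g. `"EPSG:32636"`); `"unspecified"` when
#'   unknown.
#' @param nodata Sentinel marking invalid cells (default -9999). Cells equal
#'   to the sentinel, and `NA` cells, are treated as nodata.
#' @return An object of class `ssi_grid`.
#' @examples
#' g <- make_grid(matrix(1:6, 2, 3), origin = c(0, 2), cellsize = 1)
#' grid_valid_mask(g)
#' @export
new_grid <- function(values, geotransform, crs = "unspecified",
                     nodata = -9999) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("grid must be at least 1x1", call. = FALSE)
  }
  gt <- as.numeric(geotransform)
  if (length(gt) != 6L || any(!is.finite(gt))) {
    stop("`geotransform` must be 6 finite numbers", call. = FALSE)
  }
  if (gt[3] != 0 || gt[5] != 0) {
    stop("rotated geotransforms are not supported", call. = FALSE)
  }
  if (gt[2] == 0 || gt[6] == 0) {
    stop("pixel sizes must be nonzero", call. = FALSE)
  }
  structure(
    list(values = values, geotransform = gt,
         crs = as.character(crs), nodata = as.numeric(nodata)),
    class = "ssi_grid"
  )
}

#' @param origin Coordinates `(x, y)` of the top-left corner.
#' @param cellsize Square pixel size in CRS units.
#' @rdname new_grid
#' @export
make_grid <- function(values, origin = c(0, nrow(values)), cellsize = 1,
                      crs = "unspecified", nodata = -9999) {
  new_grid(values,
           c(origin[1], cellsize, 0, origin[2], 0, -cellsize),
           crs = crs, nodata = nodata)
}

is_grid <- function(x) inherits(x, "ssi_grid")

#' @export
print.ssi_grid <- function(x, ...) {
  v <- grid_values_na(x)
  cat("<ssi_grid> ", nrow(x$values), "x", ncol(x$values),
      " cells, pixel ", x$geotransform[2], " x ", -x$geotransform[6],
      ", crs ", x$crs, "\n", sep = "")
  cat("  origin (", x$geotransform[1], ", ", x$geotransform[4],
      "), nodata ", x$nodata, ", valid cells ", sum(!is.na(v)), "\n", sep = "")
  if (any(!is.na(v))) {
    cat("  range [", format(min(v, na.rm = TRUE)), ", ",
        format(max(v, na.rm = TRUE)), "]\n", sep = "")
  }
  invisible(x)
}

#' Grid helpers
#'
#' `grid_valid_mask` marks cells that carry a real value; `grid_values_na`
#' returns the value matrix with nodata replaced by `NA`;
#' `grid_cell_centers` returns the map coordinates of every cell center.
#'
#' @param grid An `ssi_grid`.
#' @return See individual descriptions.
#' @export
grid_valid_mask <- function(grid) {
  stopifnot(is_grid(grid))
  v <- grid$values
  !is.na(v) & v != grid$nodata
}

#' @rdname grid_valid_mask
#' @export
grid_values_na <- function(grid) {
  v <- grid$values
  v[!grid_valid_mask(grid)] <- NA_real_
  v
}

#' @rdname grid_valid_mask
#' @export
grid_cell_centers <- function(grid) {
  stopifnot(is_grid(grid))
  gt <- grid$geotransform
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  x <- gt[1] + (seq_len(nc) - 0.5) * gt[2]
  y <- gt[4] + (seq_len(nr) - 0.5) * gt[6]
  list(x = x, y = y)
}

# Heuristic: is the CRS geographic (degrees)? Drives latitude-corrected
# cell areas in class_area_fractions().
is_geographic_crs <- function(crs) {
  grepl("4326|WGS\\s*84|CRS84|longlat|geographic", crs, ignore.case = TRUE)
}

#' Check that two grids are co-registered
#'
#' Returns `TRUE` iff the shapes are equal, CRS identifiers are identical
#' and every geotransform component agrees within `tol` (interpreted in CRS
#' units, default 1e-6 of a pixel). Predicate only; [ssi_grid_map()] raises
#' when it is false. Misaligned inputs must be warped externally: no
#' implicit resampling is performed, since silent resampling corrupts
#' humidity extremes.
#'
#' @param a,b `ssi_grid` objects.
#' @param tol Absolute tolerance on geotransform components.
#' @return Logical scalar.
#' @export
assert_aligned <- function(a, b, tol = NULL) {
  stopifnot(is_grid(a), is_grid(b))
  if (is.null(tol)) tol <- 1e-6 * abs(a$geotransform[2])
  if (!identical(dim(a$values), dim(b$values))) return(FALSE)
  if (!identical(a$crs, b$crs)) return(FALSE)
  all(abs(a$geotransform - b$geotransform) <= tol)
}

alignment_report <- function(a, b) {
  msgs <- character(0)
  if (!identical(dim(a$values), dim(b$values))) {
    msgs <- c(msgs, sprintf("shape %dx%d vs %dx%d",
                            nrow(a$values), ncol(a$values),
                            nrow(b$values), ncol(b$values)))
  }
  if (!identical(a$crs, b$crs)) {
    msgs <- c(msgs, sprintf("crs '%s' vs '%s'", a$crs, b$crs))
  }
  d <- which(a$geotransform != b$geotransform)
  if (length(d)) {
    msgs <- c(msgs, paste0("geotransform component(s) ",
                           paste(d, collapse = ",")))
  }
  paste(msgs, collapse = "; ")
}

# ---------------------------------------------------------------------------
# ESRI ASCII grid I/O
#
# Plain-text single-band raster interchange format (square cells,
# xllcorner/yllcorner header, NODATA_value sentinel, rows north to south).
# A JSON sidecar `<path>.aux.json` carries the CRS identifier and the
# storage dtype tag. Values are written at 17 significant digits so a
# write/read round trip reproduces doubles bit-for-bit.

#' Read a single-band raster from an ESRI ASCII grid file
#'
#' Restores values, geotransform, nodata and (from the `<path>.aux.json`
#' sidecar) the CRS. A missing sidecar yields a warning and
#' `crs = "unspecified"`.
#'
#' @param path Path to a `.asc` file.
#' @return An `ssi_grid` (or categorical grid when the sidecar dtype is
#'   `uint8`; see [write_categorical()]).
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) {
    stop("raster file not found: ", path, call. = FALSE)
  }
  con <- file(path, "r")
  on.exit(close(con))
  header <- list()
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("truncated raster header in ", path, call. = FALSE)
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1])) {
      header[[tolower(parts[1])]] <- as.numeric(parts[2])
    } else {
      seek(con, pos)
      break
    }
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(req %in% names(header))) {
    stop("invalid ASCII grid header in ", path, " (missing ",
         paste(setdiff(req, names(header)), collapse = ", "), ")",
         call. = FALSE)
  }
  nc <- as.integer(header$ncols); nr <- as.integer(header$nrows)
  nodata <- if (!is.null(header$nodata_value)) header$nodata_value else -9999
  vals <- scan(con, what = double(), n = nr * nc, quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop("raster body has ", length(vals), " values, expected ", nr * nc,
         call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  cs <- header$cellsize
  gt <- c(header$xllcorner, cs, 0, header$yllcorner + nr * cs, 0, -cs)
  aux_path <- paste0(path, ".aux.json")
  crs <- "unspecified"
  dtype <- "float"
  if (file.exists(aux_path)) {
    aux <- jsonlite::read_json(aux_path)
    if (!is.null(aux$crs)) crs <- as.character(aux$crs)
    if (!is.null(aux$dtype)) dtype <- as.character(aux$dtype)
  } else {
    warning("no CRS sidecar for ", path, "; proceeding with 'unspecified'",
            call. = FALSE)
  }
  g <- new_grid(m, gt, crs = crs, nodata = nodata)
  if (identical(dtype, "uint8")) {
    scheme_path <- paste0(tools::file_path_sans_ext(path), ".legend.json")
    scheme <- if (file.exists(scheme_path)) read_scheme(scheme_path) else NULL
    g <- grid_to_categorical(g, scheme)
  }
  g
}

#' Write a raster grid to an ESRI ASCII grid file
#'
#' Writes the header, the nodata tag and the values (full double precision),
#' plus a `<path>.aux.json` sidecar with the CRS and dtype. Requires square
#' pixels, the format's constraint.
#'
#' @param grid An `ssi_grid`.
#' @param path Output path (`.asc` conventionally).
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(is_grid(grid))
  .write_asc(grid$values, grid$geotransform, grid$nodata, path,
             fmt = "%.17g")
  jsonlite::write_json(
    list(crs = grid$crs, dtype = "float", nodata = grid$nodata),
    paste0(path, ".aux.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.write_asc <- function(values, gt, nodata, path, fmt) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cs <- gt[2]
  if (abs(abs(gt[6]) - cs) > 1e-12 * cs) {
    stop("ASCII grid format requires square pixels", call. = FALSE)
  }
  nr <- nrow(values); nc <- ncol(values)
  v <- values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", nc),
    paste("nrows", nr),
    paste("xllcorner", sprintf("%.17g", gt[1])),
    paste("yllcorner", sprintf("%.17g", gt[4] + nr * gt[6])),
    paste("cellsize", sprintf("%.17g", cs)),
    paste("NODATA_value", sprintf("%.17g", nodata))
  ), con)
  body <- apply(v, 1L, function(row) paste(sprintf(fmt, row), collapse = " "))
  writeLines(body, con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Categorical grids

#' Categorical (classified) raster grid
#'
#' Integer category codes on the same georeferencing as the source grid,
#' with nodata code 255 and a reference to the classification scheme.
#'
#' @param codes Integer matrix of category codes.
#' @param geotransform,crs As in [new_grid()].
#' @param nodata_code Integer sentinel (default 255).
#' @param scheme The [ssi_scheme()] the codes refer to (may be `NULL` when
#'   reloading without a legend sidecar).
#' @return An object of class `ssi_catgrid`.
#' @export
new_categorical <- function(codes, geotransform, crs = "unspecified",
                            nodata_code = 255L, scheme = NULL) {
  if (!is.matrix(codes)) stop("`codes` must be a matrix", call. = FALSE)
  codes <- matrix(as.integer(codes), nrow(codes), ncol(codes))
  if (!is.null(scheme)) {
    validate_scheme(scheme)
    valid <- codes[!is.na(codes) & codes != nodata_code]
    if (length(valid) && !all(valid %in% scheme$code)) {
      stop("categorical grid contains codes absent from the scheme",
           call. = FALSE)
    }
  }
  structure(
    list(codes = codes, geotransform = as.numeric(geotransform),
         crs = as.character(crs), nodata_code = as.integer(nodata_code),
         scheme = scheme),
    class = "ssi_catgrid"
  )
}

is_catgrid <- function(x) inherits(x, "ssi_catgrid")

grid_to_categorical <- function(grid, scheme) {
  codes <- grid$values
  codes[!grid_valid_mask(grid)] <- 255
  new_categorical(codes, grid$geotransform, grid$crs,
                  nodata_code = 255L, scheme = scheme)
}

#' @export
print.ssi_catgrid <- function(x, ...) {
  cat("<ssi_catgrid> ", nrow(x$codes), "x", ncol(x$codes),
      " cells, crs ", x$crs, ", nodata code ", x$nodata_code, "\n", sep = "")
  tab <- table(x$codes[x$codes != x$nodata_code])
  if (length(tab)) {
    cat("  codes:", paste(names(tab), "=", as.integer(tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Write a categorical grid (uint8) with its legend sidecar
#'
#' Stores integer codes in the ASCII grid body, `dtype: "uint8"` in the aux
#' sidecar, and the classification legend in
#' `<path minus extension>.legend.json` so [read_grid()] can restore the
#' scheme.
#'
#' @param cat An `ssi_catgrid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_categorical <- function(cat, path) {
  stopifnot(is_catgrid(cat))
  .write_asc(cat$codes, cat$geotransform, cat$nodata_code, path, fmt = "%d")
  jsonlite::write_json(
    list(crs = cat$crs, dtype = "uint8", nodata = cat$nodata_code),
    paste0(path, ".aux.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(cat$scheme)) {
    write_scheme(cat$scheme,
                 paste0(tools::file_path_sans_ext(path), ".legend.json"))
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Map algebra

#' Compute an SSI surface from temperature and humidity rasters
#'
#' Elementwise [compute_ssi_units()] over two co-registered grids. Output is
#' nodata wherever either input is nodata; georeferencing is copied from the
#' temperature grid. Humidity must lie in \[0, 100\] on valid cells unless
#' `clamp_rh = TRUE`.
#'
#' @param temp Air-temperature grid in `in_unit`.
#' @param rh Relative-humidity grid in percent.
#' @param in_unit,out_unit `"C"` or `"F"`.
#' @inheritParams compute_ssi
#' @return An `ssi_grid` of SSI values in `out_unit` (nodata -9999).
#' @export
ssi_grid_map <- function(temp, rh, in_unit = "C", out_unit = "F",
                         constants = ssi_constants(), clamp_rh = FALSE) {
  stopifnot(is_grid(temp), is_grid(rh))
  if (!assert_aligned(temp, rh)) {
    stop("temperature and humidity grids are not aligned: ",
         alignment_report(temp, rh), call. = FALSE)
  }
  tv <- grid_values_na(temp)
  rv <- grid_values_na(rh)
  valid <- !is.na(tv) & !is.na(rv)
  bad <- valid & (rv < 0 | rv > 100)
  if (any(bad) && !clamp_rh) {
    stop("relative humidity outside [0, 100] on ", sum(bad),
         " cell(s); pass clamp_rh = TRUE to clip", call. = FALSE)
  }
  out <- matrix(NA_real_, nrow(tv), ncol(tv))
  out[valid] <- compute_ssi_units(tv[valid], in_unit, rv[valid], out_unit,
                                  constants = constants, clamp_rh = clamp_rh)
  out[!valid] <- NA_real_
  new_grid(out, temp$geotransform, crs = temp$crs, nodata = -9999)
}

#' Classify an SSI raster into thermal-comfort categories
#'
#' Per-cell [classify_ssi()]; input values must be on the Fahrenheit scale
#' (convert first if the surface was produced with a Celsius display unit).
#' Nodata cells receive the nodata code 255.
#'
#' @param ssi An `ssi_grid` of Fahrenheit-scale SSI values.
#' @param scheme An [ssi_scheme()].
#' @return An `ssi_catgrid`.
#' @export
classify_grid <- function(ssi, scheme = ssi_scheme()) {
  stopifnot(is_grid(ssi))
  validate_scheme(scheme)
  v <- grid_values_na(ssi)
  codes <- matrix(255L, nrow(v), ncol(v))
  ok <- !is.na(v)
  codes[ok] <- classify_ssi(v[ok], scheme)
  new_categorical(codes, ssi$geotransform, ssi$crs,
                  nodata_code = 255L, scheme = scheme)
}

# per-cell areas; cos-latitude weighting per row for geographic CRS
# (adequate at city scale; full ellipsoidal areas are not attempted)
.cell_areas_by_row <- function(gt, nr, crs) {
  px <- abs(gt[2]); py <- abs(gt[6])
  if (is_geographic_crs(crs)) {
    lat <- gt[4] + (seq_len(nr) - 0.5) * gt[6]
    px * py * cos(lat * pi / 180)
  } else {
    rep(px * py, nr)
  }
}

#' Area share of each category in a classified grid
#'
#' Percent of valid-cell area occupied by each category. Projected CRS cells
#' all weigh `|dx|*|dy|`; geographic CRS cells are weighted by the cosine of
#' the row-center latitude. Nodata cells are never counted; shares sum to
#' 100 over the valid domain.
#'
#' @param cat An `ssi_catgrid`.
#' @param mask Optional logical matrix restricting the domain (e.g. the
#'   union of analysis zones).
#' @return A data frame with columns `code`, `label`, `area_pct`, one row
#'   per category present (plus zero rows for scheme categories absent from
#'   the grid when a scheme is attached).
#' @export
class_area_fractions <- function(cat, mask = NULL) {
  stopifnot(is_catgrid(cat))
  codes <- cat$codes
  valid <- codes != cat$nodata_code & !is.na(codes)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(codes)))
    valid <- valid & mask
  }
  if (!any(valid)) {
    stop("no valid cells in the classified grid (empty domain)",
         call. = FALSE)
  }
  row_area <- .cell_areas_by_row(cat$geotransform, nrow(codes), cat$crs)
  w <- matrix(row_area, nrow(codes), ncol(codes))  # recycles down columns
  all_codes <- if (!is.null(cat$scheme)) cat$scheme$code else
    sort(unique(codes[valid]))
  area <- vapply(all_codes, function(k) sum(w[valid & codes == k]),
                 numeric(1))
  pct <- 100 * area / sum(area)
  data.frame(
    code = as.integer(all_codes),
    label = if (!is.null(cat$scheme)) scheme_label(all_codes, cat$scheme)
            else NA_character_,
    area_pct = pct,
    stringsAsFactors = FALSE
  )
}

#' Write an area-fraction table as CSV
#'
#' @param fractions Output of [class_area_fractions()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_area_fractions <- function(fractions, path) {
  utils::write.csv(fractions, path, row.names = FALSE)
  invisible(path)
}
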