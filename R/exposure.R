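#' Population-bearing analysis zones
#'
#' A zone is a polygon (possibly with holes, possibly a multipolygon) in the
#' same CRS as the raster, carrying a zone id and a nonnegative resident
#' population. Geometry is stored as a list of parts, each part a list of
#' rings, each ring a two-column matrix of vertices (closed or open; the
#' closing vertex is implied). Cell membership uses the even-odd rule, so
#' holes need no special casing.
#'
#' @param zone_id Zone identifier (character).
#' @param geometry A single ring matrix, a list of rings (polygon with
#'   holes), or a list of lists of rings (multipolygon).
#' @param population Nonnegative integer resident count.
#' @param crs CRS identifier.
#' @return An object of class `ssi_zone`.
#' @export
zone_polygon <- function(zone_id, geometry, population, crs = "unspecified") {
  if (is.matrix(geometry)) geometry <- list(list(geometry))
  else if (is.list(geometry) && is.matrix(geometry[[1]])) {
    geometry <- list(geometry)
  }
  for (part in geometry) for (ring in part) {
    if (!is.matrix(ring) || ncol(ring) != 2L || nrow(ring) < 3L) {
      stop("each ring must be a matrix with >= 3 vertices and 2 columns",
           call. = FALSE)
    }
  }
  if (!is.numeric(population) || length(population) != 1L ||
      is.na(population) || population < 0) {
    stop("population must be a single nonnegative number", call. = FALSE)
  }
  structure(
    list(zone_id = as.character(zone_id), geometry = geometry,
         population = as.integer(round(population)),
         crs = as.character(crs)),
    class = "ssi_zone"
  )
}

is_zone <- function(x) inherits(x, "ssi_zone")

# Even-odd (ray casting) point-in-polygon over all rings of all parts.
# Vectorised over points; ring edges looped (vertex counts are small).
points_in_zone <- function(px, py, zone) {
  inside <- rep(FALSE, length(px))
  for (part in zone$geometry) for (ring in part) {
    n <- nrow(ring)
    xs <- ring[, 1]; ys <- ring[, 2]
    # drop explicit closing vertex
    if (xs[1] == xs[n] && ys[1] == ys[n]) { xs <- xs[-n]; ys <- ys[-n]; n <- n - 1L }
    j <- n
    for (i in seq_len(n)) {
      crosses <- ((ys[i] > py) != (ys[j] > py)) &
        (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
      inside <- xor(inside, crosses)
      j <- i
    }
  }
  inside
}

zone_bbox <- function(zone) {
  xs <- unlist(lapply(zone$geometry, function(p) lapply(p, function(r) r[, 1])))
  ys <- unlist(lapply(zone$geometry, function(p) lapply(p, function(r) r[, 2])))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

# Logical matrix: cells of `cat` whose centers fall inside the zone.
zone_cell_mask <- function(cat, zone) {
  ctr <- grid_cell_centers(list(values = cat$codes,
                                geotransform = cat$geotransform) |>
                             structure(class = "ssi_grid"))
  nr <- nrow(cat$codes); nc <- ncol(cat$codes)
  bb <- zone_bbox(zone)
  cols <- which(ctr$x >= bb["xmin"] & ctr$x <= bb["xmax"])
  rows <- which(ctr$y >= bb["ymin"] & ctr$y <= bb["ymax"])
  mask <- matrix(FALSE, nr, nc)
  if (!length(cols) || !length(rows)) return(mask)
  px <- rep(ctr$x[cols], each = length(rows))
  py <- rep(ctr$y[rows], times = length(cols))
  inside <- points_in_zone(px, py, zone)
  mask[rows, cols] <- matrix(inside, length(rows), length(cols))
  mask
}

#' Category area shares within one zone
#'
#' Fraction of the zone's valid-pixel area in each category, cells assigned
#' by a cell-center-in-polygon test (deterministic and fast; at coarse
#' resolutions relative to zone size this approximates exact polygon
#' clipping). A zone covering no valid cell returns all-zero shares with
#' `zero_coverage = TRUE`.
#'
#' @param cat An `ssi_catgrid`.
#' @param zone An [zone_polygon()].
#' @return List with `shares` (named numeric over category codes, summing to
#'   1 unless zero coverage), `cell_counts`, and `zero_coverage`.
#' @export
zone_category_shares <- function(cat, zone) {
  stopifnot(is_catgrid(cat), is_zone(zone))
  if (!identical(cat$crs, zone$crs)) {
    stop("CRS mismatch between grid ('", cat$crs, "') and zone ('",
         zone$crs, "'); reproject inputs first", call. = FALSE)
  }
  mask <- zone_cell_mask(cat, zone)
  valid <- mask & cat$codes != cat$nodata_code & !is.na(cat$codes)
  all_codes <- if (!is.null(cat$scheme)) cat$scheme$code else
    sort(unique(cat$codes[cat$codes != cat$nodata_code]))
  row_area <- .cell_areas_by_row(cat$geotransform, nrow(cat$codes), cat$crs)
  w <- matrix(row_area, nrow(cat$codes), ncol(cat$codes))
  area <- vapply(all_codes, function(k) sum(w[valid & cat$codes == k]),
                 numeric(1))
  counts <- vapply(all_codes, function(k) sum(valid & cat$codes == k),
                   integer(1))
  names(area) <- names(counts) <- all_codes
  tot <- sum(area)
  if (tot == 0) {
    return(list(shares = area, cell_counts = counts, zero_coverage = TRUE))
  }
  list(shares = area / tot, cell_counts = counts, zero_coverage = FALSE)
}

#' Apportion a zone population across categories
#'
#' Distributes `population` across category shares by areal weighting and
#' rounds with the largest-remainder method so that the integer counts sum
#' exactly to the input population. Ties in the remainders are broken by
#' ascending category code, making the table reproducible bit-for-bit.
#'
#' @param shares Named numeric vector of nonnegative shares summing to 1
#'   (names are category codes).
#' @param population Nonnegative integer.
#' @return Named integer vector of persons per category, summing exactly to
#'   `population`.
#' @examples
#' apportion_population(c(`4` = 0.6, `5` = 0.4), 1000)  # 600 400
#' apportion_population(c(`1` = 1, `2` = 1, `3` = 1) / 3, 10)  # 4 3 3
#' @export
apportion_population <- function(shares, population) {
  if (!is.numeric(population) || length(population) != 1L ||
      is.na(population) || population < 0) {
    stop("population must be a single nonnegative number", call. = FALSE)
  }
  population <- as.integer(round(population))
  if (any(shares < -1e-12)) stop("shares must be nonnegative", call. = FALSE)
  s <- sum(shares)
  if (s > 0 && abs(s - 1) > 1e-6) {
    stop("shares must sum to 1 (got ", format(s), ")", call. = FALSE)
  }
  if (s == 0) {  # zero coverage: caller assigns to an unclassified bucket
    out <- integer(length(shares))
    names(out) <- names(shares)
    return(out)
  }
  exact <- population * shares / s
  base <- floor(exact)
  leftover <- population - sum(base)
  rem <- exact - base
  # largest remainder; ties by ascending code order (the vector order,
  # which callers keep sorted by code)
  if (leftover > 0) {
    pick <- order(-rem, seq_along(rem))[seq_len(leftover)]
    base[pick] <- base[pick] + 1
  }
  out <- as.integer(base)
  names(out) <- names(shares)
  out
}

#' Aggregate population exposure over all zones
#'
#' For each zone, computes category area shares ([zone_category_shares()]),
#' apportions the zone population ([apportion_population()]), and sums
#' across zones. Zones with zero raster coverage contribute their entire
#' population to an `unclassified` row (code -1). Area percentages are
#' computed over the union of all zone masks.
#'
#' @param cat An `ssi_catgrid` (with a scheme attached for labels).
#' @param zones List of [zone_polygon()] objects (>= 1).
#' @param method `"areal"` (default) spreads each zone's population across
#'   categories in proportion to covered area; `"majority"` assigns the
#'   whole zone population to its modal category (ties broken by ascending
#'   code) — a sensitivity check, not a refinement.
#' @return A data frame of class `ssi_exposure` with columns `code`,
#'   `label`, `population`, `population_pct`, `area_pct`.
#' @export
aggregate_exposure <- function(cat, zones, method = c("areal", "majority")) {
  stopifnot(is_catgrid(cat), length(zones) >= 1L)
  method <- match.arg(method)
  if (is_zone(zones)) zones <- list(zones)
  all_codes <- if (!is.null(cat$scheme)) cat$scheme$code else
    sort(unique(cat$codes[cat$codes != cat$nodata_code]))
  pop <- stats::setNames(integer(length(all_codes)), all_codes)
  unclassified <- 0L
  union_mask <- matrix(FALSE, nrow(cat$codes), ncol(cat$codes))
  for (z in zones) {
    sh <- zone_category_shares(cat, z)
    union_mask <- union_mask | zone_cell_mask(cat, z)
    if (sh$zero_coverage) {
      unclassified <- unclassified + z$population
    } else if (method == "majority") {
      modal <- names(sh$shares)[which.max(sh$shares)]  # first max: low code
      pop[modal] <- pop[modal] + z$population
    } else {
      pop <- pop + apportion_population(sh$shares, z$population)
    }
  }
  total_pop <- sum(pop) + unclassified
  area <- tryCatch(class_area_fractions(cat, mask = union_mask),
                   error = function(e) NULL)
  out <- data.frame(
    code = as.integer(all_codes),
    label = if (!is.null(cat$scheme)) scheme_label(all_codes, cat$scheme)
            else NA_character_,
    population = as.integer(pop),
    population_pct = if (total_pop > 0) 100 * pop / total_pop else 0,
    area_pct = if (!is.null(area)) area$area_pct[match(all_codes, area$code)]
               else NA_real_,
    stringsAsFactors = FALSE
  )
  if (unclassified > 0L) {
    out <- rbind(out, data.frame(
      code = -1L, label = "Unclassified", population = unclassified,
      population_pct = if (total_pop > 0) 100 * unclassified / total_pop
                       else 0,
      area_pct = 0, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  structure(out, class = c("ssi_exposure", "data.frame"),
            total_population = total_pop)
}

#' Write an exposure table as CSV / JSON
#'
#' @param exposure An `ssi_exposure` table.
#' @param path Output path (`.csv` or `.json` by extension).
#' @return `path`, invisibly.
#' @export
write_exposure <- function(exposure, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(total_population = attr(exposure, "total_population"),
           rows = as.data.frame(exposure)),
      path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    utils::write.csv(as.data.frame(exposure), path, row.names = FALSE)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# GeoJSON zone I/O (jsonlite-based; FeatureCollection of (Multi)Polygons)

#' Read / write zones as GeoJSON
#'
#' Zones are exchanged as a GeoJSON FeatureCollection of Polygon or
#' MultiPolygon features. Field names for the id and population properties
#' are configurable. The CRS identifier is carried in the non-standard
#' top-level `crs_id` member (plain GeoJSON has no CRS slot).
#'
#' @param path GeoJSON path.
#' @param id_field,population_field Property names (defaults `"zone_id"`,
#'   `"population"`).
#' @return A list of [zone_polygon()] objects.
#' @export
read_zones <- function(path, id_field = "zone_id",
                       population_field = "population") {
  if (!file.exists(path)) stop("zones file not found: ", path, call. = FALSE)
  gj <- jsonlite::read_json(path)
  crs <- if (!is.null(gj$crs_id)) as.character(gj$crs_id) else "unspecified"
  ring_mat <- function(ring) {
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  }
  lapply(gj$features, function(f) {
    geom <- f$geometry
    parts <- switch(geom$type,
      Polygon = list(lapply(geom$coordinates, ring_mat)),
      MultiPolygon = lapply(geom$coordinates,
                            function(p) lapply(p, ring_mat)),
      stop("unsupported geometry type: ", geom$type, call. = FALSE))
    zone_polygon(f$properties[[id_field]], parts,
                 f$properties[[population_field]], crs = crs)
  })
}

#' @param zones List of [zone_polygon()] objects.
#' @rdname read_zones
#' @export
write_zones <- function(zones, path, id_field = "zone_id",
                        population_field = "population") {
  if (is_zone(zones)) zones <- list(zones)
  features <- lapply(zones, function(z) {
    coords <- lapply(z$geometry, function(part) {
      lapply(part, function(ring) {
        n <- nrow(ring)
        if (ring[1, 1] != ring[n, 1] || ring[1, 2] != ring[n, 2]) {
          ring <- rbind(ring, ring[1, ])
        }
        lapply(seq_len(nrow(ring)), function(i) as.list(ring[i, ]))
      })
    })
    multi <- length(coords) > 1L
    props <- list()
    props[[id_field]] <- z$zone_id
    props[[population_field]] <- z$population
    list(type = "Feature",
         properties = props,
         geometry = list(
           type = if (multi) "MultiPolygon" else "Polygon",
           coordinates = if (multi) coords else coords[[1]]))
  })
  payload <- list(type = "FeatureCollection",
                  crs_id = zones[[1]]$crs,
                  features = features)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
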