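#' Formula constants for the Summer Simmer Index
#'
#' The SSI is computed on the Fahrenheit scale as
#' \deqn{SSI = a [T_a - (b - c \cdot U_r)(T_a - pivot)] - offset}
#' with air temperature \eqn{T_a} in degrees Fahrenheit and relative humidity
#' \eqn{U_r} in percent. The defaults are the published constants of the
#' index; they are injected into [compute_ssi()] rather than inlined so that
#' they can be inspected and, if ever needed, overridden explicitly.
#'
#' @param a Leading multiplier (default 1.98).
#' @param b Humidity coefficient intercept (default 0.55).
#' @param c Humidity coefficient slope, per percent relative humidity
#'   (default 0.0055).
#' @param pivot Temperature (degrees F) at which humidity has no effect on
#'   the index (default 58).
#' @param offset Additive offset subtracted at the end (default 56.83).
#' @return A named list of class `ssi_constants`.
#' @examples
#' ssi_constants()
#' @export
ssi_constants <- function(a = 1.98, b = 0.55, c = 0.0055,
                          pivot = 58, offset = 56.83) {
  for (nm in c("a", "b", "c", "pivot", "offset")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("ssi_constants: `", nm, "` must be a single finite number",
           call. = FALSE)
    }
  }
  structure(list(a = a, b = b, c = c, pivot = pivot, offset = offset),
            class = "ssi_constants")
}

.valid_units <- c("C", "F")

normalize_unit <- function(unit) {
  if (length(unit) != 1L || is.na(unit)) {
    stop("temperature unit must be a single string", call. = FALSE)
  }
  u <- toupper(substr(as.character(unit), 1L, 1L))
  if (!u %in% .valid_units) {
    stop("unknown temperature unit '", unit, "' (expected 'C' or 'F')",
         call. = FALSE)
  }
  u
}

#' Convert temperatures between Celsius and Fahrenheit
#'
#' Applies the affine map F = C * 9/5 + 32 (or its inverse). Identity when
#' the units are equal. Vectorised; `NA` passes through.
#'
#' @param value Numeric vector of temperatures.
#' @param from,to Units, `"C"` or `"F"` (case-insensitive, may be spelled
#'   out).
#' @return Numeric vector in the target unit.
#' @examples
#' convert_temperature(0, "C", "F")    # 32
#' convert_temperature(98.6, "F", "C") # 37
#' @export
convert_temperature <- function(value, from, to) {
  from <- normalize_unit(from)
  to <- normalize_unit(to)
  if (!is.numeric(value)) stop("`value` must be numeric", call. = FALSE)
  if (from == to) return(value)
  if (from == "C") value * 9 / 5 + 32 else (value - 32) * 5 / 9
}

# Absolute-zero floor used to validate air temperatures.
.abs_zero <- c(C = -273.15, F = -459.67)

validate_air_temperature <- function(value, unit) {
  unit <- normalize_unit(unit)
  bad <- is.finite(value) & value <= .abs_zero[[unit]]
  if (any(bad)) {
    stop("air temperature at or below absolute zero (",
         sum(bad), " value(s) <= ", .abs_zero[[unit]], " degrees ", unit, ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

validate_humidity <- function(rh, clamp = FALSE) {
  if (!is.numeric(rh)) stop("relative humidity must be numeric", call. = FALSE)
  bad <- is.finite(rh) & (rh < 0 | rh > 100)
  if (any(bad)) {
    if (clamp) {
      rh <- pmin(pmax(rh, 0), 100)
    } else {
      stop("relative humidity outside [0, 100] for ", sum(bad),
           " value(s); pass clamp_rh = TRUE to clip noisy inputs",
           call. = FALSE)
    }
  }
  rh
}

#' Compute the Summer Simmer Index from Fahrenheit temperature
#'
#' Evaluates \eqn{SSI = 1.98[T_a - (0.55 - 0.0055 U_r)(T_a - 58)] - 56.83}
#' with \eqn{T_a} already on the Fahrenheit scale. The result is an
#' apparent temperature on the Fahrenheit scale. Vectorised with recycling;
#' `NA` in either input yields `NA`.
#'
#' The index is strictly increasing in temperature for any humidity, and the
#' humidity effect changes sign at 58 degrees F: above it, moist air feels
#' hotter; below it, moist air feels colder; at exactly 58 the humidity term
#' vanishes.
#'
#' @param ta_f Air temperature in degrees Fahrenheit.
#' @param ur Relative humidity in percent, in \[0, 100\].
#' @param constants An [ssi_constants()] object.
#' @param clamp_rh If `TRUE`, clip humidity into \[0, 100\] instead of
#'   raising an error (for noisy rasters); default `FALSE`.
#' @return Numeric vector of SSI values (Fahrenheit scale).
#' @examples
#' compute_ssi(100, 50)  # 118.301
#' compute_ssi(58, 75)   # 58.01, humidity has no effect at 58 F
#' @export
compute_ssi <- function(ta_f, ur, constants = ssi_constants(),
                        clamp_rh = FALSE) {
  stopifnot(inherits(constants, "ssi_constants"))
  if (!is.numeric(ta_f)) stop("`ta_f` must be numeric", call. = FALSE)
  validate_air_temperature(ta_f, "F")
  ur <- validate_humidity(ur, clamp = clamp_rh)
  k <- constants
  k$a * (ta_f - (k$b - k$c * ur) * (ta_f - k$pivot)) - k$offset
}

#' Compute SSI with explicit input and output units
#'
#' Converts the input temperature to Fahrenheit, applies [compute_ssi()],
#' and converts the resulting index value to `out_unit` if that is Celsius.
#' Classification must always use the Fahrenheit-scale value; the Celsius
#' display conversion is cosmetic.
#'
#' @param ta_value Air temperature in `in_unit`.
#' @param in_unit,out_unit `"C"` or `"F"`.
#' @param ur Relative humidity in percent.
#' @inheritParams compute_ssi
#' @return Numeric vector of SSI values in `out_unit`.
#' @examples
#' compute_ssi_units(30, "C", 60, "F") # 101.2532
#' compute_ssi_units(30, "C", 60, "C") # 38.474
#' @export
compute_ssi_units <- function(ta_value, in_unit, ur, out_unit,
                              constants = ssi_constants(),
                              clamp_rh = FALSE) {
  in_unit <- normalize_unit(in_unit)
  out_unit <- normalize_unit(out_unit)
  validate_air_temperature(ta_value, in_unit)
  ta_f <- convert_temperature(ta_value, in_unit, "F")
  ssi_f <- compute_ssi(ta_f, ur, constants = constants, clamp_rh = clamp_rh)
  convert_temperature(ssi_f, "F", out_unit)
}

# ---------------------------------------------------------------------------
# Classification scheme

.table1_bounds <- c(70, 77, 83, 91, 100, 112, 125, 150)

.table1_labels <- c(
  "Below scale", "Cold", "Cold", "Comfortable", "Warm-Hot",
  "Sweltering", "Extremely Hot", "Extremely Hot", "Deadly Hot"
)

.table1_descriptions <- c(
  "Below the published interpretation scale (cool-season or highland conditions)",
  "Cosy for most people, but a bit cool",
  "Ideal temperature; everyone feels comfortable",
  "Favourable for most people, but feels a little warm",
  "Temperatures above normal values",
  "Various disorders occur due to prolonged exposure",
  "Perceived temperatures high for almost everyone; illness with prolonged exposure",
  "Affects vital functions of vulnerable groups (patients, the elderly, children)",
  "Fatal consequences in case of prolonged exposure"
)

# Default collapse of the nine interval codes onto the six-label summer
# legend (Cold / Cool / Comfortable / Warm / Hot / So Hot). The published
# interval table does not state this mapping, so it is configurable.
.sixclass_labels <- c(
  "Cold", "Cold", "Cool", "Comfortable", "Warm",
  "Hot", "So Hot", "So Hot", "So Hot"
)

.default_colors <- c(
  "#c6dbef", "#9ecae1", "#6baed6", "#a1d99b", "#fee08b",
  "#fdae61", "#f46d43", "#d73027", "#a50026"
)

#' Thermal-comfort classification scheme for SSI values
#'
#' Builds the ordered set of half-open SSI intervals \[lower, upper) used to
#' classify Fahrenheit-scale SSI values. The eight published intervals start
#' at 70 degrees F; an explicit code-0 "Below scale" category covers
#' (-Inf, 70) because interpolated highland or cool-season pixels
#' legitimately fall below the table. An SSI of exactly 150 is assigned to
#' the top "Deadly Hot" category (the printed table leaves 150 unassigned
#' between "125 <= SSI < 150" and "150 < SSI"; closing the lower bound keeps
#' the partition total).
#'
#' The `"sixclass"` variant keeps the same nine interval codes but relabels
#' them with the six-label summer legend (Cold, Cool, Comfortable, Warm,
#' Hot, So Hot); the interval-to-label mapping is configurable through
#' `six_labels` since it is a reporting convention, not part of the index.
#'
#' @param variant `"table1"` (default) for the eight published intervals plus
#'   the below-scale category, or `"sixclass"` for the six-label legend.
#' @param six_labels Optional character vector of length 9 giving the label
#'   for each code 0..8 when `variant = "sixclass"`.
#' @return A data frame of class `ssi_scheme` with columns `code`, `label`,
#'   `lower`, `upper`, `description`, `color`, and attribute
#'   `legend_variant`.
#' @examples
#' ssi_scheme()
#' ssi_scheme("sixclass")$label
#' @export
ssi_scheme <- function(variant = c("table1", "sixclass"), six_labels = NULL) {
  variant <- match.arg(variant)
  lower <- c(-Inf, .table1_bounds)
  upper <- c(.table1_bounds, Inf)
  labels <- if (variant == "table1") {
    .table1_labels
  } else {
    lab <- if (is.null(six_labels)) .sixclass_labels else six_labels
    if (length(lab) != 9L) {
      stop("`six_labels` must map all 9 codes (length 9)", call. = FALSE)
    }
    as.character(lab)
  }
  out <- data.frame(
    code = 0:8,
    label = labels,
    lower = lower,
    upper = upper,
    description = .table1_descriptions,
    color = .default_colors,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("ssi_scheme", "data.frame"),
            legend_variant = toupper(variant))
}

validate_scheme <- function(scheme) {
  if (!inherits(scheme, "ssi_scheme")) {
    stop("`scheme` must be created by ssi_scheme() or read_scheme()",
         call. = FALSE)
  }
  stopifnot(all(scheme$lower < scheme$upper))
  if (is.unsorted(scheme$lower)) {
    stop("scheme categories must be sorted by lower bound", call. = FALSE)
  }
  # contiguity: each upper bound equals the next lower bound
  n <- nrow(scheme)
  if (n > 1L && !all(scheme$upper[-n] == scheme$lower[-1L])) {
    stop("scheme intervals must be contiguous", call. = FALSE)
  }
  invisible(TRUE)
}

#' Classify Fahrenheit-scale SSI values into comfort categories
#'
#' Maps each finite SSI value to the unique half-open interval
#' \[lower, upper) that contains it and returns the category code. Values
#' below 70 map to the below-scale code 0; exactly 150 maps to the top
#' category. `NA` inputs return `NA`; non-finite (Inf) inputs are rejected.
#'
#' @param ssi_f Numeric vector of SSI values on the Fahrenheit scale.
#' @param scheme An [ssi_scheme()] classification scheme.
#' @return Integer vector of category codes.
#' @examples
#' sch <- ssi_scheme()
#' classify_ssi(c(105, 83, 69.9), sch)  # 5, 3, 0
#' @export
classify_ssi <- function(ssi_f, scheme = ssi_scheme()) {
  validate_scheme(scheme)
  if (!is.numeric(ssi_f)) stop("`ssi_f` must be numeric", call. = FALSE)
  if (any(is.infinite(ssi_f) | is.nan(ssi_f))) {
    stop("SSI values must be finite for classification", call. = FALSE)
  }
  # left-closed/right-open: findInterval on the interior bounds
  bounds <- scheme$lower[-1L]
  idx <- findInterval(ssi_f, bounds, left.open = FALSE)
  out <- scheme$code[idx + 1L]
  out[is.na(ssi_f)] <- NA_integer_
  as.integer(out)
}

#' Look up category metadata by code
#'
#' @param code Integer vector of category codes.
#' @param scheme An [ssi_scheme()].
#' @return Character vector of labels.
#' @export
scheme_label <- function(code, scheme = ssi_scheme()) {
  validate_scheme(scheme)
  scheme$label[match(code, scheme$code)]
}

#' Write / read a classification scheme as JSON
#'
#' The legend sidecar stores codes, bounds (infinities as strings), labels,
#' descriptions and hex colors so that downstream tools can reconstruct the
#' classification exactly.
#'
#' @param scheme An [ssi_scheme()].
#' @param path File path for the JSON legend.
#' @return `write_scheme` returns `path` invisibly; `read_scheme` returns an
#'   `ssi_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  validate_scheme(scheme)
  payload <- list(
    legend_variant = attr(scheme, "legend_variant"),
    categories = lapply(seq_len(nrow(scheme)), function(i) {
      list(
        code = scheme$code[i],
        label = scheme$label[i],
        lower = if (is.infinite(scheme$lower[i])) "-Inf" else scheme$lower[i],
        upper = if (is.infinite(scheme$upper[i])) "Inf" else scheme$upper[i],
        description = scheme$description[i],
        color = scheme$color[i]
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path, call. = FALSE)
  payload <- jsonlite::read_json(path)
  cats <- payload$categories
  out <- data.frame(
    code = vapply(cats, function(x) as.integer(x$code), integer(1)),
    label = vapply(cats, function(x) as.character(x$label), character(1)),
    lower = vapply(cats, function(x) as.numeric(x$lower), numeric(1)),
    upper = vapply(cats, function(x) as.numeric(x$upper), numeric(1)),
    description = vapply(cats, function(x) as.character(x$description),
                         character(1)),
    color = vapply(cats, function(x) as.character(x$color), character(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$lower), , drop = FALSE]
  rownames(out) <- NULL
  sch <- structure(out, class = c("ssi_scheme", "data.frame"),
                   legend_variant = as.character(payload$legend_variant))
  validate_scheme(sch)
  sch
}
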