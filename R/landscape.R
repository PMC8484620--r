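#' Binary forest/non-forest landscape
#'
#' The unit of all raster computation in fragtrack: a single epoch's binary
#' forest map on a regular square-pixel grid in a projected CRS. Cell states
#' are coded `1L` (forest), `0L` (non-forest) and `NA` (nodata). The grid is
#' stored row 1 = northernmost row, so `origin` is the coordinate of the
#' *top-left corner* of pixel `[1, 1]`.
#'
#' @param values Integer (or coercible) matrix of 0/1/NA cell states.
#' @param pixel_size Side length of the square pixels, metres.
#' @param origin Numeric length-2, `(x, y)` of the grid's top-left corner in
#'   projected map units (metres).
#' @param crs_id Free-text identifier of the projected CRS (e.g. an EPSG code).
#' @param epoch_year Integer year label for this epoch, or `NA`.
#'
#' @return An object of class `binary_landscape`.
#' @export
binary_landscape <- function(values, pixel_size,
                             origin = c(0, nrow(values) * pixel_size),
                             crs_id = "local", epoch_year = NA_integer_) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("landscape grid must have at least one row and one column", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || !is.finite(pixel_size) ||
      pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (metres)", call. = FALSE)
  storage.mode(values) <- "integer"
  bad <- !(values %in% c(0L, 1L)) & !is.na(values)
  if (any(bad))
    stop("landscape cells must be 0 (non-forest), 1 (forest) or NA (nodata)",
         call. = FALSE)
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("`origin` must be finite (x, y) of the top-left corner", call. = FALSE)
  structure(
    list(values = values, pixel_size = as.numeric(pixel_size),
         origin = as.numeric(origin), crs_id = as.character(crs_id),
         epoch_year = as.integer(epoch_year)),
    class = "binary_landscape")
}

#' @export
print.binary_landscape <- function(x, ...) {
  cat(sprintf("<binary_landscape> %d x %d @ %g m%s\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              if (is.na(x$epoch_year)) "" else sprintf(", epoch %d", x$epoch_year)))
  cat(sprintf("  forest: %d px (%.4f km2)  non-forest: %d px  nodata: %d px\n",
              sum(x$values == 1L, na.rm = TRUE), forest_area_km2(x),
              sum(x$values == 0L, na.rm = TRUE), sum(is.na(x$values))))
  cat(sprintf("  origin (%g, %g), crs '%s'\n", x$origin[1], x$origin[2], x$crs_id))
  invisible(x)
}

#' Forest area of a landscape
#'
#' Area is pixel count times squared pixel size; nodata cells contribute
#' nothing. No geodesic correction is applied (projected CRS assumed).
#'
#' @param x A `binary_landscape`.
#' @return Forest area in km^2.
#' @export
forest_area_km2 <- function(x) {
  stopifnot(inherits(x, "binary_landscape"))
  sum(x$values == 1L, na.rm = TRUE) * x$pixel_size^2 / 1e6
}

#' Landscape extent
#'
#' @param x A `binary_landscape`.
#' @return Named numeric `(xmin, xmax, ymin, ymax)` in map units.
#' @export
landscape_extent <- function(x) {
  stopifnot(inherits(x, "binary_landscape"))
  c(xmin = x$origin[1],
    xmax = x$origin[1] + ncol(x$values) * x$pixel_size,
    ymin = x$origin[2] - nrow(x$values) * x$pixel_size,
    ymax = x$origin[2])
}

# Pixel-alignment check shared by every multi-raster operation. Misalignment is
# an error, never an implicit resample.
check_aligned <- function(a, b, what = "landscapes") {
  ok <- identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$pixel_size, b$pixel_size, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-6))
  if (!ok)
    stop(sprintf("%s are not pixel-aligned (shape, pixel size and origin must match)",
                 what), call. = FALSE)
  invisible(TRUE)
}

#' Ordered multi-epoch landscape series
#'
#' All members must be pixel-aligned (same shape, pixel size, origin, CRS) and
#' carry strictly increasing epoch years.
#'
#' @param ... `binary_landscape` objects, or a single list of them.
#' @return An object of class `landscape_series` (a list of landscapes).
#' @export
landscape_series <- function(...) {
  epochs <- list(...)
  if (length(epochs) == 1L && !inherits(epochs[[1]], "binary_landscape"))
    epochs <- epochs[[1]]
  if (length(epochs) < 1L) stop("a series needs at least one epoch", call. = FALSE)
  lapply(epochs, function(e) stopifnot(inherits(e, "binary_landscape")))
  years <- vapply(epochs, function(e) e$epoch_year, integer(1))
  if (anyNA(years) || any(diff(years) <= 0))
    stop("epoch years must be present and strictly increasing", call. = FALSE)
  if (length(epochs) > 1L)
    for (i in 2:length(epochs)) check_aligned(epochs[[1]], epochs[[i]], "series epochs")
  crs <- unique(vapply(epochs, function(e) e$crs_id, character(1)))
  if (length(crs) > 1L)
    stop("series epochs carry different crs_id values: ", paste(crs, collapse = ", "),
         call. = FALSE)
  structure(epochs, class = "landscape_series")
}

#' @export
print.landscape_series <- function(x, ...) {
  cat(sprintf("<landscape_series> %d epochs (%s), %d x %d @ %g m\n",
              length(x), paste(epoch_years(x), collapse = ", "),
              nrow(x[[1]]$values), ncol(x[[1]]$values), x[[1]]$pixel_size))
  invisible(x)
}

#' @rdname landscape_series
#' @param series A `landscape_series`.
#' @return `epoch_years()`: integer vector of epoch year labels.
#' @export
epoch_years <- function(series) {
  stopifnot(inherits(series, "landscape_series"))
  vapply(series, function(e) e$epoch_year, integer(1))
}

#' Point set in the raster CRS
#'
#' @param x,y Numeric coordinate vectors (map units).
#' @param year Optional integer vector of event years.
#' @param ... Further equal-length attribute vectors.
#' @return A `tbl_df` with class `point_set`.
#' @export
point_set <- function(x, y, year = NULL, ...) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("point coordinates must be finite", call. = FALSE)
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y))
  if (!is.null(year)) out$year <- as.integer(year)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  class(out) <- c("point_set", class(out))
  out
}
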