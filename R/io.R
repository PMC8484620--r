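#' Read a binary forest raster from an Arc/Info ASCII grid
#'
#' Single-band integer rasters are exchanged as Arc/Info ASCII grids (`.asc`),
#' the plain-text raster format of the landscape-ecology toolchain. Cells whose
#' value is in `forest_codes` become forest, the header's nodata value becomes
#' nodata, everything else non-forest. An optional `.prj` sidecar (same path,
#' `.prj` extension) supplies the CRS identifier.
#'
#' @param path Path to the `.asc` file.
#' @param forest_codes Non-empty integer vector of cell values mapped to forest.
#' @param epoch_year Optional epoch year label to attach.
#' @return A [binary_landscape()].
#' @export
read_binary_raster <- function(path, forest_codes = 1L, epoch_year = NA_integer_) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  if (length(forest_codes) < 1L) stop("`forest_codes` must be non-empty", call. = FALSE)
  g <- read_ascii_grid(path)
  vals <- g$values
  out <- matrix(0L, nrow(vals), ncol(vals))
  out[vals %in% as.integer(forest_codes)] <- 1L
  out[is.na(vals)] <- NA_integer_
  if (all(is.na(out)))
    warning("raster is entirely nodata: ", path, call. = FALSE)
  prj <- sub("\\.[^.]*$", ".prj", path)
  crs_id <- if (file.exists(prj)) trimws(readLines(prj, n = 1L, warn = FALSE)) else "unspecified"
  if (!nzchar(crs_id)) stop("unreadable CRS in sidecar: ", prj, call. = FALSE)
  binary_landscape(out, pixel_size = g$cellsize, origin = g$origin,
                   crs_id = crs_id, epoch_year = epoch_year)
}

# Low-level Arc/Info ASCII grid reader. Accepts the standard 6-line header
# (ncols/nrows/xllcorner/yllcorner/cellsize/nodata_value) and the dx/dy
# variant; non-square pixels (|dx - dy| > 0.1% of dx) are an error.
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows")
  if (!all(need %in% names(hdr)))
    stop("not an Arc/Info ASCII grid (missing ncols/nrows header): ", path,
         call. = FALSE)
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  if (!is.null(hdr$dx) || !is.null(hdr$dy)) {
    dx <- hdr$dx %||% hdr$dy; dy <- hdr$dy %||% hdr$dx
    if (abs(dx - dy) > 1e-3 * abs(dx))
      stop("non-square pixels (dx != dy within 0.1%) in ", path, call. = FALSE)
    cellsize <- (dx + dy) / 2
  } else if (!is.null(hdr$cellsize)) {
    cellsize <- hdr$cellsize
  } else stop("missing cellsize in ", path, call. = FALSE)
  nodata <- hdr$nodata_value %||% -9999
  body <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(body) != nrows * ncols)
    stop(sprintf("expected %d cells, found %d in %s", nrows * ncols,
                 length(body), path), call. = FALSE)
  vals <- matrix(as.integer(body), nrow = nrows, ncol = ncols, byrow = TRUE)
  vals[vals == as.integer(nodata)] <- NA_integer_
  xll <- hdr$xllcorner %||% 0
  yll <- hdr$yllcorner %||% 0
  list(values = vals, cellsize = cellsize,
       origin = c(xll, yll + nrows * cellsize))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared ASCII-grid writer for integer matrices (row 1 = top).
write_ascii_matrix <- function(values, pixel_size, origin, path, nodata = -9999L) {
  v <- values
  v[is.na(v)] <- as.integer(nodata)
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.6f", origin[1]),
           sprintf("yllcorner %.6f", origin[2] - nrow(v) * pixel_size),
           sprintf("cellsize %.6f", pixel_size),
           sprintf("NODATA_value %d", as.integer(nodata)))
  body <- apply(v, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a binary landscape as an Arc/Info ASCII grid
#'
#' Forest is written as 1, non-forest as 0, nodata as the nodata value. The
#' CRS id goes into a `.prj` sidecar.
#'
#' @param landscape A [binary_landscape()].
#' @param path Output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_binary_raster <- function(landscape, path) {
  stopifnot(inherits(landscape, "binary_landscape"))
  write_ascii_matrix(landscape$values, landscape$pixel_size, landscape$origin, path)
  writeLines(landscape$crs_id, sub("\\.[^.]*$", ".prj", path))
  invisible(path)
}

#' Write a fragmentation class raster
#'
#' Class codes 0-6 (non-forest, patch, edge, perforated, core1, core2, core3)
#' are fixed; a JSON sidecar (`<path>.json`) records the code table and the
#' classification parameters for provenance.
#'
#' @param map A [classify_fragmentation()] result.
#' @param path Output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_class_raster <- function(map, path) {
  stopifnot(inherits(map, "fragmentation_map"))
  write_ascii_matrix(map$classes, map$pixel_size, map$origin, path)
  writeLines(map$crs_id, sub("\\.[^.]*$", ".prj", path))
  par <- unclass(map$params)
  if (is.infinite(par$max_hole_area_km2)) par$max_hole_area_km2 <- "unlimited"
  sidecar <- list(
    class_codes = as.list(stats::setNames(0:6, frag_class_names())),
    params = par,
    epoch_year = if (is.na(map$epoch_year)) NULL else map$epoch_year,
    pixel_size = map$pixel_size)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a fragmentation class raster written by [write_class_raster()]
#'
#' @param path Path to the `.asc` file (expects the `.json` sidecar alongside).
#' @return A `fragmentation_map`.
#' @export
read_class_raster <- function(path) {
  g <- read_ascii_grid(path)
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing class-raster sidecar: ", side, call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (identical(meta$params$max_hole_area_km2, "unlimited"))
    meta$params$max_hole_area_km2 <- Inf
  params <- do.call(frag_params, meta$params[names(meta$params) %in%
                                               names(formals(frag_params))])
  prj <- sub("\\.[^.]*$", ".prj", path)
  crs_id <- if (file.exists(prj)) trimws(readLines(prj, n = 1L, warn = FALSE)) else "unspecified"
  cl <- g$values
  cl[is.na(cl)] <- 0L
  new_fragmentation_map(cl, params, g$cellsize, g$origin, crs_id,
                        as.integer(meta$epoch_year %||% NA_integer_))
}

#' Read conflict/event point locations from CSV
#'
#' Expects columns `x`, `y` and optionally `year`, in the raster CRS.
#'
#' @param path CSV path.
#' @return A [point_set()].
#' @export
read_points_csv <- function(path) {
  if (!file.exists(path)) stop("points file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(d)))
    stop("points CSV must have columns x, y", call. = FALSE)
  point_set(d$x, d$y, year = if ("year" %in% names(d)) d$year else NULL)
}

#' Write a point set to CSV
#' @param points A [point_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_points_csv <- function(points, path) {
  utils::write.csv(as.data.frame(points), path, row.names = FALSE)
  invisible(path)
}

#' Write an analysis grid as GeoJSON
#'
#' Each cell becomes a Polygon feature with properties `id`, `row`, `col`.
#'
#' @param grid A [make_grid()] result.
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_grid_geojson <- function(grid, path) {
  stopifnot(inherits(grid, "grid_set"))
  feats <- lapply(seq_len(nrow(grid)), function(i) {
    r <- grid[i, ]
    ring <- list(c(r$xmin, r$ymin), c(r$xmax, r$ymin), c(r$xmax, r$ymax),
                 c(r$xmin, r$ymax), c(r$xmin, r$ymin))
    list(type = "Feature",
         properties = list(id = r$id, row = r$row, col = r$col),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
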