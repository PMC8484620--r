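#' Remove forest patches below the minimum mapping unit
#'
#' Forest patches (8-connected) smaller than `min_area` are reclassified as
#' non-forest, implementing the "forest is anything larger than 0.5 ha"
#' mapping rule. Idempotent.
#'
#' @param landscape A [binary_landscape()].
#' @param min_area Minimum retained patch area, m^2 (default 5000 = 0.5 ha).
#' @return A [binary_landscape()].
#' @export
apply_mmu <- function(landscape, min_area = 5000) {
  stopifnot(inherits(landscape, "binary_landscape"), min_area >= 0)
  if (min_area == 0) return(landscape)
  lc <- label_components(landscape$values == 1L, connectivity = 8)
  if (lc$n == 0L) return(landscape)
  small <- which(lc$sizes * landscape$pixel_size^2 < min_area)
  v <- landscape$values
  v[lc$labels %in% small] <- 0L
  binary_landscape(v, landscape$pixel_size, landscape$origin,
                   landscape$crs_id, landscape$epoch_year)
}

#' Nearest-neighbour resampling to a new pixel size
#'
#' The georeferenced extent is preserved to within one target pixel: the new
#' grid keeps the same origin with `round(extent / target)` rows/columns, and
#' each new cell takes the state of the source pixel containing its centre.
#'
#' @param landscape A [binary_landscape()].
#' @param target_pixel_size New pixel size, metres.
#' @return A [binary_landscape()] at the target resolution.
#' @export
resample_to <- function(landscape, target_pixel_size) {
  stopifnot(inherits(landscape, "binary_landscape"), target_pixel_size > 0)
  ps <- landscape$pixel_size
  ratio <- max(target_pixel_size / ps, ps / target_pixel_size)
  if (ratio > 100)
    stop("resampling factor exceeds 100; check pixel-size units", call. = FALSE)
  if (isTRUE(all.equal(target_pixel_size, ps))) return(landscape)
  nr <- nrow(landscape$values); nc <- ncol(landscape$values)
  new_nr <- max(1L, as.integer(round(nr * ps / target_pixel_size)))
  new_nc <- max(1L, as.integer(round(nc * ps / target_pixel_size)))
  # source row/col containing each target pixel centre
  src_r <- pmin(nr, pmax(1L, ceiling(((seq_len(new_nr) - 0.5) * target_pixel_size) / ps)))
  src_c <- pmin(nc, pmax(1L, ceiling(((seq_len(new_nc) - 0.5) * target_pixel_size) / ps)))
  binary_landscape(landscape$values[src_r, src_c, drop = FALSE],
                   target_pixel_size, landscape$origin,
                   landscape$crs_id, landscape$epoch_year)
}

#' Build a square analysis grid over a landscape
#'
#' Cells are anchored at the raster origin (top-left) and tile the extent
#' without overlap; boundary cells are clipped to the extent, so cell areas
#' sum exactly to the extent area.
#'
#' @param landscape A [binary_landscape()].
#' @param cell_size Cell side length, metres (default 5000 = the 5 x 5 km
#'   analysis grid).
#' @return A `grid_set`: a tibble of cells (`id`, `row`, `col`, bounds,
#'   `area_m2`) with attributes `cell_size` and `extent`.
#' @export
make_grid <- function(landscape, cell_size = 5000) {
  stopifnot(inherits(landscape, "binary_landscape"))
  if (cell_size < landscape$pixel_size)
    stop("`cell_size` must be at least the pixel size", call. = FALSE)
  ext <- landscape_extent(landscape)
  width <- ext["xmax"] - ext["xmin"]; height <- ext["ymax"] - ext["ymin"]
  ncell_x <- as.integer(ceiling(width / cell_size - 1e-9))
  ncell_y <- as.integer(ceiling(height / cell_size - 1e-9))
  cells <- expand.grid(col = seq_len(ncell_x), row = seq_len(ncell_y))
  cells <- cells[order(cells$row, cells$col), ]
  xmin <- ext[["xmin"]] + (cells$col - 1) * cell_size
  ymax <- ext[["ymax"]] - (cells$row - 1) * cell_size
  out <- tibble::tibble(
    id = seq_len(nrow(cells)),
    row = cells$row, col = cells$col,
    xmin = xmin, xmax = pmin(xmin + cell_size, ext[["xmax"]]),
    ymin = pmax(ymax - cell_size, ext[["ymin"]]), ymax = ymax)
  out$area_m2 <- (out$xmax - out$xmin) * (out$ymax - out$ymin)
  attr(out, "cell_size") <- cell_size
  attr(out, "extent") <- ext
  class(out) <- c("grid_set", class(out))
  out
}

# Assign each pixel centre to a grid cell id (half-open cell intervals, so a
# pixel belongs to exactly one cell). Returns an integer matrix of cell ids.
grid_cell_of_pixels <- function(landscape, grid) {
  stopifnot(inherits(grid, "grid_set"))
  cs <- attr(grid, "cell_size")
  ext <- landscape_extent(landscape)
  nr <- nrow(landscape$values); nc <- ncol(landscape$values)
  xc <- ext[["xmin"]] + (seq_len(nc) - 0.5) * landscape$pixel_size
  yc <- ext[["ymax"]] - (seq_len(nr) - 0.5) * landscape$pixel_size
  col_idx <- pmin(max(grid$col), floor((xc - ext[["xmin"]]) / cs) + 1L)
  row_idx <- pmin(max(grid$row), floor((ext[["ymax"]] - yc) / cs) + 1L)
  ncell_x <- max(grid$col)
  matrix(as.integer((rep(row_idx, nc) - 1L) * ncell_x +
                      rep(col_idx, each = nr)), nr, nc)
}
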