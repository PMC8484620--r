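#' Percent change between two areas
#'
#' `100 (a2 - a1) / a1`; negative = loss. All internal values are signed; any
#' magnitude-plus-direction presentation belongs to the reporting layer.
#'
#' @param a1,a2 Areas (same units, typically km^2) at the earlier and later
#'   epoch. Vectorised.
#' @return Signed percent change; `NA` where `a1 <= 0`.
#' @export
percent_change <- function(a1, a2) {
  out <- ifelse(a1 > 0, 100 * (a2 - a1) / a1, NA_real_)
  if (anyNA(out)) warning("percent change undefined where a1 <= 0", call. = FALSE)
  out
}

#' Compound annual rate of change
#'
#' The continuous-compounding rate matching areas `a1`, `a2` at years `t1`,
#' `t2`: `r = 100 ln(a2 / a1) / (t2 - t1)` in percent per year. Negative =
#' loss. A vanished area (`a2 = 0`) yields `-Inf` with a warning.
#'
#' @param a1,a2 Areas at the two epochs (`a1 > 0`, `a2 >= 0`). Vectorised.
#' @param t1,t2 Epoch years, `t2 > t1`.
#' @return Signed rate, percent per year (round only at reporting time).
#' @export
annual_rate <- function(a1, a2, t1, t2) {
  if (any(t2 <= t1)) stop("`t2` must exceed `t1`", call. = FALSE)
  if (any(a1 <= 0)) stop("`a1` must be positive", call. = FALSE)
  if (any(a2 == 0)) warning("a2 = 0: rate is -Inf", call. = FALSE)
  100 * log(a2 / a1) / (t2 - t1)
}

change_codes <- function() c("stable_nonforest", "loss", "gain", "stable_forest")

#' Pixel-level change map between two epochs
#'
#' Per-pixel 2x2 classification of two aligned binary landscapes: `loss`
#' (forest at t1, non-forest at t2), `gain` (the reverse), `stable_forest`,
#' `stable_nonforest`. Nodata counts as non-forest.
#'
#' @param t1,t2 Pixel-aligned [binary_landscape()] epochs.
#' @return A `change_map` (codes 0-3 per [change_codes()]) with the epoch
#'   pair, pixel size and georeferencing.
#' @export
change_map <- function(t1, t2) {
  stopifnot(inherits(t1, "binary_landscape"), inherits(t2, "binary_landscape"))
  check_aligned(t1, t2, "change_map epochs")
  f1 <- t1$values == 1L; f1[is.na(f1)] <- FALSE
  f2 <- t2$values == 1L; f2[is.na(f2)] <- FALSE
  codes <- matrix(0L, nrow(f1), ncol(f1))
  codes[f1 & !f2] <- 1L
  codes[!f1 & f2] <- 2L
  codes[f1 & f2] <- 3L
  structure(list(codes = codes, year1 = t1$epoch_year, year2 = t2$epoch_year,
                 pixel_size = t1$pixel_size, origin = t1$origin,
                 crs_id = t1$crs_id),
            class = "change_map")
}

#' @export
print.change_map <- function(x, ...) {
  n <- tabulate(x$codes + 1L, nbins = 4L)
  km2 <- n * x$pixel_size^2 / 1e6
  cat(sprintf("<change_map> %s -> %s\n", x$year1, x$year2))
  for (i in 1:4) cat(sprintf("  %-17s %9d px %12.4f km2\n",
                             change_codes()[i], n[i], km2[i]))
  invisible(x)
}

#' Area summary of a change map
#' @param change A [change_map()].
#' @return Tibble `category`, `pixels`, `area_km2`.
#' @export
change_area_summary <- function(change) {
  stopifnot(inherits(change, "change_map"))
  n <- tabulate(change$codes + 1L, nbins = 4L)
  tibble::tibble(category = change_codes(), pixels = n,
                 area_km2 = n * change$pixel_size^2 / 1e6)
}

#' Per-grid-cell forest change summary
#'
#' Zonal forest area per epoch for every cell of an analysis grid (pixels
#' assigned by centre, half-open intervals), with first-to-last change,
#' percent change, compound annual rate and a change category:
#' `complete_loss` (had forest, lost all), `deforested` (lost some),
#' `gain`, `stable`.
#'
#' @param series A [landscape_series()].
#' @param grid A [make_grid()] result on the same extent.
#' @return A tibble with one row per grid cell: `cell`, one
#'   `area_<year>_km2` column per epoch, `delta_km2`, `pct_change`,
#'   `annual_rate`, `category`.
#' @export
grid_change_summary <- function(series, grid) {
  stopifnot(inherits(series, "landscape_series"), inherits(grid, "grid_set"))
  years <- epoch_years(series)
  cellmap <- grid_cell_of_pixels(series[[1]], grid)
  ncell <- nrow(grid)
  px_km2 <- series[[1]]$pixel_size^2 / 1e6
  areas <- vapply(series, function(ep) {
    f <- ep$values == 1L; f[is.na(f)] <- FALSE
    cnt <- tabulate(cellmap[f], nbins = ncell)
    cnt * px_km2
  }, numeric(ncell))
  areas <- matrix(areas, nrow = ncell)
  out <- tibble::tibble(cell = grid$id)
  for (j in seq_along(years)) out[[sprintf("area_%d_km2", years[j])]] <- areas[, j]
  a1 <- areas[, 1]; a2 <- areas[, ncol(areas)]
  out$delta_km2 <- a2 - a1
  out$pct_change <- suppressWarnings(percent_change(a1, a2))
  out$annual_rate <- suppressWarnings(
    ifelse(a1 > 0, 100 * log(ifelse(a2 > 0, a2 / a1, NA)) /
             (years[length(years)] - years[1]), NA_real_))
  out$annual_rate[a1 > 0 & a2 == 0] <- -Inf
  out$category <- ifelse(a1 > 0 & a2 == 0, "complete_loss",
                         ifelse(a2 < a1, "deforested",
                                ifelse(a2 > a1, "gain", "stable")))
  out
}

#' Cross-tabulate fragmentation classes between two epochs
#'
#' @param m1,m2 Aligned `fragmentation_map`s produced with identical
#'   parameters.
#' @return 7x7 area matrix (km^2), rows = classes at t1, columns = t2; row
#'   and column sums reproduce the two [class_area_summary()] tables exactly.
#' @export
crosstab <- function(m1, m2) {
  stopifnot(inherits(m1, "fragmentation_map"), inherits(m2, "fragmentation_map"))
  if (!isTRUE(all.equal(unclass(m1$params), unclass(m2$params))))
    stop("fragmentation maps were produced with different parameters", call. = FALSE)
  if (!identical(dim(m1$classes), dim(m2$classes)) ||
      !isTRUE(all.equal(m1$origin, m2$origin)) ||
      !isTRUE(all.equal(m1$pixel_size, m2$pixel_size)))
    stop("fragmentation maps are not pixel-aligned", call. = FALSE)
  lev <- frag_class_names()
  tab <- table(factor(m1$classes, levels = 0:6, labels = lev),
               factor(m2$classes, levels = 0:6, labels = lev))
  unclass(tab) * m1$pixel_size^2 / 1e6
}

#' Fraction of points falling on forest-loss pixels
#'
#' Points are mapped to the pixel containing them; points outside the raster
#' extent are excluded from the fraction but flagged in the per-point table,
#' never dropped silently.
#'
#' @param points A [point_set()].
#' @param change A [change_map()].
#' @return List: `fraction` (of in-extent points on loss pixels), `n_inside`,
#'   `n_outside`, and `labels` (per-point tibble with `inside` and `in_loss`).
#' @export
points_in_loss <- function(points, change) {
  stopifnot(inherits(points, "point_set"), inherits(change, "change_map"))
  ps <- change$pixel_size
  nr <- nrow(change$codes); nc <- ncol(change$codes)
  col <- floor((points$x - change$origin[1]) / ps) + 1
  row <- floor((change$origin[2] - points$y) / ps) + 1
  inside <- col >= 1 & col <= nc & row >= 1 & row <= nr
  if (!any(inside)) stop("no points fall inside the raster extent", call. = FALSE)
  in_loss <- rep(NA, length(inside))
  idx <- cbind(row[inside], col[inside])
  in_loss[inside] <- change$codes[idx] == 1L
  list(fraction = mean(in_loss[inside]),
       n_inside = sum(inside), n_outside = sum(!inside),
       labels = tibble::tibble(x = points$x, y = points$y,
                               inside = inside, in_loss = in_loss))
}

#' Change arithmetic table from an area series
#'
#' The tabular core of the regional report: given a matrix of forest areas
#' (regions x epochs), computes for every consecutive epoch pair plus the
#' first-to-last pair the signed change, percent change and compound annual
#' rate. Usable directly on published area tables, without rasters.
#'
#' @param areas Numeric matrix, rows = regions (rownames used as labels),
#'   columns = epochs.
#' @param years Integer vector of epoch years, one per column.
#' @return Tibble: `region`, `area_<year>_km2` columns, then for each pair
#'   `change_<y1>_<y2>_km2`, `pct_change_<y1>_<y2>`, `annual_rate_<y1>_<y2>`.
#' @export
area_change_table <- function(areas, years) {
  areas <- as.matrix(areas)
  if (ncol(areas) != length(years)) stop("one year per area column", call. = FALSE)
  if (is.null(rownames(areas))) rownames(areas) <- paste0("region_", seq_len(nrow(areas)))
  out <- tibble::tibble(region = rownames(areas))
  for (j in seq_along(years))
    out[[sprintf("area_%d_km2", years[j])]] <- unname(areas[, j])
  pairs <- epoch_pairs(years)
  for (p in pairs) {
    i <- p[1]; j <- p[2]
    tag <- sprintf("%d_%d", years[i], years[j])
    out[[paste0("change_", tag, "_km2")]] <- unname(areas[, j] - areas[, i])
    out[[paste0("pct_change_", tag)]] <-
      unname(suppressWarnings(percent_change(areas[, i], areas[, j])))
    out[[paste0("annual_rate_", tag)]] <-
      unname(suppressWarnings(annual_rate(areas[, i], pmax(areas[, j], 0),
                                          years[i], years[j])))
  }
  out
}

# all consecutive pairs plus (first, last)
epoch_pairs <- function(years) {
  n <- length(years)
  pairs <- lapply(seq_len(n - 1), function(i) c(i, i + 1))
  if (n > 2) pairs <- c(pairs, list(c(1L, n)))
  pairs
}

#' Regional report: areas, change arithmetic and class areas by region
#'
#' For each region and epoch: forest area and share of the landscape total;
#' change, percent change and annual rate for every consecutive and overall
#' epoch pair; fragmentation class areas per epoch; and per-class
#' first-to-last change. Regions are given either as a [make_grid()] result
#' (each cell a region) or as an integer matrix of region ids aligned with
#' the rasters (0/NA = outside all regions); `NULL` treats the whole
#' landscape as one region.
#'
#' @param series A [landscape_series()].
#' @param regions `NULL`, a `grid_set`, or an integer matrix of region ids.
#' @param params [frag_params()] for the per-epoch classification.
#' @return List of tibbles: `area_change` (per region, with a `total` row),
#'   `share` (region x epoch share of total, percent), `class_area`
#'   (region x epoch x class, km^2) and `class_change` (per region and class,
#'   first vs last epoch).
#' @export
regional_report <- function(series, regions = NULL, params = frag_params()) {
  stopifnot(inherits(series, "landscape_series"))
  years <- epoch_years(series)
  template <- series[[1]]
  if (is.null(regions)) {
    regmat <- matrix(1L, nrow(template$values), ncol(template$values))
    regnames <- "all"
  } else if (inherits(regions, "grid_set")) {
    regmat <- grid_cell_of_pixels(template, regions)
    regnames <- paste0("cell_", regions$id)
  } else if (is.matrix(regions)) {
    if (!identical(dim(regions), dim(template$values)))
      stop("region matrix must match the raster dimensions", call. = FALSE)
    regmat <- regions
    regmat[is.na(regmat)] <- 0L
    storage.mode(regmat) <- "integer"
    ids <- sort(unique(regmat[regmat > 0L]))
    regnames <- paste0("region_", ids)
    # compact ids to 1..K
    lut <- integer(max(ids)); lut[ids] <- seq_along(ids)
    regmat[regmat > 0L] <- lut[regmat[regmat > 0L]]
  } else stop("`regions` must be NULL, a grid_set or an id matrix", call. = FALSE)
  nreg <- length(regnames)
  px_km2 <- template$pixel_size^2 / 1e6

  areas <- vapply(series, function(ep) {
    f <- ep$values == 1L; f[is.na(f)] <- FALSE
    tabulate(regmat[f], nbins = nreg) * px_km2
  }, numeric(nreg))
  areas <- matrix(areas, nrow = nreg, dimnames = list(regnames, NULL))
  with_total <- rbind(areas, total = colSums(areas))
  area_change <- area_change_table(with_total, years)

  share <- tibble::tibble(region = regnames)
  for (j in seq_along(years))
    share[[sprintf("share_%d_pct", years[j])]] <-
      100 * areas[, j] / sum(areas[, j])

  maps <- lapply(series, classify_fragmentation, params = params)
  lev <- frag_class_names()[-1]
  class_area <- do.call(rbind, lapply(seq_along(maps), function(j) {
    cl <- maps[[j]]$classes
    do.call(rbind, lapply(seq_len(nreg), function(g) {
      sel <- regmat == g
      cnt <- tabulate(cl[sel] + 1L, nbins = 7L)[-1]
      tibble::tibble(region = regnames[g], year = years[j], class = lev,
                     area_km2 = cnt * px_km2)
    }))
  }))
  first <- class_area[class_area$year == years[1], ]
  last <- class_area[class_area$year == years[length(years)], ]
  key <- match(paste(first$region, first$class), paste(last$region, last$class))
  class_change <- tibble::tibble(
    region = first$region, class = first$class,
    area_first_km2 = first$area_km2, area_last_km2 = last$area_km2[key])
  class_change$change_km2 <- class_change$area_last_km2 - class_change$area_first_km2
  class_change$pct_change <- suppressWarnings(
    percent_change(class_change$area_first_km2, class_change$area_last_km2))

  list(area_change = area_change, share = share,
       class_area = class_area, class_change = class_change)
}
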