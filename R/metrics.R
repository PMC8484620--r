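#' Extract forest patches with raster areas and perimeters
#'
#' Patches are connected forest components. A patch's perimeter is the number
#' of pixel faces adjacent to non-forest (or to the grid boundary, when
#' `boundary_policy = "outside_is_nonforest"`) times the pixel size. Nodata
#' counts as non-forest.
#'
#' @param landscape A [binary_landscape()].
#' @param connectivity 4 or 8 (default 8).
#' @param boundary_policy Whether the world beyond the grid is non-forest
#'   (grid-boundary faces count toward perimeter) or forest (they do not).
#' @return A `patch_table`: tibble with `id`, `pixels`, `area_m2`,
#'   `perimeter_m`, carrying `pixel_size` and `landscape_area_km2` attributes.
#' @export
extract_patches <- function(landscape, connectivity = 8,
                            boundary_policy = c("outside_is_nonforest",
                                                "outside_is_forest")) {
  stopifnot(inherits(landscape, "binary_landscape"))
  boundary_policy <- match.arg(boundary_policy)
  ps <- landscape$pixel_size
  forest <- landscape$values == 1L
  forest[is.na(forest)] <- FALSE
  lc <- label_components(forest, connectivity)
  nr <- nrow(forest); nc <- ncol(forest)
  if (lc$n == 0L) {
    out <- tibble::tibble(id = integer(0), pixels = integer(0),
                          area_m2 = numeric(0), perimeter_m = numeric(0))
  } else {
    # exposed faces per cell: pad with 0 (outside non-forest) or 1 (forest)
    fill <- if (boundary_policy == "outside_is_nonforest") 0 else 1
    pad <- matrix(fill, nr + 2L, nc + 2L)
    pad[2:(nr + 1L), 2:(nc + 1L)] <- as.numeric(forest)
    rows <- 2:(nr + 1L); cols <- 2:(nc + 1L)
    exposed <- (1 - pad[rows - 1L, cols, drop = FALSE]) +
      (1 - pad[rows + 1L, cols, drop = FALSE]) +
      (1 - pad[rows, cols - 1L, drop = FALSE]) +
      (1 - pad[rows, cols + 1L, drop = FALSE])
    per <- vapply(split(exposed[forest], lc$labels[forest]), sum, numeric(1))
    per <- per[order(as.integer(names(per)))]
    out <- tibble::tibble(id = seq_len(lc$n),
                          pixels = lc$sizes,
                          area_m2 = lc$sizes * ps^2,
                          perimeter_m = as.numeric(per) * ps)
  }
  attr(out, "pixel_size") <- ps
  attr(out, "landscape_area_km2") <- nr * nc * ps^2 / 1e6
  class(out) <- c("patch_table", class(out))
  out
}

#' Landscape-level metric suite from a patch table
#'
#' The Patch-Analyst-style suite: number of patches (NumP), mean patch size
#' (MPS, km^2), patch-size standard deviation (PSSD, km^2, population
#' estimator), edge density (ED, m/km^2, denominator = total landscape area),
#' mean patch edge (MPE, m), mean shape index (MSI), mean perimeter-area ratio
#' (MPAR, m/ha) and mean patch fractal dimension (MPFD).
#'
#' By default the raster-adjusted shape formulas are used
#' (`MSI = mean(0.25 p / sqrt(a))`, `MPFD = mean(2 ln(0.25 p) / ln a)`, with
#' `p` in m and `a` in m^2), under which a perfect pixel square scores exactly
#' 1 on both. `formulas = "vector"` switches to the planimetric forms
#' `p / (2 sqrt(pi a))` and `2 ln p / ln a`.
#'
#' @param patches A [extract_patches()] result.
#' @param landscape_area_km2 Total landscape area (default: taken from the
#'   patch table's attribute).
#' @param formulas `"raster"` (default) or `"vector"`.
#' @return One-row tibble with columns `NumP`, `MPS_km2`, `PSSD_km2`,
#'   `ED_m_per_km2`, `MPE_m`, `MSI`, `MPAR_m_per_ha`, `MPFD`. With zero
#'   patches, ratio metrics are `NA`.
#' @export
landscape_metrics <- function(patches,
                              landscape_area_km2 = attr(patches, "landscape_area_km2"),
                              formulas = c("raster", "vector")) {
  stopifnot(inherits(patches, "patch_table"))
  formulas <- match.arg(formulas)
  if (is.null(landscape_area_km2) || !(landscape_area_km2 > 0))
    stop("`landscape_area_km2` must be positive", call. = FALSE)
  n <- nrow(patches)
  if (n == 0L) {
    return(tibble::tibble(NumP = 0L, MPS_km2 = NA_real_, PSSD_km2 = NA_real_,
                          ED_m_per_km2 = NA_real_, MPE_m = NA_real_,
                          MSI = NA_real_, MPAR_m_per_ha = NA_real_,
                          MPFD = NA_real_))
  }
  a <- patches$area_m2; p <- patches$perimeter_m
  a_km2 <- a / 1e6
  E <- sum(p)
  if (formulas == "raster") {
    msi <- mean(0.25 * p / sqrt(a))
    mpfd <- mean(2 * log(0.25 * p) / log(a))
  } else {
    msi <- mean(p / (2 * sqrt(pi * a)))
    mpfd <- mean(2 * log(p) / log(a))
  }
  tibble::tibble(
    NumP = n,
    MPS_km2 = mean(a_km2),
    PSSD_km2 = sqrt(mean((a_km2 - mean(a_km2))^2)),
    ED_m_per_km2 = E / landscape_area_km2,
    MPE_m = E / n,
    MSI = msi,
    MPAR_m_per_ha = mean(p / a) * 1e4,
    MPFD = mpfd)
}

#' Metric suite straight from a landscape
#'
#' Convenience wrapper: [extract_patches()] then [landscape_metrics()].
#'
#' @inheritParams extract_patches
#' @inheritParams landscape_metrics
#' @return See [landscape_metrics()]; an `epoch` column is prepended.
#' @export
landscape_metrics_of <- function(landscape, connectivity = 8,
                                 boundary_policy = "outside_is_nonforest",
                                 formulas = "raster") {
  m <- landscape_metrics(extract_patches(landscape, connectivity, boundary_policy),
                         formulas = formulas)
  tibble::tibble(epoch = landscape$epoch_year, m)
}
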