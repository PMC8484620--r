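#' Published CTML forest-cover and fragmentation tables
#'
#' Curated copies of the published regional forest-cover statistics for the
#' Chure Terai Madhesh Landscape (Nepal's elephant range), 1930-2020: forest
#' area by region and epoch, fragmentation-class area by epoch, the published
#' percent-change and compound-annual-rate figures, and the regional
#' class-area endpoints for 1930 vs 2020. These drive the change-arithmetic
#' reproduction tests and the worked examples; the raster maps behind them
#' were never deposited, so only the printed tabular values are carried.
#'
#' The published regional tables use a mixed sign convention (losses printed
#' as positive magnitudes in some columns), so percent-change columns here
#' store printed magnitudes (`*_abs`) where that convention applies. The
#' published 2000-2020 regional percent column is computed relative to the
#' 2020 area rather than the 2000 area; the `pct_basis` column (`"initial"` /
#' `"final"`) records the denominator epoch of each printed value.
#'
#' @param name One of `"forest_area"`, `"forest_change_published"`,
#'   `"class_area"`, `"class_change_published"`,
#'   `"region_class_1930_2020"`.
#' @return A tibble.
#' @export
ctml_table <- function(name = c("forest_area", "forest_change_published",
                                "class_area", "class_change_published",
                                "region_class_1930_2020")) {
  name <- match.arg(name)
  file <- switch(name,
    forest_area = "ctml_forest_area_km2.csv",
    forest_change_published = "ctml_forest_change_published.csv",
    class_area = "ctml_class_area_km2.csv",
    class_change_published = "ctml_class_change_published.csv",
    region_class_1930_2020 = "ctml_region_class_1930_2020.csv")
  path <- system.file("extdata", file, package = "fragtrack", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
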