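test_that("forest area derives from cell counts and pixel size", {
  v <- matrix(0L, 10, 10)
  v[sample(100, 40)] <- 1L
  l <- binary_landscape(v, 30)
  expect_equal(forest_area_km2(l), 0.036)
  expect_equal(forest_area_km2(binary_landscape(matrix(NA_integer_, 3, 3), 30)), 0)
})

test_that("landscape construction validates states, size and pixel size", {
  expect_error(binary_landscape(matrix(2L, 2, 2), 30), "0.*1.*NA")
  expect_error(binary_landscape(matrix(1L, 2, 2), -1), "positive")
  expect_error(binary_landscape(matrix(integer(0), 0, 0), 30), "at least one")
})

test_that("raster write/read round trip preserves all three cell states", {
  l <- random_landscape(23, 31, 0.4, seed = 11)
  l$values[c(5, 50, 200)] <- NA_integer_
  path <- withr::local_tempfile(fileext = ".asc")
  write_binary_raster(l, path)
  back <- read_binary_raster(path, forest_codes = 1L, epoch_year = 1930L)
  expect_identical(back$values, l$values)
  expect_equal(back$pixel_size, l$pixel_size)
  expect_equal(back$origin, l$origin)
  expect_equal(back$crs_id, l$crs_id)
})

test_that("forest codes map onto forest, nodata to NA, the rest to non-forest", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 3", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 30", "NODATA_value -9999",
               "5 7 0", "-9999 5 2"), path)
  l <- read_binary_raster(path, forest_codes = c(5L, 7L))
  expect_identical(l$values, matrix(c(1L, NA, 1L, 1L, 0L, 0L), 2, 3))
})

test_that("degenerate and malformed rasters are reported explicitly", {
  expect_error(read_binary_raster("no/such/file.asc"), "not found")
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 1", "xllcorner 0", "yllcorner 0",
               "cellsize 30", "NODATA_value -9999", "-9999 -9999"), path)
  expect_warning(read_binary_raster(path), "entirely nodata")
  writeLines(c("ncols 2", "nrows 1", "xllcorner 0", "yllcorner 0",
               "dx 30", "dy 31", "NODATA_value -9999", "0 1"), path)
  expect_error(read_binary_raster(path), "non-square")
})

test_that("class raster round trip preserves class counts", {
  l <- random_landscape(30, 30, 0.55, seed = 3)
  m <- classify_fragmentation(l, frag_params(edge_width = 60))
  path <- withr::local_tempfile(fileext = ".asc")
  write_class_raster(m, path)
  back <- read_class_raster(path)
  expect_identical(tabulate(back$classes + 1L, 7), tabulate(m$classes + 1L, 7))
  expect_equal(back$params$edge_width, m$params$edge_width)
})

test_that("minimum mapping unit removes sub-threshold patches", {
  v <- matrix(0L, 20, 20)
  v[3, 3:7] <- 1L                       # 5 px = 4500 m2 < 0.5 ha
  v[10:16, 10:16] <- 1L                 # 49 px, kept
  l <- binary_landscape(v, 30)
  out <- apply_mmu(l, 5000)
  expect_equal(sum(out$values == 1L), 49)
  expect_identical(apply_mmu(l, 0)$values, v)
})

test_that("minimum mapping unit matches patch enumeration and is idempotent", {
  for (seed in 1:5) {
    l <- random_landscape(25, 25, 0.35, seed = seed)
    out <- apply_mmu(l, 5000)
    lab <- flood_fill_label(l$values == 1L, 8)
    keep <- 0
    if (max(lab) > 0) for (id in seq_len(max(lab))) {
      n <- sum(lab == id)
      if (n * 900 >= 5000) keep <- keep + n
    }
    expect_equal(sum(out$values == 1L), keep)
    expect_identical(apply_mmu(out, 5000)$values, out$values)
  }
})

test_that("nearest-neighbour resampling preserves extent and aggregates blocks", {
  l <- random_landscape(10, 10, 0.5, seed = 2)
  expect_identical(resample_to(l, 30)$values, l$values)

  v <- matrix(0L, 4, 4); v[1:2, 1:2] <- 1L
  l2 <- binary_landscape(v, 30)
  out <- resample_to(l2, 60)
  expect_identical(dim(out$values), c(2L, 2L))
  expect_equal(sum(out$values == 1L), 1)
  expect_equal(forest_area_km2(out), forest_area_km2(l2))

  cb <- binary_landscape(outer(1:8, 1:8, function(r, c) (r + c) %% 2L), 30)
  out1 <- resample_to(cb, 60)
  out2 <- resample_to(cb, 60)
  expect_identical(out1$values, out2$values)
  frac <- mean(out1$values)
  expect_gte(frac, 0); expect_lte(frac, 1)
  expect_error(resample_to(l, 30 * 101), "factor")
})

test_that("analysis grids tile the extent exactly", {
  l <- binary_landscape(matrix(1L, 100, 100), 100)  # 10 x 10 km
  g <- make_grid(l, 5000)
  expect_equal(nrow(g), 4)
  expect_equal(sum(g$area_m2), 1e8, tolerance = 1e-8)

  l2 <- binary_landscape(matrix(1L, 70, 120), 100)  # 12 km wide x 7 km tall
  g2 <- make_grid(l2, 5000)
  expect_equal(nrow(g2), 3 * 2)
  expect_equal(max(g2$xmax), 12000)
  expect_equal(min(g2$ymin), 0)
  expect_true(any(g2$xmax - g2$xmin < 5000) && any(g2$ymax - g2$ymin < 5000))
  expect_equal(sum(g2$area_m2), 12000 * 7000, tolerance = 1)
  expect_error(make_grid(l, 50), "at least the pixel size")
})

test_that("series construction enforces alignment and increasing years", {
  a <- random_landscape(10, 10, 0.5, seed = 1, year = 1930L)
  b <- random_landscape(10, 10, 0.4, seed = 2, year = 1975L)
  s <- landscape_series(a, b)
  expect_equal(epoch_years(s), c(1930L, 1975L))
  b$epoch_year <- 1920L
  expect_error(landscape_series(a, b), "strictly increasing")
  d <- random_landscape(11, 10, 0.4, seed = 2, year = 1975L)
  expect_error(landscape_series(a, d), "aligned")
})
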