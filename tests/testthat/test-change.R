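test_that("percent change and compound rate reproduce the benchmark arithmetic", {
  expect_equal(round(percent_change(24315.56, 19069.14), 2), -21.58)
  expect_equal(round(percent_change(42.18, 509.25), 2), 1107.33)
  expect_equal(percent_change(123.4, 123.4), 0)
  expect_warning(expect_true(is.na(percent_change(0, 5))), "undefined")

  expect_equal(round(annual_rate(24315.56, 19069.14, 1930, 2020), 2), -0.27)
  expect_equal(round(annual_rate(24315.56, 21320.92, 1930, 1975), 2), -0.29)
  expect_equal(annual_rate(50, 100, 0, 10), 100 * log(2) / 10)
  expect_warning(r0 <- annual_rate(10, 0, 2000, 2020), "-Inf")
  expect_equal(r0, -Inf)
  expect_error(annual_rate(10, 5, 2020, 2000), "exceed")
})

test_that("percent change and rate agree in sign and compound consistently", {
  set.seed(1)
  a1 <- runif(50, 1, 1000); a2 <- runif(50, 1, 1000)
  pc <- percent_change(a1, a2)
  ar <- annual_rate(a1, a2, 0, 10)
  expect_true(all(sign(pc) == sign(ar)))
  expect_equal(annual_rate(77, 77, 1930, 2020), 0)
  for (r in c(-1, -0.27, 0.5)) {
    dt <- 90
    a2 <- 1000 * exp(r * dt / 100)
    expect_equal(percent_change(1000, a2), 100 * (exp(r * dt / 100) - 1))
    expect_equal(annual_rate(1000, a2, 0, dt), r)
  }
})

test_that("change maps tally the 2x2 transition exactly", {
  a <- random_landscape(25, 25, 0.5, seed = 21, year = 1930L)
  expect_equal(sum(change_map(a, a)$codes %in% 1:2), 0)

  cleared <- binary_landscape(matrix(0L, 25, 25), 30, epoch_year = 2020L)
  cm <- change_map(a, cleared)
  expect_equal(sum(cm$codes == 1L) * 900 / 1e6, forest_area_km2(a))

  b <- random_landscape(25, 25, 0.45, seed = 22, year = 2020L)
  cm2 <- change_map(a, b)
  f1 <- a$values == 1L; f2 <- b$values == 1L
  tab <- table(f1, f2)
  expect_equal(sum(cm2$codes == 1L), tab["TRUE", "FALSE"])
  expect_equal(sum(cm2$codes == 2L), tab["FALSE", "TRUE"])
  expect_equal(sum(cm2$codes == 3L), tab["TRUE", "TRUE"])
  # conservation: loss + stable forest = epoch-1 forest
  s <- change_area_summary(cm2)
  expect_equal(s$area_km2[s$category == "loss"] +
                 s$area_km2[s$category == "stable_forest"], forest_area_km2(a))

  misaligned <- binary_landscape(b$values, 30, origin = c(10, 10), epoch_year = 2020L)
  expect_error(change_map(a, misaligned), "aligned")
})

test_that("grid summaries categorise cells and preserve total areas", {
  a <- random_landscape(40, 40, 0.5, seed = 30, year = 1930L)
  cleared <- binary_landscape(matrix(0L, 40, 40), 30, epoch_year = 2020L)
  g <- make_grid(a, 300)
  s <- landscape_series(a, cleared)
  gt <- grid_change_summary(s, g)
  had <- gt$area_1930_km2 > 0
  expect_true(all(gt$category[had] == "complete_loss"))
  expect_true(all(gt$category[!had] == "stable"))
  expect_true(all(gt$annual_rate[had] == -Inf))

  same <- landscape_series(a, binary_landscape(a$values, 30, epoch_year = 2020L))
  expect_true(all(grid_change_summary(same, g)$category == "stable"))

  b <- random_landscape(40, 40, 0.4, seed = 31, year = 2020L)
  gt2 <- grid_change_summary(landscape_series(a, b), g)
  expect_equal(sum(gt2$area_1930_km2), forest_area_km2(a))
  expect_equal(sum(gt2$area_2020_km2), forest_area_km2(b))
})

test_that("class cross-tabulation conserves marginals exactly", {
  a <- random_landscape(30, 30, 0.6, seed = 40, year = 1930L)
  set.seed(43)
  b <- binary_landscape(ifelse(matrix(runif(900), 30, 30) < 0.9, a$values, 0L),
                        30, epoch_year = 2020L)
  p <- frag_params(edge_width = 60)
  m1 <- classify_fragmentation(a, p); m2 <- classify_fragmentation(b, p)
  xt <- crosstab(m1, m2)
  expect_equal(dim(xt), c(7, 7))
  s1 <- class_area_summary(m1); s2 <- class_area_summary(m2)
  expect_equal(unname(rowSums(xt)), s1$area_km2)
  expect_equal(unname(colSums(xt)), s2$area_km2)
  expect_equal(sum(xt), 30 * 30 * 900 / 1e6)

  xt_same <- crosstab(m1, m1)
  expect_equal(sum(xt_same) - sum(diag(xt_same)), 0)

  m3 <- classify_fragmentation(b, frag_params(edge_width = 90))
  expect_error(crosstab(m1, m3), "different parameters")
})

test_that("point overlays report loss fractions and out-of-extent points", {
  a <- random_landscape(20, 20, 0.6, seed = 50, year = 1930L)
  b <- random_landscape(20, 20, 0.4, seed = 51, year = 2020L)
  cm <- change_map(a, b)
  loss <- which(cm$codes == 1L, arr.ind = TRUE)
  xy_loss <- cbind(cm$origin[1] + (loss[, 2] - 0.5) * 30,
                   cm$origin[2] - (loss[, 1] - 0.5) * 30)
  pts <- point_set(xy_loss[, 1], xy_loss[, 2])
  expect_equal(points_in_loss(pts, cm)$fraction, 1.0)

  keep <- which(cm$codes != 1L, arr.ind = TRUE)
  pts0 <- point_set(cm$origin[1] + (keep[, 2] - 0.5) * 30,
                    cm$origin[2] - (keep[, 1] - 0.5) * 30)
  expect_equal(points_in_loss(pts0, cm)$fraction, 0.0)

  mixed <- point_set(c(xy_loss[1, 1], 1e6), c(xy_loss[1, 2], 1e6))
  ov <- points_in_loss(mixed, cm)
  expect_equal(ov$n_outside, 1)
  expect_equal(nrow(ov$labels), 2)
  expect_true(is.na(ov$labels$in_loss[2]))
  far <- point_set(1e6, 1e6)
  expect_error(points_in_loss(far, cm), "inside")
})

test_that("area change tables are additive over regions and zero under identity", {
  areas <- matrix(c(10, 10, 10), 1, 3, dimnames = list("all", NULL))
  t1 <- area_change_table(areas, c(1930, 1975, 2020))
  expect_true(all(unlist(t1[grep("change|rate", names(t1))]) == 0))

  a <- random_landscape(30, 30, 0.5, seed = 60, year = 1930L)
  b <- random_landscape(30, 30, 0.4, seed = 61, year = 2020L)
  s <- landscape_series(a, b)
  regions <- matrix(1L, 30, 30); regions[, 16:30] <- 2L
  rep <- regional_report(s, regions, frag_params(edge_width = 60))
  ac <- rep$area_change
  expect_equal(ac$area_1930_km2[ac$region == "total"],
               sum(ac$area_1930_km2[ac$region != "total"]))
  expect_equal(ac$area_2020_km2[ac$region == "total"], forest_area_km2(b))
  expect_equal(sum(rep$share$share_1930_pct), 100)
  # class areas by region sum to the landscape class summary
  cls <- rep$class_area
  m <- classify_fragmentation(a, frag_params(edge_width = 60))
  s1 <- class_area_summary(m)
  for (cn in unique(cls$class)) {
    expect_equal(sum(cls$area_km2[cls$class == cn & cls$year == 1930]),
                 s1$area_km2[s1$class == cn], label = cn)
  }
})
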