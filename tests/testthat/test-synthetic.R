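test_that("generated landscapes hit the requested cover fraction exactly", {
  cfg <- simulation_config(rows = 50, cols = 50, forest_fraction = 1, seed = 1)
  expect_true(all(generate_landscape(cfg)$values == 1L))
  cfg0 <- simulation_config(rows = 50, cols = 50, forest_fraction = 0, seed = 1)
  expect_true(all(generate_landscape(cfg0)$values == 0L))

  cfg5 <- simulation_config(rows = 200, cols = 200, forest_fraction = 0.5, seed = 9)
  expect_equal(sum(generate_landscape(cfg5)$values == 1L), 20000)
  expect_error(simulation_config(forest_fraction = 1.2), "forest_fraction")
})

test_that("identical configurations reproduce bit-identical output", {
  cfg <- simulation_config(rows = 80, cols = 80, forest_fraction = 0.5,
                           clumpiness = 3, annual_rate = -0.3,
                           epoch_years = c(1930L, 1975L, 2020L), seed = 42)
  s1 <- simulate_deforestation(generate_landscape(cfg), cfg)
  s2 <- simulate_deforestation(generate_landscape(cfg), cfg)
  for (i in seq_along(s1))
    expect_identical(s1[[i]]$values, s2[[i]]$values)

  cm <- change_map(s1[[1]], s1[[3]])
  p1 <- simulate_conflict_points(cm, conflict_config(200, 0.6, seed = 5))
  p2 <- simulate_conflict_points(cm, conflict_config(200, 0.6, seed = 5))
  expect_identical(p1$x, p2$x)
  expect_identical(p1$y, p2$y)
})

test_that("clumpiness lowers edge density at fixed cover", {
  lower <- 0L
  for (seed in 1:20) {
    base <- list(rows = 100, cols = 100, forest_fraction = 0.5, seed = seed)
    ed <- sapply(c(0, 3), function(cl) {
      l <- generate_landscape(do.call(simulation_config, c(base, clumpiness = cl)))
      landscape_metrics(extract_patches(l))$ED_m_per_km2
    })
    if (ed[2] < ed[1]) lower <- lower + 1L
  }
  expect_equal(lower, 20L)
})

test_that("zero rate leaves every epoch untouched; loss is monotone", {
  cfg <- simulation_config(rows = 60, cols = 60, annual_rate = 0, seed = 3)
  s <- simulate_deforestation(generate_landscape(cfg), cfg)
  for (ep in s) expect_identical(ep$values, s[[1]]$values)

  cfg2 <- simulation_config(rows = 60, cols = 60, annual_rate = -1, seed = 3)
  s2 <- simulate_deforestation(generate_landscape(cfg2), cfg2)
  for (i in 2:length(s2)) {
    gained <- s2[[i]]$values == 1L & s2[[i - 1]]$values == 0L
    expect_equal(sum(gained), 0)
  }
  expect_error(simulate_deforestation(generate_landscape(cfg2),
                                      do.call(simulation_config,
                                              modifyList(unclass(cfg2),
                                                         list(annual_rate = 1)))),
               "<= 0")
})

test_that("a drastic rate empties the landscape with a warning, not an error", {
  cfg <- simulation_config(rows = 10, cols = 10, forest_fraction = 0.3,
                           annual_rate = -99.9,
                           epoch_years = c(2000L, 2020L), seed = 2)
  expect_warning(s <- simulate_deforestation(generate_landscape(cfg), cfg),
                 "stopping at zero")
  expect_equal(sum(s[[2]]$values == 1L), 0)
})

test_that("the rate estimator recovers the configured compound rate", {
  cfg <- simulation_config(rows = 200, cols = 200, forest_fraction = 0.5,
                           annual_rate = -0.27, seed = 8)
  s <- simulate_deforestation(generate_landscape(cfg), cfg)
  r_hat <- annual_rate(forest_area_km2(s[[1]]), forest_area_km2(s[[4]]),
                       1930, 2020)
  expect_lt(abs(r_hat - (-0.27)), 0.02)
})

test_that("edge-biased clearing preserves more core forest at equal loss", {
  core_of <- function(edge_bias, seed) {
    cfg <- simulation_config(rows = 150, cols = 150, forest_fraction = 0.6,
                             clumpiness = 4, annual_rate = -1,
                             epoch_years = c(1930L, 1950L),
                             edge_bias = edge_bias, seed = seed)
    s <- simulate_deforestation(generate_landscape(cfg), cfg)
    se <- class_area_summary(classify_fragmentation(s[[length(s)]]))
    c(forest = forest_area_km2(s[[length(s)]]),
      core = sum(se$area_km2[se$class %in% c("core1", "core2", "core3")]))
  }
  for (seed in 1:3) {
    biased <- core_of(5, seed); random <- core_of(0, seed)
    expect_equal(biased[["forest"]], random[["forest"]])  # removal counts deterministic
    expect_gt(biased[["core"]], random[["core"]])
  }
})

test_that("conflict points obey the loss-placement probability", {
  cfg <- simulation_config(rows = 80, cols = 80, forest_fraction = 0.5,
                           annual_rate = -0.3, seed = 12)
  s <- simulate_deforestation(generate_landscape(cfg), cfg)
  cm <- change_map(s[[1]], s[[length(s)]])

  f1 <- points_in_loss(simulate_conflict_points(cm, conflict_config(300, 1, 7)), cm)
  expect_equal(f1$fraction, 1.0)
  f0 <- points_in_loss(simulate_conflict_points(cm, conflict_config(300, 0, 7)), cm)
  expect_equal(f0$fraction, 0.0)

  no_loss <- change_map(s[[1]], s[[1]])
  expect_error(simulate_conflict_points(no_loss, conflict_config(10, 0.5, 1)),
               "no loss pixels")
})
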