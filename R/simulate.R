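# Run code under a private, seeded RNG stream, restoring the caller's state.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simulation configuration for synthetic deforestation series
#'
#' Defines the study conditions the simulator emulates: a clumped initial
#' forest landscape that loses cover over decades at a target compound annual
#' rate, with clearing optionally biased toward existing forest edges. The
#' defaults mirror a 90-year observation window (epochs 1930, 1975, 2000,
#' 2020) at 30 m resolution with an overall loss rate of -0.27 %/yr.
#'
#' @param rows,cols Grid dimensions.
#' @param pixel_size Pixel size, metres (default 30).
#' @param forest_fraction Initial forest cover fraction in `[0, 1]`.
#' @param clumpiness Spectral power-law decay exponent (>= 0); 0 gives white
#'   noise, larger values give larger coherent forest blocks.
#' @param annual_rate Target compound rate, signed percent per year
#'   (loss negative; default -0.27).
#' @param epoch_years Strictly increasing years at which snapshots are taken.
#' @param edge_bias >= 0; 0 clears spatially at random, larger values
#'   concentrate clearing near forest/non-forest edges.
#' @param seed Integer RNG seed; identical configs reproduce bit-identical
#'   output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(rows = 500, cols = 500, pixel_size = 30,
                              forest_fraction = 0.5, clumpiness = 3,
                              annual_rate = -0.27,
                              epoch_years = c(1930L, 1975L, 2000L, 2020L),
                              edge_bias = 0, seed = 1L) {
  if (forest_fraction < 0 || forest_fraction > 1)
    stop("`forest_fraction` must be in [0, 1]", call. = FALSE)
  if (any(diff(epoch_years) <= 0))
    stop("`epoch_years` must be strictly increasing", call. = FALSE)
  if (clumpiness < 0 || edge_bias < 0)
    stop("`clumpiness` and `edge_bias` must be >= 0", call. = FALSE)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 pixel_size = pixel_size, forest_fraction = forest_fraction,
                 clumpiness = clumpiness, annual_rate = annual_rate,
                 epoch_years = as.integer(epoch_years),
                 edge_bias = edge_bias, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a clumped neutral binary landscape
#'
#' Spectral synthesis: a Gaussian random field is built by inverse FFT of
#' white noise shaped with a radial power-law amplitude filter
#' (power spectrum ~ f^-clumpiness), then thresholded at the empirical
#' quantile so that exactly `round(n * forest_fraction)` cells (up to ties,
#' which have probability zero for a continuous field) become forest.
#'
#' @param config A [simulation_config()].
#' @return A [binary_landscape()] labelled with the first epoch year.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  nr <- config$rows; nc <- config$cols
  n <- nr * nc
  k <- as.integer(round(n * config$forest_fraction))
  v <- matrix(0L, nr, nc)
  if (k > 0L) {
    field <- local_seed(config$seed, {
      z <- matrix(stats::rnorm(n), nr, nc)
      if (config$clumpiness > 0) {
        fr <- fft_freq(nr); fc <- fft_freq(nc)
        f <- sqrt(outer(fr^2, fc^2, `+`))
        amp <- f^(-config$clumpiness / 2)
        amp[1, 1] <- 0
        Re(stats::fft(stats::fft(z) * amp, inverse = TRUE)) / n
      } else z
    })
    if (k < n) {
      v[order(field, decreasing = TRUE)[seq_len(k)]] <- 1L
    } else v[] <- 1L
  }
  binary_landscape(v, config$pixel_size,
                   origin = c(0, nr * config$pixel_size),
                   crs_id = "synthetic",
                   epoch_year = config$epoch_years[1])
}

fft_freq <- function(n) {
  c(seq_len(ceiling(n / 2)) - 1L, -rev(seq_len(floor(n / 2)))) / n
}

#' Simulate decades of edge-biased deforestation
#'
#' Year by year, removes exactly `round(A (1 - exp(r / 100)))` forest cells
#' (`A` = current forest count, `r` = `annual_rate`), so the realised
#' compound rate matches the target up to rounding; only *which* cells go is
#' random. Cells are drawn without replacement with probability proportional
#' to `exp(edge_bias / (1 + d))`, `d` the current pixel distance to
#' non-forest (recomputed each simulated year). Snapshots are emitted at
#' `epoch_years`.
#'
#' @param initial A [binary_landscape()] with at least one forest cell
#'   (typically [generate_landscape()] output).
#' @param config A [simulation_config()]; `annual_rate` must be <= 0.
#' @return A [landscape_series()] with one epoch per `epoch_years`.
#' @export
simulate_deforestation <- function(initial, config) {
  stopifnot(inherits(initial, "binary_landscape"),
            inherits(config, "simulation_config"))
  if (config$annual_rate > 0)
    stop("`annual_rate` must be <= 0 (loss scenarios only)", call. = FALSE)
  if (sum(initial$values == 1L, na.rm = TRUE) < 1L)
    stop("initial landscape has no forest", call. = FALSE)
  years <- config$epoch_years
  loss_frac <- 1 - exp(config$annual_rate / 100)
  forest <- initial$values == 1L
  forest[is.na(forest)] <- FALSE
  snapshots <- vector("list", length(years))
  make_epoch <- function(yr) {
    v <- matrix(0L, nrow(forest), ncol(forest))
    v[forest] <- 1L
    v[is.na(initial$values)] <- NA_integer_
    binary_landscape(v, initial$pixel_size, initial$origin, initial$crs_id, yr)
  }
  snapshots[[1]] <- make_epoch(years[1])
  next_snap <- 2L
  local_seed(config$seed + 1L, {
    for (yr in seq(years[1] + 1L, years[length(years)])) {
      A <- sum(forest)
      n_rm <- as.integer(round(A * loss_frac))
      if (n_rm > 0L) {
        if (n_rm >= A) {
          warning("requested removal exceeds remaining forest; stopping at zero",
                  call. = FALSE)
          n_rm <- A
        }
        cells <- which(forest)
        if (config$edge_bias > 0) {
          d <- edt_pixels(forest, pad_nonforest = TRUE)
          w <- exp(config$edge_bias / (1 + d[cells]))
        } else w <- rep(1, length(cells))
        rm_idx <- cells[sample.int(length(cells), n_rm, prob = w)]
        forest[rm_idx] <- FALSE
      }
      if (next_snap <= length(years) && yr == years[next_snap]) {
        snapshots[[next_snap]] <- make_epoch(yr)
        next_snap <- next_snap + 1L
      }
    }
  })
  landscape_series(snapshots)
}

#' Conflict-point simulation configuration
#'
#' @param n_points Number of points to place.
#' @param p_in_loss Probability that a point falls in a forest-loss pixel
#'   (default 0.60, the observed share of conflict events in converted
#'   forest).
#' @param seed Integer RNG seed.
#' @return A `conflict_config` list.
#' @export
conflict_config <- function(n_points = 5000L, p_in_loss = 0.60, seed = 1L) {
  if (p_in_loss < 0 || p_in_loss > 1)
    stop("`p_in_loss` must be in [0, 1]", call. = FALSE)
  structure(list(n_points = as.integer(n_points), p_in_loss = p_in_loss,
                 seed = as.integer(seed)),
            class = "conflict_config")
}

#' Simulate conflict points concentrated in forest-loss areas
#'
#' Each point independently lands uniformly inside a randomly chosen loss
#' pixel with probability `p_in_loss`, else uniformly inside a non-loss
#' pixel.
#'
#' @param change A [change_map()] with at least one loss and one non-loss
#'   pixel.
#' @param config A [conflict_config()].
#' @return A [point_set()] with a logical `in_loss` attribute column.
#' @export
simulate_conflict_points <- function(change, config) {
  stopifnot(inherits(change, "change_map"), inherits(config, "conflict_config"))
  loss_cells <- which(change$codes == 1L)
  other_cells <- which(change$codes != 1L)
  if (length(loss_cells) == 0L && config$p_in_loss > 0)
    stop("no loss pixels: cannot place points with p_in_loss > 0", call. = FALSE)
  if (length(other_cells) == 0L && config$p_in_loss < 1)
    stop("no non-loss pixels: cannot place points with p_in_loss < 1", call. = FALSE)
  nr <- nrow(change$codes)
  ps <- change$pixel_size
  local_seed(config$seed, {
    n <- config$n_points
    in_loss <- stats::runif(n) < config$p_in_loss
    cell <- integer(n)
    if (any(in_loss))
      cell[in_loss] <- loss_cells[sample.int(length(loss_cells),
                                             sum(in_loss), replace = TRUE)]
    if (any(!in_loss))
      cell[!in_loss] <- other_cells[sample.int(length(other_cells),
                                               sum(!in_loss), replace = TRUE)]
    row <- (cell - 1L) %% nr + 1L
    col <- (cell - 1L) %/% nr + 1L
    x <- change$origin[1] + (col - 1L + stats::runif(n)) * ps
    y <- change$origin[2] - (row - 1L + stats::runif(n)) * ps
    point_set(x, y, in_loss = in_loss)
  })
}
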