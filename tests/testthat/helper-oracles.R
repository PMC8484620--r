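# Independent brute-force oracles and fixture builders. Everything here is
# deliberately naive (queue flood fills, exhaustive nearest-pixel scans) and
# shares no code with the package implementation.

# Queue-based flood fill labelling; labels follow row-major first-pixel order.
flood_fill_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  mask[is.na(mask)] <- FALSE
  lab <- matrix(0L, nr, nc)
  moves <- if (connectivity == 8) {
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
          c(1, -1), c(1, 0), c(1, 1))
  } else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  k <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (mask[r, c] && lab[r, c] == 0L) {
      k <- k + 1L
      stack <- matrix(c(r, c), ncol = 2)
      lab[r, c] <- k
      while (nrow(stack) > 0L) {
        p <- stack[nrow(stack), ]; stack <- stack[-nrow(stack), , drop = FALSE]
        for (i in seq_len(nrow(moves))) {
          rr <- p[1] + moves[i, 1]; cc <- p[2] + moves[i, 2]
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
              mask[rr, cc] && lab[rr, cc] == 0L) {
            lab[rr, cc] <- k
            stack <- rbind(stack, c(rr, cc))
          }
        }
      }
    }
  }
  lab
}

# Coordinates (row, col) of every non-forest pixel, including one ring of
# virtual outside pixels when the outside counts as non-forest.
nonforest_coords <- function(forest, pad) {
  nr <- nrow(forest); nc <- ncol(forest)
  nf <- which(!forest, arr.ind = TRUE)
  colnames(nf) <- NULL
  real <- nrow(nf)
  if (pad) {
    ring <- rbind(cbind(0L, 0:(nc + 1L)), cbind(nr + 1L, 0:(nc + 1L)),
                  cbind(seq_len(nr), 0L), cbind(seq_len(nr), nc + 1L))
    nf <- rbind(nf, ring)
  }
  list(coords = nf, n_real = real)
}

# Exhaustive squared pixel distance to the nearest non-forest pixel.
brute_d2 <- function(forest, pad = TRUE) {
  nr <- nrow(forest); nc <- ncol(forest)
  nf <- nonforest_coords(forest, pad)$coords
  d2 <- matrix(Inf, nr, nc)
  if (nrow(nf) == 0L) return(d2)
  for (r in seq_len(nr)) for (c in seq_len(nc))
    d2[r, c] <- min((nf[, 1] - r)^2 + (nf[, 2] - c)^2)
  d2
}

# Literal rule-by-rule fragmentation classifier (codes as in the package:
# 0 nonforest, 1 patch, 2 edge, 3 perforated, 4 core1, 5 core2, 6 core3).
oracle_classify <- function(values, params, pixel_size) {
  forest <- values == 1L
  forest[is.na(forest)] <- FALSE
  nr <- nrow(forest); nc <- ncol(forest)
  pad <- params$boundary_policy == "outside_is_nonforest"
  px_km2 <- pixel_size^2 / 1e6
  cl <- matrix(0L, nr, nc)
  if (!any(forest)) return(cl)

  nfo <- nonforest_coords(forest, pad)
  nf <- nfo$coords

  # holes: enclosed non-forest components within the size cap
  hl <- flood_fill_label(!forest, params$hole_connectivity)
  hole_label_ok <- logical(max(hl, 1L))
  if (max(hl) > 0L) {
    for (id in seq_len(max(hl))) {
      px <- which(hl == id, arr.ind = TRUE)
      touches <- any(px[, 1] %in% c(1L, nr)) || any(px[, 2] %in% c(1L, nc))
      hole_label_ok[id] <- !touches &&
        nrow(px) * px_km2 <= params$max_hole_area_km2
    }
  }
  # is each non-forest list entry (real or virtual) a hole pixel?
  in_hole <- rep(FALSE, nrow(nf))
  if (nfo$n_real > 0L) {
    for (i in seq_len(nfo$n_real))
      in_hole[i] <- hole_label_ok[hl[nf[i, 1], nf[i, 2]]]
  }

  core <- matrix(FALSE, nr, nc)
  perf <- matrix(FALSE, nr, nc)
  ew_px2 <- (params$edge_width / pixel_size)^2
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!forest[r, c]) next
    if (nrow(nf) == 0L) { core[r, c] <- TRUE; next }
    d2 <- (nf[, 1] - r)^2 + (nf[, 2] - c)^2
    dmin <- min(d2)
    if (dmin > ew_px2) { core[r, c] <- TRUE; next }
    nearest <- which(d2 == dmin)
    if (all(in_hole[nearest])) perf[r, c] <- TRUE  # any exterior tie -> edge
  }
  cl[forest] <- 2L
  cl[perf] <- 3L

  ct <- flood_fill_label(core, params$forest_connectivity)
  if (max(ct) > 0L) {
    for (id in seq_len(max(ct))) {
      a <- sum(ct == id) * px_km2
      code <- if (a < params$core_small_max_km2) 4L else
        if (a <= params$core_medium_max_km2) 5L else 6L
      cl[ct == id] <- code
    }
  }

  fp <- flood_fill_label(forest, params$forest_connectivity)
  for (id in seq_len(max(fp)))
    if (!any(core[fp == id])) cl[fp == id] <- 1L
  cl
}

# Exhaustive per-patch perimeter by scanning each pixel's four faces.
oracle_patch_table <- function(values, connectivity = 8, pad = TRUE,
                               pixel_size = 30) {
  forest <- values == 1L
  forest[is.na(forest)] <- FALSE
  nr <- nrow(forest); nc <- ncol(forest)
  lab <- flood_fill_label(forest, connectivity)
  k <- max(lab)
  if (k == 0L) return(data.frame(id = integer(0), pixels = integer(0),
                                 perimeter_m = numeric(0)))
  per <- numeric(k); npx <- integer(k)
  is_nf <- function(r, c) {
    if (r < 1 || r > nr || c < 1 || c > nc) return(pad)
    !forest[r, c]
  }
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!forest[r, c]) next
    id <- lab[r, c]
    npx[id] <- npx[id] + 1L
    per[id] <- per[id] + is_nf(r - 1, c) + is_nf(r + 1, c) +
      is_nf(r, c - 1) + is_nf(r, c + 1)
  }
  data.frame(id = seq_len(k), pixels = npx, perimeter_m = per * pixel_size)
}

# Random clumped fixture: smoothed noise thresholded to roughly `fraction`.
random_landscape <- function(nr, nc, fraction = 0.5, seed = 1,
                             pixel_size = 30, year = NA_integer_) {
  set.seed(seed)
  z <- matrix(rnorm(nr * nc), nr, nc)
  sm <- z
  if (nr > 2 && nc > 2) {
    sm <- z
    sm[2:(nr - 1), 2:(nc - 1)] <-
      (z[1:(nr - 2), 2:(nc - 1)] + z[3:nr, 2:(nc - 1)] +
         z[2:(nr - 1), 1:(nc - 2)] + z[2:(nr - 1), 3:nc] +
         z[2:(nr - 1), 2:(nc - 1)]) / 5
  }
  v <- matrix(0L, nr, nc)
  v[sm > quantile(sm, 1 - fraction)] <- 1L
  binary_landscape(v, pixel_size, epoch_year = year)
}
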