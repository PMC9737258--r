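# Independent brute-force oracles used to verify the vectorised implementations.

# Per-pixel zone binning oracle: loops over every pixel, thresholds, computes
# the radial distance of the pixel centre, and bins into zones (0 = outside).
# Returns integer counts per zone (named 0..n_zones) per channel and z slice,
# summed over z.
oracle_zone_counts <- function(stack, geometry, thresholds) {
  d <- dim(stack$pixels)
  s <- stack$um_per_px
  R <- geometry$diameter_um / 2
  w <- R / geometry$n_zones
  cy <- geometry$center_xy[["y"]]; cx <- geometry$center_xy[["x"]]
  out <- list()
  for (ch in seq_along(stack$channel_names)) {
    counts <- integer(geometry$n_zones + 1L)
    for (z in seq_len(d[3])) {
      for (i in seq_len(d[1])) {
        for (j in seq_len(d[2])) {
          if (stack$pixels[i, j, z, ch] > thresholds[ch]) {
            r <- sqrt(((i - 1) * s - cy)^2 + ((j - 1) * s - cx)^2)
            k <- if (r > R) 0L else min(floor(r / w) + 1L, geometry$n_zones)
            counts[k + 1L] <- counts[k + 1L] + 1L
          }
        }
      }
    }
    out[[stack$channel_names[ch]]] <- counts
  }
  out
}

# Weighted-centroid oracle: direct sum(I * p) / sum(I) over all pixels.
oracle_centroid <- function(stack) {
  d <- dim(stack$pixels)
  s <- stack$um_per_px
  num_y <- num_x <- den <- 0
  for (ch in seq_len(d[4])) for (z in seq_len(d[3])) {
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      v <- stack$pixels[i, j, z, ch]
      num_y <- num_y + v * (i - 1) * s
      num_x <- num_x + v * (j - 1) * s
      den <- den + v
    }
  }
  c(y = unname(num_y / den), x = unname(num_x / den))
}

# Closed-form least squares for y = a + b x via the normal equations.
oracle_ls_slope <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}

# Spearman rho for untied rank vectors: 1 - 6 sum d^2 / (n (n^2 - 1)).
oracle_spearman <- function(r1, r2) {
  n <- length(r1)
  1 - 6 * sum((r1 - r2)^2) / (n * (n^2 - 1))
}

# Random multichannel fixture for oracle-equivalence tests.
random_stack <- function(ny, nx, nz = 1L, n_channels = 1L, um_per_px = 1) {
  arr <- array(runif(ny * nx * nz * n_channels), dim = c(ny, nx, nz, n_channels))
  multichannel_stack(arr, channel_names = paste0("ch", seq_len(n_channels)),
                     um_per_px = um_per_px)
}

# A stack with all of one channel's signal concentrated inside Zone I.
zone1_stack <- function(seed = 11, n_cells = 2000) {
  pops <- tibble::tibble(
    label = "core", channel = "red", n_cells = n_cells,
    placement = list(zone_placement(c(1, 0, 0, 0, 0)))
  )
  simulate_aggregate_image(pops, seed = seed)
}

centered_geometry <- function(n_px = 500, um_per_px = 1, diameter_um = 500,
                              n_zones = 5) {
  c_um <- (n_px - 1) / 2 * um_per_px
  well_geometry(diameter_um = diameter_um, n_zones = n_zones,
                um_per_px = um_per_px, center_xy = c(y = c_um, x = c_um))
}
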