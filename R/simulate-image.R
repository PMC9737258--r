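#' Radial placement models for synthetic aggregates
#'
#' Two ways to specify where a labelled population sits radially inside a
#' well. `zone_placement(probs)` places each cell in zone k with probability
#' `probs[k]`, then uniformly by area within that annulus, so the `probs` are
#' target occupancy probabilities. `core_shell_placement()` emulates sorted
#' (segregated) aggregates: each cell goes to the shell (the annulus outside
#' `core_fraction` of the well radius) with probability `shell_bias`,
#' otherwise to the core, again area-uniformly. Angles are always uniform.
#'
#' @param probs Non-negative weights, one per zone, summing to 1 (within 1e-9
#'   after normalisation they are checked, not rescaled).
#' @param core_fraction Fraction of the well radius occupied by the core, in
#'   \[0, 1\].
#' @param shell_bias Probability a cell is placed in the shell rather than the
#'   core, in \[0, 1\].
#' @return An object of class `radial_placement`.
#' @examples
#' zone_placement(c(0.57, 0.42, 0.01, 0, 0))   # core-seeking, U251-like
#' core_shell_placement(0.6, shell_bias = 0.9) # periphery-seeking
#' @export
zone_placement <- function(probs) {
  if (!is.numeric(probs) || length(probs) < 1L || any(!is.finite(probs)) ||
      any(probs < 0)) {
    abort("`probs` must be finite non-negative zone weights.")
  }
  if (abs(sum(probs) - 1) > 1e-9) {
    abort(sprintf("`probs` must sum to 1 (got %.12g).", sum(probs)))
  }
  structure(list(mode = "zone_probabilities", zone_probs = probs),
            class = "radial_placement")
}

#' @rdname zone_placement
#' @export
core_shell_placement <- function(core_fraction, shell_bias) {
  stopifnot_scalar_number(core_fraction, "core_fraction", min = 0, max = 1)
  stopifnot_scalar_number(shell_bias, "shell_bias", min = 0, max = 1)
  structure(list(mode = "core_shell", core_fraction = core_fraction,
                 shell_bias = shell_bias),
            class = "radial_placement")
}

#' @export
print.radial_placement <- function(x, ...) {
  if (x$mode == "zone_probabilities") {
    cat("<radial_placement> zone probabilities:",
        paste(signif(x$zone_probs, 3), collapse = ", "), "\n")
  } else {
    cat(sprintf("<radial_placement> core-shell: core_fraction %g, shell_bias %g\n",
                x$core_fraction, x$shell_bias))
  }
  invisible(x)
}

# Area-uniform radius inside the annulus [a, b]: density proportional to r.
sample_annulus_radius <- function(n, a, b) sqrt(runif(n, a^2, b^2))

sample_radii <- function(placement, n, radius_um, n_zones) {
  if (placement$mode == "zone_probabilities") {
    probs <- placement$zone_probs
    if (length(probs) != n_zones) {
      abort(sprintf("placement has %d zone weights but the well has %d zones.",
                    length(probs), n_zones))
    }
    w <- radius_um / n_zones
    k <- sample.int(n_zones, n, replace = TRUE, prob = probs)
    sample_annulus_radius(n, (k - 1) * w, k * w)
  } else {
    r_core <- placement$core_fraction * radius_um
    shell <- runif(n) < placement$shell_bias
    r <- numeric(n)
    r[shell] <- sample_annulus_radius(sum(shell), r_core, radius_um)
    r[!shell] <- sample_annulus_radius(sum(!shell), 0, r_core)
    r
  }
}

# Paint anti-aliased disks of one radius into a single slice matrix.
# Coverage ramps linearly across one pixel width at the rim; overlapping
# disks saturate (pmax), mimicking a binary stain rather than photon counts.
paint_disks <- function(mat, cy_px, cx_px, radius_px) {
  ny <- nrow(mat); nx <- ncol(mat)
  for (j in seq_along(cy_px)) {
    cy <- cy_px[j]; cx <- cx_px[j]
    y0 <- max(0L, floor(cy - radius_px - 1)); y1 <- min(ny - 1L, ceiling(cy + radius_px + 1))
    x0 <- max(0L, floor(cx - radius_px - 1)); x1 <- min(nx - 1L, ceiling(cx + radius_px + 1))
    if (y0 > y1 || x0 > x1) next
    ys <- y0:y1; xs <- x0:x1
    dist <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
    cov <- pmin(1, pmax(0, radius_px - dist + 0.5))
    idx_y <- ys + 1L; idx_x <- xs + 1L
    mat[idx_y, idx_x] <- pmax(mat[idx_y, idx_x], cov)
  }
  mat
}

#' Simulate a multichannel microwell aggregate image
#'
#' Renders labelled cell populations into a seeded synthetic fluorescence
#' stack of one microwell. Each population is drawn as uniform-intensity,
#' anti-aliased disks on its own channel; radial positions follow the
#' population's [zone_placement()] or [core_shell_placement()] model, angles
#' are uniform, and each cell is assigned uniformly to one z slice. Additive
#' Gaussian pixel noise (clipped at zero) is applied last. With the same
#' `populations`, `geometry` and `seed` the output is bit-identical.
#'
#' The default rendered footprint (`cell_radius_um = 0.75` at 1 um/px, 10 z
#' slices) is deliberately small relative to the 50-um zone width, so that
#' thresholded-area occupancy fractions track the placement probabilities
#' instead of saturating the inner zones; see the methods vignette.
#'
#' @param populations Data frame with one row per population and columns
#'   `label` (unique), `channel` (unique), `n_cells` (>= 0), `placement`
#'   (list-column of `radial_placement` objects), and optionally
#'   `cell_radius_um` (> 0, default 0.75).
#' @param geometry A [well_geometry()]; its centre defaults to the image
#'   centre.
#' @param z_slices Number of z slices (>= 1).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise, in
#'   intensity units on the \[0, 1\] scale of the rendered disks.
#' @param seed Optional integer seed; the generator uses (and restores) its
#'   own RNG stream.
#' @return A [multichannel_stack()] with attribute `cell_centers`, a tibble of
#'   the sampled cell centres (`label`, `channel`, `y_um`, `x_um`, `r_um`,
#'   `z`) relative to the image origin (`r_um` is radial distance from the
#'   well centre).
#' @examples
#' pops <- tibble::tibble(
#'   label = c("U251", "U87"), channel = c("red", "green"),
#'   n_cells = c(200, 200),
#'   placement = list(zone_placement(c(0.57, 0.42, 0.01, 0, 0)),
#'                    zone_placement(c(0.05, 0.48, 0.45, 0.02, 0)))
#' )
#' stk <- simulate_aggregate_image(pops, seed = 1)
#' quantify_zones(stk)
#' @export
simulate_aggregate_image <- function(populations, geometry = well_geometry(),
                                     z_slices = 10, noise_sd = 0.02,
                                     seed = NULL) {
  require_columns(populations, c("label", "channel", "n_cells", "placement"),
                  "populations")
  if (!inherits(geometry, "well_geometry")) {
    abort("`geometry` must be a well_geometry object.")
  }
  if (!"cell_radius_um" %in% names(populations)) {
    populations$cell_radius_um <- 0.75
  }
  if (anyDuplicated(populations$label)) {
    abort("`label` values must be unique across populations.")
  }
  dup <- unique(populations$channel[duplicated(populations$channel)])
  if (length(dup)) {
    abort(sprintf("channel collision: `channel` '%s' is used by more than one population.",
                  paste(dup, collapse = "', '")))
  }
  if (any(populations$n_cells < 0)) abort("`n_cells` must be >= 0.")
  R <- well_radius_um(geometry)
  if (any(populations$cell_radius_um <= 0)) {
    abort("`cell_radius_um` must be > 0.")
  }
  if (any(populations$cell_radius_um >= R)) {
    abort(sprintf("`cell_radius_um` must be smaller than the well radius (%g um).", R))
  }
  stopifnot_scalar_number(z_slices, "z_slices", min = 1)
  stopifnot_scalar_number(noise_sd, "noise_sd", min = 0)
  z_slices <- as.integer(z_slices)
  bad <- !vapply(populations$placement, inherits, logical(1), "radial_placement")
  if (any(bad)) {
    abort("`placement` must be a list of radial_placement objects.")
  }

  n_px <- round(geometry$diameter_um / geometry$um_per_px)
  if (n_px < 1) abort("`diameter_um` / `um_per_px` yields a zero-area well image.")
  center <- geometry$center_xy %||%
    c(y = (n_px - 1) / 2 * geometry$um_per_px,
      x = (n_px - 1) / 2 * geometry$um_per_px)

  with_seed_if(seed, {
    arr <- array(0, dim = c(n_px, n_px, z_slices, nrow(populations)))
    centers <- vector("list", nrow(populations))
    for (i in seq_len(nrow(populations))) {
      n <- populations$n_cells[i]
      if (n == 0) {
        centers[[i]] <- tibble(label = character(), channel = character(),
                               y_um = numeric(), x_um = numeric(),
                               r_um = numeric(), z = integer())
        next
      }
      r <- sample_radii(populations$placement[[i]], n, R, geometry$n_zones)
      theta <- runif(n, 0, 2 * pi)
      y_um <- center[["y"]] + r * sin(theta)
      x_um <- center[["x"]] + r * cos(theta)
      z <- sample.int(z_slices, n, replace = TRUE)
      rad_px <- populations$cell_radius_um[i] / geometry$um_per_px
      for (zz in unique(z)) {
        sel <- z == zz
        arr[, , zz, i] <- paint_disks(arr[, , zz, i],
                                      y_um[sel] / geometry$um_per_px,
                                      x_um[sel] / geometry$um_per_px,
                                      rad_px)
      }
      centers[[i]] <- tibble(label = populations$label[i],
                             channel = populations$channel[i],
                             y_um = y_um, x_um = x_um, r_um = r, z = z)
    }
    if (noise_sd > 0) {
      arr <- pmax(arr + rnorm(length(arr), sd = noise_sd), 0)
    }
    stk <- multichannel_stack(arr, channel_names = populations$channel,
                              um_per_px = geometry$um_per_px)
    attr(stk, "cell_centers") <- bind_rows(centers)
    stk
  })
}
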