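#' Locate the well centre from image intensity
#'
#' Returns the intensity-weighted centroid of the image summed over channels
#' and z slices, in micrometre pixel-centre coordinates (0-based indices
#' scaled by `um_per_px`). An all-zero image falls back to the geometric image
#' centre, flagged in the `fallback` column.
#'
#' @param stack A [multichannel_stack()].
#' @return A one-row tibble with columns `y_um`, `x_um`, `fallback`.
#' @examples
#' m <- matrix(0, 32, 32); m[11, 21] <- 1   # 0-based (y = 10, x = 20)
#' locate_well_center(multichannel_stack(m, "red"))
#' @export
locate_well_center <- function(stack) {
  if (!inherits(stack, "multichannel_stack")) {
    abort("`stack` must be a multichannel_stack.")
  }
  d <- dim(stack$pixels)
  w <- apply(stack$pixels, c(1L, 2L), sum)
  total <- sum(w)
  s <- stack$um_per_px
  if (total == 0) {
    return(tibble(y_um = (d[1] - 1) / 2 * s, x_um = (d[2] - 1) / 2 * s,
                  fallback = TRUE))
  }
  ys <- (seq_len(d[1]) - 1) * s
  xs <- (seq_len(d[2]) - 1) * s
  tibble(y_um = sum(rowSums(w) * ys) / total,
         x_um = sum(colSums(w) * xs) / total,
         fallback = FALSE)
}

#' Label image pixels by concentric zone
#'
#' Builds an integer matrix assigning every pixel to a concentric zone of the
#' well: zone k covers radial distances `[(k-1) R/n, k R/n)` from the well
#' centre (half-open bins, with the outermost bin closed at `r = R`), and 0
#' marks pixels outside the well. Distances use pixel-centre coordinates
#' (0-based indices times `um_per_px`). Zone 1 is innermost.
#'
#' @param geometry A [well_geometry()] with a resolved `center_xy`.
#' @param dim Integer vector `c(ny, nx)`, the image dimensions in pixels.
#' @return An integer matrix of zone labels with dimensions `dim`.
#' @examples
#' g <- well_geometry(diameter_um = 10, n_zones = 5, center_xy = c(y = 5, x = 5))
#' zone_mask(g, c(11, 11))
#' @export
zone_mask <- function(geometry, dim) {
  if (!inherits(geometry, "well_geometry")) {
    abort("`geometry` must be a well_geometry object.")
  }
  if (is.null(geometry$center_xy)) {
    abort("`geometry` has no resolved centre; set `center_xy` or use locate_well_center().")
  }
  dim <- as.integer(dim)
  if (length(dim) < 2L) abort("`dim` must give at least c(ny, nx).")
  ny <- dim[1]; nx <- dim[2]
  s <- geometry$um_per_px
  R <- well_radius_um(geometry)
  cy <- geometry$center_xy[["y"]]; cx <- geometry$center_xy[["x"]]
  if (cy - R < -s / 2 || cx - R < -s / 2 ||
      cy + R > (ny - 1) * s + s / 2 || cx + R > (nx - 1) * s + s / 2) {
    warn("well circle extends beyond the image; the zone mask is truncated.")
  }
  ys <- (seq_len(ny) - 1) * s - cy
  xs <- (seq_len(nx) - 1) * s - cx
  r <- sqrt(outer(ys^2, xs^2, "+"))
  w <- R / geometry$n_zones
  zone <- floor(r / w) + 1
  zone[r > R] <- 0
  zone <- pmin(zone, geometry$n_zones)   # close the outer bin at r = R
  matrix(as.integer(zone), ny, nx)
}

resolve_threshold <- function(threshold, stack, mask, channel) {
  if (is.numeric(threshold)) {
    stopifnot_scalar_number(threshold, "threshold")
    return(threshold)
  }
  if (!identical(threshold, "otsu")) {
    abort("`threshold` must be \"otsu\" or a fixed numeric value.")
  }
  proj <- max_projection(stack, channel)
  vals <- proj[mask > 0L]
  rng <- range(vals)
  if (diff(rng) == 0) return(Inf)  # flat channel: nothing above threshold
  EBImage::otsu(matrix(vals, ncol = 1L), range = rng, levels = 256L)
}

#' Quantify per-channel zone occupancy of an aggregate image
#'
#' The concentric-zone ("circular sector") quantification: for each channel,
#' pixels above threshold are counted per zone in every z slice, counts are
#' summed over z and converted to um^2, and per-channel occupancy fractions
#' are computed over zones 1..n. Above-threshold signal outside the well is
#' excluded from the fractions and reported in the `outside_area_um2`
#' attribute (a warning fires when it exceeds 5% of a channel's signal,
#' suggesting a mis-centred well). A channel with no above-threshold pixels
#' gets `NA` fractions with a warning, not zeros.
#'
#' The default threshold is Otsu's method computed per channel over the
#' in-well region of the max-intensity z projection and applied to every
#' slice; pass a number for a fixed threshold.
#'
#' @param stack A [multichannel_stack()].
#' @param geometry A [well_geometry()]; when `NULL`, a default 5-zone well
#'   spanning the image at the stack's scale is used. An unresolved centre is
#'   estimated with [locate_well_center()].
#' @param threshold `"otsu"` or a fixed numeric intensity threshold.
#' @param well_id Optional identifier prepended as a `well_id` column.
#' @return A tibble (the zone profile) with columns `well_id` (if given),
#'   `channel`, `zone`, `area_um2`, `fraction`, carrying attributes
#'   `outside_area_um2` (named per channel), `threshold` (named per channel)
#'   and `geometry`.
#' @examples
#' pops <- tibble::tibble(label = "a", channel = "red", n_cells = 300,
#'                        placement = list(zone_placement(c(1, 0, 0, 0, 0))))
#' quantify_zones(simulate_aggregate_image(pops, seed = 2))
#' @export
quantify_zones <- function(stack, geometry = NULL, threshold = "otsu",
                           well_id = NULL) {
  if (!inherits(stack, "multichannel_stack")) {
    abort("`stack` must be a multichannel_stack.")
  }
  d <- dim(stack$pixels)
  if (is.null(geometry)) {
    geometry <- well_geometry(
      diameter_um = min(d[1], d[2]) * stack$um_per_px,
      um_per_px = stack$um_per_px
    )
  }
  if (is.null(geometry$center_xy)) {
    ctr <- locate_well_center(stack)
    geometry$center_xy <- c(y = ctr$y_um, x = ctr$x_um)
  }
  mask <- zone_mask(geometry, d[1:2])
  nz <- geometry$n_zones
  out <- vector("list", length(stack$channel_names))
  outside <- thr_used <- stats::setNames(numeric(length(stack$channel_names)),
                                         stack$channel_names)
  for (ci in seq_along(stack$channel_names)) {
    ch <- stack$channel_names[ci]
    thr <- resolve_threshold(threshold, stack, mask, ch)
    thr_used[ch] <- thr
    counts <- integer(nz + 1L)  # slot 1 = outside (zone 0)
    for (z in seq_len(d[3])) {
      above <- stack$pixels[, , z, ci] > thr
      if (any(above)) {
        counts <- counts + tabulate(mask[above] + 1L, nbins = nz + 1L)
      }
    }
    area <- counts * stack$um_per_px^2
    outside[ch] <- area[1L]
    in_total <- sum(area[-1L])
    if (in_total == 0) {
      warn(sprintf("channel '%s' has no above-threshold signal inside the well; fractions are undefined.", ch))
      frac <- rep(NA_real_, nz)
    } else {
      frac <- area[-1L] / in_total
      if (outside[ch] > 0.05 * (in_total + outside[ch])) {
        warn(sprintf("channel '%s': %.1f%% of signal lies outside the outermost zone; the well may be mis-centred.",
                     ch, 100 * outside[ch] / (in_total + outside[ch])))
      }
    }
    out[[ci]] <- tibble(channel = ch, zone = seq_len(nz),
                        area_um2 = area[-1L], fraction = frac)
  }
  profile <- bind_rows(out)
  if (!is.null(well_id)) {
    profile <- tibble(well_id = well_id, profile)
  }
  attr(profile, "outside_area_um2") <- outside
  attr(profile, "threshold") <- thr_used
  attr(profile, "geometry") <- geometry
  profile
}
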