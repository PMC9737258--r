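#' Describe a microwell and its concentric-zone partition
#'
#' A `well_geometry` records the physical description of one microwell and how
#' it is divided into concentric zones: well diameter in micrometres, the
#' number of equal-radial-width zones, the image scale, and (optionally) the
#' well centre in micrometre coordinates. The default is the 500-um-diameter
#' well of a microwell aggregation array, divided into five zones (Zone 1
#' innermost, Zone `n_zones` outermost) at 1 um per pixel.
#'
#' Zones have equal radial width `R / n_zones` (not equal area), so for five
#' zones the annulus areas are in the ratio 1:3:5:7:9.
#'
#' @param diameter_um Well diameter in micrometres. Must be > 0.
#' @param n_zones Number of concentric zones (>= 1).
#' @param um_per_px Image scale, micrometres per pixel (> 0).
#' @param center_xy Optional named numeric `c(y = , x = )` giving the well
#'   centre in micrometres (pixel-centre coordinates, 0-based indices scaled
#'   by `um_per_px`). When `NULL` the centre is estimated from the image by
#'   [locate_well_center()].
#' @return An object of class `well_geometry`.
#' @examples
#' well_geometry()
#' well_geometry(diameter_um = 400, n_zones = 4, center_xy = c(y = 200, x = 200))
#' @export
well_geometry <- function(diameter_um = 500, n_zones = 5, um_per_px = 1,
                          center_xy = NULL) {
  stopifnot_scalar_number(diameter_um, "diameter_um", min = 0, strict_min = TRUE)
  stopifnot_scalar_number(n_zones, "n_zones", min = 1)
  if (n_zones != round(n_zones)) abort("`n_zones` must be a whole number.")
  stopifnot_scalar_number(um_per_px, "um_per_px", min = 0, strict_min = TRUE)
  if (!is.null(center_xy)) {
    if (!is.numeric(center_xy) || length(center_xy) != 2L ||
        !all(c("y", "x") %in% names(center_xy))) {
      abort("`center_xy` must be a named numeric vector c(y = , x = ) in um.")
    }
    center_xy <- center_xy[c("y", "x")]
  }
  structure(
    list(diameter_um = diameter_um, n_zones = as.integer(n_zones),
         um_per_px = um_per_px, center_xy = center_xy),
    class = "well_geometry"
  )
}

well_radius_um <- function(geometry) geometry$diameter_um / 2

#' @export
print.well_geometry <- function(x, ...) {
  cat(sprintf("<well_geometry> %g um diameter, %d zones, %g um/px\n",
              x$diameter_um, x$n_zones, x$um_per_px))
  if (is.null(x$center_xy)) {
    cat("  centre: unresolved (estimated from the image)\n")
  } else {
    cat(sprintf("  centre: (y = %g, x = %g) um\n",
                x$center_xy[["y"]], x$center_xy[["x"]]))
  }
  invisible(x)
}

#' Reference zone occupancy profiles of the U251 and U87 lines
#'
#' Published zone occupancies of the two glioblastoma reference lines in
#' heterotypic aggregates: U251 (strong homotypic affinity) concentrates in
#' Zones I (57%) and II (42%); U87 (weak affinity) occupies Zones II (48%)
#' and III (45%). The small remainders are assigned to the adjacent zones
#' (Zone III for U251; Zones I and IV for U87) so each profile sums to 1.
#' These profiles anchor the internal and external ends of the radial-score
#' scale and serve as classification references.
#'
#' @return A tibble with columns `label`, `zone` (1..5) and `fraction`.
#' @examples
#' reference_profiles() |> radial_score()
#' @export
reference_profiles <- function() {
  tibble(
    label = rep(c("U251", "U87"), each = 5L),
    zone = rep(1:5, 2L),
    fraction = c(0.57, 0.42, 0.01, 0.00, 0.00,
                 0.05, 0.48, 0.45, 0.02, 0.00)
  )
}
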