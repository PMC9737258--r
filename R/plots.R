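#' Plot a zone occupancy profile
#'
#' Bar chart of per-zone occupancy fractions by channel or label, the
#' histogram companion of the circular-zone quantification.
#'
#' @param profile A zone profile tibble (columns `zone`, `fraction`, and
#'   `label` or `channel`).
#' @return A ggplot object.
#' @examples
#' plot_zone_profile(reference_profiles())
#' @export
plot_zone_profile <- function(profile) {
  require_columns(profile, c("zone", "fraction"), "profile")
  id <- profile_id_column(profile)
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = factor(.data$zone), y = .data$fraction,
                               fill = .data[[id]])) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = "Zone (1 = innermost)", y = "Occupancy fraction",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn km_estimate Step-function survival curves with censoring
#'   marks.
#' @param object A `km_fit` object.
#' @method autoplot km_fit
#' @export
autoplot.km_fit <- function(object, ...) {
  curves <- tidy(object)
  start <- curves |> distinct(.data$group) |>
    mutate(time = 0, survival = 1, n_censor = 0L)
  dat <- bind_rows(start, curves) |> arrange(.data$group, .data$time)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$survival,
                                    colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = dplyr::filter(dat, .data$n_censor > 0),
                        shape = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot paired rankings as a concordance heatmap
#'
#' Tile plot of ranks across several rank tables (e.g. spatial configuration
#' versus drug response, proliferation, invasion), one column per ranking,
#' rows ordered by the first ranking.
#'
#' @param ... Named rank tables over the same labels.
#' @return A ggplot object.
#' @examples
#' r1 <- rank_populations(tibble::tibble(label = letters[1:4], score = 1:4))
#' plot_rank_heatmap(spatial = r1, resistance = r1)
#' @export
plot_rank_heatmap <- function(...) {
  tables <- list(...)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    abort("all rank tables must be named, e.g. plot_rank_heatmap(spatial = , ...).")
  }
  long <- bind_rows(lapply(names(tables), function(nm) {
    tibble(ranking = nm, label = tables[[nm]]$label, rank = tables[[nm]]$rank)
  }))
  order_labels <- tables[[1]]$label[order(tables[[1]]$rank)]
  long$label <- factor(long$label, levels = rev(order_labels))
  long$ranking <- factor(long$ranking, levels = names(tables))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ranking, y = .data$label,
                                     fill = .data$rank)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Rank") +
    ggplot2::theme_minimal()
}
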