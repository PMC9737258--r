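#' Drug-resistance metric: mean viability over log dose
#'
#' Scalarises a dose-viability curve as the trapezoidal mean of viability
#' over log10(dose) across the tested range, clipped to \[0, 1\]: 1 is fully
#' resistant (viability 1 everywhere), 0 fully sensitive. Replicates are
#' averaged per dose first. Rows at dose 0 are treated as the untreated
#' control and used only to normalise viabilities (divide by the mean control
#' viability); they are excluded from the integral. This normalised log-dose
#' AUC is robust where sigmoidal IC50 fits fail, e.g. on flat curves of fully
#' resistant lines.
#'
#' @param doses Tibble with columns `label`, `dose_uM` (>= 0), `viability`
#'   (fraction of untreated control, >= 0); replicates allowed.
#' @return Tibble with columns `label`, `resistance`.
#' @examples
#' d <- tibble::tibble(label = "a", dose_uM = c(10, 100, 1000),
#'                     viability = c(0.9, 0.5, 0.1))
#' resistance_metric(d)  # 0.5
#' @export
resistance_metric <- function(doses) {
  require_columns(doses, c("label", "dose_uM", "viability"), "doses")
  if (any(doses$dose_uM < 0) || any(!is.finite(doses$dose_uM))) {
    abort("`dose_uM` must be finite and >= 0 (dose 0 rows are the control).")
  }
  doses |>
    group_by(.data$label) |>
    summarise(resistance = {
      v <- .data$viability; d <- .data$dose_uM
      ctrl <- v[d == 0]
      if (length(ctrl) && mean(ctrl) > 0) v <- v / mean(ctrl)
      pos <- d > 0
      per_dose <- tapply(v[pos], d[pos], mean)
      dd <- as.numeric(names(per_dose))
      if (length(dd) < 3L) {
        abort(sprintf("label '%s' needs >= 3 distinct positive doses.",
                      dplyr::cur_group()$label))
      }
      o <- order(dd)
      x <- log10(dd[o])
      y <- as.numeric(per_dose[o])
      min(max(pracma::trapz(x, y) / (max(x) - min(x)), 0), 1)
    }, .groups = "drop")
}

#' Proliferation metric: log-linear growth rate
#'
#' Fits a least-squares line to `ln(od)` versus time per label and returns
#' its slope (per hour). Using the rate rather than the endpoint absorbance
#' makes the metric insensitive to seeding density. Non-positive absorbances
#' are dropped with a warning; labels with fewer than 3 usable points get an
#' `NA` rate with a warning.
#'
#' @param growth Tibble with columns `label`, `time_h`, `od` (absorbance,
#'   e.g. at 550 nm).
#' @return Tibble with columns `label`, `growth_rate` (per hour).
#' @examples
#' g <- tibble::tibble(label = "a", time_h = c(0, 24, 48, 72),
#'                     od = 0.2 * 2^(c(0, 24, 48, 72) / 24))
#' growth_rate(g)  # log(2) / 24
#' @export
growth_rate <- function(growth) {
  require_columns(growth, c("label", "time_h", "od"), "growth")
  if (any(growth$od <= 0)) {
    warn("dropping rows with non-positive absorbance before log-linear fit.")
    growth <- growth[growth$od > 0, ]
  }
  out <- growth |>
    group_by(.data$label) |>
    summarise(growth_rate = {
      if (dplyr::n() < 3L) NA_real_
      else unname(coef(lm(log(.data$od) ~ .data$time_h))[2])
    }, .groups = "drop")
  if (anyNA(out$growth_rate)) {
    warn(sprintf("fewer than 3 usable points for: %s; growth rate is NA.",
                 paste(out$label[is.na(out$growth_rate)], collapse = ", ")))
  }
  out
}

#' Invasion metric: relative change in invaded area
#'
#' Computes `(area(to) - area(from)) / area(from)` per label from an
#' invaded-area time series, by default from 0 h to 72 h. Replicate areas at
#' a time point are averaged. A zero starting area leaves the metric missing
#' with a warning.
#'
#' @param invasion Tibble with columns `label`, `time_h`, `area_um2` (>= 0).
#' @param from,to Times (h) whose areas define the change; both must be
#'   present for every label.
#' @return Tibble with columns `label`, `invasion_change` (dimensionless).
#' @examples
#' inv <- tibble::tibble(label = "a", time_h = c(0, 72), area_um2 = c(100, 300))
#' invasion_change(inv)  # 2
#' @export
invasion_change <- function(invasion, from = 0, to = 72) {
  require_columns(invasion, c("label", "time_h", "area_um2"), "invasion")
  out <- invasion |>
    group_by(.data$label) |>
    summarise(invasion_change = {
      a0 <- mean(.data$area_um2[.data$time_h == from])
      a1 <- mean(.data$area_um2[.data$time_h == to])
      if (!is.finite(a0) || !is.finite(a1)) {
        abort(sprintf("label '%s' lacks an area at %g h and %g h.",
                      dplyr::cur_group()$label, from, to))
      }
      if (a0 == 0) NA_real_ else (a1 - a0) / a0
    }, .groups = "drop")
  if (anyNA(out$invasion_change)) {
    warn(sprintf("zero starting area for: %s; invasion change is NA.",
                 paste(out$label[is.na(out$invasion_change)], collapse = ", ")))
  }
  out
}

#' Rank a phenotype metric and split into subgroups
#'
#' Applies the same ranking, tie-break and median-split semantics as
#' [rank_populations()] to any per-label scalar metric. With
#' `direction = "ascending"` (default) low values take rank 1 and the
#' `internal` subgroup, matching the sensitive-to-resistant and low-to-high
#' orderings used alongside the spatial ranking; `"descending"` reverses the
#' ranks.
#'
#' @param metrics Tibble whose first column is `label` and whose second
#'   column is the metric (any name); `NA` metrics are excluded with a
#'   warning.
#' @param direction `"ascending"` or `"descending"`.
#' @param split Passed to [rank_populations()].
#' @return A rank table (see [rank_populations()]); `score` holds the metric
#'   value.
#' @examples
#' rank_and_split(tibble::tibble(label = letters[1:4],
#'                               resistance = c(0.8, 0.2, 0.5, 0.9)))
#' @export
rank_and_split <- function(metrics, direction = c("ascending", "descending"),
                           split = NULL) {
  direction <- match.arg(direction)
  if (ncol(metrics) < 2L || names(metrics)[1] != "label") {
    abort("`metrics` must have `label` as its first column and the metric as its second.")
  }
  value <- metrics[[2]]
  if (!is.numeric(value)) abort("the metric column must be numeric.")
  scores <- tibble(label = metrics$label,
                   score = if (direction == "ascending") value else -value)
  ranked <- rank_populations(scores, split = split)
  ranked$score <- value[match(ranked$label, metrics$label)]
  ranked
}

#' Concordance between two rankings
#'
#' Measures agreement between two rank tables over the same labels:
#' `spearman_rho`, the Spearman rank correlation of the two rank vectors, and
#' `group_agreement`, the fraction of labels assigned to the same
#' internal/external subgroup. Used to compare the spatial-configuration
#' ranking with drug-response, proliferation or invasion rankings.
#'
#' @param a,b Rank tables from [rank_populations()] or [rank_and_split()]
#'   with identical label sets.
#' @return A one-row tibble: `spearman_rho`, `group_agreement`, `n_labels`.
#' @examples
#' r <- rank_populations(tibble::tibble(label = letters[1:4], score = 1:4))
#' concordance(r, r)
#' @export
concordance <- function(a, b) {
  require_columns(a, c("label", "rank", "subgroup"), "a")
  require_columns(b, c("label", "rank", "subgroup"), "b")
  if (!setequal(a$label, b$label) || nrow(a) != nrow(b)) {
    abort("`a` and `b` must cover the same set of labels.")
  }
  j <- inner_join(a, b, by = "label", suffix = c("_a", "_b"))
  tibble(
    spearman_rho = cor(j$rank_a, j$rank_b, method = "spearman"),
    group_agreement = mean(as.character(j$subgroup_a) == as.character(j$subgroup_b)),
    n_labels = nrow(j)
  )
}
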