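#' Simulate phenotype tables coupled to spatial scores
#'
#' Generates the three per-population phenotype tables the ranking stage
#' consumes: a temozolomide-style dose-viability table, a proliferation
#' (time-absorbance) table, and an invasion (time-area) table. With
#' `direction = "resistant_when_external"` the dose-response half-effect
#' concentration increases monotonically (and deterministically) with the
#' population's radial score, reproducing the coupling in which
#' periphery-seeking populations resist treatment; with `"independent"` the
#' half-effect dose is drawn at random, breaking the coupling. Growth and
#' invasion tables are always generated independently of the score.
#'
#' Dose-response curves follow a four-parameter logistic
#' `v(d) = bottom + (top - bottom) / (1 + (d / EC50)^h)` with `top = 1`,
#' `bottom = 0.05`, `h = 1.5`, and `log10(EC50)` mapped linearly from the
#' score range \[1, 5\] onto \[1.2, 3.2\] (12 to 1600 uM, spanning the default
#' 10-1000 uM dose range). Gaussian noise of sd `noise_sd` is added to every
#' measured value (clipped below at 0).
#'
#' @param spatial_scores Tibble with columns `label`, `score` (>= 2 labels,
#'   finite scores).
#' @param direction `"resistant_when_external"` or `"independent"`.
#' @param noise_sd Measurement noise sd (>= 0) on the viability / relative
#'   od / relative area scale.
#' @param seed Optional integer seed.
#' @param doses_uM Tested doses; 0 is the untreated control.
#' @param times_h Time points for the growth and invasion tables.
#' @return A named list of tibbles: `doses` (`label`, `dose_uM`,
#'   `viability`), `growth` (`label`, `time_h`, `od`), `invasion` (`label`,
#'   `time_h`, `area_um2`).
#' @examples
#' sc <- tibble::tibble(label = c("a", "b", "c"), score = c(1.5, 3, 4.5))
#' tabs <- simulate_phenotypes(sc, noise_sd = 0, seed = 1)
#' resistance_metric(tabs$doses)
#' @export
simulate_phenotypes <- function(spatial_scores,
                                direction = c("resistant_when_external",
                                              "independent"),
                                noise_sd = 0.05, seed = NULL,
                                doses_uM = c(0, 10, 25, 63, 158, 398, 1000),
                                times_h = seq(0, 72, by = 24)) {
  direction <- match.arg(direction)
  require_columns(spatial_scores, c("label", "score"), "spatial_scores")
  if (nrow(spatial_scores) < 2L) {
    abort("`spatial_scores` needs >= 2 labels; ranking is undefined for one.")
  }
  if (anyDuplicated(spatial_scores$label)) abort("labels must be unique.")
  if (any(!is.finite(spatial_scores$score))) abort("scores must be finite.")
  stopifnot_scalar_number(noise_sd, "noise_sd", min = 0)

  labels <- spatial_scores$label
  n <- length(labels)
  top <- 1; bottom <- 0.05; hill <- 1.5
  pos_doses <- doses_uM[doses_uM > 0]

  with_seed_if(seed, {
    log_ec50 <- if (direction == "resistant_when_external") {
      s <- pmin(pmax(spatial_scores$score, 1), 5)
      1.2 + (s - 1) / 4 * 2
    } else {
      runif(n, 1.2, 3.2)
    }
    ec50 <- 10^log_ec50

    doses <- tidyr::expand_grid(label = labels, dose_uM = doses_uM) |>
      mutate(
        viability = {
          e <- ec50[match(.data$label, labels)]
          v <- ifelse(.data$dose_uM == 0, top,
                      bottom + (top - bottom) / (1 + (.data$dose_uM / e)^hill))
          pmax(v + rnorm(length(v), sd = noise_sd), 0)
        }
      )

    rate <- runif(n, 0.005, 0.03)      # per hour, independent of score
    growth <- tidyr::expand_grid(label = labels, time_h = times_h) |>
      mutate(od = {
        r <- rate[match(.data$label, labels)]
        pmax(0.2 * exp(r * .data$time_h) *
               (1 + rnorm(length(r), sd = noise_sd)), 1e-6)
      })

    area0 <- runif(n, 5e4, 1e5)        # um^2, independent of score
    rel_gain <- runif(n, 0.2, 2)
    invasion <- tidyr::expand_grid(label = labels, time_h = times_h) |>
      mutate(area_um2 = {
        i <- match(.data$label, labels)
        pmax(area0[i] * (1 + rel_gain[i] * .data$time_h / 72) *
               (1 + rnorm(length(i), sd = noise_sd)), 0)
      })

    list(doses = doses, growth = growth, invasion = invasion)
  })
}
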