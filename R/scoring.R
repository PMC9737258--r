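profile_id_column <- function(profile) {
  if ("label" %in% names(profile)) return("label")
  if ("channel" %in% names(profile)) return("channel")
  abort("profile needs a `label` or `channel` column identifying populations.")
}

#' Radial score: area-weighted mean zone index
#'
#' Summarises a zone occupancy profile as the scalar
#' `score = sum(k * fraction_k)` over zones `k = 1..n`. The score lives on the
#' zone-index scale: 1 means all signal in the innermost zone, `n_zones` all
#' signal in the outermost; higher is more external. It is linear in the
#' profile and strictly increases under any transfer of mass to an outer
#' zone, which is what makes it usable for internal-to-external ranking.
#'
#' @param profile A zone profile: tibble with columns `zone`, `fraction`, and
#'   an identifying column `label` or `channel` (e.g. the output of
#'   [quantify_zones()] or [reference_profiles()]). Multiple wells per label
#'   (a `well_id` column) are scored per well and averaged, with the per-well
#'   standard deviation reported.
#' @return A tibble with columns `label`, `score` (and `n_wells`, `score_sd`
#'   when a `well_id` column is present). Profiles with missing fractions (no
#'   signal) yield `NA` scores, propagated with a warning.
#' @examples
#' radial_score(reference_profiles())  # U251 1.44, U87 2.44
#' @export
radial_score <- function(profile) {
  require_columns(profile, c("zone", "fraction"), "profile")
  id <- profile_id_column(profile)
  per_well <- "well_id" %in% names(profile)
  keys <- if (per_well) c(id, "well_id") else id
  scored <- profile |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(
      score = {
        f <- .data$fraction
        if (anyNA(f)) NA_real_
        else {
          if (abs(sum(f) - 1) > 1e-6) {
            abort(sprintf("fractions for '%s' sum to %.6f, not 1.",
                          dplyr::cur_group()[[1]], sum(f)))
          }
          sum(.data$zone * f)
        }
      },
      .groups = "drop"
    )
  if (anyNA(scored$score)) {
    warn(sprintf("missing zone fractions for: %s; scores propagated as NA.",
                 paste(unique(scored[[id]][is.na(scored$score)]), collapse = ", ")))
  }
  if (per_well) {
    scored <- scored |>
      group_by(across(dplyr::all_of(id))) |>
      summarise(n_wells = dplyr::n(), score_sd = stats::sd(.data$score),
                score = mean(.data$score), .groups = "drop") |>
      dplyr::select(dplyr::all_of(id), "score", "n_wells", "score_sd")
  }
  names(scored)[names(scored) == id] <- "label"
  scored
}

#' Classify a population against internal and external references
#'
#' Places each test population on the internal/intermediate/external scale
#' defined by two reference populations of known behaviour (by default the
#' strongly cohesive U251 line anchors "internal" and the weakly cohesive U87
#' line "external"). A test score below the internal reference (minus
#' `margin`) is called `internal`; above the external reference (plus
#' `margin`), `external`; anything else - including exact ties with a
#' reference when `margin = 0` - is `intermediate`.
#'
#' @param scores A tibble of radial scores (`label`, `score`), including the
#'   two reference labels.
#' @param ref_inner,ref_outer Labels of the internal and external reference
#'   populations. If the internal reference scores above the external one the
#'   two are swapped with a warning.
#' @param margin Non-negative dead-band added around each reference score.
#'   References closer than `2 * margin` are indistinguishable and the call
#'   is refused.
#' @return A tibble with columns `label`, `score`, `call` (factor internal /
#'   intermediate / external) for the non-reference labels.
#' @examples
#' scores <- dplyr::bind_rows(radial_score(reference_profiles()),
#'                            tibble::tibble(label = "GC01", score = 1.2))
#' classify_configuration(scores, "U251", "U87")
#' @export
classify_configuration <- function(scores, ref_inner = "U251",
                                   ref_outer = "U87", margin = 0) {
  require_columns(scores, c("label", "score"), "scores")
  stopifnot_scalar_number(margin, "margin", min = 0)
  for (ref in c(ref_inner, ref_outer)) {
    if (!ref %in% scores$label) {
      abort(sprintf("reference label '%s' not found in `scores`.", ref))
    }
  }
  si <- scores$score[scores$label == ref_inner][1]
  so <- scores$score[scores$label == ref_outer][1]
  if (!is.finite(si) || !is.finite(so)) {
    abort("reference scores must be finite.")
  }
  if (si > so) {
    warn(sprintf("internal reference '%s' (%.3g) scores above external reference '%s' (%.3g); swapping.",
                 ref_inner, si, ref_outer, so))
    tmp <- si; si <- so; so <- tmp
  }
  if (abs(so - si) <= 2 * margin) {
    abort("reference scores are indistinguishable at this margin; classification refused.")
  }
  scores |>
    filter(!.data$label %in% c(ref_inner, ref_outer)) |>
    mutate(call = factor(
      case_when(.data$score < si - margin ~ "internal",
                .data$score > so + margin ~ "external",
                TRUE ~ "intermediate"),
      levels = c("internal", "intermediate", "external"))) |>
    dplyr::select("label", "score", "call")
}

#' Rank populations from internal to external
#'
#' Orders populations by ascending score (rank 1 = lowest score = most
#' internal), breaking ties by label so the ranking is deterministic, and
#' splits the ranking into an `internal` subgroup (ranks `1..split`) and an
#' `external` subgroup. The default split at the median rank `ceiling(n / 2)`
#' generalises the 4/4 split used for eight patient-derived lines.
#'
#' @param scores A tibble with columns `label`, `score`. Labels with missing
#'   scores are excluded with a warning.
#' @param split Rank of the last `internal` member; default `ceiling(n / 2)`.
#' @return A rank table: tibble with columns `label`, `score`, `rank` (1..n),
#'   `subgroup` (factor internal/external), sorted by rank.
#' @examples
#' rank_populations(tibble::tibble(label = c("a", "b", "c", "d"),
#'                                 score = c(3.1, 1.2, 4.0, 2.2)))
#' @export
rank_populations <- function(scores, split = NULL) {
  require_columns(scores, c("label", "score"), "scores")
  if (anyNA(scores$score)) {
    dropped <- scores$label[is.na(scores$score)]
    warn(sprintf("excluding label(s) with missing scores: %s.",
                 paste(dropped, collapse = ", ")))
    scores <- scores[!is.na(scores$score), ]
  }
  n <- nrow(scores)
  if (n < 2L) abort("ranking needs at least 2 scored populations.")
  split <- split %||% ceiling(n / 2)
  stopifnot_scalar_number(split, "split", min = 1, max = n)
  scores |>
    arrange(.data$score, .data$label) |>
    mutate(rank = row_number(),
           subgroup = factor(if_else(.data$rank <= split, "internal", "external"),
                             levels = c("internal", "external"))) |>
    dplyr::select("label", "score", "rank", "subgroup")
}
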