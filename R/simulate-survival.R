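#' Simulate a two-group right-censored survival cohort
#'
#' Generates exponential event times for two patient groups with a specified
#' hazard ratio: the first group has median survival `baseline_median` (its
#' hazard is `log(2) / baseline_median`), and the second group's hazard is
#' `hazard_ratio` times that, so `hazard_ratio > 1` makes the second group
#' (conventionally the external/resistant one) die faster. Each subject is
#' independently censored with probability `censor_prob`, at a time uniform
#' on (0, event time), so `censor_prob = 1` censors every record.
#'
#' @param groups Either a character vector of exactly two group names (first
#'   = baseline), or a data frame with `label` and `group`/`subgroup` columns
#'   (e.g. a rank table), whose two distinct groups are used in order of
#'   appearance and whose labels are recycled as patient `label`s.
#' @param hazard_ratio Hazard of the second group relative to the first
#'   (> 0).
#' @param baseline_median Median survival time of the first group (> 0), in
#'   whatever unit the study uses (e.g. months).
#' @param censor_prob Per-subject censoring probability in \[0, 1\].
#' @param n_per_group Number of subjects per group (>= 1).
#' @param seed Optional integer seed.
#' @return A tibble of survival records: `label`, `time` (> 0), `event`
#'   (1 = death observed, 0 = censored), `group`.
#' @examples
#' simulate_survival(c("internal", "external"), hazard_ratio = 3,
#'                   n_per_group = 5, seed = 1)
#' @export
simulate_survival <- function(groups = c("internal", "external"),
                              hazard_ratio = 3, baseline_median = 24,
                              censor_prob = 0.2, n_per_group = 30,
                              seed = NULL) {
  if (is.data.frame(groups)) {
    gcol <- intersect(c("group", "subgroup"), names(groups))[1]
    if (is.na(gcol) || !"label" %in% names(groups)) {
      abort("`groups` data frame needs `label` and `group` (or `subgroup`) columns.")
    }
    map <- tibble(label = as.character(groups$label),
                  group = as.character(groups[[gcol]]))
    group_names <- unique(map$group)
  } else {
    group_names <- as.character(groups)
    map <- NULL
  }
  if (length(group_names) != 2L) {
    abort("exactly two distinct groups are required.")
  }
  stopifnot_scalar_number(hazard_ratio, "hazard_ratio", min = 0, strict_min = TRUE)
  stopifnot_scalar_number(baseline_median, "baseline_median", min = 0,
                          strict_min = TRUE)
  stopifnot_scalar_number(censor_prob, "censor_prob", min = 0, max = 1)
  stopifnot_scalar_number(n_per_group, "n_per_group", min = 1)
  n_per_group <- as.integer(n_per_group)

  base_hazard <- log(2) / baseline_median
  with_seed_if(seed, {
    recs <- map2(group_names, c(1, hazard_ratio), function(g, hr) {
      t_event <- rexp(n_per_group, rate = base_hazard * hr)
      censored <- rbinom(n_per_group, 1L, censor_prob) == 1L
      time <- ifelse(censored, runif(n_per_group, 0, t_event), t_event)
      labs <- if (!is.null(map)) {
        rep_len(map$label[map$group == g], n_per_group)
      } else {
        sprintf("%s_%02d", g, seq_len(n_per_group))
      }
      tibble(label = labs, time = time, event = as.integer(!censored),
             group = g)
    })
    bind_rows(recs)
  })
}
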