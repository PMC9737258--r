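km_one_group <- function(time, event) {
  o <- order(time)
  time <- time[o]; event <- event[o]
  times <- sort(unique(time))
  n_total <- length(time)
  n_risk <- n_event <- n_censor <- integer(length(times))
  for (i in seq_along(times)) {
    t <- times[i]
    # ties at t: events are processed before censorings, so a subject
    # censored at t is still at risk for the events at t
    n_risk[i] <- sum(time >= t)
    n_event[i] <- sum(time == t & event == 1L)
    n_censor[i] <- sum(time == t & event == 0L)
  }
  surv <- cumprod(1 - n_event / n_risk)
  # Greenwood: var(S) = S^2 * sum d / (n (n - d)); terms with n = d give S = 0
  gw_terms <- ifelse(n_risk > n_event, n_event / (n_risk * (n_risk - n_event)), 0)
  std_err <- surv * sqrt(cumsum(gw_terms))
  tibble(time = times, n_risk = n_risk, n_event = n_event,
         n_censor = n_censor, survival = surv, std_err = std_err)
}

#' Kaplan-Meier product-limit survival estimate
#'
#' Estimates the survival function `S(t) = prod_{t_i <= t} (1 - d_i / n_i)`
#' per group from right-censored records, with Greenwood standard errors.
#' The curve starts at 1, is non-increasing and right-continuous; subjects
#' censored at an event time are kept in the risk set for that time (events
#' are processed before censorings).
#'
#' @param records Tibble with columns `time` (> 0), `event` (1 = death
#'   observed, 0 = censored) and optionally `group`; without `group` a single
#'   curve labelled `"all"` is fitted.
#' @return An object of class `km_fit`. [tidy()] returns the per-group step
#'   curve (`group`, `time`, `n_risk`, `n_event`, `n_censor`, `survival`,
#'   `std_err`); [glance()] returns per-group sample size, event count, and
#'   median survival; [autoplot()] draws the curves.
#' @examples
#' rec <- tibble::tibble(time = c(1, 2, 3, 4), event = c(1, 0, 1, 1))
#' tidy(km_estimate(rec))
#' @export
km_estimate <- function(records) {
  require_columns(records, c("time", "event"), "records")
  if (nrow(records) < 1L) abort("`records` must contain at least one record.")
  if (any(records$time <= 0) || any(!is.finite(records$time))) {
    abort("`time` must be finite and > 0.")
  }
  if (!all(records$event %in% c(0, 1))) {
    abort("`event` must be 0 (censored) or 1 (death observed).")
  }
  grp <- if ("group" %in% names(records)) as.character(records$group) else
    rep("all", nrow(records))
  curves <- bind_rows(lapply(split(seq_len(nrow(records)), grp), function(i) {
    tibble(group = grp[i[1]],
           km_one_group(records$time[i], as.integer(records$event[i])))
  }))
  structure(list(curves = curves,
                 n = table(grp)),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("<km_fit> Kaplan-Meier product-limit estimate\n")
  print(glance(x))
  invisible(x)
}

#' @rdname km_estimate
#' @param x A `km_fit` object.
#' @param ... Unused.
#' @method tidy km_fit
#' @export
tidy.km_fit <- function(x, ...) x$curves

#' @rdname km_estimate
#' @method glance km_fit
#' @export
glance.km_fit <- function(x, ...) {
  x$curves |>
    group_by(.data$group) |>
    summarise(
      n = sum(.data$n_event + .data$n_censor),
      events = sum(.data$n_event),
      median_survival = {
        hit <- .data$time[.data$survival <= 0.5]
        if (length(hit)) min(hit) else NA_real_
      },
      .groups = "drop"
    )
}

#' Two-group log-rank test
#'
#' Compares the survival distributions of exactly two groups with the
#' (unweighted) log-rank test: at each distinct event time the expected
#' number of events in group 1 is the hypergeometric mean
#' `d * n1 / n`, with variance `d (n1/n) (1 - n1/n) (n - d) / (n - 1)`, and
#' the statistic `(sum(O - E))^2 / sum(V)` is referred to a chi-square
#' distribution with 1 degree of freedom. `weighting = "wilcoxon"` applies
#' Gehan-Wilcoxon weights (`n` at risk), emphasising early differences.
#'
#' @param records Tibble with columns `time` (> 0), `event` (0/1), `group`
#'   (exactly two distinct values, each non-empty); at least one event is
#'   required.
#' @param weighting `"logrank"` (default) or `"wilcoxon"`.
#' @return An object of class `logrank_test` with elements `statistic`,
#'   `p_value`, `df`, `observed`, `expected` (named per group) and `method`.
#'   [tidy()]/[glance()] return a one-row tibble.
#' @examples
#' rec <- simulate_survival(hazard_ratio = 3, n_per_group = 30, seed = 1)
#' logrank_test(rec)
#' @export
logrank_test <- function(records, weighting = c("logrank", "wilcoxon")) {
  weighting <- match.arg(weighting)
  require_columns(records, c("time", "event", "group"), "records")
  if (any(records$time <= 0)) abort("`time` must be > 0.")
  groups <- unique(as.character(records$group))
  if (length(groups) != 2L) abort("exactly two groups are required.")
  g1 <- as.character(records$group) == groups[1]
  if (sum(g1) == 0L || sum(!g1) == 0L) abort("both groups must be non-empty.")
  if (sum(records$event) < 1) abort("at least one observed event is required.")

  event_times <- sort(unique(records$time[records$event == 1]))
  U <- Var <- 0
  O1 <- E1 <- 0
  for (t in event_times) {
    at_risk <- records$time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(records$time == t & records$event == 1)
    d1 <- sum(records$time == t & records$event == 1 & g1)
    e1 <- d * n1 / n
    v <- if (n > 1) d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1) else 0
    w <- if (weighting == "wilcoxon") n else 1
    U <- U + w * (d1 - e1)
    Var <- Var + w^2 * v
    O1 <- O1 + d1; E1 <- E1 + e1
  }
  statistic <- if (Var > 0) U^2 / Var else 0
  p <- pchisq(statistic, df = 1, lower.tail = FALSE)
  total_events <- sum(records$event)
  structure(
    list(statistic = statistic, p_value = p, df = 1L,
         observed = stats::setNames(c(O1, total_events - O1), groups),
         expected = stats::setNames(c(E1, total_events - E1), groups),
         method = if (weighting == "logrank") "log-rank" else "Gehan-Wilcoxon"),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("<logrank_test> %s test: chi-square = %.4g on %d df, p = %.4g\n",
              x$method, x$statistic, x$df, x$p_value))
  cat(sprintf("  observed events: %s\n",
              paste(names(x$observed), x$observed, sep = " = ", collapse = ", ")))
  cat(sprintf("  expected events: %s\n",
              paste(names(x$expected), signif(x$expected, 4), sep = " = ",
                    collapse = ", ")))
  invisible(x)
}

#' @rdname logrank_test
#' @param x A `logrank_test` object.
#' @param ... Unused.
#' @method tidy logrank_test
#' @export
tidy.logrank_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, df = x$df,
         method = x$method)
}

#' @rdname logrank_test
#' @method glance logrank_test
#' @export
glance.logrank_test <- function(x, ...) tidy(x)
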