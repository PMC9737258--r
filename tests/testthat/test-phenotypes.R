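dose_table <- function(label, doses, viab) {
  tibble::tibble(label = label, dose_uM = doses, viability = viab)
}

test_that("resistance metric hits its extremes and the hand trapezoid", {
  d <- c(10, 100, 1000)
  expect_equal(resistance_metric(dose_table("a", d, c(1, 1, 1)))$resistance, 1)
  expect_equal(resistance_metric(dose_table("a", d, c(0, 0, 0)))$resistance, 0)
  # symmetric curve: trapezoid over log10 dose gives exactly 0.5
  expect_equal(resistance_metric(dose_table("a", d, c(0.9, 0.5, 0.1)))$resistance,
               0.5, tolerance = 1e-12)
})

test_that("dose-0 rows normalise and replicates average before integration", {
  base <- dose_table("a", c(10, 100, 1000), c(0.9, 0.5, 0.1))
  with_ctrl <- dose_table("a", c(0, 0, 10, 100, 1000),
                          2 * c(1, 1, 0.9, 0.5, 0.1))
  expect_equal(resistance_metric(with_ctrl)$resistance,
               resistance_metric(base)$resistance, tolerance = 1e-12)
  dup <- dplyr::bind_rows(base, base[2, ])  # duplicate one dose row
  expect_equal(resistance_metric(dup)$resistance,
               resistance_metric(base)$resistance, tolerance = 1e-12)
})

test_that("pointwise-higher viability never lowers the resistance metric", {
  withr::with_seed(12, {
    doses <- 10^runif(5, 1, 3)
    for (rep in 1:10) {
      v <- runif(5)
      v_hi <- pmin(v + runif(5, 0, 0.3), 1)
      lo <- resistance_metric(dose_table("a", doses, v))$resistance
      hi <- resistance_metric(dose_table("a", doses, v_hi))$resistance
      expect_gte(hi, lo)
    }
  })
})

test_that("negative doses are rejected", {
  expect_error(resistance_metric(dose_table("a", c(-1, 10, 100), c(1, 1, 1))),
               "dose_uM")
})

test_that("growth rate is exact on noiseless exponentials", {
  t <- c(0, 24, 48, 72)
  g <- tibble::tibble(label = "a", time_h = t, od = 0.3 * 2^(t / 24))
  expect_equal(growth_rate(g)$growth_rate, log(2) / 24, tolerance = 1e-12)
  flat <- tibble::tibble(label = "a", time_h = t, od = 0.4)
  expect_equal(growth_rate(flat)$growth_rate, 0, tolerance = 1e-12)
  withr::with_seed(6, {
    for (rate in c(0.003, 0.02, 0.08)) {
      tt <- sort(runif(6, 0, 96))
      gg <- tibble::tibble(label = "a", time_h = tt, od = 0.2 * exp(rate * tt))
      expect_equal(growth_rate(gg)$growth_rate, rate, tolerance = 1e-9)
    }
  })
})

test_that("growth rate matches the normal-equations oracle on noisy data", {
  withr::with_seed(42, {
    t <- seq(0, 72, by = 12)
    od <- 0.2 * exp(0.02 * t) * exp(rnorm(length(t), sd = 0.1))
    g <- tibble::tibble(label = "a", time_h = t, od = od)
    expect_equal(growth_rate(g)$growth_rate, oracle_ls_slope(t, log(od)),
                 tolerance = 1e-10)
  })
})

test_that("non-positive absorbances are dropped and sparse labels go missing", {
  g <- tibble::tibble(label = "a", time_h = c(0, 24, 48, 72),
                      od = c(0.2, 0, 0.3, 0.4))
  expect_warning(out <- growth_rate(g), "non-positive")
  expect_false(is.na(out$growth_rate))
  g2 <- tibble::tibble(label = "a", time_h = c(0, 24, 48), od = c(0.2, -1, 0.3))
  suppressWarnings(expect_warning(out2 <- growth_rate(g2), "fewer than 3"))
  expect_true(is.na(out2$growth_rate))
})

test_that("invasion change is the relative area change from 0 h to 72 h", {
  inv <- tibble::tibble(label = "a", time_h = c(0, 72), area_um2 = c(100, 300))
  expect_equal(invasion_change(inv)$invasion_change, 2)
  const <- tibble::tibble(label = "a", time_h = c(0, 24, 72),
                          area_um2 = c(500, 500, 500))
  expect_equal(invasion_change(const)$invasion_change, 0)
  zero <- tibble::tibble(label = "a", time_h = c(0, 72), area_um2 = c(0, 10))
  expect_warning(out <- invasion_change(zero), "zero starting area")
  expect_true(is.na(out$invasion_change))
})

test_that("invasion change from thresholded pixel counting matches a per-pixel oracle", {
  # synthetic invasion frames: a disk growing from radius 20 px to 35 px
  frame <- function(radius) {
    m <- matrix(0, 101, 101)
    paint <- function(i, j) sqrt((i - 51)^2 + (j - 51)^2) <= radius
    idx <- which(outer(1:101, 1:101, paint))
    m[idx] <- 1
    m
  }
  areas <- vapply(c(20, 35), function(r) sum(frame(r) > 0.5), numeric(1))
  inv <- tibble::tibble(label = "a", time_h = c(0, 72), area_um2 = areas)
  expect_equal(invasion_change(inv)$invasion_change,
               (areas[2] - areas[1]) / areas[1], tolerance = 1e-12)
})

test_that("rank_and_split shares ranking semantics and honours direction", {
  metrics <- tibble::tibble(label = sprintf("p%d", 1:8),
                            resistance = c(0.2, 0.9, 0.4, 0.7, 0.1, 0.8, 0.3, 0.6))
  rt <- rank_and_split(metrics)
  expect_identical(rt$rank, 1:8)
  expect_identical(rt$label[rt$rank == 1], "p5")
  rev_rt <- rank_and_split(metrics, direction = "descending")
  expect_identical(rev_rt$rank[match(rt$label, rev_rt$label)], 9L - rt$rank)
  expect_equal(rt$score, metrics$resistance[match(rt$label, metrics$label)])
})

test_that("a missing metric drops to a 7-row table split 4/3", {
  metrics <- tibble::tibble(label = sprintf("p%d", 1:8),
                            resistance = c(0.2, NA, 0.4, 0.7, 0.1, 0.8, 0.3, 0.6))
  expect_warning(rt <- rank_and_split(metrics), "p2")
  expect_equal(nrow(rt), 7)
  expect_equal(as.integer(table(rt$subgroup)), c(4L, 3L))
})

test_that("concordance matches hand fixtures and is symmetric", {
  mk <- function(labels, ranks, split = ceiling(length(ranks) / 2)) {
    tibble::tibble(label = labels, score = ranks, rank = as.integer(ranks),
                   subgroup = factor(ifelse(ranks <= split, "internal", "external"),
                                     levels = c("internal", "external")))
  }
  a <- mk(letters[1:8], 1:8)
  expect_equal(unlist(concordance(a, a)[1, 1:2]),
               c(spearman_rho = 1, group_agreement = 1))
  b <- mk(letters[1:8], 8:1)
  expect_equal(unlist(concordance(a, b)[1, 1:2]),
               c(spearman_rho = -1, group_agreement = 0))
  c1 <- mk(letters[1:4], 1:4)
  c2 <- mk(letters[1:4], c(2, 1, 3, 4))
  expect_equal(concordance(c1, c2)$spearman_rho, 0.8, tolerance = 1e-12)
  expect_equal(concordance(c1, c2)$spearman_rho,
               oracle_spearman(1:4, c(2, 1, 3, 4)), tolerance = 1e-12)
  expect_equal(concordance(c2, c1), concordance(c1, c2))
  expect_error(concordance(c1, mk(letters[2:5], 1:4)), "same set")
})

test_that("noiseless external-resistant coupling yields perfect subgroup agreement end-to-end", {
  scores <- tibble::tibble(label = sprintf("p%d", 1:8),
                           score = seq(1.2, 4.8, length.out = 8))
  spatial <- rank_populations(scores)
  tabs <- simulate_phenotypes(scores, noise_sd = 0, seed = 19)
  res_rank <- rank_and_split(resistance_metric(tabs$doses))
  cc <- concordance(spatial, res_rank)
  expect_equal(cc$spearman_rho, 1)
  expect_equal(cc$group_agreement, 1)
})
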