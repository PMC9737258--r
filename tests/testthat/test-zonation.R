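test_that("the well centre is the intensity-weighted centroid", {
  m <- matrix(0, 32, 32)
  m[11, 21] <- 1   # 0-based (y = 10, x = 20)
  ctr <- locate_well_center(multichannel_stack(m, "red"))
  expect_equal(ctr$y_um, 10)
  expect_equal(ctr$x_um, 20)
  expect_false(ctr$fallback)
})

test_that("an all-zero image falls back to the geometric centre with a flag", {
  ctr <- locate_well_center(multichannel_stack(matrix(0, 21, 41), "red"))
  expect_equal(ctr$y_um, 10)
  expect_equal(ctr$x_um, 20)
  expect_true(ctr$fallback)
})

test_that("a two-blob centroid matches the direct weighted-mean oracle", {
  withr::with_seed(31, {
    m <- matrix(0, 48, 64)
    m[5:9, 10:14] <- runif(25)
    m[30:40, 50:60] <- runif(121)
    stk <- multichannel_stack(array(m, dim = c(48, 64, 1, 1)), "red",
                              um_per_px = 0.8)
    ctr <- locate_well_center(stk)
    ref <- oracle_centroid(stk)
    expect_equal(ctr$y_um, ref[["y"]], tolerance = 1e-12)
    expect_equal(ctr$x_um, ref[["x"]], tolerance = 1e-12)
  })
})

test_that("zone binning is half-open with Zone 1 at the centre and a closed outer rim", {
  g <- well_geometry(diameter_um = 100, n_zones = 5, um_per_px = 1,
                     center_xy = c(y = 50, x = 50))
  mask <- zone_mask(g, c(101, 101))
  expect_identical(mask[51, 51], 1L)          # r = 0
  expect_identical(mask[51, 101], 5L)         # r = R exactly, closed outer bin
  expect_identical(mask[51, 61], 2L)          # r = 10 = R/5, half-open boundary
  expect_true(all(mask[1, ] %in% c(0L, 5L)))  # corners outside the well
  expect_identical(mask[1, 1], 0L)
})

test_that("equal-width zones reproduce the 1:3:5:7:9 annulus-area ratio", {
  g <- centered_geometry()
  counts <- tabulate(zone_mask(g, c(500, 500)), nbins = 5)
  theoretical <- pi * 250^2 * (2 * (1:5) - 1) / 25
  expect_true(all(abs(counts - theoretical) / theoretical < 0.01))
})

test_that("zone quantification matches the per-pixel oracle exactly on random fixtures", {
  withr::with_seed(17, {
    for (rep in 1:25) {
      ny <- sample(16:64, 1); nx <- sample(16:64, 1)
      nz <- sample(1:3, 1); nch <- sample(1:2, 1)
      stk <- random_stack(ny, nx, nz, nch)
      thr <- runif(1, 0.2, 0.8)
      g <- well_geometry(diameter_um = min(ny, nx) - 2, n_zones = sample(3:5, 1),
                         center_xy = c(y = (ny - 1) / 2, x = (nx - 1) / 2))
      prof <- suppressWarnings(quantify_zones(stk, g, threshold = thr))
      ref <- oracle_zone_counts(stk, g, rep(thr, nch))
      for (ch in stk$channel_names) {
        got <- prof$area_um2[prof$channel == ch]
        expect_identical(got, as.numeric(ref[[ch]][-1]))
        expect_identical(attr(prof, "outside_area_um2")[[ch]],
                         as.numeric(ref[[ch]][1]))
      }
    }
  })
})

test_that("signal confined to Zone I gives fractions (1, 0, 0, 0, 0)", {
  m <- matrix(0, 100, 100)
  m[49:53, 49:53] <- 1
  stk <- multichannel_stack(m, "red")
  g <- well_geometry(diameter_um = 99, center_xy = c(y = 49.5, x = 49.5))
  prof <- quantify_zones(stk, g, threshold = 0.5)
  expect_equal(prof$fraction, c(1, 0, 0, 0, 0))
  expect_equal(sum(prof$fraction), 1, tolerance = 1e-9)
})

test_that("zone profiles are invariant under quarter-turn rotations", {
  stk <- zone1_stack(seed = 13, n_cells = 300)
  pops <- tibble::tibble(label = "b", channel = "red", n_cells = 500,
                         placement = list(core_shell_placement(0.5, 0.9)))
  stk2 <- simulate_aggregate_image(pops, seed = 14)
  for (s in list(stk, stk2)) {
    prof <- quantify_zones(s, centered_geometry())
    rot <- s
    for (z in seq_len(dim(s$pixels)[3])) {
      rot$pixels[, , z, 1] <- t(apply(s$pixels[, , z, 1], 2, rev))
    }
    prof_rot <- quantify_zones(rot, centered_geometry())
    expect_equal(prof_rot$area_um2, prof$area_um2)
    expect_equal(prof_rot$fraction, prof$fraction)
  }
})

test_that("fractions sum to one per channel whenever signal exists", {
  withr::with_seed(23, {
    for (rep in 1:10) {
      stk <- random_stack(40, 40, nz = 2)
      prof <- suppressWarnings(quantify_zones(stk, threshold = 0.5))
      expect_equal(sum(prof$fraction), 1, tolerance = 1e-9)
    }
  })
})

test_that("a channel with no above-threshold pixels reports missing fractions, not zeros", {
  arr <- array(0, dim = c(30, 30, 1, 2))
  arr[15, 15, 1, 1] <- 1
  stk <- multichannel_stack(arr, c("red", "green"))
  g <- well_geometry(diameter_um = 29, center_xy = c(y = 14.5, x = 14.5))
  expect_warning(prof <- quantify_zones(stk, g, threshold = 0.5), "green")
  expect_true(all(is.na(prof$fraction[prof$channel == "green"])))
  expect_false(anyNA(prof$fraction[prof$channel == "red"]))
})

test_that("signal outside the outermost zone is reported and excluded from fractions", {
  m <- matrix(0, 40, 40)
  m[20, 20] <- 1   # inside
  m[1, 1] <- 1     # corner, outside the inscribed well
  stk <- multichannel_stack(m, "red")
  g <- well_geometry(diameter_um = 39, center_xy = c(y = 19.5, x = 19.5))
  expect_warning(prof <- quantify_zones(stk, g, threshold = 0.5), "outside")
  expect_equal(sum(prof$area_um2), 1)
  expect_equal(attr(prof, "outside_area_um2")[["red"]], 1)
})

test_that("doubling the resolution changes fractions by less than 0.01 on a smooth fixture", {
  render <- function(um_per_px) {
    n <- round(200 / um_per_px)
    g <- well_geometry(diameter_um = 200, um_per_px = um_per_px,
                      center_xy = c(y = (n - 1) / 2 * um_per_px,
                                    x = (n - 1) / 2 * um_per_px))
    pops <- tibble::tibble(label = "a", channel = "red", n_cells = 1500,
                           cell_radius_um = 3,
                           placement = list(core_shell_placement(0.6, 0.5)))
    stk <- simulate_aggregate_image(pops, geometry = g, z_slices = 6,
                                    noise_sd = 0, seed = 77)
    quantify_zones(stk, g)
  }
  f1 <- render(1)$fraction
  f2 <- render(0.5)$fraction
  expect_true(all(abs(f1 - f2) < 0.01))
})

test_that("translating signal radially outward never decreases the radial score", {
  base <- c(0.6, 0.3, 0.1, 0, 0)
  shifted <- c(0, 0.6, 0.3, 0.1, 0)   # same mass one zone further out
  render <- function(probs) {
    pops <- tibble::tibble(label = "a", channel = "red", n_cells = 1500,
                           placement = list(zone_placement(probs)))
    stk <- simulate_aggregate_image(pops, seed = 41)
    radial_score(quantify_zones(stk, centered_geometry()))$score
  }
  expect_gt(render(shifted), render(base))
})
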