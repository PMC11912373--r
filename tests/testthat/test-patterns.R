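test_that("the 1D band profile encodes its parameters exactly", {
  g0 <- make_band_1d(256, band_L = 0)
  expect_true(all(g0[region_labels(g0) == 4] == 1))
  g5 <- make_band_1d(256, band_L = 5)
  expect_equal(unique(g5[region_labels(g5) == 4]), exp(-0.05))
  expect_equal(unique(g5[region_labels(g5) == 3]), 0.5)
  expect_true(all(g5[region_labels(g5) %in% c(1, 2)] == 1))
  expect_error(make_band_1d(256, band_range = c(10, 40)), "overlap")
})

test_that("the boxes map has walls, interiors, and an exact hole", {
  g <- make_boxes_2d(c(64, 64), wall_thickness = 4)
  lab <- region_labels(g)
  expect_equal(unique(g[lab == 0]), 0.1)
  expect_true(all(g[lab %in% c(1, 2)] == 1))
  # intact middle wall: a contiguous block of wall columns
  mid_cols <- 64 %/% 2 - 2 + 0:3
  expect_true(all(g[, mid_cols] == 0.1))
  # hole restores exactly width x thickness sites
  gh <- make_boxes_2d(c(64, 64), wall_thickness = 4, hole = c(28, 35))
  expect_identical(sum(gh == 1) - sum(g == 1), 8L * 4L)
  expect_error(make_boxes_2d(c(64, 64), wall_thickness = 4, hole = c(2, 10)),
               "hole")
})

test_that("labyrinths are deterministic and split at the median", {
  m1 <- make_labyrinth(c(64, 64), seed = 3)
  m2 <- make_labyrinth(c(64, 64), seed = 3)
  expect_identical(m1, m2)
  expect_false(identical(m1, make_labyrinth(c(64, 64), seed = 4)))
  # without wall regularization a 0.5-quantile threshold is a median split
  raw <- make_labyrinth(c(64, 64), threshold_quantile = 0.5, min_wall = 0,
                        seed = 3)
  expect_equal(mean(raw), 0.5, tolerance = 2 / 64)
  expect_error(make_labyrinth(c(64, 64), band_low = 10, band_high = 5),
               "band")
})

test_that("gamma_from_mask maps regions to the requested values", {
  m <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  g <- gamma_from_mask(m, gamma_go = 1, gamma_nogo = 0.01)
  expect_identical(g[m], rep(1, 3))
  expect_identical(g[!m], 0.01)
  expect_error(gamma_from_mask(m, gamma_nogo = 0), "positive|> 0")
})

test_that("the annulus has a quarter gap, periodic angle, exact taper", {
  shape <- c(128, 128)
  g1 <- make_annulus(shape, c(18, 24), rotation_angle = 0.7)
  g2 <- make_annulus(shape, c(18, 24), rotation_angle = 0.7 + 2 * pi)
  expect_equal(g1, g2, tolerance = 1e-12)
  # sample the wall profile on a mid-radius circle: about a quarter is open
  th <- seq(0, 2 * pi, length.out = 720)[-1]
  r <- 21
  ri <- round((128 + 1) / 2 + r * cos(th))
  ci <- round((128 + 1) / 2 + r * sin(th))
  vals <- g1[cbind(ri, ci)]
  expect_equal(mean(vals > 0.55), 0.25, tolerance = 0.03)
  # taper endpoints: exactly the wall value on the lattice edge, exactly 1
  # at taper_width sites inward
  expect_equal(g1[1, 64], 0.1, tolerance = 1e-12)
  expect_equal(g1[10, 64], 1, tolerance = 1e-12)
  expect_error(make_annulus(c(32, 32), c(10, 20)), "fit")
})

test_that("flood fill matches the morphological oracle exactly", {
  set.seed(41)
  for (rep in 1:20) {
    m <- matrix(runif(24 * 24) < 0.55, 24, 24)
    seeds <- which(m, arr.ind = TRUE)
    s <- seeds[sample(nrow(seeds), 1), ]
    expect_identical(floodfill_oracle(m, s), dilation_fill(m, s))
  }
})

test_that("flood fill fills components and rejects no-go seeds", {
  m <- matrix(FALSE, 16, 16)
  m[3:6, 3:6] <- TRUE
  m[10:13, 10:13] <- TRUE
  f <- floodfill_oracle(m, c(4, 4))
  expect_identical(sum(f), 16L)
  expect_true(all(f[3:6, 3:6]))
  lab <- label_components(m)
  expect_identical(sort(unique(as.vector(lab))), c(0L, 1L, 2L))
  # fully connected go region fills entirely
  full <- matrix(TRUE, 8, 8)
  expect_true(all(floodfill_oracle(full, c(1, 1))))
  expect_error(floodfill_oracle(m, c(1, 1)), "no-go")
})

test_that("1D flood fill respects the periodic boundary", {
  m <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE)
  f <- floodfill_oracle(m, 1)
  expect_identical(which(f), c(1L, 2L, 8L))
})

test_that("filled-region detection shrinks monotonically in the threshold", {
  set.seed(42)
  amp <- matrix(runif(100), 10, 10)
  comp <- matrix(TRUE, 10, 10)
  d1 <- detect_filled_region(amp, comp, 0.2)
  d2 <- detect_filled_region(amp, comp, 0.6)
  d3 <- detect_filled_region(amp, comp, 0.95)
  expect_true(all(d2 <= d1))
  expect_true(all(d3 <= d2))
  expect_error(detect_filled_region(matrix(0, 4, 4), matrix(TRUE, 4, 4)),
               "zero")
})

test_that("frequency maps recover a uniform rotation and mask silence", {
  Zb <- rcfield(c(16, 16), seed = 43)
  omega <- 0.011
  Za <- exp(1i * omega * 200) * Zb
  f <- frequency_map(Za, Zb, 200)
  expect_equal(f, matrix(omega, 16, 16), tolerance = 1e-12)
  Zb[3, 3] <- 0
  expect_true(is.na(frequency_map(Za, Zb, 200)[3, 3]))
})

test_that("wall margins mark exactly the sites near the no-go region", {
  m <- matrix(TRUE, 9, 9)
  m[5, 5] <- FALSE
  w <- wall_margin(m, 1)
  expect_identical(sum(w), 4L)  # 4-neighbors of the single no-go site
  expect_true(all(w[cbind(c(4, 6, 5, 5), c(5, 5, 4, 6))]))
})

test_that("synchrony summary separates locked and unlocked domains", {
  lab <- matrix(0L, 20, 20)
  lab[2:9, 2:9] <- 1L
  lab[12:19, 12:19] <- 2L
  set.seed(44)
  freq <- matrix(NA_real_, 20, 20)
  freq[lab == 1] <- 0.010 + rnorm(64, sd = 1e-5)   # locked domain
  freq[lab == 2] <- -0.008 + rnorm(64, sd = 1e-5)  # locked, far frequency
  s <- synchrony_summary(freq, lab, lag = 50, min_size = 50)
  expect_identical(nrow(s$domains), 2L)
  expect_equal(s$frac_synchronized, 1)
  expect_error(synchrony_summary(freq, matrix(1L, 20, 20), 50, min_size = 500),
               "two domains")
})
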