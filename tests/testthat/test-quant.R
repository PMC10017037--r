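test_that("line profiles average correctly and respect image bounds", {
  img <- matrix(3.7, 64, 64)
  p <- line_profile(img, c(32, 32), c(1, 0), 600, width_px = 5)
  expect_true(all(abs(p$intensity - 3.7) < 1e-12))
  expect_equal(length(p$position_nm), 2 * floor(600 / 34) + 1)

  # band perpendicular to the profile: single max at the band centre
  img2 <- matrix(0, 64, 64)
  img2[30:32, ] <- 1   # band centred on 0-based x = 30
  p2 <- line_profile(img2, c(30, 32), c(1, 0), 800, width_px = 9)
  plateau <- p2$position_nm[p2$intensity > max(p2$intensity) - 1e-9]
  expect_lt(abs(mean(plateau)), 17 / 2 + 1e-9)

  expect_error(line_profile(img, c(2, 32), c(1, 0), 600), "bounds")
})

test_that("width averaging reduces profile variance like a mean", {
  set.seed(11)
  v1 <- numeric(100); v25 <- numeric(100)
  for (k in 1:100) {
    im <- matrix(rnorm(120 * 120), 120)
    v1[k] <- var(line_profile(im, c(60, 60), c(1, 0), 1000, 1)$intensity)
    v25[k] <- var(line_profile(im, c(60, 60), c(1, 0), 1000, 25)$intensity)
  }
  expect_equal(mean(v25) / mean(v1), 1 / 25, tolerance = 0.2)
})

test_that("fwhm matches the analytic Gaussian width and is invariant", {
  xs <- seq(-120, 120, by = 4)
  prof <- list(position_nm = xs, intensity = dnorm(xs, sd = 10))
  expect_equal(fwhm(prof), 2.354820045 * 10, tolerance = 0.01)
  # intensity scaling and offset leave it unchanged
  prof2 <- list(position_nm = xs, intensity = 7 + 3 * prof$intensity)
  expect_equal(fwhm(prof2), fwhm(prof), tolerance = 1e-9)
  # monotonic profile has no interior maximum
  expect_error(fwhm(list(position_nm = xs, intensity = seq_along(xs))),
               "maximum")
})

test_that("ring diameters are recovered to sub-pixel accuracy", {
  tr <- ground_truth(size_px = 128,
                     geometry = list(ring_diameters_nm = list(r = 1210)))
  img <- render_rings(tr)$channels$r
  expect_lt(abs(ring_diameter(img) - 1210), 8.5)
  # translation by whole pixels leaves the diameter unchanged
  img_sh <- matrix(0, 128, 128)
  img_sh[9:128, 5:128] <- img[1:120, 1:124]
  expect_equal(ring_diameter(img_sh), ring_diameter(img), tolerance = 1e-6)
  expect_error(ring_diameter(matrix(0, 64, 64)), "blank")
})

test_that("two-channel diameter offsets recover the planted 40 nm", {
  offs <- vapply(1:6, function(k) {
    tr <- ground_truth(size_px = 128, poisson = TRUE, seed = 400 + k,
                       geometry = list(ring_diameters_nm =
                                         list(inner = 1210, outer = 1250)))
    unname(channel_offset(render_rings(tr))[1])
  }, numeric(1))
  expect_lt(abs(mean(offs) - 40), 10)
})

test_that("cytoplasmic fraction validates masks", {
  img <- matrix(1, 32, 32)
  cell <- matrix(TRUE, 32, 32)
  expect_error(cytoplasmic_fraction(img, cell, cell), "cytoplasm")
  ring_out <- matrix(FALSE, 32, 32); ring_out[1, 1] <- TRUE
  cell2 <- matrix(FALSE, 32, 32); cell2[10:20, 10:20] <- TRUE
  expect_error(cytoplasmic_fraction(img, cell2, ring_out), "outside")
})

test_that("cytoplasmic means compare across conditions", {
  mk <- function(f, seed) {
    tr <- ground_truth(size_px = 128, poisson = TRUE, seed = seed,
                       geometry = list(ring_fraction = f,
                                       cell_diameter_nm = 1800,
                                       ring_diameter_nm = 1000))
    s <- render_cell(tr)
    cytoplasmic_fraction(s$channels$cell, s$cell_mask, s$ring_mask, 3)
  }
  lo <- mk(1 - 1 / 6, 21)$cytoplasm_mean   # cytoplasm carries 1/6
  hi <- mk(1 - 5 / 6, 22)$cytoplasm_mean   # cytoplasm carries 5/6
  expect_equal(hi / lo, 5, tolerance = 0.1 * 5)
})

test_that("constriction rates are exact on linear series", {
  for (slope in c(0.05, 0.11, 0.2, 0.5)) {
    t <- seq(0, 0.9 / slope, length.out = 25)
    r <- constriction_rate(t, 1 - slope * t)
    expect_equal(r$rate, slope, tolerance = 1e-10)
  }
  expect_error(constriction_rate(c(0, 1), c(1, 0.5)), "3 frames")
})

test_that("mean rate over noisy series recovers the planted rate", {
  mk <- function(seed, rate) {
    tr <- ground_truth(seed = seed, geometry = list(
      start_diameter_um = 1, rate_um_min = rate, noise_sd_um = 0.03))
    render_timelapse(tr, n_frames = 40, frame_interval_s = 15)
  }
  est <- constriction_rate_multi(lapply(1:50, mk, rate = 0.11))
  expect_lt(abs(est$mean_rate - 0.11), 0.01)
  expect_identical(est$n_cells, 50L)
})

test_that("abscission scoring counts exactly", {
  expect_equal(abscission_curve(c(1, 2, 3), 20)$fraction_within, 100)
  expect_equal(abscission_curve(c(25, 40), 20)$fraction_within, 0)
  set.seed(8)
  times <- rexp(200, rate = 1 / 12)
  res <- abscission_curve(times, 20)
  expect_equal(res$fraction_within, 100 * sum(times <= 20) / 200)
  expect_equal(max(res$curve$cumulative_percent),
               100 * mean(is.finite(times)))
  # censored cells count in the denominator
  expect_equal(abscission_curve(c(5, NA, NA, NA), 20)$fraction_within, 25)
  expect_error(abscission_curve(numeric(0)), "empty")
})
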