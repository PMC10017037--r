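test_that("a noiseless point emitter peaks at its pixel and conserves flux", {
  tr <- ground_truth(psf_fwhm_nm = 30, size_px = 65,
                     geometry = list(point_emitter = TRUE))
  img <- render_rings(tr)$channels[[1]]
  mx <- which(img == max(img), arr.ind = TRUE)
  expect_equal(unname(mx[1, ]), c(33, 33))  # centre pixel of a 65-px field
  expect_equal(sum(img), tr$photon_budget, tolerance = 1e-6)
})

test_that("a face-on ring peaks radially at half its diameter", {
  tr <- ground_truth(size_px = 128,
                     geometry = list(ring_diameters_nm = list(ring = 1210)))
  img <- render_rings(tr)$channels$ring
  expect_equal(sum(img), tr$photon_budget, tolerance = 1e-6)
  d <- ring_diameter(img, pixel_nm = tr$pixel_nm)
  expect_lt(abs(d - 1210), 2 * tr$pixel_nm / 2)  # within a pixel on diameter
})

test_that("rings larger than the field are rejected", {
  tr <- ground_truth(size_px = 32,
                     geometry = list(ring_diameters_nm = list(ring = 1210)))
  expect_error(render_rings(tr), "field of view")
})

test_that("two bands separated by 3 PSF widths resolve into two maxima", {
  bands <- data.frame(channel = "a", position_nm = c(-45, 45),
                      width_nm = 20)
  tr <- ground_truth(size_px = 65, psf_fwhm_nm = 30,
                     geometry = list(bands = bands))
  img <- render_rings(tr)$channels[[1]]
  p <- line_profile(img, anchor = c(32, 32), direction = c(1, 0),
                    length_nm = 600, width_px = 15, pixel_nm = 17)
  y <- p$intensity
  interior <- 2:(length(y) - 1)
  n_max <- sum(y[interior] > y[interior - 1] & y[interior] > y[interior + 1] &
                 y[interior] > max(y) / 4)
  expect_identical(n_max, 2L)
})

test_that("time-lapse diameters decrease linearly and floor at zero", {
  tr <- ground_truth(seed = 5, geometry = list(
    start_diameter_um = 1, rate_um_min = 0.3, noise_sd_um = 0))
  tl <- render_timelapse(tr, n_frames = 20, frame_interval_s = 15)
  expect_equal(tl$diameter_um,
               pmax(1 - 0.3 * (0:19) * 15 / 60, 0), tolerance = 1e-12)
  expect_true(all(tl$diameter_true_um[tl$time_min > 1 / 0.3] == 0))

  trn <- ground_truth(seed = 5, geometry = list(
    start_diameter_um = 1, rate_um_min = 0.1, noise_sd_um = 0.05))
  a <- render_timelapse(trn, 20, 15)
  b <- render_timelapse(trn, 20, 15)
  expect_identical(a$diameter_um, b$diameter_um)  # seeded determinism
  trn2 <- trn; trn2$seed <- 6L
  c2 <- render_timelapse(trn2, 20, 15)
  expect_false(identical(a$diameter_um, c2$diameter_um))
})

test_that("noise application is seeded and deterministic", {
  tr <- ground_truth(size_px = 64, poisson = TRUE, read_sd = 2, seed = 9,
                     geometry = list(ring_diameters_nm = list(r = 600)))
  a <- render_rings(tr)$channels$r
  b <- render_rings(tr)$channels$r
  expect_identical(a, b)
})

test_that("cell renderer splits the budget between ring and cytoplasm", {
  mk <- function(f) render_cell(ground_truth(size_px = 128, geometry = list(
    ring_fraction = f, cell_diameter_nm = 1800, ring_diameter_nm = 1000)))
  all_ring <- mk(1)
  cf1 <- cytoplasmic_fraction(all_ring$channels$cell, all_ring$cell_mask,
                              all_ring$ring_mask, dilate_px = 3)
  expect_lte(cf1$cytoplasmic_share, 0.02)

  no_ring <- mk(0)
  cf0 <- cytoplasmic_fraction(no_ring$channels$cell, no_ring$cell_mask,
                              no_ring$ring_mask, dilate_px = 3)
  expect_equal(cf0$ring_mean, cf0$cytoplasm_mean,
               tolerance = 0.05 * cf0$cytoplasm_mean)

  planted <- mk(0.3)
  cf <- cytoplasmic_fraction(planted$channels$cell, planted$cell_mask,
                             planted$ring_mask, dilate_px = 3)
  expect_equal(cf$cytoplasmic_share, 0.7, tolerance = 0.02)
  expect_equal(sum(planted$channels$cell),
               planted$truth$photon_budget, tolerance = 1e-6)
})

test_that("image sets round-trip to TIFF with a JSON truth sidecar", {
  tr <- ground_truth(size_px = 32, seed = 3,
                     geometry = list(ring_diameters_nm = list(r = 300)))
  set <- render_rings(tr)
  path <- file.path(tempdir(), "rings.tif")
  write_image_set(set, path)
  expect_true(file.exists(path))
  sidecar <- sub("\\.tiff?$", ".json", path)
  expect_true(file.exists(sidecar))
  truth <- jsonlite::read_json(sidecar)
  expect_equal(truth$pixel_nm, 17)
  img <- tiff::readTIFF(path, all = TRUE)
  expect_length(img, 1)
})
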