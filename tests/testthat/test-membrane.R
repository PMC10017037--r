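test_that("tube construction tiles the cylinder correctly", {
  m <- init_tube_membrane(17, 68, 1.05)
  rad <- sqrt(m$positions[, 1]^2 + m$positions[, 2]^2)
  expect_equal(mean(rad), 17, tolerance = 0.1 / 17)

  expected_n <- round(2 * pi * 17 * 68 / 1.05^2)
  expect_lt(abs(nrow(m$positions) - expected_n) / expected_n, 0.05)

  rhat <- cbind(m$positions[, 1], m$positions[, 2], 0)
  rhat <- rhat / sqrt(rowSums(rhat^2))
  expect_gt(mean(rowSums(m$directors * rhat)), 0.99)
  expect_lt(max(abs(rowSums(m$directors^2) - 1)), 1e-9)
})

test_that("tube construction rejects bad geometry", {
  expect_error(init_tube_membrane(5, 30, particle_spacing = 6),
               "under-resolved")
  expect_error(init_tube_membrane(8, 20, 1), "4x")
})

test_that("membrane pair energy has the documented shape", {
  p <- membrane_params()
  mk <- function(pos, dir) list(pos = pos, dir = dir / sqrt(sum(dir^2)))
  # beyond cutoff: exactly zero
  e <- membrane_pair_energy(mk(c(0, 0, 0), c(0, 0, 1)),
                            mk(c(p$r_cut + 0.01, 0, 0), c(0, 0, 1)), p)
  expect_identical(e, 0)
  # global pair minimum: r_min apart, parallel directors perpendicular to
  # the separation
  e0 <- membrane_pair_energy(mk(c(0, 0, 0), c(0, 0, 1)),
                             mk(c(p$r_min, 0, 0), c(0, 0, 1)), p)
  expect_equal(e0, -p$epsilon, tolerance = 1e-12)
  # any misalignment or stretch raises it
  e_tilt <- membrane_pair_energy(mk(c(0, 0, 0), c(0, 0, 1)),
                                 mk(c(p$r_min, 0, 0), c(0.3, 0, 1)), p)
  e_far <- membrane_pair_energy(mk(c(0, 0, 0), c(0, 0, 1)),
                                mk(c(p$r_min * 1.3, 0, 0), c(0, 0, 1)), p)
  expect_gt(e_tilt, e0)
  expect_gt(e_far, e0)
  # coincident particles are singular
  expect_error(membrane_pair_energy(mk(c(0, 0, 0), c(0, 0, 1)),
                                    mk(c(0, 0, 0), c(0, 0, 1)), p),
               "coincident")
})

test_that("membrane pair energy is frame invariant", {
  p <- membrane_params()
  set.seed(4)
  for (k in 1:5) {
    x1 <- rnorm(3); x2 <- x1 + c(1.2, 0.3, 0.1)
    d1 <- rnorm(3); d1 <- d1 / sqrt(sum(d1^2))
    d2 <- rnorm(3); d2 <- d2 / sqrt(sum(d2^2))
    e0 <- membrane_pair_energy(list(pos = x1, dir = d1),
                               list(pos = x2, dir = d2), p)
    rot <- random_rotation(k)
    sh <- rnorm(3, sd = 4)
    e1 <- membrane_pair_energy(
      list(pos = drop(rot %*% x1) + sh, dir = drop(rot %*% d1)),
      list(pos = drop(rot %*% x2) + sh, dir = drop(rot %*% d2)), p)
    expect_equal(e1, e0, tolerance = 1e-9)
  }
})

test_that("adhesion prefers the target tilt and vanishes beyond range", {
  sp0 <- adhesion_spec(strength = 6, range = 2, tilt_target = 0)
  mem <- list(pos = c(0, 0, 0), dir = c(0, 0, 1))
  at_angle <- function(psi_deg, spec) {
    # bead below the membrane particle at contact distance; director at
    # angle psi from the inward membrane normal (-z is "facing")
    psi <- psi_deg * pi / 180
    bead <- list(pos = c(0, 0, -1), dir = c(sin(psi), 0, -cos(psi)))
    adhesion_energy(bead, mem, spec)
  }
  # face-on contact minimises the untilted adhesion over orientations
  angles <- seq(0, 180, by = 10)
  es <- vapply(angles, at_angle, numeric(1), spec = sp0)
  expect_equal(which.min(es), 1L)
  # the 40-degree species prefers 40 over both 0 and 80
  sp40 <- adhesion_spec(strength = 6, range = 2, tilt_target = 40)
  expect_lt(at_angle(40, sp40), at_angle(0, sp40))
  expect_lt(at_angle(40, sp40), at_angle(80, sp40))
  # zero beyond range
  far <- list(pos = c(0, 0, -2.5), dir = c(0, 0, 1))
  expect_identical(adhesion_energy(far, mem, sp0), 0)
})

test_that("a free tube neither collapses nor ruptures at working temperature", {
  cfg <- simulation_config(
    tube_radius = 6, tube_length = 24, n_steps = 4000, snap_every = 4000,
    arrangement = data.frame(species = character(0),
                             axial_offset = numeric(0),
                             phase = numeric(0)))
  st <- assemble_state(cfg)
  n0 <- nrow(st$membrane$positions)
  st <- step_state(st, 4000, seed = 21)
  expect_identical(nrow(st$membrane$positions), n0)  # conservation
  r <- cdvsim:::tube_mean_radius(st$membrane$positions)
  expect_lt(abs(r - 6) / 6, 0.10)
})
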