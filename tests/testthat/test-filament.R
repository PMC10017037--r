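test_that("helical construction subtends the requested turn angle", {
  for (loops in c(0.5, 1.0, 1.05, 2.0)) {
    spec <- filament_preset("cdvb2", loops = loops)
    f <- build_helical_filament(spec, tube_radius = 8)
    expect_equal(filament_turn_angle(f), loops * 360, tolerance = 3e-4)
  }
})

test_that("a full planar loop closes and beads sit on the cylinder", {
  spec <- filament_preset("cdvb2", loops = 1, preferred_pitch = 0)
  f <- build_helical_filament(spec, tube_radius = 10)
  gap <- sqrt(sum((f$beads[1, ] - f$beads[nrow(f$beads), ])^2))
  expect_lte(gap, spec$bead_spacing)

  f17 <- build_helical_filament(filament_preset("cdvb"), tube_radius = 17)
  rad <- sqrt(f17$beads[, 1]^2 + f17$beads[, 2]^2)
  expect_true(all(abs(rad - 17) < 1e-6))
})

test_that("construction validates inputs and bead spacing", {
  spec <- filament_preset("cdvb2")
  expect_error(build_helical_filament(spec, tube_radius = -1), "tube_radius")
  tiny <- filament_preset("cdvb2", loops = 0.05, bead_spacing = 2)
  expect_error(build_helical_filament(tiny, tube_radius = 1), "3 beads")

  f <- build_helical_filament(spec, tube_radius = 8)
  bl <- sqrt(rowSums(diff(f$beads)^2))
  expect_true(all(abs(bl - spec$bead_spacing) < 0.2 * spec$bead_spacing))
  # orthonormal frames
  fr <- f$frames
  expect_lt(max(abs(rowSums(fr$tangent * fr$director))), 1e-9)
  expect_lt(max(abs(rowSums(fr$tangent^2) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(fr$binormal^2) - 1)), 1e-9)
})

test_that("rest geometry matches the inscribed-polygon closed form", {
  # chord 1 sigma on a circle of radius 4 sigma: interior angle of the
  # inscribed polygon is pi - 2*asin(chord / (2*radius))
  spec <- filament_spec("x", preferred_radius = 40, preferred_pitch = 0,
                        bead_spacing = 1, bond_stiffness = 250)
  rg <- rest_geometry(spec)
  # rest chord implied by the same discretisation
  n_bonds <- rg$n_bonds
  dphi <- spec$loops * 2 * pi / n_bonds
  chord <- 2 * 4 * sin(dphi / 2)
  expect_equal(rg$rest_length, chord, tolerance = 1e-12)
  expect_equal(rg$rest_angle, pi - 2 * asin(chord / (2 * 4)),
               tolerance = 1e-9)
  expect_equal(rg$rest_dihedral, 0, tolerance = 1e-12)

  straight <- filament_spec("x", preferred_radius = Inf)
  expect_equal(rest_geometry(straight)$rest_angle, pi)
})

test_that("zero tilt keeps the binding director in the curvature plane", {
  spec <- filament_preset("cdvb2", preferred_pitch = 0, tilt = 0)
  f <- build_helical_filament(spec, tube_radius = 6)
  # planar circle in xy: curvature plane is xy, so directors have no z
  expect_lt(max(abs(f$directors[, 3])), 1e-9)
})

test_that("energy vanishes at the preferred geometry for random specs", {
  set.seed(42)
  for (k in 1:8) {
    spec <- filament_spec("x",
                          preferred_radius = runif(1, 30, 150),
                          preferred_pitch = runif(1, 0, 20),
                          tilt = runif(1, -45, 45),
                          bond_stiffness = runif(1, 20, 300),
                          loops = runif(1, 0.6, 1.6))
    a <- spec$preferred_radius / spec$us$sigma_nm
    f <- build_helical_filament(spec, tube_radius = a)
    e <- filament_energy(f, spec)
    expect_lt(e$total, 1e-8)
    expect_gte(e$stretch, 0)
    expect_gte(e$bend, 0)
    expect_equal(e$total, e$stretch + e$bend + e$twist_tilt)
  }
})

test_that("stretch energy is harmonic and scales with bond stiffness", {
  stretch_of <- function(k_bond, delta) {
    spec <- filament_spec("x", preferred_radius = 40, preferred_pitch = 0,
                          bond_stiffness = k_bond)
    f <- build_helical_filament(spec, tube_radius = 4)
    n <- nrow(f$beads)
    u <- f$beads[n, ] - f$beads[n - 1, ]
    f$beads[n, ] <- f$beads[n, ] + delta * u / sqrt(sum(u^2))
    filament_energy(f, spec)$stretch
  }
  expect_equal(stretch_of(250, 0.2) / stretch_of(250, 0.1), 4,
               tolerance = 1e-9)
  expect_equal(stretch_of(250, 0.1) / stretch_of(50, 0.1), 5,
               tolerance = 1e-9)
})

test_that("energy is invariant under rigid motions", {
  spec <- filament_preset("cdvb1")
  f <- perturb_filament(build_helical_filament(spec, 8), 0.1, 7)
  e0 <- filament_energy(f, spec)$total
  for (k in 1:5) {
    fm <- rigid_move(f, random_rotation(k), rnorm(3, sd = 5))
    expect_equal(filament_energy(fm, spec)$total, e0,
                 tolerance = 1e-8)
  }
})

test_that("energy requires matching species", {
  f <- build_helical_filament(filament_preset("cdvb2"), 8)
  expect_error(filament_energy(f, filament_preset("cdvb1")),
               "species mismatch")
})

test_that("analytic elastic gradient matches finite differences", {
  set.seed(3)
  spec <- filament_spec("x", preferred_radius = 50, bond_stiffness = 120,
                        bend_stiffness = 90, twist_stiffness = 40)
  f <- perturb_filament(build_helical_filament(spec, 6), 0.15, 5)
  pos <- f$beads[1:10, ]
  g <- cdvsim:::filament_positional_gradient(pos, spec)
  h <- 1e-6
  for (i in c(1, 4, 7)) for (j in 1:3) {
    pp <- pos; pp[i, j] <- pp[i, j] + h
    pm <- pos; pm[i, j] <- pm[i, j] - h
    num <- (cdvsim:::filament_positional_energy(pp, spec) -
            cdvsim:::filament_positional_energy(pm, spec)) / (2 * h)
    expect_equal(g[i, j], num, tolerance = 1e-4)
  }
})

test_that("R and compiled elastic energies agree", {
  spec <- filament_preset("cdvb1")
  rg <- rest_geometry(spec)
  for (seed in 1:3) {
    f <- perturb_filament(build_helical_filament(spec, 8), 0.15, seed)
    eR <- cdvsim:::filament_positional_energy(f$beads, spec)
    eC <- cdvsim:::.cpp_filament_eg(f$beads, spec$bond_stiffness,
                                    rg$rest_length, spec$bend_stiffness,
                                    rg$rest_angle, spec$twist_stiffness,
                                    rg$rest_dihedral)$energy
    expect_equal(eR, eC, tolerance = 1e-10)
  }
})

test_that("circle fit recovers exact and noisy radii and rejects lines", {
  for (r in c(2, 5, 10, 20)) {
    th <- seq(0, 2 * pi, length.out = 65)[-65]
    pts <- cbind(r * cos(th), r * sin(th), 0)
    expect_equal(fit_circle_radius(pts), r * 10, tolerance = 1e-9)
  }
  set.seed(9)
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  pts <- cbind(4 * cos(th), 4 * sin(th), 0) +
    matrix(rnorm(192, sd = 0.05), 64, 3)
  expect_equal(fit_circle_radius(pts), 40, tolerance = 0.02 * 40)
  expect_error(fit_circle_radius(cbind(1:3, 1:3, 1:3)), "collinear")
})

test_that("spec validation and YAML round trip", {
  expect_error(filament_spec("x", preferred_radius = -1), "preferred_radius")
  expect_error(filament_spec("x", 40, tilt = 120), "tilt")
  expect_error(filament_spec("x", 40, bond_stiffness = -5), "bond_stiffness")
  sp <- filament_preset("cdvb1")
  txt <- write_filament_spec(sp)
  sp2 <- read_filament_spec(txt)
  expect_equal(sp2$preferred_radius, 65)
  expect_equal(sp2$tilt, 40)
  expect_equal(sp2$bond_stiffness, 50)
})

test_that("preset parameters carry the published model values", {
  expect_equal(filament_preset("cdvb")$preferred_radius, 170)
  expect_equal(filament_preset("cdvb1")$preferred_radius, 65)
  expect_equal(filament_preset("cdvb2")$preferred_radius, 40)
  expect_equal(filament_preset("cdvb")$bond_stiffness, 250)
  expect_equal(filament_preset("cdvb2")$bond_stiffness, 250)
  expect_equal(filament_preset("cdvb1")$bond_stiffness, 50)
  expect_equal(filament_preset("cdvb1")$tilt, 40)
  expect_equal(filament_preset("cdvb")$loops, 1.05)
})
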