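# analysers exercised on hand-built trajectories with known structure

fake_traj <- function(bead_z_by_species, L = 40, R = 8, n_snaps = 1) {
  snaps <- lapply(seq_len(n_snaps), function(k) {
    list(time = k, membrane = matrix(0, 0, 3),
         beads = lapply(bead_z_by_species, function(z)
           cbind(0, 0, z)))
  })
  list(snapshots = snaps, config = list(tube_length = L, tube_radius = R))
}

test_that("axial density localises and normalises correctly", {
  tr <- fake_traj(list(A = rep(13.1, 50)))
  p <- axial_density(tr, "A", n_bins = 10)
  expect_equal(max(p$density), 1)
  expect_identical(sum(p$density > 0), 1L)
  expect_identical(which.max(p$density), 4L)  # bin covering z = 13.1 of 40

  pint <- axial_density(tr, "A", n_bins = 10, normalize = "integral")
  expect_equal(sum(pint$density) * pint$bin_width, 1, tolerance = 1e-9)

  expect_error(axial_density(tr, "B", 10), "absent")
})

test_that("uniform beads give flat density within multinomial noise", {
  set.seed(2)
  n <- 4000; nb <- 8
  tr <- fake_traj(list(A = runif(n, 0, 40)))
  p <- axial_density(tr, "A", n_bins = nb, normalize = "integral")
  counts <- p$density * n * p$bin_width
  expected <- n / nb
  sd_mult <- sqrt(n * (1 / nb) * (1 - 1 / nb))
  expect_true(all(abs(counts - expected) < 3 * sd_mult))
})

test_that("replicate aggregation returns per-bin mean and dispersion", {
  mk <- function(dens) structure(
    list(bin_centers = c(1, 2, 3), density = dens, species = "A",
         bin_width = 1, n_snapshots = 1, normalize = "peak"),
    class = "cdv_density_profile")
  agg <- aggregate_density(list(mk(c(0, 1, 0)), mk(c(0, 0, 1))))
  expect_equal(agg$mean, c(0, 0.5, 0.5))
  expect_equal(agg$sd, c(0, 0.5, 0.5))
  expect_identical(agg$n_replicates, 2L)
  expect_error(aggregate_density(list(mk(c(0, 1, 0)), structure(
    list(bin_centers = c(1, 2, 4), density = c(0, 1, 0)),
    class = "cdv_density_profile"))), "mismatched")
})

test_that("separation score is an overlap with the documented anchors", {
  mk <- function(dens) structure(
    list(bin_centers = seq_along(dens), density = dens),
    class = "cdv_density_profile")
  a <- mk(c(0, 2, 3, 1, 0, 0, 0, 0))
  expect_equal(separation_score(a, a), 1)
  b <- mk(c(0, 0, 0, 0, 0, 1, 2, 1))
  expect_equal(separation_score(a, b), 0)
  expect_equal(separation_score(b, a), 0)  # symmetric
  # two unit boxes overlapping over half their width
  box1 <- mk(c(1, 1, 1, 1, 0, 0) / 4)
  box2 <- mk(c(0, 0, 1, 1, 1, 1) / 4)
  expect_equal(separation_score(box1, box2), 0.5)
  # symmetry on random profiles
  set.seed(7)
  for (k in 1:10) {
    x <- mk(runif(12)); y <- mk(runif(12))
    expect_equal(separation_score(x, y), separation_score(y, x))
    expect_gte(separation_score(x, y), 0)
    expect_lte(separation_score(x, y), 1)
  }
})

test_that("constriction traces find planted necks", {
  # perfect cylinder: min radius R, no necks
  cyl <- modulated_tube_traj(function(z) rep(8, length(z)))
  tr <- constriction_trace(cyl, n_bins = 20)
  expect_equal(tr$trace$min_radius, 8, tolerance = 1e-9)
  expect_identical(tr$trace$neck_count, 0L)

  # hourglass with one cosine minimum at z = 20 (depth 0.5 R)
  hour <- modulated_tube_traj(function(z) 8 - 4 * cos(2 * pi * z / 40)^2 *
                                (abs(z - 20) < 10))
  hour <- modulated_tube_traj(function(z) 8 - 4 * exp(-(z - 20)^2 / 18))
  tr1 <- constriction_trace(hour, n_bins = 20)
  expect_identical(tr1$trace$neck_count, 1L)
  expect_lt(abs(tr1$neck_positions[[1]] - 20), 2.5)

  # two planted necks at z = 10 and z = 30
  dbl <- modulated_tube_traj(function(z)
    8 - 4 * exp(-(z - 10)^2 / 8) - 4 * exp(-(z - 30)^2 / 8))
  tr2 <- constriction_trace(dbl, n_bins = 20)
  expect_identical(tr2$trace$neck_count, 2L)
  expect_equal(sort(tr2$neck_positions[[1]]), c(10, 30), tolerance = 2.5)
})

test_that("an empty axial bin flags rupture and truncates the trace", {
  gap <- modulated_tube_traj(function(z) rep(8, length(z)))
  mem <- gap$snapshots[[1]]$membrane
  keep <- mem[, 3] < 18 | mem[, 3] > 22
  gap$snapshots[[1]]$membrane <- mem[keep, ]
  tr <- constriction_trace(gap, n_bins = 20)
  expect_true(tr$ruptured)
  expect_null(tr$trace)
})
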