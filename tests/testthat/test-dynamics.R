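# integrator and protocol behaviour on small systems

test_that("zero temperature at a pair minimum leaves positions unchanged", {
  # two membrane particles at the pair minimum: no net force or torque
  cfg <- simulation_config(
    tube_radius = 8, tube_length = 32, temperature = 0,
    arrangement = data.frame(species = character(0),
                             axial_offset = numeric(0),
                             phase = numeric(0)))
  p <- membrane_params()
  mem_x <- rbind(c(0, 0, 10), c(p$r_min, 0, 10))
  mem_n <- rbind(c(0, 0, 1), c(0, 0, 1))
  res <- cdvsim:::.cpp_langevin_run(
    mem_x, mem_n, matrix(0, 0, 3), matrix(0, 0, 3), integer(0), integer(0),
    matrix(0, 1, 10), cdvsim:::mem_params_vec(p), 32, 1e-3, 0, 50, 0L, 1L)
  expect_lt(max(abs(res$mem_x - mem_x)), 1e-9)
})

test_that("a free particle diffuses with the Einstein relation", {
  # single membrane particle, no interactions: MSD = 6 D t with D = kBT
  p <- membrane_params()
  nrep <- 400; nst <- 50; dt <- 1e-3
  msd <- vapply(seq_len(nrep), function(s) {
    res <- cdvsim:::.cpp_langevin_run(
      matrix(c(0, 0, 500), 1), matrix(c(0, 0, 1), 1),
      matrix(0, 0, 3), matrix(0, 0, 3), integer(0), integer(0),
      matrix(0, 1, 10), cdvsim:::mem_params_vec(p), 1000, dt, 1,
      nst, 0L, s)
    sum((res$mem_x - c(0, 0, 500))^2)
  }, numeric(1))
  expect_equal(mean(msd), 6 * 1 * nst * dt, tolerance = 0.05 * 3)
})

test_that("identical config and seed reproduce trajectories bitwise", {
  cfg <- simulation_config(tube_radius = 5, tube_length = 20,
                           membrane_spacing = 1.2, n_steps = 200,
                           snap_every = 100, seed = 42L,
                           arrangement = fig5_arrangement(5, ring_gap = 1.5))
  t1 <- run_protocol(cfg)
  t2 <- run_protocol(cfg)
  expect_identical(t1$snapshots[[length(t1$snapshots)]]$membrane,
                   t2$snapshots[[length(t2$snapshots)]]$membrane)
  expect_identical(t1$snapshots[[2]]$beads, t2$snapshots[[2]]$beads)

  cfg2 <- cfg; cfg2$seed <- 43L
  t3 <- run_protocol(cfg2)
  expect_gt(max(abs(t3$snapshots[[length(t3$snapshots)]]$membrane -
                      t1$snapshots[[length(t1$snapshots)]]$membrane)), 0)
})

test_that("protocols conserve or remove species per the schedule", {
  base <- simulation_config(tube_radius = 5, tube_length = 20,
                            membrane_spacing = 1.2, n_steps = 300,
                            snap_every = 100, seed = 7L,
                            arrangement = fig5_arrangement(5, ring_gap = 1.5))
  minus <- run_protocol(base)
  counts <- t(vapply(minus$snapshots, function(s)
    vapply(c("CdvB", "CdvB1", "CdvB2"), function(sp)
      if (is.null(s$beads[[sp]])) 0L else nrow(s$beads[[sp]]),
      integer(1)), integer(3)))
  expect_true(all(apply(counts, 2, function(x) length(unique(x)) == 1)))
  expect_true(all(counts > 0))
  expect_identical(nrow(minus$events), 0L)

  plus <- base
  plus$schedule <- data.frame(step = 100L, species = "CdvB")
  pl <- run_protocol(plus)
  for (s in pl$snapshots) {
    if (s$time >= 100 * base$dt) expect_null(s$beads[["CdvB"]])
    else expect_gt(nrow(s$beads[["CdvB"]]), 0)
  }
  expect_identical(pl$events$species, "CdvB")
  expect_identical(pl$events$step, 100L)
  # snapshot times strictly increasing
  tms <- vapply(pl$snapshots, `[[`, numeric(1), "time")
  expect_true(all(diff(tms) > 0))
})

test_that("membrane count is conserved without removal events", {
  cfg <- simulation_config(tube_radius = 5, tube_length = 20,
                           membrane_spacing = 1.2, n_steps = 200,
                           snap_every = 200, seed = 3L)
  tr <- run_protocol(cfg)
  ns <- vapply(tr$snapshots, function(s) nrow(s$membrane), integer(1))
  expect_identical(length(unique(ns)), 1L)
})

test_that("the parameter scan reproduces its grid and a direct run", {
  base <- simulation_config(tube_radius = 5, tube_length = 20,
                            membrane_spacing = 1.2, n_steps = 200,
                            snap_every = 100, seed = 11L,
                            arrangement = fig5_arrangement(5, ring_gap = 1.5),
                            schedule = data.frame(step = 100L,
                                                  species = "CdvB"))
  g1 <- data.frame(tilt = 40)
  res1 <- scan_cdvb1_parameters(base, g1)
  expect_identical(nrow(res1), 1L)
  expect_false(res1$failed)
  # equals a direct protocol run + analysis at the derived seed
  direct <- base
  direct$seed <- (base$seed + 7919L) %% .Machine$integer.max
  traj <- run_protocol(direct)
  tr <- constriction_trace(traj)
  expect_equal(res1$min_radius, tr$trace$min_radius[nrow(tr$trace)])
  expect_equal(res1$neck_count, tr$trace$neck_count[nrow(tr$trace)])

  g9 <- expand.grid(bond_stiffness = c(25, 50, 100), tilt = c(0, 20, 40))
  res9 <- scan_cdvb1_parameters(
    simulation_config(tube_radius = 5, tube_length = 20,
                      membrane_spacing = 1.2, n_steps = 50,
                      snap_every = 50, seed = 1L,
                      arrangement = fig5_arrangement(5, ring_gap = 1.5)),
    g9)
  expect_identical(nrow(res9), 9L)
  expect_equal(res9$bond_stiffness, g9$bond_stiffness)
  expect_equal(res9$tilt, g9$tilt)
})

test_that("planted density profiles are classified by separation score", {
  mk <- function(dens) structure(
    list(bin_centers = seq_along(dens), density = dens),
    class = "cdv_density_profile")
  separated <- list(a = mk(c(3, 1, 0, 0, 0, 0)), b = mk(c(0, 0, 0, 0, 1, 3)))
  mixed <- list(a = mk(c(1, 2, 3, 2, 1, 0)), b = mk(c(0, 1, 3, 2, 1, 1)))
  expect_lt(separation_score(separated$a, separated$b), 0.2)
  expect_gt(separation_score(mixed$a, mixed$b), 0.6)
})

test_that("trajectories export to extended XYZ and read back", {
  cfg <- simulation_config(tube_radius = 5, tube_length = 20,
                           membrane_spacing = 1.2, n_steps = 100,
                           snap_every = 100, seed = 2L,
                           arrangement = fig5_arrangement(5, ring_gap = 1.5))
  tr <- run_protocol(cfg)
  path <- file.path(tempdir(), "traj.xyz")
  write_trajectory_xyz(tr, path)
  frames <- read_trajectory_xyz(path)
  expect_length(frames, length(tr$snapshots))
  last <- frames[[length(frames)]]
  snap <- tr$snapshots[[length(tr$snapshots)]]
  expect_equal(sum(last$types == "MEM"), nrow(snap$membrane))
  expect_equal(sum(last$types == "CdvB2"), nrow(snap$beads$CdvB2))
  mem_rt <- last$positions[last$types == "MEM", ]
  expect_equal(mem_rt, snap$membrane, tolerance = 1e-5,
               ignore_attr = TRUE)
})
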