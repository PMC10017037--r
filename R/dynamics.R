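#' Simulation configuration
#'
#' Bundles the geometry, membrane and filament parameters, integrator
#' settings and the event schedule for a tube-constriction protocol. The
#' tube geometry defaults to the desk-scale replica used throughout the
#' package: radius 8 sigma, length 32 sigma, with the three division
#' filament species scaled so their preferred-radius ratios match the
#' full-scale values (170:65:40) and the largest ring equals the tube
#' radius.
#'
#' @param tube_radius Tube radius, sigma.
#' @param tube_length Tube length (periodic in z), sigma.
#' @param membrane_spacing Membrane particle spacing, sigma.
#' @param species Named list of \code{\link{filament_spec}} objects.
#' @param arrangement Data frame with one row per filament: \code{species},
#'   \code{axial_offset} (sigma, relative to the tube midplane),
#'   \code{phase} (radians).
#' @param temperature Temperature, kBT.
#' @param dt Integrator timestep (reduced time units).
#' @param n_steps Total number of Langevin steps.
#' @param snap_every Snapshot interval, steps.
#' @param seed Integer seed; together with the config it fully determines
#'   the trajectory.
#' @param schedule Event schedule: data frame with columns \code{step} and
#'   \code{species} (each species removed at most once, steps
#'   non-decreasing); \code{NULL} or empty for a Vps4-minus protocol.
#' @param membrane \code{\link{membrane_params}}.
#' @param us Unit system.
#' @return An object of class \code{cdv_config}.
#' @export
simulation_config <- function(tube_radius = 8, tube_length = 32,
                              membrane_spacing = 0.90,
                              species = NULL, arrangement = NULL,
                              temperature = 1, dt = 5e-4,
                              n_steps = 20000, snap_every = 1000,
                              seed = 1L, schedule = NULL,
                              membrane = membrane_params(),
                              us = unit_system()) {
  if (is.null(species)) species <- fig5_species(tube_radius, us = us)
  if (is.null(arrangement)) arrangement <- fig5_arrangement(tube_radius)
  stopifnot(tube_radius > 0, tube_length >= 4 * tube_radius, dt > 0,
            n_steps >= 1, temperature >= 0)
  if (!all(arrangement$species %in% names(species)))
    stop("arrangement references species without a spec")
  if (any(abs(arrangement$axial_offset) > tube_length / 2))
    stop("arrangement axial positions fall outside the tube")
  if (!is.null(schedule) && nrow(schedule)) {
    if (!all(schedule$species %in% names(species)))
      stop("schedule references unknown species: ",
           paste(setdiff(schedule$species, names(species)), collapse = ", "))
    if (anyDuplicated(schedule$species))
      stop("each species may be removed at most once")
    if (is.unsorted(schedule$step))
      stop("schedule steps must be non-decreasing")
  }
  structure(list(
    tube_radius = tube_radius, tube_length = tube_length,
    membrane_spacing = membrane_spacing, species = species,
    arrangement = arrangement, temperature = temperature, dt = dt,
    friction = 1, n_steps = as.integer(n_steps),
    snap_every = as.integer(snap_every), seed = as.integer(seed),
    schedule = schedule, membrane = membrane, us = us
  ), class = "cdv_config")
}

#' @rdname simulation_config
#' @param ring_radius Radius of a membrane-bound ring, sigma. Filaments sit
#'   one adhesion contact distance inside the tube, so the largest ring --
#'   CdvB, whose preferred radius is the inner radius of the membrane --
#'   is at rest at \code{tube_radius - 1} and acts as a passive template.
#' @details \code{fig5_species} returns the three division-filament presets
#'   rescaled so the preferred-radius ratios match the full-scale values
#'   (170:65:40, i.e. a 17-sigma cell) with CdvB's preferred radius equal
#'   to \code{ring_radius}, keeping the published stiffnesses and tilt.
#' @export
fig5_species <- function(tube_radius = 8, us = unit_system(),
                         ring_radius = tube_radius - 1) {
  scale <- ring_radius * us$sigma_nm / 170
  list(
    # the template ring is discretised more finely than the contractile
    # species so its stiffness and adhesion anchoring per unit length do
    # not dilute at reduced scale
    CdvB  = filament_preset("cdvb",  preferred_radius = 170 * scale,
                            bead_spacing = 0.7, us = us),
    CdvB1 = filament_preset("cdvb1", preferred_radius = 65 * scale, us = us),
    CdvB2 = filament_preset("cdvb2", preferred_radius = 40 * scale, us = us)
  )
}

#' @rdname simulation_config
#' @param ring_gap Axial spacing between adjacent rings, sigma.
#' @param inverted If TRUE, swap CdvB1 and CdvB2 so CdvB1 sits inside
#'   (the arrangement the study found unable to focus constriction).
#' @details \code{fig5_arrangement} encodes the favoured pre-division
#'   pattern: a central CdvB ring flanked by two CdvB2 rings, with the two
#'   CdvB1 rings outside.
#' @export
fig5_arrangement <- function(tube_radius = 8, ring_gap = 1.2,
                             inverted = FALSE) {
  inner <- if (inverted) "CdvB1" else "CdvB2"
  outer <- if (inverted) "CdvB2" else "CdvB1"
  data.frame(
    species = c(outer, inner, "CdvB", inner, outer),
    axial_offset = c(-2 * ring_gap, -ring_gap, 0, ring_gap, 2 * ring_gap),
    phase = c(0.5, 2.5, 0, 4.2, 3.4),
    stringsAsFactors = FALSE
  )
}

# species parameter matrix for the C++ kernels (one row per species);
# the final column is the rest dot product of successive binding
# directors, measured off the preferred helix
species_param_matrix <- function(species, contact = 1, range = 2) {
  rows <- lapply(species, function(sp) {
    rg <- rest_geometry(sp)
    pref_sigma <- if (is.finite(sp$preferred_radius))
      sp$preferred_radius / sp$us$sigma_nm else 1e6
    fr <- build_helical_filament(sp, pref_sigma)
    mid <- max(2, floor(nrow(fr$directors) / 2))
    ddot <- sum(fr$directors[mid, ] * fr$directors[mid + 1, ])
    c(sp$bond_stiffness, rg$rest_length, sp$bend_stiffness, rg$rest_angle,
      sp$twist_stiffness, rg$rest_dihedral, sp$tilt * pi / 180,
      sp$adhesion_strength, contact, range, ddot)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(species)
  m
}

#' Assemble the initial simulation state
#'
#' Builds the membrane tube and places the filaments of the arrangement on
#' its inner surface (one adhesion contact distance inside the tube
#' radius), centred on the tube midplane, with binding directors at their
#' rest orientation.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return An object of class \code{cdv_state}.
#' @export
assemble_state <- function(config) {
  mem <- init_tube_membrane(config$tube_radius, config$tube_length,
                            config$membrane_spacing, config$membrane,
                            config$us)
  mem$positions[, 3] <- mem$positions[, 3]  # z in [0, L)
  mid <- config$tube_length / 2
  fil_radius <- config$tube_radius - 1
  fils <- lapply(seq_len(nrow(config$arrangement)), function(i) {
    row <- config$arrangement[i, ]
    build_helical_filament(config$species[[row$species]], fil_radius,
                           axial_center = mid + row$axial_offset,
                           phase = row$phase)
  })
  structure(list(membrane = mem, filaments = fils, config = config,
                 time = 0, us = config$us), class = "cdv_state")
}

#' @export
print.cdv_state <- function(x, ...) {
  sp <- vapply(x$filaments, function(f) f$species, character(1))
  cat(sprintf("<cdv_state> t = %g: %d membrane particles, %d filaments (%s)\n",
              x$time, nrow(x$membrane$positions), length(x$filaments),
              paste(sp, collapse = ", ")))
  invisible(x)
}

# pack/unpack between cdv_state and the flat arrays the C++ kernels use
state_arrays <- function(state) {
  fils <- state$filaments
  fil_x <- do.call(rbind, c(lapply(fils, `[[`, "beads"), list(matrix(0, 0, 3))))
  fil_d <- do.call(rbind, c(lapply(fils, `[[`, "directors"),
                            list(matrix(0, 0, 3))))
  fil_len <- vapply(fils, function(f) nrow(f$beads), integer(1))
  sp_names <- names(state$config$species)
  sp_idx <- vapply(fils, function(f)
    match(f$species, sp_names) - 1L, integer(1))
  list(fil_x = fil_x, fil_d = fil_d, fil_len = fil_len, sp_idx = sp_idx,
       sp_mat = species_param_matrix(state$config$species),
       mem_vec = mem_params_vec(state$membrane$params))
}

unpack_state <- function(state, res) {
  state$membrane$positions <- res$mem_x
  state$membrane$directors <- res$mem_n
  off <- 0L
  for (i in seq_along(state$filaments)) {
    n <- nrow(state$filaments[[i]]$beads)
    idx <- seq_len(n) + off
    state$filaments[[i]]$beads <- res$fil_x[idx, , drop = FALSE]
    state$filaments[[i]]$directors <- res$fil_d[idx, , drop = FALSE]
    off <- off + n
  }
  state
}

run_segment <- function(state, n_steps, seed, snap_every = 0L) {
  a <- state_arrays(state)
  cfg <- state$config
  res <- .cpp_langevin_run(state$membrane$positions, state$membrane$directors,
                           a$fil_x, a$fil_d, a$fil_len, a$sp_idx, a$sp_mat,
                           a$mem_vec, cfg$tube_length, cfg$dt,
                           cfg$temperature, as.integer(n_steps),
                           as.integer(snap_every), as.integer(seed))
  res
}

#' Advance the state by Langevin steps
#'
#' Overdamped (first-order) Langevin update with unit friction: positions
#' move along the deterministic force plus seeded thermal noise; directors
#' are rotated by the elastic and adhesive torques and re-normalised. At
#' zero temperature and a local energy minimum the state is unchanged.
#'
#' @param state A \code{cdv_state}.
#' @param n_steps Number of steps.
#' @param seed Integer seed for the thermal noise of this call.
#' @return The advanced \code{cdv_state}.
#' @export
step_state <- function(state, n_steps = 1L, seed = 1L) {
  res <- run_segment(state, n_steps, seed)
  state <- unpack_state(state, res)
  state$time <- state$time + n_steps * state$config$dt
  state
}

#' Total potential energy of a state, by component
#'
#' @param state A \code{cdv_state}.
#' @return Named list: membrane, adhesion, excluded, stretch, bend,
#'   twist_tilt, total (kBT).
#' @export
state_energy <- function(state) {
  a <- state_arrays(state)
  .cpp_total_energy(state$membrane$positions, state$membrane$directors,
                    a$fil_x, a$fil_d, a$fil_len, a$sp_idx, a$sp_mat,
                    a$mem_vec, state$config$tube_length)
}

#' Run a full division protocol
#'
#' Integrates the configuration from its assembled initial state, applying
#' the event schedule: at each scheduled step all beads of the named
#' species are removed instantaneously (Vps4-style disassembly). With an
#' empty schedule (Vps4-minus) every species persists to the end.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A \code{cdv_trajectory}: list with \code{snapshots} (each holding
#'   \code{time}, \code{membrane} positions/directors and per-species bead
#'   matrices), \code{events}, \code{energies} and the \code{config}.
#' @export
run_protocol <- function(config) {
  state <- assemble_state(config)
  sched <- config$schedule
  if (is.null(sched)) sched <- data.frame(step = integer(0),
                                          species = character(0))
  sched <- sched[order(sched$step), , drop = FALSE]
  bounds <- unique(c(0L, pmin(sched$step, config$n_steps), config$n_steps))
  snapshots <- list()
  energies <- list()
  events <- list()
  take_snapshot <- function(state) {
    fil_split <- split(lapply(state$filaments, `[[`, "beads"),
                       vapply(state$filaments, `[[`, "", "species"))
    list(time = state$time,
         step = round(state$time / config$dt),
         membrane = state$membrane$positions,
         directors = state$membrane$directors,
         beads = lapply(fil_split, function(l) do.call(rbind, l)))
  }
  snapshots[[1]] <- take_snapshot(state)
  energies[[1]] <- c(time = state$time, unlist(state_energy(state)))
  seg_id <- 0L
  for (k in seq_len(length(bounds) - 1)) {
    from <- bounds[k]; to <- bounds[k + 1]
    # events scheduled at the start of this segment
    due <- sched[sched$step == from, , drop = FALSE]
    for (spn in due$species) {
      keep <- vapply(state$filaments, function(f) f$species != spn,
                     logical(1))
      state$filaments <- state$filaments[keep]
      events[[length(events) + 1]] <- data.frame(
        step = from, time = from * config$dt, action = "remove_species",
        species = spn, stringsAsFactors = FALSE)
    }
    if (nrow(due)) {
      # the snapshot at the event time reflects the post-removal state
      last <- length(snapshots)
      if (snapshots[[last]]$step == from) {
        snapshots[[last]] <- take_snapshot(state)
        energies[[last]] <- c(time = state$time,
                              unlist(state_energy(state)))
      }
    }
    if (to > from) {
      n_seg <- to - from
      n_chunks <- max(1L, ceiling(n_seg / config$snap_every))
      for (ch in seq_len(n_chunks)) {
        n_do <- min(config$snap_every, n_seg - (ch - 1L) * config$snap_every)
        if (n_do <= 0) break
        seg_id <- seg_id + 1L
        seed_k <- (config$seed * 1000L + seg_id) %% .Machine$integer.max
        state <- step_state(state, n_do, seed_k)
        snapshots[[length(snapshots) + 1]] <- take_snapshot(state)
        energies[[length(energies) + 1]] <-
          c(time = state$time, unlist(state_energy(state)))
      }
    }
  }
  structure(list(
    snapshots = snapshots,
    events = if (length(events)) do.call(rbind, events) else
      data.frame(step = integer(0), time = numeric(0),
                 action = character(0), species = character(0)),
    energies = as.data.frame(do.call(rbind, energies)),
    config = config, final_state = state
  ), class = "cdv_trajectory")
}

#' @export
print.cdv_trajectory <- function(x, ...) {
  cat(sprintf("<cdv_trajectory> %d snapshots, %d events, %d steps\n",
              length(x$snapshots), nrow(x$events), x$config$n_steps))
  invisible(x)
}

#' Scan CdvB1 mechanical parameters
#'
#' Runs one complete protocol per grid point, varying the CdvB1 bond
#' stiffness (bend and twist stiffnesses co-scaled), tilt and/or preferred
#' radius, and reduces each run to a separation score (CdvB1 vs CdvB2 axial
#' density overlap), neck count and final minimum tube radius. Seeds are
#' derived deterministically from the base seed and grid index. Failed grid
#' points are flagged, not dropped.
#'
#' @param base_config A \code{\link{simulation_config}}.
#' @param grid Data frame; columns may include \code{bond_stiffness},
#'   \code{tilt}, \code{preferred_radius} (nm).
#' @return Data frame with the grid columns plus \code{separation_score},
#'   \code{neck_count}, \code{min_radius} (sigma), \code{failed}.
#' @export
scan_cdvb1_parameters <- function(base_config, grid) {
  stopifnot(nrow(grid) >= 1)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- base_config
    sp <- cfg$species$CdvB1
    if ("bond_stiffness" %in% names(grid)) {
      ratio <- grid$bond_stiffness[i] / sp$bond_stiffness
      sp$bond_stiffness <- grid$bond_stiffness[i]
      sp$bend_stiffness <- sp$bend_stiffness * ratio
      sp$twist_stiffness <- sp$twist_stiffness * ratio
    }
    if ("tilt" %in% names(grid)) sp$tilt <- grid$tilt[i]
    if ("preferred_radius" %in% names(grid))
      sp$preferred_radius <- grid$preferred_radius[i]
    cfg$species$CdvB1 <- sp
    cfg$seed <- (base_config$seed + 7919L * i) %% .Machine$integer.max
    res <- tryCatch({
      traj <- run_protocol(cfg)
      tr <- constriction_trace(traj)
      last <- nrow(tr$trace)
      sep <- tryCatch({
        d1 <- axial_density(traj, "CdvB1", n_bins = 16)
        d2 <- axial_density(traj, "CdvB2", n_bins = 16)
        separation_score(d1, d2)
      }, error = function(e) NA_real_)
      data.frame(separation_score = sep,
                 neck_count = tr$trace$neck_count[last],
                 min_radius = tr$trace$min_radius[last], failed = FALSE)
    }, error = function(e)
      data.frame(separation_score = NA_real_, neck_count = NA_integer_,
                 min_radius = NA_real_, failed = TRUE))
    out[[i]] <- cbind(grid[i, , drop = FALSE], res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
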