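#' Zero-temperature relaxation
#'
#' Gradient descent with backtracking line search on the total elastic
#' energy. Every accepted step strictly decreases the energy; iteration
#' stops when the decrease per accepted step falls below \code{tolerance}
#' or the step budget is exhausted (in which case the best state reached is
#' returned with \code{converged = FALSE} and a warning).
#'
#' For a free filament (no membrane) the positional energy is minimised;
#' binding directors are slaved to their rest orientation in the relaxed
#' frame. A flexible CdvB1 or stiff CdvB2 filament perturbed off its
#' preferred helix relaxes back to a circle of its preferred radius (65 and
#' 40 nm for the presets), which \code{\link{fit_circle_radius}} verifies.
#'
#' @param state Object to relax (a \code{cdv_filament} or \code{cdv_state}).
#' @param ... Method arguments.
#' @return The relaxed object with attributes \code{converged},
#'   \code{energy} and \code{iterations}.
#' @export
relax_zero_temperature <- function(state, ...) UseMethod("relax_zero_temperature")

#' @rdname relax_zero_temperature
#' @param spec The filament's \code{\link{filament_spec}}.
#' @param tolerance Stop when the energy decrease of an accepted step is
#'   below this value (kBT).
#' @param max_steps Step budget.
#' @param step0 Initial step size (sigma^2/kBT scale).
#' @export
relax_zero_temperature.cdv_filament <- function(state, spec,
                                                tolerance = 1e-10,
                                                max_steps = 50000,
                                                step0 = 1e-3, ...) {
  stopifnot(inherits(spec, "cdv_filament_spec"))
  if (!identical(state$species, spec$species))
    stop("species mismatch between filament and spec")
  rg <- rest_geometry(spec)
  pos <- state$beads
  eg <- function(p) .cpp_filament_eg(p, spec$bond_stiffness, rg$rest_length,
                                     spec$bend_stiffness, rg$rest_angle,
                                     spec$twist_stiffness, rg$rest_dihedral)
  cur <- eg(pos)
  e <- cur$energy
  # Polak-Ribiere conjugate gradient with backtracking line search; every
  # accepted move strictly lowers the energy. When progress along the
  # conjugate direction dries up, restart along steepest descent before
  # declaring convergence.
  g <- cur$gradient
  dirn <- -g
  s <- step0
  it <- 0L
  converged <- FALSE
  restarted <- FALSE
  while (it < max_steps) {
    it <- it + 1L
    accepted <- FALSE
    while (s > 1e-15) {
      trial <- pos + s * dirn
      et <- eg(trial)$energy
      if (et < e) {
        accepted <- TRUE
        de <- e - et
        pos <- trial
        e <- et
        s <- s * 1.6
        break
      }
      s <- s / 2
    }
    if (!accepted || de < tolerance) {
      if (restarted) { converged <- TRUE; break }
      restarted <- TRUE
      g <- eg(pos)$gradient
      dirn <- -g
      s <- step0
      next
    }
    restarted <- FALSE
    gn <- eg(pos)$gradient
    beta <- max(0, sum(gn * (gn - g)) / max(sum(g * g), 1e-300))
    dirn <- -gn + beta * dirn
    if (sum(dirn * gn) > 0) dirn <- -gn   # restart if not a descent direction
    g <- gn
  }
  if (!converged)
    warning("relaxation did not converge within the step budget")
  dirs <- filament_rest_directors(pos, spec$tilt)
  out <- structure(list(species = state$species, beads = pos,
                        directors = dirs,
                        frames = filament_frames(pos, dirs), us = state$us),
                   class = "cdv_filament")
  attr(out, "converged") <- converged
  attr(out, "energy") <- e
  attr(out, "iterations") <- it
  out
}

#' Perturb filament bead positions with seeded Gaussian displacements
#'
#' @param f A \code{cdv_filament}.
#' @param sd Displacement SD per coordinate, sigma.
#' @param seed Integer seed (local RNG; the global RNG state is preserved).
#' @return The perturbed filament.
#' @export
perturb_filament <- function(f, sd = 0.2, seed = 1L) {
  pos <- f$beads + with_local_seed(seed, matrix(
    stats::rnorm(length(f$beads), sd = sd), nrow(f$beads), 3))
  dirs <- filament_rest_directors(pos, 0)
  structure(list(species = f$species, beads = pos, directors = dirs,
                 frames = filament_frames(pos, dirs), us = f$us),
            class = "cdv_filament")
}

# evaluate expr with a temporary RNG seed, restoring global state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
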