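#' Membrane model parameters
#'
#' The membrane is a one-particle-thick fluid sheet: oriented particles with
#' an anisotropic pair potential whose radial part has a repulsive core
#' below \code{r_min} and a smooth attractive tail to \code{r_cut}, and
#' whose orientation factor favours co-planar, mutually aligned neighbours.
#' The defaults (\code{epsilon = 4.34} kBT at a working temperature of 1
#' kBT, \code{mu = 3}, \code{zeta = 4}, cutoff \code{2.6} in units of the
#' particle size) lie in the fluid-membrane region of this model family's
#' phase diagram.
#'
#' @param epsilon Pair interaction depth, kBT.
#' @param mu Orientation-coupling strength (dimensionless).
#' @param zeta Attraction decay exponent (integer).
#' @param r_min Equilibrium pair spacing, sigma.
#' @param r_cut Interaction cutoff, sigma.
#' @param wca_eps,wca_sigma Bead excluded-volume parameters (kBT, sigma).
#' @param align_w Width (in cosine units) of the adhesion angular factor.
#' @return An object of class \code{cdv_membrane_params}.
#' @export
membrane_params <- function(epsilon = 4.34, mu = 3, zeta = 4,
                            r_min = 1.122, r_cut = 2.6,
                            wca_eps = 1, wca_sigma = 1, align_w = 0.35) {
  stopifnot(epsilon >= 0, r_min > 0, r_cut > r_min, align_w > 0)
  structure(list(epsilon = epsilon, mu = mu, zeta = as.integer(zeta),
                 r_min = r_min, r_cut = r_cut, wca_eps = wca_eps,
                 wca_sigma = wca_sigma, align_w = align_w),
            class = "cdv_membrane_params")
}

mem_params_vec <- function(p) {
  c(p$epsilon, p$mu, p$zeta, p$r_min, p$r_cut, p$wca_eps, p$wca_sigma,
    p$align_w)
}

#' Initialise a membrane tube
#'
#' Particles tile a cylinder of the given radius and length (periodic in z)
#' on rows of near-uniform spacing, with outward radial directors. Alternate
#' rows are offset by half the azimuthal step so the initial tiling is close
#' to triangular.
#'
#' @param radius Tube radius, sigma.
#' @param length Tube length (periodic box), sigma; must be at least 4x the
#'   radius.
#' @param particle_spacing Target particle spacing, sigma; must not exceed
#'   the radius.
#' @param params \code{\link{membrane_params}}.
#' @param us Unit system.
#' @return An object of class \code{cdv_membrane}: \code{positions} (n x 3),
#'   \code{directors} (n x 3), \code{radius}, \code{length}, \code{params}.
#' @examples
#' m <- init_tube_membrane(8, 32, 1.05)
#' nrow(m$positions)
#' @export
init_tube_membrane <- function(radius, length, particle_spacing = 1.05,
                               params = membrane_params(),
                               us = unit_system()) {
  stopifnot(radius > 0, length > 0, particle_spacing > 0)
  if (particle_spacing > radius)
    stop("particle_spacing exceeds the tube radius (under-resolved tube)")
  if (length < 4 * radius)
    stop("tube length must be at least 4x the radius")
  n_z <- max(3L, round(length / particle_spacing))
  dz <- length / n_z
  n_phi <- max(3L, round(2 * pi * radius / particle_spacing))
  dphi <- 2 * pi / n_phi
  rows <- lapply(seq_len(n_z) - 1L, function(iz) {
    off <- if (iz %% 2 == 1) dphi / 2 else 0
    phi <- off + (seq_len(n_phi) - 1L) * dphi
    cbind(radius * cos(phi), radius * sin(phi), iz * dz)
  })
  pos <- do.call(rbind, rows)
  dirs <- cbind(pos[, 1], pos[, 2], 0)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  structure(list(positions = pos, directors = dirs, radius = radius,
                 length = length, spacing = particle_spacing,
                 params = params, us = us),
            class = "cdv_membrane")
}

#' @export
print.cdv_membrane <- function(x, ...) {
  cat(sprintf("<cdv_membrane> tube: %d particles, radius %g sigma, length %g sigma\n",
              nrow(x$positions), x$radius, x$length))
  invisible(x)
}

#' Pair energy between two membrane particles
#'
#' Zero beyond the cutoff; minimised (at \code{-epsilon}) for two particles
#' at \code{r_min} with parallel directors perpendicular to their
#' separation; director misalignment (bending) and spacing deviations
#' (stretching) raise the energy.
#'
#' @param p1,p2 Lists with elements \code{pos} (length-3) and \code{dir}
#'   (length-3 unit vector).
#' @param params \code{\link{membrane_params}}.
#' @return Energy in kBT.
#' @export
membrane_pair_energy <- function(p1, p2, params = membrane_params()) {
  if (sum((p1$pos - p2$pos)^2) < 1e-12)
    stop("coincident membrane particles")
  e <- .cpp_total_energy(rbind(p1$pos, p2$pos), rbind(p1$dir, p2$dir),
                         matrix(0, 0, 3), matrix(0, 0, 3),
                         integer(0), integer(0),
                         matrix(0, 1, 10), mem_params_vec(params), 1e9)
  e$membrane
}

#' Adhesion between a filament bead and a membrane particle
#'
#' Short-ranged attraction with the same radial shape as the membrane pair
#' potential, modulated by the facing angle psi between the bead's binding
#' director and the inward membrane normal: the angular factor is a Gaussian
#' in cos(psi) centred on the target tilt, so the energy is minimal when the
#' binding interface is rotated by \code{tilt_target} away from face-on
#' contact. Zero beyond \code{range}.
#'
#' @param bead List with \code{pos} and \code{dir} (binding director).
#' @param particle List with \code{pos} and \code{dir} (membrane director).
#' @param spec An \code{\link{adhesion_spec}}.
#' @param params \code{\link{membrane_params}} (supplies the angular width).
#' @return Energy in kBT.
#' @export
adhesion_energy <- function(bead, particle, spec = adhesion_spec(),
                            params = membrane_params()) {
  sp <- matrix(0, 1, 10)
  sp[1, 7] <- spec$tilt_target * pi / 180
  sp[1, 8] <- spec$strength
  sp[1, 9] <- spec$contact
  sp[1, 10] <- spec$range
  e <- .cpp_total_energy(rbind(particle$pos), rbind(particle$dir),
                         rbind(bead$pos), rbind(bead$dir),
                         1L, 0L, sp, mem_params_vec(params), 1e9)
  e$adhesion
}

#' @rdname adhesion_energy
#' @param strength Well depth, kBT (must be >= 0).
#' @param range Interaction cutoff, sigma (> 0).
#' @param tilt_target Preferred facing angle, degrees.
#' @param contact Contact (minimum-energy) distance, sigma.
#' @export
adhesion_spec <- function(strength = 6, range = 2, tilt_target = 0,
                          contact = 1) {
  stopifnot(strength >= 0, range > 0, contact > 0, contact < range)
  structure(list(strength = strength, range = range,
                 tilt_target = tilt_target, contact = contact),
            class = "cdv_adhesion_spec")
}

# mean radial distance of tube particles from the z axis
tube_mean_radius <- function(pos) mean(sqrt(pos[, 1]^2 + pos[, 2]^2))
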