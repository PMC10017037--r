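# Discrete helix construction and rest geometry.
#
# A filament is a chain of beads on a helix plus a per-bead orthonormal frame
# (tangent, binding director, binormal). The binding director marks the
# membrane-binding interface; at rest it points toward the local centre of
# curvature, rotated by the species tilt about the tangent toward the
# discrete binormal ("inward tilt", toward the helix axis).

helix_points <- function(radius, pitch_per_turn, phase, n_bonds, dphi,
                         axial_center = 0) {
  k <- 0:n_bonds
  phi <- phase + k * dphi
  c_rise <- pitch_per_turn / (2 * pi)      # rise per radian
  z <- c_rise * (phi - phase)
  z <- z - mean(z) + axial_center
  cbind(radius * cos(phi), radius * sin(phi), z)
}

# number of bonds implied by arc-length spacing on a helix subtending `loops`
helix_n_bonds <- function(radius, pitch_per_turn, bead_spacing, loops) {
  theta <- loops * 2 * pi
  c_rise <- pitch_per_turn / (2 * pi)
  arc_per_rad <- sqrt(radius^2 + c_rise^2)
  round(theta * arc_per_rad / bead_spacing)
}

# Rest binding directors from the discrete frame of a bead chain:
# m_hat = bisector of the two bonds at an interior bead (points toward the
# local centre of curvature), b_hat = normalized cross of the two bonds.
# The director is m_hat rotated by `tilt_deg` toward b_hat. End beads copy
# their interior neighbour. Returns an n x 3 matrix of unit vectors.
filament_rest_directors <- function(pos, tilt_deg) {
  n <- nrow(pos)
  stopifnot(n >= 3)
  d <- matrix(NA_real_, n, 3)
  tau <- tilt_deg * pi / 180
  for (i in 2:(n - 1)) {
    a <- pos[i - 1, ] - pos[i, ]
    b <- pos[i + 1, ] - pos[i, ]
    m <- a / sqrt(sum(a^2)) + b / sqrt(sum(b^2))
    nm <- sqrt(sum(m^2))
    if (nm < 1e-12) {  # locally straight: no curvature plane
      d[i, ] <- NA_real_
      next
    }
    m <- m / nm
    bb <- vcross(-a, b)
    nb <- sqrt(sum(bb^2))
    if (nb < 1e-12) { d[i, ] <- NA_real_; next }
    bb <- bb / nb
    d[i, ] <- cos(tau) * m + sin(tau) * bb
  }
  if (anyNA(d[2, ])) d[2, ] <- d[which(!is.na(d[, 1]))[1], ]
  d[1, ] <- d[2, ]
  d[n, ] <- d[n - 1, ]
  # fill any interior straight spots from neighbours
  for (i in seq_len(n)) if (anyNA(d[i, ])) d[i, ] <- d[i - 1, ]
  d
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# per-bead orthonormal triads (tangent, director, binormal) from positions
# and binding directors; the director is re-orthogonalized against the
# tangent so each triad is right-handed orthonormal to machine precision.
filament_frames <- function(pos, directors) {
  n <- nrow(pos)
  tangent <- matrix(0, n, 3)
  tangent[1, ] <- pos[2, ] - pos[1, ]
  tangent[n, ] <- pos[n, ] - pos[n - 1, ]
  if (n > 2) tangent[2:(n - 1), ] <- pos[3:n, ] - pos[1:(n - 2), ]
  tangent <- tangent / sqrt(rowSums(tangent^2))
  d <- directors - tangent * rowSums(directors * tangent)
  d <- d / sqrt(rowSums(d^2))
  b <- cbind(tangent[, 2] * d[, 3] - tangent[, 3] * d[, 2],
             tangent[, 3] * d[, 1] - tangent[, 1] * d[, 3],
             tangent[, 1] * d[, 2] - tangent[, 2] * d[, 1])
  list(tangent = tangent, director = d, binormal = b)
}

#' Build a helical filament bead chain on a membrane tube
#'
#' Beads are laid on a helix of the given tube radius (the initial radius
#' equals the cell radius regardless of the species' preferred radius),
#' subtending \code{spec$loops} full turns, with the species' bead spacing
#' along the arc. Binding directors are initialised at their rest
#' orientation in the discrete frame (toward the local centre of curvature,
#' tilted by \code{spec$tilt} toward the binormal).
#'
#' @param spec A \code{\link{filament_spec}}.
#' @param tube_radius Helix (tube) radius, sigma.
#' @param axial_center Axial position of the filament centre, sigma.
#' @param phase Starting azimuthal angle, radians.
#' @return An object of class \code{cdv_filament}: list with \code{species},
#'   \code{beads} (n x 3, sigma), \code{directors} (n x 3 unit vectors) and
#'   \code{frames}.
#' @examples
#' f <- build_helical_filament(filament_preset("cdvb2"), tube_radius = 8)
#' filament_turn_angle(f)  # 378 degrees = 1.05 turns
#' @export
build_helical_filament <- function(spec, tube_radius, axial_center = 0,
                                   phase = 0) {
  stopifnot(inherits(spec, "cdv_filament_spec"))
  if (tube_radius <= 0) stop("tube_radius must be > 0")
  pitch_sigma <- spec$preferred_pitch / spec$us$sigma_nm
  nb <- helix_n_bonds(tube_radius, pitch_sigma, spec$bead_spacing, spec$loops)
  if (nb < 2) stop("loops/bead_spacing imply fewer than 3 beads")
  dphi <- spec$loops * 2 * pi / nb
  pos <- helix_points(tube_radius, pitch_sigma, phase, nb, dphi, axial_center)
  dirs <- filament_rest_directors(pos, spec$tilt)
  structure(list(species = spec$species, beads = pos, directors = dirs,
                 frames = filament_frames(pos, dirs), us = spec$us),
            class = "cdv_filament")
}

#' @export
print.cdv_filament <- function(x, ...) {
  cat(sprintf("<cdv_filament> %s: %d beads\n", x$species, nrow(x$beads)))
  invisible(x)
}

#' Summed projected turn angle of a filament, degrees
#'
#' Bead positions are projected onto the best-fit plane (via SVD of the
#' centred coordinates) and the signed angles between consecutive projected
#' radius vectors are accumulated. A filament built with \code{loops = 1.05}
#' subtends 378 degrees.
#'
#' @param f A \code{cdv_filament}.
#' @return Total turn angle in degrees.
#' @export
filament_turn_angle <- function(f) {
  pos <- f$beads
  n <- nrow(pos)
  # helix axis: mean cross product of consecutive bonds (exact for a helix)
  bonds <- pos[-1, , drop = FALSE] - pos[-n, , drop = FALSE]
  cr <- colSums(cbind(
    bonds[-nrow(bonds), 2] * bonds[-1, 3] - bonds[-nrow(bonds), 3] * bonds[-1, 2],
    bonds[-nrow(bonds), 3] * bonds[-1, 1] - bonds[-nrow(bonds), 1] * bonds[-1, 3],
    bonds[-nrow(bonds), 1] * bonds[-1, 2] - bonds[-nrow(bonds), 2] * bonds[-1, 1]))
  axis <- cr / sqrt(sum(cr^2))
  # in-plane basis
  e1 <- vcross(axis, if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- vcross(axis, e1)
  x <- sweep(pos, 2, colMeans(pos))
  u <- drop(x %*% e1)
  v <- drop(x %*% e2)
  # circle centre in the projection plane (Kasa fit) for unbiased angles
  A <- cbind(2 * u, 2 * v, 1)
  sol <- qr.solve(A, u^2 + v^2)
  u <- u - sol[1]; v <- v - sol[2]
  ang <- atan2(v, u)
  d <- diff(ang)
  d <- (d + pi) %% (2 * pi) - pi        # unwrap step-wise
  abs(sum(d)) * 180 / pi
}

#' Per-bond rest geometry of a filament species
#'
#' Rest parameters are measured off the preferred helix discretised with the
#' same rounding rule used by \code{\link{build_helical_filament}}: the rest
#' bond length is the chord length, the rest bend angle the interior angle at
#' a bead, and the rest dihedral the torsion angle over four consecutive
#' beads. A filament placed exactly on its preferred helix therefore has zero
#' elastic energy. An infinite preferred radius yields a straight rod (rest
#' angle 180 degrees, zero dihedral).
#'
#' @param spec A \code{\link{filament_spec}}.
#' @return List with \code{rest_length} (sigma), \code{rest_angle} (radians),
#'   \code{rest_dihedral} (radians), \code{dphi} (turn per bond, radians) and
#'   \code{n_bonds} of the canonical discretisation.
#' @export
rest_geometry <- function(spec) {
  stopifnot(inherits(spec, "cdv_filament_spec"))
  s <- spec$bead_spacing
  if (!is.finite(spec$preferred_radius)) {
    return(list(rest_length = s, rest_angle = pi, rest_dihedral = 0,
                dphi = 0, n_bonds = helix_n_bonds(1e9, 0, s, spec$loops)))
  }
  a <- spec$preferred_radius / spec$us$sigma_nm
  p <- spec$preferred_pitch / spec$us$sigma_nm
  nb <- helix_n_bonds(a, p, s, spec$loops)
  nb <- max(nb, 3L)
  dphi <- spec$loops * 2 * pi / nb
  pts <- helix_points(a, p, 0, min(nb, 4L), dphi)
  rest_length <- sqrt(sum((pts[2, ] - pts[1, ])^2))
  rest_angle <- bend_angle(pts[1, ], pts[2, ], pts[3, ])
  rest_dihedral <- if (nrow(pts) >= 4)
    dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ]) else 0
  list(rest_length = rest_length, rest_angle = rest_angle,
       rest_dihedral = rest_dihedral, dphi = dphi, n_bonds = nb)
}

bend_angle <- function(p0, p1, p2) {
  a <- p0 - p1; b <- p2 - p1
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(max(-1, min(1, ca)))
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  b2h <- b2 / sqrt(sum(b2^2))
  m1 <- vcross(n1, b2h)
  atan2(sum(m1 * n2), sum(n1 * n2))
}

#' Least-squares circle radius of a filament's beads
#'
#' Beads are projected onto their best-fit plane and an algebraic
#' least-squares circle (Kasa fit) is solved on the projected coordinates.
#' Used to verify that relaxed filaments attain their preferred radii.
#'
#' @param f A \code{cdv_filament} or an n x 3 position matrix (sigma).
#' @param us Unit system used to report the radius in nm (taken from the
#'   filament if available).
#' @return Fitted radius in nm.
#' @export
fit_circle_radius <- function(f, us = NULL) {
  if (inherits(f, "cdv_filament")) {
    if (is.null(us)) us <- f$us
    pos <- f$beads
  } else pos <- as.matrix(f)
  if (is.null(us)) us <- unit_system()
  if (nrow(pos) < 3) stop("need at least 3 beads")
  x <- sweep(pos, 2, colMeans(pos))
  sv <- svd(x)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("beads are collinear; circle radius undefined")
  u <- x %*% sv$v[, 1]
  v <- x %*% sv$v[, 2]
  # Kasa fit: minimize sum((u^2+v^2) - 2au - 2bv - c)^2
  A <- cbind(2 * u, 2 * v, 1)
  z <- u^2 + v^2
  sol <- qr.solve(A, z)
  r_sigma <- sqrt(sol[3] + sol[1]^2 + sol[2]^2)
  unname(sigma_to_nm(r_sigma, us))
}
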