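# Elastic energy of a discrete helical filament.
#
# Harmonic discrete-rod energy measured against the species rest geometry:
#   stretch    = k_bond/2  * sum_bonds  (|b_i| - l0)^2
#   bend       = kc/2      * sum_beads  (cos(theta_i) - cos(theta0))^2
#   twist_tilt = k_twist/2 * sum_quads  w_i * wrap(phi_i - phi0)^2
#              + k_twist   * sum_beads  (1 - d_i . e_i)
# with w_i = S(|b x b'|^2) S(|b' x b''|^2), S(x) = x/(x + 5e-4), a smooth
# switch that turns the torsion off (with bounded forces) at collinear
# triples, where the dihedral angle is undefined.
# where e_i is the rest binding director in the current discrete frame
# (curvature bisector rotated by the species tilt toward the binormal).
# The bend term is cosine-harmonic with kc = k_bend / sin^2(theta0), which
# matches a harmonic-in-angle stiffness k_bend near the rest angle while
# staying smooth at straight configurations. All terms vanish on the
# preferred helix with rest directors.

wrap_angle <- function(x) (x + pi) %% (2 * pi) - pi

# curvature-matched cosine-bend prefactor (floor keeps straight rods finite)
bend_kc <- function(k_bend, th0) k_bend / max(1 - cos(th0)^2, 0.01)

torsion_switch_c <- 5e-4

torsion_terms <- function(pos, phi0) {
  n <- nrow(pos)
  t(vapply(1:(n - 3), function(i) {
    b1 <- pos[i + 1, ] - pos[i, ]
    b2 <- pos[i + 2, ] - pos[i + 1, ]
    b3 <- pos[i + 3, ] - pos[i + 2, ]
    n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
    n1s <- sum(n1^2); n2s <- sum(n2^2)
    if (n1s < 1e-14 || n2s < 1e-14) return(c(0, 0, 0, 0))
    phi <- dihedral_angle(pos[i, ], pos[i + 1, ], pos[i + 2, ], pos[i + 3, ])
    w <- (n1s / (n1s + torsion_switch_c)) * (n2s / (n2s + torsion_switch_c))
    c(wrap_angle(phi - phi0), w, n1s, n2s)
  }, numeric(4)))
}


#' Elastic energy of a filament
#'
#' @param f A \code{cdv_filament}.
#' @param spec The matching \code{\link{filament_spec}} (species labels must
#'   agree).
#' @return List of class \code{cdv_energy}: \code{stretch}, \code{bend},
#'   \code{twist_tilt} and \code{total}, all in kBT.
#' @examples
#' spec <- filament_preset("cdvb2")
#' f <- build_helical_filament(spec, tube_radius = 4)  # at preferred radius
#' filament_energy(f, spec)$total
#' @export
filament_energy <- function(f, spec) {
  stopifnot(inherits(f, "cdv_filament"), inherits(spec, "cdv_filament_spec"))
  if (!identical(f$species, spec$species))
    stop(sprintf("species mismatch: filament is %s, spec is %s",
                 f$species, spec$species))
  rg <- rest_geometry(spec)
  pos <- f$beads
  n <- nrow(pos)
  bonds <- pos[-1, , drop = FALSE] - pos[-n, , drop = FALSE]
  blen <- sqrt(rowSums(bonds^2))
  stretch <- spec$bond_stiffness / 2 * sum((blen - rg$rest_length)^2)

  bend <- 0
  if (n >= 3) {
    th <- vapply(2:(n - 1), function(i)
      bend_angle(pos[i - 1, ], pos[i, ], pos[i + 1, ]), numeric(1))
    kc <- bend_kc(spec$bend_stiffness, rg$rest_angle)
    bend <- kc / 2 * sum((cos(th) - cos(rg$rest_angle))^2)
  }

  twist <- 0
  if (n >= 4 && spec$twist_stiffness > 0) {
    tt <- torsion_terms(pos, rg$rest_dihedral)
    twist <- spec$twist_stiffness / 2 * sum(tt[, 2] * tt[, 1]^2)
  }
  if (!is.null(f$directors) && spec$twist_stiffness > 0) {
    e <- filament_rest_directors(pos, spec$tilt)
    twist <- twist +
      spec$twist_stiffness * sum(1 - rowSums(f$directors * e))
  }

  structure(list(stretch = stretch, bend = bend, twist_tilt = twist,
                 total = stretch + bend + twist), class = "cdv_energy")
}

#' @export
print.cdv_energy <- function(x, ...) {
  cat(sprintf("<cdv_energy> total %.6g kBT (stretch %.4g, bend %.4g, twist/tilt %.4g)\n",
              x$total, x$stretch, x$bend, x$twist_tilt))
  invisible(x)
}

# Positional energy (stretch + bend + dihedral; directors assumed relaxed to
# their rest orientation in the instantaneous frame) and its analytic
# gradient. Used by zero-temperature relaxation of free filaments.
filament_positional_energy <- function(pos, spec, rg = rest_geometry(spec)) {
  n <- nrow(pos)
  bonds <- pos[-1, , drop = FALSE] - pos[-n, , drop = FALSE]
  blen <- sqrt(rowSums(bonds^2))
  e <- spec$bond_stiffness / 2 * sum((blen - rg$rest_length)^2)
  if (n >= 3) {
    th <- vapply(2:(n - 1), function(i)
      bend_angle(pos[i - 1, ], pos[i, ], pos[i + 1, ]), numeric(1))
    kc <- bend_kc(spec$bend_stiffness, rg$rest_angle)
    e <- e + kc / 2 * sum((cos(th) - cos(rg$rest_angle))^2)
  }
  if (n >= 4 && spec$twist_stiffness > 0) {
    tt <- torsion_terms(pos, rg$rest_dihedral)
    e <- e + spec$twist_stiffness / 2 * sum(tt[, 2] * tt[, 1]^2)
  }
  e
}

filament_positional_gradient <- function(pos, spec, rg = rest_geometry(spec)) {
  n <- nrow(pos)
  g <- matrix(0, n, 3)
  # stretch
  for (i in 1:(n - 1)) {
    b <- pos[i + 1, ] - pos[i, ]
    l <- sqrt(sum(b^2))
    co <- spec$bond_stiffness * (l - rg$rest_length) / l
    g[i + 1, ] <- g[i + 1, ] + co * b
    g[i, ] <- g[i, ] - co * b
  }
  # bend (cosine-harmonic)
  if (n >= 3) {
    kc <- bend_kc(spec$bend_stiffness, rg$rest_angle)
    c0 <- cos(rg$rest_angle)
    for (i in 2:(n - 1)) {
      a <- pos[i - 1, ] - pos[i, ]; b <- pos[i + 1, ] - pos[i, ]
      la <- sqrt(sum(a^2)); lb <- sqrt(sum(b^2))
      ah <- a / la; bh <- b / lb
      ct <- sum(ah * bh)
      dEdc <- kc * (ct - c0)
      dc_da <- (bh - ct * ah) / la
      dc_db <- (ah - ct * bh) / lb
      g[i - 1, ] <- g[i - 1, ] + dEdc * dc_da
      g[i + 1, ] <- g[i + 1, ] + dEdc * dc_db
      g[i, ] <- g[i, ] - dEdc * (dc_da + dc_db)
    }
  }
  # softened dihedral
  if (n >= 4 && spec$twist_stiffness > 0) for (i in 1:(n - 3)) {
    p1 <- pos[i, ]; p2 <- pos[i + 1, ]; p3 <- pos[i + 2, ]; p4 <- pos[i + 3, ]
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
    n1s <- sum(n1^2); n2s <- sum(n2^2)
    if (n1s < 1e-14 || n2s < 1e-14) next
    lb2 <- sqrt(sum(b2^2))
    phi <- dihedral_angle(p1, p2, p3, p4)
    dphi <- wrap_angle(phi - rg$rest_dihedral)
    cc <- torsion_switch_c
    S1 <- n1s / (n1s + cc); S2 <- n2s / (n2s + cc)
    w <- S1 * S2
    dEdphi <- spec$twist_stiffness * w * dphi
    # Blondel-Karplus torsion gradient, sign-matched to dihedral_angle()
    u12 <- sum(b1 * b2) / (lb2 * n1s)
    u32 <- sum(b3 * b2) / (lb2 * n2s)
    dp1 <- (lb2 / n1s) * n1
    dp4 <- -(lb2 / n2s) * n2
    dp2 <- -dp1 - u12 * n1 - u32 * n2
    dp3 <- -dp4 + u12 * n1 + u32 * n2
    g[i, ] <- g[i, ] + dEdphi * dp1
    g[i + 1, ] <- g[i + 1, ] + dEdphi * dp2
    g[i + 2, ] <- g[i + 2, ] + dEdphi * dp3
    g[i + 3, ] <- g[i + 3, ] + dEdphi * dp4
    # switch gradient
    pref <- spec$twist_stiffness / 2 * dphi^2
    dS1 <- cc / (n1s + cc)^2 * S2 * pref
    dS2 <- cc / (n2s + cc)^2 * S1 * pref
    dn1_db1 <- 2 * sum(b2^2) * b1 - 2 * sum(b1 * b2) * b2
    dn1_db2 <- 2 * sum(b1^2) * b2 - 2 * sum(b1 * b2) * b1
    dn2_db2 <- 2 * sum(b3^2) * b2 - 2 * sum(b2 * b3) * b3
    dn2_db3 <- 2 * sum(b2^2) * b3 - 2 * sum(b2 * b3) * b2
    g[i, ] <- g[i, ] - dS1 * dn1_db1
    g[i + 1, ] <- g[i + 1, ] + dS1 * dn1_db1 - dS1 * dn1_db2 - dS2 * dn2_db2
    g[i + 2, ] <- g[i + 2, ] + dS1 * dn1_db2 + dS2 * dn2_db2 - dS2 * dn2_db3
    g[i + 3, ] <- g[i + 3, ] + dS2 * dn2_db3
  }
  g
}
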