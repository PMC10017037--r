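#' Mechanical specification of a helical ESCRT-III filament
#'
#' A filament species is described by its preferred helical geometry (radius,
#' pitch per turn, tilt of the membrane-binding interface), its harmonic
#' stiffnesses, bead discretisation and membrane adhesion strength. Presets
#' for the three Sulfolobus division paralogs carry the published model
#' parameters: preferred radii \eqn{R_{CdvB}=170}, \eqn{R_{CdvB1}=65},
#' \eqn{R_{CdvB2}=40} nm, CdvB1 tilt \eqn{\tau = 40^\circ}, and bond
#' stiffnesses \eqn{k_{CdvB}=k_{CdvB2}=250}, \eqn{k_{CdvB1}=50}
#' \eqn{k_BT/\sigma^2}.
#'
#' Bend and twist stiffnesses are not published for this model; by default
#' they scale with the bond stiffness (bend is three times the bond
#' stiffness numerically, in \eqn{k_BT/rad^2} -- calibrated once so the
#' contractile species deform the membrane tube at desk scale; twist is one
#' fifth of the bond stiffness), so the flexible species is flexible in
#' every mode. The default adhesion strength (12 kBT at contact) keeps a
#' constricting filament's membrane annulus attached as it tightens. The
#' preferred pitch defaults to one bead diameter of rise per turn, a
#' near-planar helix.
#'
#' @param species Species label (e.g. "CdvB", "CdvB1", "CdvB2", or custom).
#' @param preferred_radius Preferred (spontaneous) helix radius, nm.
#' @param preferred_pitch Preferred rise per full turn, nm. Default: one bead
#'   spacing.
#' @param tilt Tilt of the membrane-binding director relative to the local
#'   curvature plane, degrees, in \[-90, 90\]. Positive tilt rotates the
#'   binding director toward the helix axis ("inward tilt").
#' @param bond_stiffness Harmonic bond (stretch) stiffness, kBT/sigma^2.
#' @param bend_stiffness Harmonic bend stiffness, kBT/rad^2. Default
#'   \code{3 * bond_stiffness}.
#' @param twist_stiffness Harmonic twist/tilt stiffness, kBT/rad^2 (dihedral)
#'   and kBT (director restoring). Default \code{bond_stiffness / 5}.
#' @param bead_spacing Arc-length spacing between consecutive beads, sigma.
#' @param loops Angular extent of the filament in full turns (1.05 = one full
#'   loop plus a small overlap).
#' @param adhesion_strength Depth of the bead-membrane adhesion well, kBT.
#' @param us Unit system (\code{\link{unit_system}}).
#' @return An object of class \code{cdv_filament_spec}.
#' @examples
#' filament_preset("cdvb2")
#' filament_spec("custom", preferred_radius = 80, bond_stiffness = 100)
#' @export
filament_spec <- function(species,
                          preferred_radius,
                          preferred_pitch = NULL,
                          tilt = 0,
                          bond_stiffness = 250,
                          bend_stiffness = NULL,
                          twist_stiffness = NULL,
                          bead_spacing = 1,
                          loops = 1.05,
                          adhesion_strength = 12,
                          us = unit_system()) {
  if (is.null(preferred_pitch)) preferred_pitch <- bead_spacing * us$sigma_nm
  if (is.null(bend_stiffness)) bend_stiffness <- 3 * bond_stiffness
  if (is.null(twist_stiffness)) twist_stiffness <- bond_stiffness / 5
  spec <- structure(list(
    species = as.character(species),
    preferred_radius = preferred_radius,
    preferred_pitch = preferred_pitch,
    tilt = tilt,
    bond_stiffness = bond_stiffness,
    bend_stiffness = bend_stiffness,
    twist_stiffness = twist_stiffness,
    bead_spacing = bead_spacing,
    loops = loops,
    adhesion_strength = adhesion_strength,
    us = us
  ), class = "cdv_filament_spec")
  validate_filament_spec(spec)
  spec
}

validate_filament_spec <- function(spec) {
  with(spec, {
    if (!(is.finite(preferred_radius) && preferred_radius > 0) &&
        !identical(preferred_radius, Inf))
      stop("preferred_radius must be > 0 (Inf allowed for a straight filament)")
    if (loops <= 0) stop("loops must be > 0")
    if (tilt < -90 || tilt > 90) stop("tilt must lie in [-90, 90] degrees")
    for (k in c("bond_stiffness", "bend_stiffness", "twist_stiffness"))
      if (spec[[k]] < 0) stop(k, " must be >= 0")
    if (bead_spacing <= 0) stop("bead_spacing must be > 0")
    if (adhesion_strength < 0) stop("adhesion_strength must be >= 0")
  })
  invisible(spec)
}

#' @rdname filament_spec
#' @param name Preset name: one of "cdvb", "cdvb1", "cdvb2" (case
#'   insensitive).
#' @param ... Overrides passed to \code{\link{filament_spec}}.
#' @export
filament_preset <- function(name, ..., us = unit_system()) {
  presets <- list(
    cdvb  = list(species = "CdvB",  preferred_radius = 170, tilt = 0,
                 bond_stiffness = 250),
    cdvb1 = list(species = "CdvB1", preferred_radius = 65,  tilt = 40,
                 bond_stiffness = 50),
    cdvb2 = list(species = "CdvB2", preferred_radius = 40,  tilt = 0,
                 bond_stiffness = 250)
  )
  key <- tolower(name)
  if (!key %in% names(presets))
    stop("unknown filament preset: ", name)
  args <- utils::modifyList(c(presets[[key]], list(us = us)), list(...))
  do.call(filament_spec, args)
}

#' @export
print.cdv_filament_spec <- function(x, ...) {
  cat(sprintf(
    "<cdv_filament_spec> %s: R0 = %g nm, pitch = %g nm/turn, tilt = %g deg\n",
    x$species, x$preferred_radius, x$preferred_pitch, x$tilt))
  cat(sprintf("  k_bond = %g kBT/sigma^2, k_bend = %g, k_twist = %g\n",
              x$bond_stiffness, x$bend_stiffness, x$twist_stiffness))
  cat(sprintf("  bead_spacing = %g sigma, loops = %g, adhesion = %g kBT\n",
              x$bead_spacing, x$loops, x$adhesion_strength))
  invisible(x)
}

#' Serialize / deserialize filament specs
#'
#' Specs round-trip through a plain key-value YAML document so simulation
#' configurations can be kept under version control as text.
#'
#' @param spec A \code{cdv_filament_spec}.
#' @param path File path; if \code{NULL}, the YAML text is returned.
#' @return \code{write_filament_spec}: the YAML text, invisibly if written to
#'   a file. \code{read_filament_spec}: a \code{cdv_filament_spec}.
#' @export
write_filament_spec <- function(spec, path = NULL) {
  lst <- unclass(spec)
  lst$us <- list(sigma_nm = spec$us$sigma_nm)
  txt <- yaml::as.yaml(lst)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname write_filament_spec
#' @param input Path to, or text of, a YAML spec document.
#' @export
read_filament_spec <- function(input) {
  lst <- if (file.exists(input)) yaml::read_yaml(input)
         else yaml::yaml.load(input)
  us <- unit_system(lst$us$sigma_nm %||% 10)
  lst$us <- NULL
  do.call(filament_spec, c(lst, list(us = us)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
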