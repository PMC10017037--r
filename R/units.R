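#' Simulation unit system
#'
#' The simulator works in reduced units: length in \eqn{\sigma} (the
#' simulation unit of length) and energy in \eqn{k_B T}. A unit system fixes
#' the physical size of \eqn{\sigma} so that filament radii quoted in
#' nanometres can be mapped onto the bead scale. With the default
#' \code{sigma_nm = 10} the three division-filament radii (170, 65, 40 nm)
#' become 17, 6.5 and 4 \eqn{\sigma}.
#'
#' @param sigma_nm Physical length of one \eqn{\sigma} in nanometres.
#' @return An object of class \code{cdv_units}.
#' @examples
#' us <- unit_system(10)
#' nm_to_sigma(170, us)  # 17
#' @export
unit_system <- function(sigma_nm = 10) {
  stopifnot(is.numeric(sigma_nm), length(sigma_nm) == 1, is.finite(sigma_nm),
            sigma_nm > 0)
  structure(list(sigma_nm = sigma_nm, kBT = 1), class = "cdv_units")
}

#' @rdname unit_system
#' @param x Lengths to convert.
#' @param us A \code{cdv_units} object.
#' @export
nm_to_sigma <- function(x, us = unit_system()) x / us$sigma_nm

#' @rdname unit_system
#' @export
sigma_to_nm <- function(x, us = unit_system()) x * us$sigma_nm

#' @export
print.cdv_units <- function(x, ...) {
  cat(sprintf("<cdv_units> sigma = %g nm, kBT = %g\n", x$sigma_nm, x$kBT))
  invisible(x)
}
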