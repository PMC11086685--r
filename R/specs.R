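# Domain specification objects. All fields are stored in SI units;
# constructors take the bench units a user would read off the instrument
# (mT, Hz, micrometres, g/cm^3, mPa s).

#' Rotating magnetic field specification
#'
#' Describes the applied rotating field: flux density \eqn{B}, rotation
#' frequency \eqn{f}, and the rotation-axis unit vector \eqn{\hat\Omega}.
#' Cambering the axis off the surface normal (\code{c(0, 0, -1)}) converts
#' spinning into rolling; the default axis \code{c(0, cos(pi/6), -1/2)}
#' drives wheels in the +x direction (see [rolling_direction()]).
#'
#' @param flux_density_mT magnetic flux density in millitesla (>= 0).
#' @param frequency_Hz field rotation frequency in hertz (>= 0).
#' @param axis rotation-axis unit vector, length 3.
#' @return an object of class \code{field_spec} with SI fields
#'   \code{flux_density} (T), \code{frequency} (Hz), \code{axis}.
#' @examples
#' field_spec(3.4, 40)
#' @export
field_spec <- function(flux_density_mT = 3.4, frequency_Hz = 40,
                       axis = c(0, cos(pi / 6), -1 / 2)) {
  check_scalar(flux_density_mT, "flux_density_mT", lower = 0)
  check_scalar(frequency_Hz, "frequency_Hz", lower = 0)
  check_unit_axis(axis)
  structure(list(flux_density = flux_density_mT * 1e-3,
                 frequency = frequency_Hz,
                 axis = as.numeric(axis)),
            class = "field_spec")
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf("<field_spec> B = %.3g mT, f = %.3g Hz, axis = [%s]\n",
              x$flux_density * 1e3, x$frequency,
              paste(sprintf("%.4g", x$axis), collapse = ", ")))
  invisible(x)
}

#' Superparamagnetic bead specification
#'
#' The building block of a microwheel: a superparamagnetic colloidal bead.
#' Defaults describe 4.5 um epoxy Dynabead-class particles
#' (density 1.5 g/cm^3). The imaginary susceptibility \eqn{\chi''} sets the
#' time-averaged magnetic torque in a rotating field; it is rarely quoted by
#' vendors, so it is a model parameter here (default 0.1) and can be
#' recovered from track data with [fit_scaling()].
#'
#' @param diameter_um bead diameter in micrometres (> 0).
#' @param density_g_cm3 mass density in g/cm^3 (> 0).
#' @param chi_imag imaginary part of the magnetic susceptibility (>= 0).
#' @return an object of class \code{bead_spec} with SI fields
#'   \code{diameter} (m), \code{radius} (m), \code{density} (kg/m^3),
#'   \code{volume} (m^3), \code{chi_imag}.
#' @examples
#' bead_spec()
#' @export
bead_spec <- function(diameter_um = 4.5, density_g_cm3 = 1.5,
                      chi_imag = 0.1) {
  check_scalar(diameter_um, "diameter_um", lower = 0, strict = TRUE)
  check_scalar(density_g_cm3, "density_g_cm3", lower = 0, strict = TRUE)
  check_scalar(chi_imag, "chi_imag", lower = 0)
  d <- diameter_um * 1e-6
  structure(list(diameter = d,
                 radius = d / 2,
                 density = density_g_cm3 * 1e3,
                 volume = bead_volume(d),
                 chi_imag = chi_imag),
            class = "bead_spec")
}

#' @export
print.bead_spec <- function(x, ...) {
  cat(sprintf(
    "<bead_spec> d = %.3g um, rho = %.3g g/cm3, chi'' = %.3g, v = %.4g m^3\n",
    x$diameter * 1e6, x$density / 1e3, x$chi_imag, x$volume))
  invisible(x)
}

#' Fluid specification
#'
#' @param viscosity_mPa_s dynamic viscosity in mPa s (> 0); 1 mPa s is water
#'   at room temperature.
#' @return an object of class \code{fluid_spec} with SI field
#'   \code{viscosity} (Pa s).
#' @examples
#' fluid_spec(1)
#' @export
fluid_spec <- function(viscosity_mPa_s = 1) {
  check_scalar(viscosity_mPa_s, "viscosity_mPa_s", lower = 0, strict = TRUE)
  structure(list(viscosity = viscosity_mPa_s * 1e-3), class = "fluid_spec")
}

#' @export
print.fluid_spec <- function(x, ...) {
  cat(sprintf("<fluid_spec> eta = %.4g mPa s\n", x$viscosity * 1e3))
  invisible(x)
}

#' Microwheel state at torque balance
#'
#' Assembles the steady-state description of an N-bead microwheel under a
#' given field and fluid: radius from the planar disk-area estimate
#' \eqn{R = a\sqrt{N}}, rotation rate from the torque balance, translational
#' velocity from the wet-friction coupling \eqn{V = \beta \omega N}, and
#' power \eqn{P = \tau\omega}.
#'
#' @param n_beads integer number of beads N (>= 1); may be a vector.
#' @param bead a [bead_spec()].
#' @param field a [field_spec()].
#' @param fluid a [fluid_spec()].
#' @param coupling_length_um wet-friction coupling length \eqn{\beta} in
#'   micrometres (see [translation_velocity()]).
#' @return a data.frame of class \code{micro_wheel} with one row per wheel:
#'   \code{n_beads}, \code{radius_um}, \code{rotation_rate_rad_s},
#'   \code{velocity_um_s}, \code{power_W}.
#' @examples
#' micro_wheel(c(7, 50, 200), bead_spec(), field_spec(), fluid_spec())
#' @export
micro_wheel <- function(n_beads, bead = bead_spec(), field = field_spec(),
                        fluid = fluid_spec(), coupling_length_um = 0.05) {
  if (any(n_beads < 1) || any(n_beads != round(n_beads)))
    stop("'n_beads' must be positive integers", call. = FALSE)
  H <- field_H_from_B(field$flux_density)
  R <- radius_from_count(n_beads, bead$radius)
  omega <- rotation_rate(n_beads, bead, H, fluid$viscosity, R)
  V <- translation_velocity(omega, n_beads, coupling_length_um * 1e-6)
  P <- wheel_power(magnetic_torque(n_beads, bead, H), omega)
  structure(data.frame(n_beads = n_beads,
                       radius_um = R * 1e6,
                       rotation_rate_rad_s = omega,
                       velocity_um_s = V * 1e6,
                       power_W = P),
            class = c("micro_wheel", "data.frame"))
}
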