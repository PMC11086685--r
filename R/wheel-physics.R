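# Torque-balance model of microwheel rotation, power and rolling
# translation. A rotating field of strength H exerts a time-averaged
# magnetic torque on an N-bead wheel,
#
#     tau_m = N v mu0 chi'' H^2 ,
#
# with v the single-bead volume and chi'' the imaginary susceptibility.
# Balancing against the rotational drag of a thin disk of radius R,
#
#     tau_v = 32 eta omega R^3 / 3 ,
#
# gives the steady rotation rate
#
#     omega = 3 N v mu0 chi'' H^2 / (32 eta R^3) .
#
# With the planar-packing estimate R = a sqrt(N) these imply omega ~ 1/R,
# P = tau omega ~ R and, through the wet-friction coupling V = beta omega N,
# V ~ R: larger wheels roll faster and deliver more power.

#' Volume of a spherical bead
#'
#' @param diameter bead diameter in metres (>= 0); vectorised.
#' @return volume \eqn{(\pi/6) d^3} in m^3.
#' @examples
#' bead_volume(4.5e-6)
#' @export
bead_volume <- function(diameter) {
  if (any(!is.finite(diameter)) || any(diameter < 0))
    stop("'diameter' must be finite and >= 0", call. = FALSE)
  (pi / 6) * diameter^3
}

#' Field strength H from flux density B
#'
#' Converts flux density to field strength via \eqn{H = B/\mu_0}, the
#' vacuum relation appropriate for coil-driven fields in dilute aqueous
#' suspensions.
#'
#' @param flux_density flux density in tesla (>= 0); vectorised.
#' @return field strength in A/m.
#' @examples
#' field_H_from_B(3.4e-3)
#' @export
field_H_from_B <- function(flux_density) {
  if (any(!is.finite(flux_density)) || any(flux_density < 0))
    stop("'flux_density' must be finite and >= 0", call. = FALSE)
  flux_density / MU0
}

#' Time-averaged magnetic torque on an N-bead wheel
#'
#' \eqn{\tau = N \nu \mu_0 \chi'' H^2}: linear in the bead count and
#' quadratic in the field strength.
#'
#' @param n_beads number of beads N (>= 1); vectorised.
#' @param bead a [bead_spec()].
#' @param field_strength H in A/m.
#' @return torque in N m.
#' @examples
#' magnetic_torque(7, bead_spec(), field_H_from_B(3.4e-3))
#' @export
magnetic_torque <- function(n_beads, bead, field_strength) {
  stopifnot(inherits(bead, "bead_spec"))
  if (any(n_beads < 1)) stop("'n_beads' must be >= 1", call. = FALSE)
  n_beads * bead$volume * MU0 * bead$chi_imag * field_strength^2
}

#' Viscous rotational torque on a spinning disk
#'
#' Drag torque of a thin disk rotating about its axis near a wall,
#' \eqn{\tau = 32 \eta \omega R^3 / 3}.
#'
#' @param viscosity dynamic viscosity in Pa s.
#' @param rotation_rate angular speed in rad/s; vectorised.
#' @param radius disk radius in metres (> 0); vectorised.
#' @return torque in N m.
#' @examples
#' viscous_torque(1e-3, 10, 20e-6)
#' @export
viscous_torque <- function(viscosity, rotation_rate, radius) {
  if (any(radius <= 0)) stop("'radius' must be > 0", call. = FALSE)
  32 * viscosity * rotation_rate * radius^3 / 3
}

#' Steady-state rotation rate from the torque balance
#'
#' Equates the magnetic and viscous torques and solves for
#' \eqn{\omega = 3 N \nu \mu_0 \chi'' H^2 / (32 \eta R^3)}. At the returned
#' rate [magnetic_torque()] equals [viscous_torque()] identically.
#'
#' @param n_beads number of beads N (>= 1); vectorised.
#' @param bead a [bead_spec()].
#' @param field_strength H in A/m.
#' @param viscosity dynamic viscosity in Pa s (> 0).
#' @param radius wheel radius in metres (> 0); defaults to the planar
#'   packing estimate [radius_from_count()].
#' @return rotation rate in rad/s.
#' @examples
#' rotation_rate(7, bead_spec(), field_H_from_B(3.4e-3), 1e-3)
#' @export
rotation_rate <- function(n_beads, bead, field_strength, viscosity,
                          radius = radius_from_count(n_beads, bead$radius)) {
  stopifnot(inherits(bead, "bead_spec"))
  if (any(viscosity <= 0)) stop("'viscosity' must be > 0", call. = FALSE)
  if (any(radius <= 0)) stop("'radius' must be > 0", call. = FALSE)
  3 * magnetic_torque(n_beads, bead, field_strength) /
    (32 * viscosity * radius^3)
}

#' Wheel radius from bead count
#'
#' Planar-packing estimate: the wheel's disk area \eqn{\pi R^2} equals N
#' times the cross-sectional area of one bead, so \eqn{R = a\sqrt{N}}.
#'
#' @param n_beads number of beads N (>= 1); vectorised.
#' @param bead_radius single-bead radius a in metres.
#' @return wheel radius in metres.
#' @examples
#' radius_from_count(7, 2.25e-6)
#' @export
radius_from_count <- function(n_beads, bead_radius) {
  if (any(n_beads < 1)) stop("'n_beads' must be >= 1", call. = FALSE)
  bead_radius * sqrt(n_beads)
}

#' Mechanical power of a spinning wheel
#'
#' \eqn{P = \tau \omega}.
#'
#' @param torque torque in N m (>= 0); vectorised.
#' @param rotation_rate angular speed in rad/s (>= 0); vectorised.
#' @return power in watts.
#' @export
wheel_power <- function(torque, rotation_rate) {
  if (any(torque < 0) || any(rotation_rate < 0))
    stop("'torque' and 'rotation_rate' must be >= 0", call. = FALSE)
  torque * rotation_rate
}

#' Power from measured rotation rate and radius
#'
#' The experimentally accessible route to power: the viscous torque needed
#' to spin a disk of measured radius R at measured rate \eqn{\omega}, times
#' \eqn{\omega}: \eqn{P = (32/3)\eta\omega^2 R^3}.
#'
#' @param viscosity dynamic viscosity in Pa s.
#' @param rotation_rate measured rate in rad/s; vectorised.
#' @param radius measured radius in metres; vectorised.
#' @return power in watts.
#' @examples
#' power_from_measurement(1e-3, 10, 20e-6)
#' @export
power_from_measurement <- function(viscosity, rotation_rate, radius) {
  viscous_torque(viscosity, rotation_rate, radius) * rotation_rate
}

#' Rolling translational velocity
#'
#' Microwheels roll by wet friction with the nearby wall and translate at
#' \eqn{V = \beta \omega N}, with \eqn{\beta} an empirical coupling length
#' absorbing the slip between rotation and translation. With the
#' torque-balance \eqn{\omega} and \eqn{N = (R/a)^2} this gives the linear
#' size scaling \eqn{V \sim R}.
#'
#' @param rotation_rate rotation rate in rad/s (>= 0); vectorised.
#' @param n_beads number of beads (>= 1); vectorised.
#' @param coupling_length coupling length \eqn{\beta} in metres
#'   (default 0.05 um, giving speeds of tens to hundreds of um/s for
#'   typical wheels in water).
#' @return velocity in m/s.
#' @examples
#' translation_velocity(136.5, 7)
#' @export
translation_velocity <- function(rotation_rate, n_beads,
                                 coupling_length = 0.05e-6) {
  if (any(rotation_rate < 0)) stop("'rotation_rate' must be >= 0",
                                   call. = FALSE)
  if (any(n_beads < 1)) stop("'n_beads' must be >= 1", call. = FALSE)
  coupling_length * rotation_rate * n_beads
}

#' Rolling direction from the field rotation axis
#'
#' A wheel spinning about axis \eqn{\hat\Omega} rolls along the in-plane
#' (xy) component of the axis rotated -90 degrees about z: the camber
#' tilts the wheel so that its contact line advances perpendicular to the
#' tilt. The default axis \code{c(0, cos(pi/6), -1/2)} therefore drives
#' wheels in +x. For an uncambered axis (no in-plane component) the wheel
#' spins in place and \code{NULL} is returned.
#'
#' Note the sign convention: the -90 degree rotation is fixed so that a +y
#' axis tilt produces +x rolling; for axes tilted along +x it yields -y
#' rolling. If your coil geometry uses the opposite handedness, negate the
#' result.
#'
#' @param axis rotation-axis unit 3-vector.
#' @return in-plane unit 2-vector \code{c(x, y)}, or \code{NULL} when the
#'   in-plane component is below 1e-12.
#' @examples
#' rolling_direction(c(0, cos(pi / 6), -1 / 2))  # +x
#' rolling_direction(c(0, 0, -1))                # NULL: spins in place
#' @export
rolling_direction <- function(axis) {
  check_unit_axis(axis)
  ip <- axis[1:2]
  # rotate (x, y) by -90 deg about z: (x, y) -> (y, -x)
  dir <- c(ip[2], -ip[1])
  nrm <- sqrt(sum(dir^2))
  if (nrm < 1e-12) return(NULL)
  dir / nrm
}
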