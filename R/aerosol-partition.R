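# Statistics of bead-laden aerosol generation. A jet nebulizer produces a
# droplet-number distribution that is well described as lognormal; the
# nebulizer is rated by its mass median diameter (MMD), while sampling
# needs the count median diameter (CMD). For a lognormal distribution the
# two are linked by the Hatch-Choate relation
#
#     CMD = MMD exp(-3 ln^2 sigma_g) .
#
# Beads suspended at number concentration c partition into droplets as a
# Poisson process on droplet volume (dilute, well-mixed): a droplet of
# diameter d carries Poisson(lambda) beads with lambda = c (pi/6) d^3.

#' Count median diameter from mass median diameter
#'
#' Hatch-Choate conversion for a lognormal size distribution:
#' \eqn{CMD = MMD\,e^{-3\ln^2\sigma_g}}.
#'
#' @param mass_median_diameter MMD (> 0), any length unit; vectorised.
#' @param geometric_std geometric standard deviation \eqn{\sigma_g} (> 1).
#' @return CMD in the unit of the input.
#' @examples
#' cmd_from_mmd(3.5e-6, 2.0)  # 0.8278 um
#' @export
cmd_from_mmd <- function(mass_median_diameter, geometric_std) {
  if (any(mass_median_diameter <= 0))
    stop("'mass_median_diameter' must be > 0", call. = FALSE)
  if (any(geometric_std <= 1))
    stop("'geometric_std' must be > 1", call. = FALSE)
  mass_median_diameter * exp(-3 * log(geometric_std)^2)
}

#' Mass median diameter from count median diameter
#'
#' Inverse of [cmd_from_mmd()]: \eqn{MMD = CMD\,e^{3\ln^2\sigma_g}}.
#'
#' @param count_median_diameter CMD (> 0); vectorised.
#' @param geometric_std geometric standard deviation (> 1).
#' @return MMD in the unit of the input.
#' @export
mmd_from_cmd <- function(count_median_diameter, geometric_std) {
  if (any(count_median_diameter <= 0))
    stop("'count_median_diameter' must be > 0", call. = FALSE)
  if (any(geometric_std <= 1))
    stop("'geometric_std' must be > 1", call. = FALSE)
  count_median_diameter * exp(3 * log(geometric_std)^2)
}

#' Droplet population parameters
#'
#' Lognormal droplet-size model of a nebulized aerosol, parameterised
#' either by the nebulizer's rated MMD or directly by the CMD. The default
#' matches a Pari LC Sprint class jet nebulizer (MMD 3.5 um) with a typical
#' geometric standard deviation of 2.0.
#'
#' @param mmd_um mass median diameter in micrometres (used when
#'   \code{cmd_um} is \code{NULL}).
#' @param gsd geometric standard deviation (> 1).
#' @param cmd_um count median diameter in micrometres, overrides
#'   \code{mmd_um}.
#' @return an object of class \code{droplet_population} with fields
#'   \code{cmd} (m), \code{mmd} (m), \code{gsd}.
#' @examples
#' droplet_population(mmd_um = 3.5, gsd = 2)
#' @export
droplet_population <- function(mmd_um = 3.5, gsd = 2.0, cmd_um = NULL) {
  check_scalar(gsd, "gsd", lower = 1, strict = TRUE)
  if (is.null(cmd_um)) {
    check_scalar(mmd_um, "mmd_um", lower = 0, strict = TRUE)
    cmd <- cmd_from_mmd(mmd_um * 1e-6, gsd)
  } else {
    check_scalar(cmd_um, "cmd_um", lower = 0, strict = TRUE)
    cmd <- cmd_um * 1e-6
  }
  structure(list(cmd = cmd, mmd = mmd_from_cmd(cmd, gsd), gsd = gsd),
            class = "droplet_population")
}

#' @export
print.droplet_population <- function(x, ...) {
  cat(sprintf("<droplet_population> MMD = %.4g um, CMD = %.4g um, GSD = %.3g\n",
              x$mmd * 1e6, x$cmd * 1e6, x$gsd))
  invisible(x)
}

#' Sample droplet diameters
#'
#' Draws \code{n} diameters from the lognormal number distribution of a
#' [droplet_population()]. Reproducible under \code{seed}; the caller's RNG
#' state is untouched.
#'
#' @param population a [droplet_population()].
#' @param n number of droplets (>= 1).
#' @param seed integer seed or \code{NULL}.
#' @return numeric vector of diameters in metres.
#' @examples
#' d <- sample_droplets(droplet_population(), 1e4, seed = 1)
#' median(d) * 1e6  # close to the CMD, 0.83 um
#' @export
sample_droplets <- function(population, n, seed = NULL) {
  stopifnot(inherits(population, "droplet_population"))
  check_scalar(n, "n", lower = 1)
  with_seed(seed,
            stats::rlnorm(n, meanlog = log(population$cmd),
                          sdlog = log(population$gsd)))
}

#' Mass median of a diameter sample
#'
#' The diameter at which the cumulative \eqn{d^3}-weighted (mass) fraction
#' reaches 50%, with linear interpolation between order statistics. This is
#' the statistic nebulizers are rated by.
#'
#' @param diameters nonempty numeric vector of diameters (> 0), any unit.
#' @return mass median in the unit of the input.
#' @examples
#' mass_median(c(1, 1, 1, 2))  # 1.3125: the single 2 holds 8/11 of the mass
#' @export
mass_median <- function(diameters) {
  if (length(diameters) == 0L)
    stop("'diameters' must be nonempty", call. = FALSE)
  if (any(!is.finite(diameters)) || any(diameters <= 0))
    stop("'diameters' must be finite and > 0", call. = FALSE)
  d <- sort(diameters)
  cum <- cumsum(d^3)
  cum <- cum / cum[length(cum)]
  i <- which(cum >= 0.5)[1L]
  if (i == 1L) return(d[1L])
  frac <- (0.5 - cum[i - 1L]) / (cum[i] - cum[i - 1L])
  d[i - 1L] + frac * (d[i] - d[i - 1L])
}

#' Seed beads into droplets by Poisson partitioning
#'
#' Each droplet of diameter \eqn{d_i} receives a Poisson count with mean
#' \eqn{\lambda_i = c (\pi/6) d_i^3}. When \code{bead_diameter} is given,
#' droplets smaller than the bead are forced to zero beads (a 4.5 um bead
#' cannot sit inside a smaller droplet).
#'
#' @param diameters droplet diameters in metres.
#' @param concentration bead number concentration in beads per m^3
#'   (multiply a per-mL value by 1e6).
#' @param seed integer seed or \code{NULL}.
#' @param bead_diameter optional physical-fit cutoff in metres.
#' @return integer vector of per-droplet bead counts.
#' @examples
#' d <- sample_droplets(droplet_population(), 1e4, seed = 1)
#' counts <- seed_beads(d, concentration = 4e6 * 1e6, seed = 2,
#'                      bead_diameter = 4.5e-6)
#' mean(counts > 0)
#' @export
seed_beads <- function(diameters, concentration, seed = NULL,
                       bead_diameter = NULL) {
  check_scalar(concentration, "concentration", lower = 0)
  lambda <- concentration * (pi / 6) * diameters^3
  counts <- with_seed(seed, stats::rpois(length(diameters), lambda))
  if (!is.null(bead_diameter))
    counts[diameters < bead_diameter] <- 0L
  counts
}

#' Analytic fraction of droplets containing beads
#'
#' Expected fraction of droplets carrying at least one bead under the
#' Poisson-on-volume partition, \eqn{E[1 - e^{-cV(d)}]}, integrated over
#' the lognormal number distribution by adaptive quadrature (in the
#' standard-normal variable \eqn{z = \ln(d/CMD)/\ln\sigma_g}).
#'
#' @param concentration bead number concentration in beads per m^3.
#' @param population a [droplet_population()].
#' @param bead_diameter optional fit cutoff in metres: droplets below it
#'   are counted as bead-free (matching [seed_beads()]).
#' @param rel_tol relative quadrature tolerance.
#' @return expected fraction in [0, 1].
#' @examples
#' fraction_containing(4e6 * 1e6, droplet_population())
#' @export
fraction_containing <- function(concentration, population,
                                bead_diameter = NULL, rel_tol = 1e-9) {
  stopifnot(inherits(population, "droplet_population"))
  check_scalar(concentration, "concentration", lower = 0)
  if (concentration == 0) return(0)
  lsg <- log(population$gsd)
  lower <- if (is.null(bead_diameter)) -Inf
           else log(bead_diameter / population$cmd) / lsg
  integrand <- function(z) {
    d <- population$cmd * exp(z * lsg)
    stats::dnorm(z) * (1 - exp(-concentration * (pi / 6) * d^3))
  }
  stats::integrate(integrand, lower = lower, upper = Inf,
                   rel.tol = rel_tol, abs.tol = 0,
                   subdivisions = 500L)$value
}

#' Empirical fraction of droplets containing beads
#'
#' @param bead_counts integer vector of per-droplet bead counts.
#' @return fraction of droplets with at least one bead.
#' @export
fraction_containing_empirical <- function(bead_counts) {
  if (length(bead_counts) == 0L)
    stop("'bead_counts' must be nonempty", call. = FALSE)
  mean(bead_counts >= 1)
}

#' Aerodynamic diameter of a dense particle
#'
#' Diameter of the unit-density (water) sphere with the same settling
#' behaviour: \eqn{d_a = d\sqrt{\rho/\rho_w}} with
#' \eqn{\rho_w = 1000} kg/m^3.
#'
#' @param geometric_diameter physical diameter in metres (> 0); vectorised.
#' @param density particle density in kg/m^3 (> 0); vectorised.
#' @return aerodynamic diameter in metres.
#' @examples
#' aerodynamic_diameter(4.5e-6, 1500) * 1e6  # 5.51 um
#' @export
aerodynamic_diameter <- function(geometric_diameter, density) {
  if (any(geometric_diameter <= 0) || any(density <= 0))
    stop("inputs must be > 0", call. = FALSE)
  geometric_diameter * sqrt(density / 1000)
}

#' Airway deposition regime of an aerosol particle
#'
#' Size-based classification of where an inhaled particle deposits:
#' particles above 5 um impact in the upper airway; 0.1-5 um particles
#' sediment in the conducting airways (the therapeutic window is 1-5 um);
#' sub-0.1 um particles can penetrate deep but are mostly exhaled; only
#' particles of about 10 nm and below reach the alveoli by diffusion.
#'
#' @param aerodynamic_diameter aerodynamic diameter in metres (> 0);
#'   vectorised.
#' @return factor with levels \code{upper-airway-impaction},
#'   \code{conducting-airway-sedimentation},
#'   \code{deep-penetration-mostly-exhaled}, \code{alveolar-diffusion}.
#' @examples
#' classify_deposition(c(6e-6, 3.5e-6, 10e-9))
#' @export
classify_deposition <- function(aerodynamic_diameter) {
  if (any(aerodynamic_diameter <= 0))
    stop("'aerodynamic_diameter' must be > 0", call. = FALSE)
  lv <- c("upper-airway-impaction", "conducting-airway-sedimentation",
          "deep-penetration-mostly-exhaled", "alveolar-diffusion")
  d <- aerodynamic_diameter
  out <- ifelse(d <= 10e-9, lv[4],
         ifelse(d < 0.1e-6, lv[3],
         ifelse(d <= 5e-6, lv[2], lv[1])))
  factor(out, levels = lv)
}
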