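# Synthetic particle-tracking tables emulating video analysis of rolling
# microwheels: translating/rotating wheels obeying the torque-balance
# model, plus the two nuisance classes a tracker picks up -- stuck objects
# (negligible drift) and free monomers (single 4.5 um beads) -- with
# Gaussian localization noise.

#' Generate a synthetic microwheel track table with ground truth
#'
#' Wheels are assigned bead counts N drawn log-uniformly from
#' \code{n_beads_range}, giving radii \eqn{R = a\sqrt N}; each rotates at
#' the torque-balance rate and translates at \eqn{V = \beta\omega N} along
#' [rolling_direction()] of the field axis. Orientation advances by
#' \eqn{\omega \Delta t} and is reported wrapped to \eqn{(-\pi, \pi]}.
#' Stuck objects drift slower than 3 um/s in a random direction; monomers
#' have equivalent diameter 4.5 um and modest speeds. Positions carry
#' Gaussian localization noise; orientation is defined (non-NA) only for
#' wheels.
#'
#' The frame rate must oversample rotation (\eqn{\omega\Delta t < \pi});
#' a warning is issued otherwise, since aliased orientations cannot be
#' unwrapped downstream.
#'
#' @param n_wheels,n_stuck,n_monomers class counts.
#' @param n_beads_range range of wheel bead counts (log-uniform).
#' @param bead a [bead_spec()] (its \code{chi_imag} is the ground truth
#'   recovered by [fit_scaling()]).
#' @param field a [field_spec()].
#' @param fluid a [fluid_spec()].
#' @param coupling_length_um wet-friction coupling length in um.
#' @param frame_rate frames per second (> 0).
#' @param duration_s recording length in seconds (> 0).
#' @param position_noise_um localization noise SD, um.
#' @param orientation_noise_rad orientation noise SD, rad.
#' @param diameter_noise_um per-frame equivalent-diameter noise SD, um.
#' @param arena_um side of the square field of view, um.
#' @param seed integer seed; generation is a pure function of
#'   (arguments, seed).
#' @return an object of class \code{track_table}: list with \code{tracks}
#'   (object_id, frame, time_s, x_um, y_um, equivalent_diameter_um,
#'   orientation_rad) and \code{truth} (object_id, class, n_beads,
#'   radius_um, omega_rad_s, velocity_um_s), plus generating parameters.
#' @examples
#' tt <- generate_tracks(n_wheels = 5, seed = 1)
#' head(tt$tracks)
#' @export
generate_tracks <- function(n_wheels = 50, n_stuck = 5, n_monomers = 5,
                            n_beads_range = c(5, 320),
                            bead = bead_spec(), field = field_spec(),
                            fluid = fluid_spec(),
                            coupling_length_um = 0.05,
                            frame_rate = 200, duration_s = 1,
                            position_noise_um = 0.1,
                            orientation_noise_rad = 0.1,
                            diameter_noise_um = 0.05,
                            arena_um = 2000, seed = NULL) {
  stopifnot(inherits(bead, "bead_spec"), inherits(field, "field_spec"),
            inherits(fluid, "fluid_spec"))
  check_scalar(frame_rate, "frame_rate", lower = 0, strict = TRUE)
  check_scalar(duration_s, "duration_s", lower = 0, strict = TRUE)
  with_seed(seed, {
    n_obj <- n_wheels + n_stuck + n_monomers
    if (n_obj < 1) stop("no objects requested", call. = FALSE)
    cls <- rep(c("wheel", "stuck", "monomer"),
               c(n_wheels, n_stuck, n_monomers))
    H <- field_H_from_B(field$flux_density)
    dirv <- rolling_direction(field$axis)
    if (is.null(dirv)) dirv <- c(0, 0)  # uncambered: spins in place

    N <- rep(NA_real_, n_obj)
    R_um <- omega <- V_um <- numeric(n_obj)
    if (n_wheels > 0) {
      w <- which(cls == "wheel")
      N[w] <- round(exp(stats::runif(n_wheels, log(n_beads_range[1]),
                                     log(n_beads_range[2]))))
      R_m <- radius_from_count(N[w], bead$radius)
      omega[w] <- rotation_rate(N[w], bead, H, fluid$viscosity, R_m)
      V_um[w] <- translation_velocity(omega[w], N[w],
                                      coupling_length_um * 1e-6) * 1e6
      R_um[w] <- R_m * 1e6
    }
    if (n_stuck > 0) {
      s <- which(cls == "stuck")
      R_um[s] <- stats::runif(n_stuck, 4, 15)
      V_um[s] <- stats::runif(n_stuck, 0, 3)
      omega[s] <- NA_real_
    }
    if (n_monomers > 0) {
      m <- which(cls == "monomer")
      R_um[m] <- bead$radius * 1e6
      V_um[m] <- stats::runif(n_monomers, 0, 15)
      omega[m] <- NA_real_
    }
    dt <- 1 / frame_rate
    if (any(is.finite(omega) & omega * dt >= pi))
      warning("frame rate undersamples rotation (omega * dt >= pi); ",
              "orientation will alias")

    n_frames <- max(2L, floor(duration_s * frame_rate) + 1L)
    t_s <- (seq_len(n_frames) - 1L) * dt
    x0 <- stats::runif(n_obj, 0, arena_um)
    y0 <- stats::runif(n_obj, 0, arena_um)
    theta0 <- stats::runif(n_obj, -pi, pi)
    # non-wheel headings are random in-plane directions
    head_ang <- stats::runif(n_obj, 0, 2 * pi)
    ux <- ifelse(cls == "wheel", dirv[1], cos(head_ang))
    uy <- ifelse(cls == "wheel", dirv[2], sin(head_ang))

    obj <- rep(seq_len(n_obj), each = n_frames)
    tt <- rep(t_s, times = n_obj)
    x <- x0[obj] + V_um[obj] * tt * ux[obj] +
      stats::rnorm(length(obj), 0, position_noise_um)
    y <- y0[obj] + V_um[obj] * tt * uy[obj] +
      stats::rnorm(length(obj), 0, position_noise_um)
    d <- 2 * R_um[obj] + stats::rnorm(length(obj), 0, diameter_noise_um)
    ori <- ifelse(cls[obj] == "wheel",
                  theta0[obj] + omega[obj] * tt +
                    stats::rnorm(length(obj), 0, orientation_noise_rad),
                  NA_real_)
    ori <- ((ori + pi) %% (2 * pi)) - pi  # wrap to (-pi, pi]

    structure(list(
      tracks = data.frame(object_id = obj,
                          frame = rep(seq_len(n_frames), times = n_obj),
                          time_s = tt, x_um = x, y_um = y,
                          equivalent_diameter_um = pmax(d, 0),
                          orientation_rad = ori),
      truth = data.frame(object_id = seq_len(n_obj), class = cls,
                         n_beads = N, radius_um = R_um,
                         omega_rad_s = omega, velocity_um_s = V_um),
      bead = bead, field = field, fluid = fluid,
      coupling_length_um = coupling_length_um,
      frame_rate = frame_rate),
      class = "track_table")
  })
}

#' @export
print.track_table <- function(x, ...) {
  cat(sprintf("<track_table> %d objects (%s), %d rows at %g fps\n",
              nrow(x$truth),
              paste(names(table(x$truth$class)),
                    table(x$truth$class), sep = ":", collapse = ", "),
              nrow(x$tracks), x$frame_rate))
  invisible(x)
}

#' Write / read track tables as CSV
#'
#' The CSV column contract is that of \code{track_table$tracks}:
#' object_id, frame, time_s, x_um, y_um, equivalent_diameter_um,
#' orientation_rad.
#'
#' @param x a \code{track_table} or a tracks data.frame.
#' @param path CSV path.
#' @return \code{path} (write) or a tracks data.frame (read).
#' @export
write_tracks <- function(x, path) {
  df <- if (inherits(x, "track_table")) x$tracks else x
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  utils::read.csv(path)
}
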