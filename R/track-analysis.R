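# Per-object measurement of tracked microwheels, the stuck/monomer
# exclusion filter, scaling-law fits, and recovery of the imaginary
# susceptibility from the omega-vs-1/R slope.

# least squares through the origin; returns slope, its SE and the
# uncentered R^2 (appropriate for a model with no intercept)
fit_origin <- function(x, y) {
  sxx <- sum(x^2)
  if (sxx == 0) stop("degenerate fit: no spread in x", call. = FALSE)
  slope <- sum(x * y) / sxx
  r <- y - slope * x
  n <- length(x)
  se <- if (n > 1) sqrt(sum(r^2) / (n - 1) / sxx) else NA_real_
  r2 <- if (sum(y^2) > 0) 1 - sum(r^2) / sum(y^2) else NA_real_
  list(slope = slope, se = se, r_squared = r2)
}

slope_lm <- function(t, v) {
  tc <- t - mean(t)
  sum(tc * (v - mean(v))) / sum(tc^2)
}

#' Measure velocity, size and rotation rate per tracked object
#'
#' For each object: translational speed is the magnitude of the slope
#' vector of the straight-line position-versus-time fit; equivalent
#' diameter is the per-frame median; rotation rate is the slope of the
#' unwrapped orientation versus time (frame-to-frame phase steps wrapped
#' to \eqn{(-\pi,\pi]} before accumulation, so wrapped input is handled);
#' power is [power_from_measurement()] at the measured \eqn{\omega} and R.
#' Rows are sorted by frame internally, so input row order is irrelevant.
#' Objects with fewer than two frames are skipped with a warning.
#'
#' @param tracks a \code{track_table} from [generate_tracks()] or a tracks
#'   data.frame with its column contract.
#' @param fluid a [fluid_spec()] used for the power estimate.
#' @return data.frame of class \code{object_summary}: \code{object_id},
#'   \code{n_frames}, \code{velocity_um_s}, \code{diameter_um},
#'   \code{omega_rad_s} (NA without orientation data), \code{power_W}.
#' @examples
#' tt <- generate_tracks(n_wheels = 3, n_stuck = 1, seed = 1)
#' measure_objects(tt)
#' @export
measure_objects <- function(tracks, fluid = fluid_spec()) {
  df <- if (inherits(tracks, "track_table")) tracks$tracks else tracks
  need <- c("object_id", "frame", "time_s", "x_um", "y_um",
            "equivalent_diameter_um")
  if (!all(need %in% names(df)))
    stop("tracks are missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  has_ori <- "orientation_rad" %in% names(df)
  groups <- split(df, df$object_id)
  res <- lapply(groups, function(g) {
    if (nrow(g) < 2L) {
      warning("object ", g$object_id[1],
              " has a single frame; skipped")
      return(NULL)
    }
    g <- g[order(g$frame), , drop = FALSE]
    t <- g$time_s
    vx <- slope_lm(t, g$x_um)
    vy <- slope_lm(t, g$y_um)
    v <- sqrt(vx^2 + vy^2)
    dia <- stats::median(g$equivalent_diameter_um)
    om <- NA_real_
    if (has_ori && all(is.finite(g$orientation_rad))) {
      dphi <- diff(g$orientation_rad)
      dphi <- ((dphi + pi) %% (2 * pi)) - pi
      unwrapped <- c(0, cumsum(dphi))
      om <- slope_lm(t, unwrapped)
    }
    pw <- if (is.finite(om))
      power_from_measurement(fluid$viscosity, abs(om), dia / 2 * 1e-6)
    else NA_real_
    data.frame(object_id = g$object_id[1], n_frames = nrow(g),
               velocity_um_s = v, diameter_um = dia,
               omega_rad_s = om, power_W = pw)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("object_summary", "data.frame")
  out
}

#' Exclude stuck beads and monomers from object summaries
#'
#' Tracked objects that are not functioning microwheels are removed by two
#' per-class rules: stuck objects by velocity below \code{v_min}
#' (default 5 um/s) and monomers by equivalent diameter below \code{d_min}
#' (default 6.75 um, 1.5 bead diameters). In \code{mode = "or"} (default)
#' an object failing either rule is excluded; \code{mode = "and"} excludes
#' only objects failing both. The filter is idempotent.
#'
#' @param summaries data.frame from [measure_objects()].
#' @param v_min velocity threshold, um/s.
#' @param d_min diameter threshold, um.
#' @param mode \code{"or"} or \code{"and"}.
#' @return the summaries with added \code{kept} (logical) and
#'   \code{exclusion_reason} (\code{"stuck"}, \code{"monomer"},
#'   \code{"stuck+monomer"} or NA).
#' @examples
#' s <- data.frame(object_id = 1:3, n_frames = 10,
#'                 velocity_um_s = c(4, 50, 50),
#'                 diameter_um = c(20, 4.5, 20),
#'                 omega_rad_s = NA, power_W = NA)
#' exclusion_filter(s)$kept
#' @export
exclusion_filter <- function(summaries, v_min = 5, d_min = 6.75,
                             mode = c("or", "and")) {
  mode <- match.arg(mode)
  stuck <- summaries$velocity_um_s < v_min
  mono <- summaries$diameter_um < d_min
  excluded <- if (mode == "or") stuck | mono else stuck & mono
  summaries$kept <- !excluded
  summaries$exclusion_reason <- ifelse(!excluded, NA_character_,
    ifelse(stuck & mono, "stuck+monomer",
           ifelse(stuck, "stuck", "monomer")))
  summaries
}

#' Fit the microwheel scaling laws and recover the susceptibility
#'
#' Fits, by least squares through the origin, the three proportionalities
#' of the torque-balance model on filtered object summaries:
#' \eqn{V \propto R}, \eqn{P \propto R} and \eqn{\omega \propto 1/R}.
#' The \eqn{\omega}-vs-\eqn{1/R} slope is then inverted for the imaginary
#' susceptibility using \eqn{R = a\sqrt N}:
#' \deqn{\chi'' = 32 \eta a^2 \,\mathrm{slope}_\omega / (3 \nu \mu_0 H^2).}
#'
#' @param summaries data.frame from [measure_objects()], ideally after
#'   [exclusion_filter()] (rows with \code{kept == FALSE} are dropped).
#' @param field a [field_spec()].
#' @param fluid a [fluid_spec()].
#' @param bead a [bead_spec()] (geometry only; its \code{chi_imag} is not
#'   used).
#' @param with_intercept also report free-intercept diagnostic fits.
#' @return an object of class \code{scaling_fit}: per-law lists
#'   \code{v_vs_r}, \code{p_vs_r}, \code{omega_vs_inv_r} (slope, se,
#'   r_squared; SI units, radius in metres), \code{chi_imag} estimate and
#'   \code{n_objects}.
#' @examples
#' tt <- generate_tracks(n_wheels = 50, seed = 2)
#' s <- exclusion_filter(measure_objects(tt))
#' fit_scaling(s, tt$field, tt$fluid, tt$bead)
#' @export
fit_scaling <- function(summaries, field = field_spec(),
                        fluid = fluid_spec(), bead = bead_spec(),
                        with_intercept = FALSE) {
  stopifnot(inherits(field, "field_spec"), inherits(fluid, "fluid_spec"),
            inherits(bead, "bead_spec"))
  if ("kept" %in% names(summaries))
    summaries <- summaries[summaries$kept, , drop = FALSE]
  summaries <- summaries[is.finite(summaries$omega_rad_s), , drop = FALSE]
  if (nrow(summaries) < 3L)
    stop("degenerate fit: need at least 3 kept objects", call. = FALSE)
  R <- summaries$diameter_um / 2 * 1e-6
  if (max(R) / min(R) < 2)
    stop("degenerate fit: kept radii span less than a factor of 2",
         call. = FALSE)
  V <- summaries$velocity_um_s * 1e-6
  om <- abs(summaries$omega_rad_s)
  P <- summaries$power_W

  fits <- list(v_vs_r = fit_origin(R, V),
               p_vs_r = fit_origin(R, P),
               omega_vs_inv_r = fit_origin(1 / R, om))
  if (with_intercept) {
    fits$diagnostic <- list(
      v_vs_r = stats::coef(stats::lm(V ~ R)),
      omega_vs_inv_r = stats::coef(stats::lm(om ~ I(1 / R))))
  }
  H <- field_H_from_B(field$flux_density)
  fits$chi_imag <- 32 * fluid$viscosity * bead$radius^2 *
    fits$omega_vs_inv_r$slope / (3 * bead$volume * MU0 * H^2)
  fits$n_objects <- nrow(summaries)
  class(fits) <- "scaling_fit"
  fits
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> %d objects\n", x$n_objects))
  cat(sprintf("  V  ~ R   : slope %.4g 1/s (se %.2g, R2 %.4f)\n",
              x$v_vs_r$slope, x$v_vs_r$se, x$v_vs_r$r_squared))
  cat(sprintf("  P  ~ R   : slope %.4g W/m (se %.2g, R2 %.4f)\n",
              x$p_vs_r$slope, x$p_vs_r$se, x$p_vs_r$r_squared))
  cat(sprintf("  om ~ 1/R : slope %.4g m/s (se %.2g, R2 %.4f)\n",
              x$omega_vs_inv_r$slope, x$omega_vs_inv_r$se,
              x$omega_vs_inv_r$r_squared))
  cat(sprintf("  chi'' estimate: %.4g\n", x$chi_imag))
  invisible(x)
}

#' Compare two microwheel populations
#'
#' Mirrors the pre- versus post-aerosolization comparison: per-population
#' radius histograms and velocity-versus-radius slopes (through the
#' origin), with a seeded bootstrap interval on the slope difference.
#'
#' @param summaries_a,summaries_b data.frames from [measure_objects()]
#'   (rows with \code{kept == FALSE} are dropped; both must be nonempty
#'   after filtering).
#' @param n_boot bootstrap resamples.
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level of the percentile interval.
#' @param hist_breaks histogram cell count or breaks vector (um).
#' @return an object of class \code{population_comparison}: per-population
#'   slopes (1/s, SI) with SEs, radius histograms, the slope difference
#'   (a - b) and its bootstrap percentile interval.
#' @examples
#' a <- exclusion_filter(measure_objects(generate_tracks(30, seed = 1)))
#' b <- exclusion_filter(measure_objects(generate_tracks(
#'   30, n_beads_range = c(5, 80), seed = 2)))
#' compare_populations(a, b, n_boot = 200, seed = 3)
#' @export
compare_populations <- function(summaries_a, summaries_b, n_boot = 2000,
                                seed = NULL, conf = 0.95,
                                hist_breaks = 20) {
  keep <- function(s) {
    if ("kept" %in% names(s)) s <- s[s$kept, , drop = FALSE]
    if (nrow(s) == 0L)
      stop("a population is empty after filtering", call. = FALSE)
    s
  }
  a <- keep(summaries_a); b <- keep(summaries_b)
  slope_vr <- function(s) fit_origin(s$diameter_um / 2, s$velocity_um_s)
  fa <- slope_vr(a); fb <- slope_vr(b)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      ia <- sample.int(nrow(a), replace = TRUE)
      ib <- sample.int(nrow(b), replace = TRUE)
      slope_vr(a[ia, ])$slope - slope_vr(b[ib, ])$slope
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  brks <- if (length(hist_breaks) == 1L)
    seq(0, max(a$diameter_um, b$diameter_um) / 2 * 1.05,
        length.out = hist_breaks + 1L) else hist_breaks
  structure(list(
    slope_a = fa, slope_b = fb,
    slope_diff = fa$slope - fb$slope,
    slope_diff_ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
    radius_hist_a = graphics::hist(a$diameter_um / 2, breaks = brks,
                                   plot = FALSE),
    radius_hist_b = graphics::hist(b$diameter_um / 2, breaks = brks,
                                   plot = FALSE),
    n_a = nrow(a), n_b = nrow(b), n_boot = n_boot, conf = conf),
    class = "population_comparison")
}

#' @export
print.population_comparison <- function(x, ...) {
  cat(sprintf(
    "<population_comparison> n = %d vs %d\n", x$n_a, x$n_b))
  cat(sprintf("  V~R slope A: %.4g 1/s (se %.2g)\n",
              x$slope_a$slope, x$slope_a$se))
  cat(sprintf("  V~R slope B: %.4g 1/s (se %.2g)\n",
              x$slope_b$slope, x$slope_b$se))
  cat(sprintf("  difference : %.4g, %d%% bootstrap CI [%.4g, %.4g]\n",
              x$slope_diff, round(100 * x$conf),
              x$slope_diff_ci[1], x$slope_diff_ci[2]))
  invisible(x)
}
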