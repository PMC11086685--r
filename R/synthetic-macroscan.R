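# Synthetic brightfield macroscan of aerosol droplets sprayed into oil.
# Droplets are rendered as bright disks with a slightly darker rim on a
# darker background; embedded beads are dark disks. Ground truth (droplet
# and bead tables) is recorded exactly, making the scene a benchmark for
# the segmentation/assignment pipeline.

#' Imaging configuration for synthetic macroscans
#'
#' Default geometry corresponds to a 20x-objective scan: 0.323 um/px,
#' 8-bit intensities. Intensity levels are chosen so that droplet interior
#' and rim both sit well above the background while beads sit well below
#' it, as in brightfield images of aqueous droplets with dark beads.
#'
#' @param pixel_size_um physical pixel size in um/px; must be <= 0.5 so the
#'   0.5 um detection floor is resolvable.
#' @param background background grey level (0-255).
#' @param droplet_intensity droplet interior grey level.
#' @param rim_intensity droplet rim grey level.
#' @param bead_intensity bead grey level.
#' @param rim_width_um rim thickness in um.
#' @param noise_sd additive Gaussian noise, grey levels.
#' @return a list of class \code{imaging_config}.
#' @export
imaging_config <- function(pixel_size_um = 0.323, background = 100,
                           droplet_intensity = 210, rim_intensity = 160,
                           bead_intensity = 20, rim_width_um = 0.4,
                           noise_sd = 3) {
  check_scalar(pixel_size_um, "pixel_size_um", lower = 0, strict = TRUE)
  if (pixel_size_um > 0.5)
    stop("'pixel_size_um' must be <= 0.5 to resolve the detection floor",
         call. = FALSE)
  structure(list(pixel_size_um = pixel_size_um, background = background,
                 droplet_intensity = droplet_intensity,
                 rim_intensity = rim_intensity,
                 bead_intensity = bead_intensity,
                 rim_width_um = rim_width_um, noise_sd = noise_sd),
            class = "imaging_config")
}

# Place circles of radius r_um (sorted or not) uniformly in a side x side
# square without overlap, using a cell-list neighbourhood search. Returns
# centres plus the index set of circles that could not be placed without
# overlap after `tries` attempts (they are placed anyway).
place_circles <- function(r_um, side_um, tries = 100L) {
  n <- length(r_um)
  ord <- order(r_um, decreasing = TRUE)  # largest first: packs reliably
  cell <- max(2 * max(r_um), 1)
  ncell <- max(1L, ceiling(side_um / cell))
  cells <- vector("list", ncell * ncell)
  x <- numeric(n); y <- numeric(n)
  forced <- logical(n)
  for (i in ord) {
    r <- r_um[i]
    lo <- r; hi <- side_um - r
    if (hi <= lo) { lo <- side_um / 2; hi <- side_um / 2 }
    ok <- FALSE
    for (t in seq_len(tries)) {
      px <- stats::runif(1, lo, hi)
      py <- stats::runif(1, lo, hi)
      cx <- min(ncell, max(1L, ceiling(px / cell)))
      cy <- min(ncell, max(1L, ceiling(py / cell)))
      idx <- integer(0)
      for (dx in -1:1) {
        gx <- cx + dx
        if (gx < 1L || gx > ncell) next
        for (dy in -1:1) {
          gy <- cy + dy
          if (gy < 1L || gy > ncell) next
          idx <- c(idx, cells[[(gx - 1L) * ncell + gy]])
        }
      }
      if (length(idx) == 0L ||
          all((x[idx] - px)^2 + (y[idx] - py)^2 > (r_um[idx] + r)^2)) {
        ok <- TRUE
        break
      }
    }
    x[i] <- px; y[i] <- py
    forced[i] <- !ok
    ci <- (min(ncell, max(1L, ceiling(px / cell))) - 1L) * ncell +
      min(ncell, max(1L, ceiling(py / cell)))
    cells[[ci]] <- c(cells[[ci]], i)
  }
  list(x = x, y = y, forced = which(forced))
}

# Linear indices of the pixels of a filled disk, so callers can paint with
# img[disk_idx(...)] <- value without copying the image. Coordinates in um,
# pixel centres at (i - 0.5) * px; image indexed [row = y, col = x].
disk_idx <- function(dim_img, cx, cy, r, px) {
  nr <- dim_img[1L]; nc <- dim_img[2L]
  j0 <- max(1L, floor((cx - r) / px) + 1L)
  j1 <- min(nc, ceiling((cx + r) / px))
  i0 <- max(1L, floor((cy - r) / px) + 1L)
  i1 <- min(nr, ceiling((cy + r) / px))
  if (j1 < j0 || i1 < i0) return(integer(0))
  xs <- ((j0:j1) - 0.5) * px - cx
  ys <- ((i0:i1) - 0.5) * px - cy
  d2 <- outer(ys^2, xs^2, `+`)
  w <- which(d2 <= r^2)
  nw <- i1 - i0 + 1L
  rr <- ((w - 1L) %% nw) + i0
  cc <- ((w - 1L) %/% nw) + j0
  (cc - 1L) * nr + rr
}

#' Generate a synthetic droplet macroscan with ground truth
#'
#' Samples droplet diameters from a lognormal [droplet_population()],
#' seeds beads into droplets, lays the droplets out without overlap (up to
#' a budget) in a square field sized for a target packing fraction, and
#' renders an 8-bit image with additive Gaussian noise. Two seeding modes:
#'
#' \describe{
#'   \item{Poisson}{\code{concentration_per_ml} given: per-droplet bead
#'     counts are Poisson on droplet volume ([seed_beads()]), with droplets
#'     smaller than the bead forced bead-free when
#'     \code{fit_constraint = TRUE}.}
#'   \item{Bernoulli}{\code{bead_prob} given: each recordable droplet
#'     (diameter at least \code{2 * min_radius_um}) independently carries
#'     exactly one bead with that probability. This mode exists for
#'     pipeline-recovery benchmarks where a target bead-containing fraction
#'     among recorded droplets is prescribed directly.}
#' }
#'
#' A droplet that captures a bead cannot be smaller than the bead: host
#' diameters are raised to 1.1 x the bead diameter (the bead plus a thin
#' liquid envelope) where needed. Bead centres are rejection-sampled to lie
#' fully inside their host; beads in the same host avoid each other when
#' space permits.
#'
#' @param n_droplets number of droplets to render (>= 1).
#' @param population a [droplet_population()].
#' @param bead a [bead_spec()].
#' @param concentration_per_ml bead concentration in beads/mL (Poisson
#'   mode), or \code{NULL}.
#' @param bead_prob per-droplet bead probability (Bernoulli mode), or
#'   \code{NULL}. Exactly one of the two modes must be selected unless no
#'   beads are wanted (both \code{NULL} / 0).
#' @param fit_constraint force bead counts of droplets smaller than the
#'   bead to zero in Poisson mode.
#' @param imaging an [imaging_config()].
#' @param packing_fraction target droplet area fraction of the field.
#' @param max_overlap maximum tolerated overlapping-droplet area fraction;
#'   if exceeded the scene is regenerated (larger field) with a warning.
#' @param min_radius_um detection floor used to define "recordable" in
#'   Bernoulli mode.
#' @param seed integer seed; the generator is a pure function of
#'   (arguments, seed).
#' @return an object of class \code{macroscan_scene}: list with
#'   \code{image} (numeric matrix, grey levels 0-255),
#'   \code{pixel_size_um}, \code{droplet_truth} (id, x_um, y_um, radius_um,
#'   n_beads), \code{bead_truth} (id, x_um, y_um, droplet_id), and the
#'   generating parameters.
#' @examples
#' sc <- generate_macroscan(500, bead_prob = 0.05, seed = 1)
#' nrow(sc$bead_truth)
#' @export
generate_macroscan <- function(n_droplets,
                               population = droplet_population(),
                               bead = bead_spec(),
                               concentration_per_ml = NULL,
                               bead_prob = NULL,
                               fit_constraint = TRUE,
                               imaging = imaging_config(),
                               packing_fraction = 0.06,
                               max_overlap = 0.02,
                               min_radius_um = 0.5,
                               seed = NULL) {
  stopifnot(inherits(population, "droplet_population"),
            inherits(bead, "bead_spec"),
            inherits(imaging, "imaging_config"))
  check_scalar(n_droplets, "n_droplets", lower = 1)
  if (!is.null(concentration_per_ml) && !is.null(bead_prob))
    stop("give either 'concentration_per_ml' or 'bead_prob', not both",
         call. = FALSE)
  with_seed(seed, {
    d_um <- sample_droplets(population, n_droplets) * 1e6
    bead_d_um <- bead$diameter * 1e6

    counts <- integer(n_droplets)
    if (!is.null(concentration_per_ml)) {
      counts <- seed_beads(d_um * 1e-6, concentration_per_ml * 1e6,
                           bead_diameter = if (fit_constraint) bead$diameter)
    } else if (!is.null(bead_prob)) {
      check_scalar(bead_prob, "bead_prob", lower = 0)
      eligible <- d_um >= 2 * min_radius_um
      counts[eligible] <- stats::rbinom(sum(eligible), 1L, bead_prob)
    }
    # liquid envelope: a bead-bearing droplet is at least the bead plus a
    # ~1 um liquid shell (also keeps the bright rim resolvable at 20x)
    d_um[counts > 0] <- pmax(d_um[counts > 0], 1.45 * bead_d_um)
    r_um <- d_um / 2

    px <- imaging$pixel_size_um
    area <- sum(pi * r_um^2)
    for (attempt in 1:3) {
      side_um <- sqrt(area / packing_fraction)
      side_um <- max(side_um, 2.5 * max(d_um))
      pl <- place_circles(r_um, side_um)
      ov_frac <- sum(pi * r_um[pl$forced]^2) / area
      if (ov_frac <= max_overlap) break
      warning(sprintf(
        "droplet overlap fraction %.3g exceeds budget %.3g; regenerating in a larger field",
        ov_frac, max_overlap))
      packing_fraction <- packing_fraction / 2
    }

    npx <- ceiling(side_um / px)
    img <- matrix(imaging$background, nrow = npx, ncol = npx)
    dm <- dim(img)
    rim_in <- pmax(r_um - imaging$rim_width_um, 0)
    for (i in order(r_um, decreasing = TRUE)) {
      img[disk_idx(dm, pl$x[i], pl$y[i], r_um[i], px)] <-
        imaging$rim_intensity
      if (rim_in[i] > 0)
        img[disk_idx(dm, pl$x[i], pl$y[i], rim_in[i], px)] <-
          imaging$droplet_intensity
    }

    # bead positions: uniform in the host, fully inside, avoiding siblings
    host <- rep.int(seq_len(n_droplets), counts)
    nb <- length(host)
    bx <- numeric(nb); by <- numeric(nb)
    if (nb > 0) {
      rb <- bead_d_um / 2
      min_rim <- 2 * px  # keep the bright rim unbroken around the bead
      sep <- 2 * rb + 2 * px  # sibling beads stay visually separable
      n_tries <- 100L
      k <- 1L
      for (i in which(counts > 0)) {
        free <- max(r_um[i] - rb - min_rim, 0)  # max offset from centre
        placed_x <- numeric(0); placed_y <- numeric(0)
        for (b in seq_len(counts[i])) {
          for (t in seq_len(n_tries)) {
            rho <- free * sqrt(stats::runif(1))
            th <- stats::runif(1, 0, 2 * pi)
            cand <- c(pl$x[i] + rho * cos(th), pl$y[i] + rho * sin(th))
            if (length(placed_x) == 0L ||
                all((placed_x - cand[1])^2 + (placed_y - cand[2])^2 >
                    sep^2) || t == n_tries) break
          }
          placed_x <- c(placed_x, cand[1]); placed_y <- c(placed_y, cand[2])
          bx[k] <- cand[1]; by[k] <- cand[2]
          k <- k + 1L
        }
      }
      for (b in seq_len(nb))
        img[disk_idx(dm, bx[b], by[b], bead_d_um / 2, px)] <-
          imaging$bead_intensity
    }

    if (imaging$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, imaging$noise_sd)
    img <- matrix(round(pmin(pmax(img, 0), 255)), nrow = npx)

    structure(list(
      image = img,
      pixel_size_um = px,
      droplet_truth = data.frame(id = seq_len(n_droplets),
                                 x_um = pl$x, y_um = pl$y,
                                 radius_um = r_um, n_beads = counts),
      bead_truth = data.frame(id = seq_len(nb),
                              x_um = bx[seq_len(nb)], y_um = by[seq_len(nb)],
                              droplet_id = host),
      population = population, bead = bead, imaging = imaging,
      side_um = side_um,
      overlap_fraction = sum(pi * r_um[pl$forced]^2) / area),
      class = "macroscan_scene")
  })
}

#' @export
print.macroscan_scene <- function(x, ...) {
  cat(sprintf(
    "<macroscan_scene> %d x %d px (%.0f x %.0f um at %.3g um/px)\n",
    nrow(x$image), ncol(x$image), x$side_um, x$side_um, x$pixel_size_um))
  cat(sprintf("  %d droplets, %d beads (%.3g%% of droplets bead-laden)\n",
              nrow(x$droplet_truth), nrow(x$bead_truth),
              100 * mean(x$droplet_truth$n_beads > 0)))
  invisible(x)
}

#' Write a macroscan image to disk
#'
#' Writes the image as single-channel TIFF or PNG (chosen by extension)
#' with the pixel size recorded in a JSON sidecar, and, for a full scene,
#' the ground-truth tables as CSV next to it.
#'
#' @param x a \code{macroscan_scene} or a plain numeric matrix (grey
#'   levels 0-255).
#' @param path image path ending in \code{.tif}, \code{.tiff} or
#'   \code{.png}.
#' @param pixel_size_um required when \code{x} is a plain matrix.
#' @param truth write the ground-truth CSVs (scene input only).
#' @return \code{path}, invisibly.
#' @export
write_macroscan <- function(x, path, pixel_size_um = NULL, truth = TRUE) {
  if (inherits(x, "macroscan_scene")) {
    img <- x$image
    pixel_size_um <- x$pixel_size_um
  } else {
    img <- x
    if (is.null(pixel_size_um))
      stop("'pixel_size_um' is required for a plain matrix", call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  norm <- img / 255
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = 8)
  } else if (ext == "png") {
    png::writePNG(norm, path)
  } else stop("unsupported image extension: ", ext, call. = FALSE)
  jsonlite::write_json(list(pixel_size_um = pixel_size_um),
                       paste0(path, ".json"), auto_unbox = TRUE)
  if (truth && inherits(x, "macroscan_scene")) {
    base <- tools::file_path_sans_ext(path)
    utils::write.csv(x$droplet_truth, paste0(base, "_droplets.csv"),
                     row.names = FALSE)
    utils::write.csv(x$bead_truth, paste0(base, "_beads.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a macroscan image and its pixel-size sidecar
#'
#' @param path image path (TIFF or PNG) with a \code{<path>.json} sidecar
#'   holding \code{pixel_size_um}.
#' @return a list of class \code{macroscan_image} with \code{image}
#'   (grey levels 0-255) and \code{pixel_size_um}.
#' @export
read_macroscan <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else if (ext == "png") png::readPNG(path)
         else stop("unsupported image extension: ", ext, call. = FALSE)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing pixel-size sidecar: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar)
  structure(list(image = img * 255,
                 pixel_size_um = as.numeric(meta$pixel_size_um)),
            class = "macroscan_image")
}
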