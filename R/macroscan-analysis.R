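# Droplet characterization pipeline: threshold segmentation of droplets,
# detection of embedded beads, bead-to-droplet assignment, and population
# summaries. Works on synthetic scenes from generate_macroscan() or on
# images read with read_macroscan().

as_macroscan_image <- function(x) {
  if (inherits(x, c("macroscan_scene", "macroscan_image"))) {
    if (is.null(x$pixel_size_um))
      stop("image is missing pixel-size metadata", call. = FALSE)
    return(list(image = x$image, pixel_size_um = x$pixel_size_um))
  }
  stop("expected a 'macroscan_scene' or 'macroscan_image'", call. = FALSE)
}

# Label-matrix features without per-object loops: pixel areas, centroids
# (um, pixel centres at (i - 0.5) * px) and equivalent-circle radii.
label_features <- function(lab, px) {
  idx <- which(lab > 0L)
  if (length(idx) == 0L)
    return(data.frame(label = integer(0), x_um = numeric(0),
                      y_um = numeric(0), area_px = numeric(0),
                      radius_um = numeric(0)))
  l <- lab[idx]
  nr <- nrow(lab)
  yy <- ((idx - 1L) %% nr) + 1L
  xx <- ((idx - 1L) %/% nr) + 1L
  area <- tabulate(l)
  keep <- which(area > 0L)
  sx <- rowsum(as.numeric(xx), l)[, 1]
  sy <- rowsum(as.numeric(yy), l)[, 1]
  data.frame(label = keep,
             x_um = (sx / area[keep] - 0.5) * px,
             y_um = (sy / area[keep] - 0.5) * px,
             area_px = area[keep],
             radius_um = sqrt(area[keep] / pi) * px)
}

#' Segment droplets in a macroscan by global thresholding
#'
#' Binarizes the image (Otsu's method by default, or a fixed grey-level
#' threshold), fills interior holes (dark beads punch holes in bright
#' droplets), labels connected components and measures equivalent-circle
#' radii from pixel areas. Detections below the resolution floor
#' (radius < 0.5 um by default) are not recorded.
#'
#' @param x a \code{macroscan_scene} or \code{macroscan_image}.
#' @param method \code{"otsu"} or \code{"fixed"}.
#' @param threshold grey level (0-255) for \code{method = "fixed"}.
#' @param min_radius_um detection floor in um.
#' @param fill_holes fill holes before labelling.
#' @return data.frame with \code{id}, \code{x_um}, \code{y_um},
#'   \code{radius_um}, \code{area_px}.
#' @examples
#' sc <- generate_macroscan(200, bead_prob = 0.05, seed = 1)
#' head(segment_droplets(sc))
#' @export
segment_droplets <- function(x, method = c("otsu", "fixed"),
                             threshold = NULL, min_radius_um = 0.5,
                             fill_holes = TRUE) {
  method <- match.arg(method)
  m <- as_macroscan_image(x)
  img <- m$image / 255
  thr <- if (method == "otsu") {
    EBImage::otsu(EBImage::Image(img), range = c(0, 1), levels = 256)
  } else {
    if (is.null(threshold))
      stop("'threshold' is required for method = \"fixed\"", call. = FALSE)
    threshold / 255
  }
  mask <- EBImage::Image(img > thr)
  if (fill_holes) mask <- EBImage::fillHull(mask)
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  feats <- label_features(lab, m$pixel_size_um)
  feats <- feats[feats$radius_um >= min_radius_um, , drop = FALSE]
  feats <- feats[order(feats$label), , drop = FALSE]
  data.frame(id = seq_len(nrow(feats)), x_um = feats$x_um,
             y_um = feats$y_um, radius_um = feats$radius_um,
             area_px = feats$area_px)
}

#' Detect beads in a macroscan
#'
#' Beads appear as dark disks of known diameter. Pixels below a fixed dark
#' threshold are labelled and components whose equivalent diameter falls
#' within a tolerance band around the bead diameter are reported.
#'
#' @param x a \code{macroscan_scene} or \code{macroscan_image}.
#' @param bead a [bead_spec()].
#' @param threshold dark grey-level threshold (0-255).
#' @param tol relative tolerance on the equivalent diameter (default 0.25:
#'   accept 4.5 um beads measured between 3.4 and 5.6 um).
#' @return data.frame with \code{id}, \code{x_um}, \code{y_um},
#'   \code{diameter_um}.
#' @export
detect_beads <- function(x, bead = bead_spec(), threshold = 60, tol = 0.25) {
  m <- as_macroscan_image(x)
  mask <- EBImage::Image(m$image < threshold)
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  feats <- label_features(lab, m$pixel_size_um)
  d_um <- 2 * feats$radius_um
  nominal <- bead$diameter * 1e6
  keep <- d_um >= (1 - tol) * nominal & d_um <= (1 + tol) * nominal
  feats <- feats[keep, , drop = FALSE]
  data.frame(id = seq_len(nrow(feats)), x_um = feats$x_um,
             y_um = feats$y_um, diameter_um = 2 * feats$radius_um)
}

#' Assign detected beads to detected droplets
#'
#' Each bead is assigned to the droplet whose circle contains its centre;
#' if several circles contain it, the droplet with the nearest centre wins
#' (ties by lowest droplet id). A bead inside no circle is assigned to the
#' nearest droplet whose edge is within \code{tolerance_um}, else left
#' unassigned. The result is deterministic and independent of input row
#' order.
#'
#' @param beads data.frame from [detect_beads()] (needs \code{id},
#'   \code{x_um}, \code{y_um}).
#' @param droplets data.frame from [segment_droplets()] (needs \code{id},
#'   \code{x_um}, \code{y_um}, \code{radius_um}).
#' @param tolerance_um maximum edge gap for out-of-circle assignment
#'   (default one bead radius, 2.25 um).
#' @return data.frame with \code{bead_id}, \code{x_um}, \code{y_um},
#'   \code{droplet_id} (NA when unassigned).
#' @export
assign_beads <- function(beads, droplets, tolerance_um = 2.25) {
  stopifnot(all(c("id", "x_um", "y_um") %in% names(beads)),
            all(c("id", "x_um", "y_um", "radius_um") %in% names(droplets)))
  beads <- beads[order(beads$id), , drop = FALSE]
  droplets <- droplets[order(droplets$id), , drop = FALSE]
  nb <- nrow(beads)
  assigned <- rep.int(NA_integer_, nb)
  if (nb > 0 && nrow(droplets) > 0) {
    dx <- droplets$x_um; dy <- droplets$y_um
    dr <- droplets$radius_um; did <- droplets$id
    for (b in seq_len(nb)) {
      dist <- sqrt((dx - beads$x_um[b])^2 + (dy - beads$y_um[b])^2)
      inside <- dist <= dr
      if (any(inside)) {
        cand <- which(inside)
        assigned[b] <- did[cand[which.min(dist[cand])]]
      } else {
        gap <- dist - dr
        j <- which.min(gap)
        if (gap[j] <= tolerance_um) assigned[b] <- did[j]
      }
    }
  }
  data.frame(bead_id = beads$id, x_um = beads$x_um, y_um = beads$y_um,
             droplet_id = assigned)
}

#' Summarize a macroscan analysis
#'
#' Aggregates droplet detections and bead assignments into the population
#' statistics reported for aerosolized suspensions: droplet radius
#' histogram, count- and mass-median diameters, per-droplet bead counts,
#' and the fraction of droplets containing at least one assigned bead.
#'
#' @param droplets data.frame from [segment_droplets()] (nonempty).
#' @param assignments data.frame from [assign_beads()] (may be empty).
#' @param hist_breaks number of histogram cells or a breaks vector (um).
#' @return a list of class \code{macroscan_summary}: \code{n_droplets},
#'   \code{radius_hist} (counts/mids in um), \code{count_median_diameter_um},
#'   \code{mass_median_diameter_um}, \code{bead_counts} (per droplet id),
#'   \code{fraction_containing}.
#' @export
summarize_macroscan <- function(droplets, assignments = NULL,
                                hist_breaks = 50) {
  if (is.null(droplets) || nrow(droplets) == 0L)
    stop("'droplets' must be nonempty", call. = FALSE)
  diam <- 2 * droplets$radius_um
  counts <- integer(nrow(droplets))
  names(counts) <- droplets$id
  if (!is.null(assignments) && nrow(assignments) > 0) {
    tab <- table(assignments$droplet_id[!is.na(assignments$droplet_id)])
    counts[names(tab)] <- as.integer(tab)
  }
  h <- graphics::hist(droplets$radius_um, breaks = hist_breaks,
                      plot = FALSE)
  structure(list(
    n_droplets = nrow(droplets),
    radius_hist = data.frame(mid_um = h$mids, count = h$counts),
    count_median_diameter_um = stats::median(diam),
    mass_median_diameter_um = mass_median(diam),
    bead_counts = counts,
    fraction_containing = mean(counts >= 1)),
    class = "macroscan_summary")
}

#' @export
print.macroscan_summary <- function(x, ...) {
  cat(sprintf(
    "<macroscan_summary> %d droplets; CMD %.3g um, MMD %.3g um; %.4g%% bead-containing\n",
    x$n_droplets, x$count_median_diameter_um, x$mass_median_diameter_um,
    100 * x$fraction_containing))
  invisible(x)
}

#' Run the full macroscan pipeline
#'
#' Convenience wrapper: [segment_droplets()], [detect_beads()],
#' [assign_beads()], [summarize_macroscan()].
#'
#' @param x a \code{macroscan_scene} or \code{macroscan_image}.
#' @param bead a [bead_spec()].
#' @param ... passed to [segment_droplets()].
#' @return list with \code{droplets}, \code{beads}, \code{assignments},
#'   \code{summary}.
#' @examples
#' sc <- generate_macroscan(300, bead_prob = 0.05, seed = 7)
#' analyze_macroscan(sc)$summary
#' @export
analyze_macroscan <- function(x, bead = bead_spec(), ...) {
  droplets <- segment_droplets(x, ...)
  beads <- detect_beads(x, bead = bead)
  assignments <- assign_beads(beads, droplets,
                              tolerance_um = bead$radius * 1e6)
  list(droplets = droplets, beads = beads, assignments = assignments,
       summary = summarize_macroscan(droplets, assignments))
}
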