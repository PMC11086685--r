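# Droplet segmentation, bead detection, assignment and summaries,
# validated against generator ground truth.

# match detections to truth by nearest centre within a radius
match_truth <- function(det, truth, max_dist_um = 1.5) {
  vapply(seq_len(nrow(truth)), function(i) {
    d <- sqrt((det$x_um - truth$x_um[i])^2 + (det$y_um - truth$y_um[i])^2)
    j <- which.min(d)
    if (length(j) == 1 && d[j] <= max_dist_um) j else NA_integer_
  }, integer(1))
}

test_that("segmentation recovers droplets above 1 um radius with sub-pixel accuracy", {
  sc <- generate_macroscan(2000, bead_prob = 0.02, seed = 31)
  det <- segment_droplets(sc)
  truth <- sc$droplet_truth[sc$droplet_truth$radius_um >= 1, ]
  m <- match_truth(det, truth)
  expect_gte(mean(!is.na(m)), 0.98)
  err <- abs(det$radius_um[m[!is.na(m)]] - truth$radius_um[!is.na(m)])
  # radius error within one pixel equivalent
  expect_lt(stats::median(err), sc$pixel_size_um)
  expect_lt(stats::quantile(err, 0.95), 2 * sc$pixel_size_um)
})

test_that("the 0.5 um radius recording floor is applied", {
  # scene dominated by sub-floor droplets
  pop <- droplet_population(cmd_um = 0.4, gsd = 1.3)
  sc <- generate_macroscan(500, population = pop, seed = 6)
  expect_gt(sum(sc$droplet_truth$radius_um < 0.45), 0)
  det <- segment_droplets(sc)
  expect_true(all(det$radius_um >= 0.5))
  # a clearly sub-floor truth droplet has no matching detection
  small <- sc$droplet_truth[sc$droplet_truth$radius_um < 0.4, ]
  if (nrow(small) > 0) {
    m <- match_truth(det, small, max_dist_um = 0.5)
    expect_true(all(is.na(m)))
  }
})

test_that("blank images yield empty tables and missing metadata errors", {
  blank <- structure(list(image = matrix(100, 200, 200),
                          pixel_size_um = 0.323),
                     class = "macroscan_image")
  expect_equal(nrow(segment_droplets(blank)), 0L)
  expect_equal(nrow(detect_beads(blank)), 0L)
  no_px <- structure(list(image = matrix(100, 10, 10),
                          pixel_size_um = NULL),
                     class = "macroscan_image")
  expect_error(segment_droplets(no_px), "pixel-size")
  expect_error(summarize_macroscan(data.frame()), "nonempty")
})

test_that("bead detection reaches the recall/precision targets and keeps multiplicity", {
  sc <- generate_macroscan(3000, bead_prob = 0.08, seed = 33)
  beads <- detect_beads(sc)
  truth <- sc$bead_truth
  m <- match_truth(beads, truth, max_dist_um = 1.5)
  expect_gte(mean(!is.na(m)), 0.95)               # recall
  expect_lte(nrow(beads) - sum(!is.na(m)), 0.02 * nrow(truth))  # false pos.
  # several beads in one droplet give one detection each
  sc2 <- generate_macroscan(1, population = droplet_population(cmd_um = 30,
                                                               gsd = 1.01),
                            concentration_per_ml = 5e8, seed = 40)
  expect_gte(nrow(sc2$bead_truth), 2)
  expect_equal(nrow(detect_beads(sc2)), nrow(sc2$bead_truth))
})

test_that("bead assignment follows containment, nearest-centre and tolerance rules", {
  droplets <- data.frame(id = c(1, 2, 3),
                         x_um = c(10, 16, 50), y_um = c(10, 10, 50),
                         radius_um = c(5, 5, 4))
  beads <- data.frame(id = 1:3,
                      x_um = c(10, 13.4, 80), y_um = c(10, 10, 80))
  out <- assign_beads(beads, droplets, tolerance_um = 2.25)
  expect_equal(out$droplet_id[1], 1)   # at a droplet centre
  # bead 2 is inside both circles (d1 = 3.4 < 5, d2 = 2.6 < 5): nearer
  # centre (droplet 2) wins — brute force over both candidates
  expect_equal(out$droplet_id[2], 2)
  expect_true(is.na(out$droplet_id[3]))  # far beyond tolerance
  # just-outside bead within tolerance attaches to the nearest droplet
  near <- data.frame(id = 1, x_um = 56, y_um = 50)
  expect_equal(assign_beads(near, droplets)$droplet_id, 3)
  # permutation invariance of input order
  perm <- assign_beads(beads[c(3, 1, 2), ], droplets[c(2, 3, 1), ])
  expect_equal(perm, out)
})

test_that("the full pipeline recovers seeded fraction and population MMD", {
  pop <- droplet_population(mmd_um = 3.5, gsd = 2)
  p <- 0.05
  sc <- generate_macroscan(8000, population = pop, bead_prob = p, seed = 44)
  res <- analyze_macroscan(sc)
  n_rec <- sum(sc$droplet_truth$radius_um >= 0.5)
  expect_lt(abs(res$summary$fraction_containing - p),
            3 * sqrt(p * (1 - p) / n_rec))
  # mass median of recovered diameters close to the truth mass median
  truth_mmd <- mass_median(2 * sc$droplet_truth$radius_um)
  expect_equal(res$summary$mass_median_diameter_um, truth_mmd,
               tolerance = 0.05)
})
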