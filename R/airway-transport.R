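# Minimal planar branching-airway geometry and heading-controlled routing
# of rolling microwheels: an abstract stand-in for a 3D-printed
# pediatric-scale lung model (tracheal diameter ~8 mm) in which the field
# rotation axis steers wheels branch by branch.

#' Build a symmetric planar airway tree
#'
#' Binary tree in the xy plane: the tracheal inlet (root) points along +x;
#' each branch spawns two children rotated by plus and minus the branching
#' angle from the parent direction. Diameters and segment lengths shrink
#' by fixed ratios per generation (the 0.78 diameter ratio is a standard
#' regular-dichotomy value for conducting airways).
#'
#' @param depth number of bifurcation levels (>= 1).
#' @param root_diameter_mm tracheal diameter, mm (default 8, infant
#'   scale).
#' @param root_length_mm length of the two first-generation segments, mm.
#' @param branch_angle_deg half-angle between sibling branches, degrees.
#' @param diameter_ratio child/parent diameter ratio.
#' @param length_ratio child/parent segment-length ratio.
#' @return an object of class \code{airway_tree}: \code{nodes} (id, x_mm,
#'   y_mm, diameter_mm, level), \code{edges} (parent, child, length_mm,
#'   dir_x, dir_y). Node 1 is the inlet; node count is 2^(depth+1) - 1.
#' @examples
#' build_tree(depth = 3)
#' @export
build_tree <- function(depth, root_diameter_mm = 8, root_length_mm = 20,
                       branch_angle_deg = 35, diameter_ratio = 0.78,
                       length_ratio = 0.78) {
  check_scalar(depth, "depth", lower = 1)
  ang <- branch_angle_deg * pi / 180
  n_nodes <- 2L^(depth + 1L) - 1L
  nodes <- data.frame(id = seq_len(n_nodes), x_mm = 0, y_mm = 0,
                      diameter_mm = root_diameter_mm, level = 0L)
  theta <- numeric(n_nodes)  # direction of the edge arriving at the node
  edges <- data.frame(parent = integer(0), child = integer(0),
                      length_mm = numeric(0), dir_x = numeric(0),
                      dir_y = numeric(0))
  for (p in seq_len(2L^depth - 1L)) {
    lvl <- nodes$level[p] + 1L
    len <- root_length_mm * length_ratio^(lvl - 1L)
    for (k in 0:1) {
      ch <- 2L * p + k
      th <- theta[p] + (if (k == 0) ang else -ang)
      theta[ch] <- th
      nodes$x_mm[ch] <- nodes$x_mm[p] + len * cos(th)
      nodes$y_mm[ch] <- nodes$y_mm[p] + len * sin(th)
      nodes$diameter_mm[ch] <- nodes$diameter_mm[p] * diameter_ratio
      nodes$level[ch] <- lvl
      edges <- rbind(edges, data.frame(parent = p, child = ch,
                                       length_mm = len,
                                       dir_x = cos(th), dir_y = sin(th)))
    }
  }
  structure(list(nodes = nodes, edges = edges, depth = depth),
            class = "airway_tree")
}

#' @export
print.airway_tree <- function(x, ...) {
  leaf_d <- min(x$nodes$diameter_mm)
  cat(sprintf(
    "<airway_tree> depth %d: %d nodes, diameters %.3g -> %.3g mm\n",
    x$depth, nrow(x$nodes), max(x$nodes$diameter_mm), leaf_d))
  invisible(x)
}

#' Heading plan: a schedule of field rotation axes
#'
#' @param axes numeric matrix (k x 3) or list of unit 3-vectors, one per
#'   plan segment.
#' @param durations_s segment durations in seconds (> 0), length k.
#' @return an object of class \code{heading_plan}.
#' @examples
#' heading_plan(rbind(c(0, cos(pi / 6), -0.5),
#'                    c(cos(pi / 6), 0, -0.5)), c(60, 300))
#' @export
heading_plan <- function(axes, durations_s) {
  if (is.list(axes)) axes <- do.call(rbind, axes)
  axes <- matrix(as.numeric(axes), ncol = 3)
  apply(axes, 1, check_unit_axis)
  if (length(durations_s) != nrow(axes))
    stop("'durations_s' must match the number of axes", call. = FALSE)
  if (any(durations_s <= 0))
    stop("'durations_s' must be > 0", call. = FALSE)
  structure(list(axes = axes, durations_s = as.numeric(durations_s)),
            class = "heading_plan")
}

#' Route a microwheel through an airway tree under a heading plan
#'
#' The wheel starts at the inlet and rolls edge by edge at constant speed.
#' At each bifurcation the child edge maximizing the dot product between
#' its direction and the current rolling direction
#' ([rolling_direction()] of the axis active at the arrival time) is
#' taken; ties break toward the lower child id. Transit time per edge is
#' length/velocity. If the plan runs out (or the active axis has no
#' in-plane component) before a leaf is reached, the partial path is
#' returned with \code{complete = FALSE}.
#'
#' @param tree an [build_tree()] result.
#' @param plan a [heading_plan()].
#' @param velocity_um_s rolling speed in um/s (> 0).
#' @return an object of class \code{airway_route}: \code{path} (node ids),
#'   \code{arrival_s} (cumulative times, starting at 0 for the inlet),
#'   \code{complete}, \code{reason} (when incomplete).
#' @examples
#' tr <- build_tree(3)
#' pl <- heading_plan(rbind(c(0, cos(pi / 6), -0.5)), 1e5)
#' route(tr, pl, velocity_um_s = 100)
#' @export
route <- function(tree, plan, velocity_um_s) {
  stopifnot(inherits(tree, "airway_tree"), inherits(plan, "heading_plan"))
  check_scalar(velocity_um_s, "velocity_um_s", lower = 0, strict = TRUE)
  cum_plan <- cumsum(plan$durations_s)
  node <- 1L
  t_now <- 0
  path <- node
  arrival <- 0
  complete <- TRUE
  reason <- NA_character_
  repeat {
    kids <- tree$edges[tree$edges$parent == node, , drop = FALSE]
    if (nrow(kids) == 0L) break  # leaf
    seg <- which(t_now < cum_plan)[1L]
    if (is.na(seg)) {
      complete <- FALSE; reason <- "plan exhausted"; break
    }
    dirv <- rolling_direction(plan$axes[seg, ])
    if (is.null(dirv)) {
      complete <- FALSE; reason <- "no in-plane heading (spinning in place)"
      break
    }
    score <- kids$dir_x * dirv[1] + kids$dir_y * dirv[2]
    best <- which(score > max(score) - 1e-12)
    pick <- kids[best[which.min(kids$child[best])], ]
    t_now <- t_now + pick$length_mm * 1e3 / velocity_um_s
    node <- pick$child
    path <- c(path, node)
    arrival <- c(arrival, t_now)
  }
  structure(list(path = path, arrival_s = arrival, complete = complete,
                 reason = reason),
            class = "airway_route")
}

#' @export
print.airway_route <- function(x, ...) {
  cat(sprintf("<airway_route> %s: %s (%.3g s)%s\n",
              if (x$complete) "complete" else "partial",
              paste(x$path, collapse = " -> "),
              x$arrival_s[length(x$arrival_s)],
              if (x$complete) "" else paste0(" [", x$reason, "]")))
  invisible(x)
}

#' Rescale a rolling velocity for a different viscosity
#'
#' Rolling speed is inversely proportional to viscosity at fixed wheel
#' size: \eqn{V' = V \eta_{ref} / \eta_{new}}.
#'
#' @param velocity reference velocity (any unit); vectorised.
#' @param eta_ref reference viscosity (> 0).
#' @param eta_new new viscosity (> 0), same unit as \code{eta_ref}.
#' @return velocity in the input unit.
#' @examples
#' viscosity_slowdown(100, 1, 2)  # 50
#' @export
viscosity_slowdown <- function(velocity, eta_ref, eta_new) {
  if (any(eta_ref <= 0) || any(eta_new <= 0))
    stop("viscosities must be > 0", call. = FALSE)
  velocity * eta_ref / eta_new
}

#' Serialize / load an airway tree as JSON
#'
#' @param tree an \code{airway_tree}.
#' @param path JSON path.
#' @return \code{path} (write) or an \code{airway_tree} (read).
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "airway_tree"))
  jsonlite::write_json(list(nodes = tree$nodes, edges = tree$edges,
                            depth = tree$depth),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(nodes = as.data.frame(obj$nodes),
                 edges = as.data.frame(obj$edges),
                 depth = as.integer(obj$depth)),
            class = "airway_tree")
}
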