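#' Synthetic vascular tree presets
#'
#' Each preset emulates one class of vascular anatomy at the scale the
#' planner is benchmarked on: a 2D femoral-like tree (highly tortuous
#' projections, sharp bifurcation), 2D lower-limb arteries (long and nearly
#' straight), a 3D aorta-like vessel, and a 3D coronary-like tree (small
#' radii, tight turns).  A preset fixes the target arc-chord tortuosity
#' (mean and between-seed sd), the branch geometry, the radius profile and
#' point spacing, and the device curvature limit S used when planning on
#' models from that preset.
#'
#' Trees are assembled from circular-arc serpentines: arcs of radius
#' \code{arc_radius} turning alternately left and right through angles drawn
#' around \code{turn_angle} (radians).  For an ideal alternating serpentine
#' the tortuosity is \eqn{\theta / \sin\theta}; the stored
#' \code{turn_angle} values are calibrated numerically on the full
#' generator (junction kink included) so that the mean main-path tortuosity
#' over many seeds matches \code{tortuosity_mean}.  The sharp presets
#' (femoral2d, coronary3d) join the goal branch at a reflex angle through a
#' sub-millimetre fillet, which makes any centerline-following curve exceed
#' S at the bifurcation — the situation the local optimizer exists for.
#'
#' @param name one of \code{"femoral2d"}, \code{"lowerlimb2d"},
#'   \code{"aorta3d"}, \code{"coronary3d"}, or \code{"straight2d"} (a
#'   degenerate single straight vessel used for sanity checks).
#' @return an object of class \code{synth_preset}.
#' @export
synth_preset <- function(name) {
  presets <- list(
    femoral2d = list(
      dim = 2L, tortuosity_mean = 2.365, tortuosity_sd = 0.100,
      curvature_limit = 0.08, point_spacing = 2.0,
      arc_radius = 18, trunk_arcs = 3L, branch_arcs = 2L,
      turn_angle = 3.650, turn_angle_sd = 0.120,
      junction_angle = 50 * pi / 180, fillet_radius = 0.8,
      radius_root = 3.5, radius_tip = 2.4, junction_bump = 1.5,
      stub_length = 12, junction_leg = 20, plane_tilt_sd = 0),
    lowerlimb2d = list(
      dim = 2L, tortuosity_mean = 1.067, tortuosity_sd = 0.015,
      curvature_limit = 0.10, point_spacing = 2.5,
      arc_radius = 45, trunk_arcs = 2L, branch_arcs = 2L,
      turn_angle = 1.030, turn_angle_sd = 0.105,
      junction_angle = 35 * pi / 180, fillet_radius = 15,
      radius_root = 3.2, radius_tip = 2.0, junction_bump = 0.5,
      stub_length = 15, junction_leg = 0, plane_tilt_sd = 0),
    aorta3d = list(
      dim = 3L, tortuosity_mean = 1.075, tortuosity_sd = 0.045,
      curvature_limit = 0.08, point_spacing = 3.0,
      arc_radius = 60, trunk_arcs = 2L, branch_arcs = 2L,
      turn_angle = 1.000, turn_angle_sd = 0.250,
      junction_angle = 40 * pi / 180, fillet_radius = 25,
      radius_root = 11, radius_tip = 6, junction_bump = 2,
      stub_length = 20, junction_leg = 0, plane_tilt_sd = 0.3),
    coronary3d = list(
      dim = 3L, tortuosity_mean = 1.501, tortuosity_sd = 0.120,
      curvature_limit = 0.20, point_spacing = 0.9,
      arc_radius = 8, trunk_arcs = 3L, branch_arcs = 2L,
      turn_angle = 2.340, turn_angle_sd = 0.130,
      junction_angle = 45 * pi / 180, fillet_radius = 0.7,
      radius_root = 2.0, radius_tip = 1.3, junction_bump = 1.0,
      stub_length = 6, junction_leg = 8, plane_tilt_sd = 0.4),
    straight2d = list(
      dim = 2L, tortuosity_mean = 1.0, tortuosity_sd = 0,
      curvature_limit = 0.08, point_spacing = 2.0,
      arc_radius = Inf, trunk_arcs = 1L, branch_arcs = 0L,
      turn_angle = 0, turn_angle_sd = 0,
      junction_angle = 0, fillet_radius = 0,
      radius_root = 3.0, radius_tip = 2.5, junction_bump = 0,
      stub_length = 0, junction_leg = 0, plane_tilt_sd = 0,
      straight_length = 120)
  )
  if (!name %in% names(presets)) {
    stopf("unknown preset '%s' (choose from %s)", name,
          paste(names(presets), collapse = ", "))
  }
  structure(c(list(name = name), presets[[name]]), class = "synth_preset")
}

#' @export
print.synth_preset <- function(x, ...) {
  cat(sprintf("<synth_preset> %s: N = %d, tortuosity %.3f +/- %.3f, S = %.2f mm^-1\n",
              x$name, x$dim, x$tortuosity_mean, x$tortuosity_sd, x$curvature_limit))
  invisible(x)
}

# Rotate vector v around unit axis a by angle phi (Rodrigues); 3D only.
rotate_about <- function(v, a, phi) {
  v * cos(phi) + cross3(a, v) * sin(phi) + a * sum(a * v) * (1 - cos(phi))
}
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Points along a circular arc from x0 with unit heading h, in-plane turn
# direction b (unit, perpendicular to h), radius R, turn angle theta > 0,
# sampled at ~spacing.  Returns points excluding x0 plus the end frame.
arc_points <- function(x0, h, b, R, theta, spacing) {
  len <- R * theta
  n <- max(1L, round(len / spacing))
  phi <- seq_len(n) * theta / n
  center <- x0 + R * b
  pts <- t(vapply(phi, function(p) center - R * b * cos(p) + R * h * sin(p),
                  numeric(length(x0))))
  list(pts = pts,
       h = b * sin(theta) + h * cos(theta),
       b = b * cos(theta) - h * sin(theta))
}

# Straight run from x0 along h of given length.
straight_points <- function(x0, h, length, spacing) {
  n <- max(1L, round(length / spacing))
  d <- seq_len(n) * length / n
  t(vapply(d, function(s) x0 + s * h, numeric(length(x0))))
}

# Serpentine of `n_arcs` alternating arcs; returns points (excluding start)
# and the end frame.  In 3D each arc's plane is tilted about the current
# heading by a random angle (sd = plane_tilt_sd).
serpentine <- function(x0, h, b, n_arcs, R, angles, spacing, tilt_sd, sign0 = 1) {
  pts <- NULL
  s <- sign0
  for (j in seq_len(n_arcs)) {
    bj <- s * b
    if (tilt_sd > 0 && length(x0) == 3L) {
      bj <- rotate_about(bj, h, stats::rnorm(1L, 0, tilt_sd))
      bj <- bj - sum(bj * h) * h
      bj <- bj / sqrt(sum(bj^2))
    }
    a <- arc_points(x0, h, bj, R, angles[j], spacing)
    pts <- rbind(pts, a$pts)
    x0 <- a$pts[nrow(a$pts), ]
    h <- a$h
    b <- s * a$b           # restore a side-consistent reference normal
    s <- -s
  }
  list(pts = pts, h = h, b = b)
}

#' Generate a synthetic branching centerline tree
#'
#' Deterministic given \code{(preset, seed)}.  The tree consists of a trunk
#' serpentine, a bifurcation where a short stub continues along the trunk
#' heading while the goal branch leaves at the preset's junction angle
#' (through a fillet of the preset's radius), and a branch serpentine.  The
#' per-point radii taper linearly from root to tip with a smooth widening
#' around the bifurcation, as maximal-inscribed-sphere radii do at real
#' junctions.
#'
#' @param preset a \code{\link{synth_preset}} or preset name.
#' @param seed integer seed.
#' @return a \code{\link{centerline_model}} with \code{start_index} at the
#'   trunk root, \code{goal_index} at the branch tip, an attribute
#'   \code{main_path} (indices of the start-to-goal path), and the preset's
#'   curvature limit attached.
#' @examples
#' m <- generate_synthetic_tree("femoral2d", seed = 1)
#' tortuosity(m$points[attr(m, "main_path"), ])
#' @export
generate_synthetic_tree <- function(preset, seed = 0L) {
  if (is.character(preset)) preset <- synth_preset(preset)
  stopifnot(inherits(preset, "synth_preset"))
  with_seed(child_seed(seed, 11L), generate_tree_impl(preset, seed))
}

generate_tree_impl <- function(p, seed) {
  N <- p$dim
  x0 <- rep(0, N)
  h <- c(1, rep(0, N - 1L))
  b <- c(0, 1, rep(0, N - 2L))

  if (p$name == "straight2d") {
    pts <- rbind(x0, straight_points(x0, h, p$straight_length, p$point_spacing))
    n <- nrow(pts)
    radii <- seq(p$radius_root, p$radius_tip, length.out = n)
    m <- centerline_model(pts, radii, polylines = list(seq_len(n)),
                          name = "straight2d", start_index = 1L, goal_index = n,
                          curvature_limit = p$curvature_limit)
    attr(m, "main_path") <- seq_len(n)
    attr(m, "seed") <- seed
    return(m)
  }

  angles_t <- stats::rnorm(p$trunk_arcs, p$turn_angle, p$turn_angle_sd)
  angles_b <- stats::rnorm(p$branch_arcs, p$turn_angle, p$turn_angle_sd)
  angles_t <- pmax(angles_t, 0.05)
  angles_b <- pmax(angles_b, 0.05)

  trunk <- serpentine(x0, h, b, p$trunk_arcs, p$arc_radius, angles_t,
                      p$point_spacing, p$plane_tilt_sd)
  trunk_pts <- rbind(x0, trunk$pts)
  # vessels straighten on the approach to a bifurcation: a straight lead-in
  if (p$junction_leg > 0) {
    leg <- straight_points(trunk_pts[nrow(trunk_pts), ], trunk$h,
                           p$junction_leg, p$point_spacing)
    trunk_pts <- rbind(trunk_pts, leg)
  }
  nt <- nrow(trunk_pts)
  junction <- trunk_pts[nt, ]

  # stub: the other child of the bifurcation, continuing the trunk heading
  stub_pts <- straight_points(junction, trunk$h, p$stub_length, p$point_spacing)
  ns <- nrow(stub_pts)

  # goal branch: fillet turn of junction_angle, straight lead-out, then its
  # own serpentine
  s_fillet <- -sign_of_last(p$trunk_arcs)
  fil <- arc_points(junction, trunk$h, s_fillet * trunk$b,
                    p$fillet_radius, p$junction_angle, p$point_spacing)
  branch_pts <- fil$pts
  branch0 <- branch_pts[nrow(branch_pts), ]
  if (p$junction_leg > 0) {
    leg <- straight_points(branch0, fil$h, p$junction_leg, p$point_spacing)
    branch_pts <- rbind(branch_pts, leg)
    branch0 <- branch_pts[nrow(branch_pts), ]
  }
  br <- serpentine(branch0, fil$h, s_fillet * fil$b, p$branch_arcs,
                   p$arc_radius, angles_b, p$point_spacing, p$plane_tilt_sd,
                   sign0 = -1)
  branch_pts <- rbind(branch_pts, br$pts)
  nb <- nrow(branch_pts)

  pts <- rbind(trunk_pts, stub_pts, branch_pts)
  n <- nrow(pts)
  trunk_idx <- seq_len(nt)
  stub_idx <- nt + seq_len(ns)
  branch_idx <- nt + ns + seq_len(nb)
  main_path <- c(trunk_idx, branch_idx)

  # radii: linear taper along the main path arc length, junction widening
  arc_pos <- numeric(n)
  arc_pos[main_path] <- c(0, cumsum(row_norms(diff(pts[main_path, , drop = FALSE]))))
  arc_pos[stub_idx] <- arc_pos[nt] + seq_len(ns) * p$point_spacing
  total <- max(arc_pos)
  radii <- p$radius_root + (p$radius_tip - p$radius_root) * arc_pos / total
  dj <- abs(arc_pos - arc_pos[nt])
  radii <- radii + p$junction_bump * exp(-dj^2 / (2 * (4 * p$point_spacing)^2))
  radii <- radii + 0.05 * p$radius_tip * sin(arc_pos / (8 * p$point_spacing))
  radii <- pmax(radii, 0.3 * p$radius_tip)

  m <- centerline_model(
    pts, radii,
    polylines = list(main_path, c(nt, stub_idx)),
    name = p$name, start_index = 1L, goal_index = n,
    curvature_limit = p$curvature_limit)
  attr(m, "main_path") <- main_path
  attr(m, "seed") <- seed
  m
}

# Turn sign of the last arc of a serpentine started with sign +1.
sign_of_last <- function(n_arcs) if (n_arcs %% 2L == 1L) 1 else -1
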