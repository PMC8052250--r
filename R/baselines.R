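#' Centerline-sampling RRT and RRT* baseline planners
#'
#' Sampling-based comparison methods.  Instead of sampling the full
#' vascular volume, samples are drawn uniformly from the centerline points;
#' tree extension connects the nearest tree node to the sample by a
#' straight segment accepted only if every interpolated test point stays
#' inside the vessel (within the radius of its nearest centerline point,
#' tested every quarter local radius so a segment cannot tunnel through a
#' wall between test points).  With the configured probability a direct
#' connection to the goal is attempted.  The starred variant additionally
#' chooses the best parent among, and rewires, a bounded number of nearby
#' tree nodes.  Neither baseline enforces the curvature limit — their
#' curvature is only measured, which is exactly the contrast the benchmark
#' exists to show.
#'
#' @name baselines
NULL

#' Configuration for the RRT/RRT* baselines
#'
#' @param max_samples sample budget before the trial times out (4048).
#' @param goal_connect_prob probability of attempting a goal connection at
#'   each iteration (0.1).
#' @param rewire_count nearby branches considered for parent choice and
#'   rewiring in RRT* (32); 0 reduces RRT* to plain RRT.
#' @param seed integer seed.
#' @return object of class \code{rrt_config}.
#' @export
rrt_config <- function(max_samples = 4048L, goal_connect_prob = 0.1,
                       rewire_count = 32L, seed = 1L) {
  stopifnot(max_samples >= 1L, goal_connect_prob > 0, goal_connect_prob < 1)
  structure(list(max_samples = as.integer(max_samples),
                 goal_connect_prob = goal_connect_prob,
                 rewire_count = as.integer(rewire_count),
                 seed = as.integer(seed)),
            class = "rrt_config")
}

# Straight-segment collision test: interpolate at steps of a quarter of the
# smallest local radius and require every test point inside the vessel.
segment_free <- function(a, b, model) {
  len <- sqrt(sum((b - a)^2))
  if (len == 0) return(TRUE)
  step <- max(min(model$radii) / 4, 1e-6)
  n <- max(2L, ceiling(len / step) + 1L)
  tt <- seq(0, 1, length.out = n)
  pts <- outer(1 - tt, a) + outer(tt, b)
  dc <- distance_to_centerline(pts, model)
  all(dc$dist <= dc$radius)
}

#' Plan with the centerline-sampling RRT baseline
#'
#' @param model a \code{\link{centerline_model}}.
#' @param p0_index,pG_index 1-based start/goal point indices.
#' @param config a \code{\link{rrt_config}}; \code{rewire_count} is ignored
#'   (forced to 0).
#' @return a \code{path_curve} (node sequence smoothed with the same
#'   B-spline fit as the global planner) or a \code{plan_failure} after the
#'   sample budget is exhausted.
#' @export
rrt_plan <- function(model, p0_index, pG_index, config = rrt_config()) {
  config$rewire_count <- 0L
  rrt_star_plan(model, p0_index, pG_index, config)
}

#' Plan with the centerline-sampling RRT* baseline
#'
#' As \code{\link{rrt_plan}}, plus optimal parent choice among and
#' rewiring of up to \code{rewire_count} nearest tree nodes whenever that
#' shortens the cumulative path and the connection is collision-free.
#'
#' @inheritParams rrt_plan
#' @export
rrt_star_plan <- function(model, p0_index, pG_index, config = rrt_config()) {
  stopifnot(inherits(model, "centerline_model"), inherits(config, "rrt_config"))
  n <- nrow(model$points)
  p0_index <- as.integer(p0_index); pG_index <- as.integer(pG_index)
  if (p0_index < 1L || p0_index > n || pG_index < 1L || pG_index > n)
    stopf("start/goal index out of range")
  pts <- model$points
  # goal acceptance radius: one local point spacing
  nn <- cross_dist(pts[pG_index, , drop = FALSE], pts)
  goal_radius <- min(nn[nn > 0])

  if (p0_index == pG_index) {
    wp <- pts[c(p0_index, p0_index), , drop = FALSE]
    return(structure(plan_failure("start equals goal: trivial path"),
                     trivial = TRUE))
  }

  with_seed(config$seed, {
    tree_nodes <- p0_index          # centerline indices of tree nodes
    parent <- 0L
    cost <- 0
    goal_node <- NA_integer_
    draws <- 0L

    add_node <- function(idx, par, c_new) {
      tree_nodes[length(tree_nodes) + 1L] <<- idx
      parent[length(parent) + 1L] <<- par
      cost[length(cost) + 1L] <<- c_new
      length(tree_nodes)
    }

    try_connect <- function(sample_idx) {
      p_new <- pts[sample_idx, ]
      tp <- pts[tree_nodes, , drop = FALSE]
      d <- as.vector(cross_dist(matrix(p_new, 1L), tp))
      near_i <- which.min(d)
      if (d[near_i] == 0) return(NA_integer_)      # already in tree
      if (!segment_free(pts[tree_nodes[near_i], ], p_new, model)) return(NA_integer_)
      par <- near_i
      c_new <- cost[near_i] + d[near_i]
      if (config$rewire_count > 0L) {
        nb <- order(d)[seq_len(min(config$rewire_count, length(d)))]
        for (j in nb) {
          cj <- cost[j] + d[j]
          if (cj < c_new && segment_free(pts[tree_nodes[j], ], p_new, model)) {
            par <- j; c_new <- cj
          }
        }
      }
      node <- add_node(sample_idx, par, c_new)
      if (config$rewire_count > 0L) {
        nb <- order(d)[seq_len(min(config$rewire_count, length(d) - 1L))]
        for (j in nb) {
          c_thr <- c_new + d[j]
          if (c_thr < cost[j] &&
              segment_free(p_new, pts[tree_nodes[j], ], model)) {
            parent[j] <<- node
            cost[j] <<- c_thr
          }
        }
      }
      node
    }

    while (draws < config$max_samples && is.na(goal_node)) {
      draws <- draws + 1L
      sample_idx <- sample.int(n, 1L)
      node <- try_connect(sample_idx)
      if (!is.na(node) &&
          sqrt(sum((pts[sample_idx, ] - pts[pG_index, ])^2)) <= goal_radius) {
        goal_node <- node
      }
      if (is.na(goal_node) && stats::runif(1L) < config$goal_connect_prob) {
        gnode <- try_connect(pG_index)
        if (!is.na(gnode)) goal_node <- gnode
      }
    }

    if (is.na(goal_node)) {
      return(plan_failure(sprintf("no path found within %d samples",
                                  config$max_samples)))
    }
    seq_nodes <- goal_node
    while (parent[seq_nodes[1L]] != 0L) seq_nodes <- c(parent[seq_nodes[1L]], seq_nodes)
    waypoints <- pts[tree_nodes[seq_nodes], , drop = FALSE]
    if (tree_nodes[goal_node] != pG_index) {
      waypoints <- rbind(waypoints, pts[pG_index, ])
    }
    curve <- fit_bspline(waypoints)
    attr(curve, "tree_size") <- length(tree_nodes)
    attr(curve, "draws") <- draws
    curve
  })
}
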