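#' Build the k-nearest-neighbour connectivity graph over centerline points
#'
#' Each point is linked to its k nearest points by Euclidean distance; the
#' adjacency is then symmetrized (an edge is kept if either endpoint
#' selects the other).  The graph is the search space of the global
#' breadth-first planner.  Neighbour lists are stored sorted in ascending
#' index order, which fixes the BFS visiting order and makes planning
#' deterministic.
#'
#' @param model a \code{\link{centerline_model}} with at least 2 points.
#' @param k neighbours per node; default 4 in 2D and 6 in 3D, the smallest
#'   values that keep typical centerline point spacings connected across
#'   bifurcations.
#' @return the model with \code{$graph} set (list of sorted integer
#'   neighbour vectors, attribute \code{k}).
#' @export
build_knn_graph <- function(model, k = NULL) {
  stopifnot(inherits(model, "centerline_model"))
  n <- nrow(model$points)
  if (n < 2L) stopf("need at least 2 points to build a graph")
  if (is.null(k)) k <- if (model$N == 2L) 4L else 6L
  k <- as.integer(k)
  if (k < 1L) stopf("k must be >= 1")
  if (k >= n) stopf("k (%d) must be smaller than the point count (%d)", k, n)

  D <- cross_dist(model$points, model$points)
  diag(D) <- Inf
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    adj[[i]] <- order(D[i, ])[seq_len(k)]
  }
  # symmetrize: union of selections in both directions
  sym <- vector("list", n)
  for (i in seq_len(n)) sym[[i]] <- adj[[i]]
  for (i in seq_len(n)) for (j in adj[[i]]) sym[[j]] <- c(sym[[j]], i)
  model$graph <- lapply(sym, function(v) sort(unique(v)))
  attr(model$graph, "k") <- k
  model
}

#' Breadth-first search for a minimum-hop path between centerline points
#'
#' Classic BFS over the k-NN graph: nodes are expanded in hop-count order
#' (neighbours in ascending index order for determinism), and the waypoint
#' sequence is recovered by backtracking through the BFS parent tree.  The
#' returned path has the minimum possible number of hops.
#'
#' @param model a \code{centerline_model} with a graph (see
#'   \code{\link{build_knn_graph}}).
#' @param p0_index,pG_index 1-based start/goal point indices.
#' @return integer vector of point indices from start to goal, or
#'   \code{integer(0)} if the goal is unreachable (the planner reports this
#'   as an unsuccessful plan, not an error).
#' @export
bfs_path <- function(model, p0_index, pG_index) {
  stopifnot(inherits(model, "centerline_model"))
  if (is.null(model$graph)) stopf("model has no graph; call build_knn_graph() first")
  n <- nrow(model$points)
  p0_index <- as.integer(p0_index); pG_index <- as.integer(pG_index)
  if (p0_index < 1L || p0_index > n || pG_index < 1L || pG_index > n)
    stopf("start/goal index out of range")
  if (p0_index == pG_index) return(p0_index)

  parent <- integer(n)
  visited <- logical(n)
  visited[p0_index] <- TRUE
  queue <- p0_index
  head <- 1L
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L
    for (u in model$graph[[v]]) {
      if (!visited[u]) {
        visited[u] <- TRUE
        parent[u] <- v
        if (u == pG_index) {
          path <- u
          while (path[1L] != p0_index) path <- c(parent[path[1L]], path)
          return(path)
        }
        queue <- c(queue, u)
      }
    }
  }
  integer(0)
}

plan_failure <- function(reason) {
  structure(list(success = FALSE, reason = reason), class = "plan_failure")
}

#' Phase one: global planning of the tentative curve
#'
#' Composes \code{\link{build_knn_graph}}, \code{\link{bfs_path}} and
#' \code{\link{fit_bspline}}: the minimum-hop waypoint sequence between the
#' endpoints is smoothed into a cubic B-spline, the tentative curve that the
#' local optimizer inspects for curvature violations.  The curve starts and
#' ends exactly at the start and goal points.
#'
#' @inheritParams bfs_path
#' @param k neighbours for graph construction (see \code{\link{build_knn_graph}}).
#' @param dense_n dense sample count for the fitted curve (default 10 per
#'   waypoint).
#' @return a \code{path_curve}, or a \code{plan_failure} object (with
#'   \code{$success = FALSE} and a reason) when no path exists.
#' @export
plan_global <- function(model, p0_index, pG_index, k = NULL, dense_n = NULL) {
  if (is.null(model$graph) || !is.null(k)) model <- build_knn_graph(model, k)
  path <- bfs_path(model, p0_index, pG_index)
  if (!length(path)) return(plan_failure("no path exists between start and goal"))
  if (length(path) == 1L) return(plan_failure("start equals goal: nothing to plan"))
  curve <- fit_bspline(model$points[path, , drop = FALSE], dense_n)
  attr(curve, "waypoint_indices") <- path
  curve
}
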