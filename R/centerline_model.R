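#' Vascular centerline models
#'
#' A centerline model is the planner's search space: an ordered set of
#' centerline points \eqn{p_i} (2D or 3D, millimetres) with per-point
#' maximal-inscribed-sphere radii \eqn{r_i} (the minimum distance from the
#' point to the vascular wall), a set of polylines describing the branching
#' structure, and — once built — a k-nearest-neighbour connectivity graph.
#'
#' @param points numeric matrix, one row per centerline point, 2 or 3
#'   columns (millimetres).
#' @param radii positive numeric vector of per-point wall distances
#'   (millimetres), one per point.
#' @param polylines list of integer vectors (1-based point indices), each an
#'   ordered run along one vessel branch.  Defaults to a single run over all
#'   points.
#' @param name optional model/preset tag.
#' @param start_index,goal_index optional default planning endpoints
#'   (1-based point indices).
#' @param curvature_limit optional device curvature limit S associated with
#'   the model (mm^-1).
#' @return an object of class \code{centerline_model} with fields
#'   \code{points}, \code{radii}, \code{N} (dimensionality), \code{polylines},
#'   \code{graph} (NULL until \code{\link{build_knn_graph}}), and metadata.
#' @seealso \code{\link{read_centerlines}}, \code{\link{generate_synthetic_tree}}
#' @export
centerline_model <- function(points, radii, polylines = NULL, name = NULL,
                             start_index = NULL, goal_index = NULL,
                             curvature_limit = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points)
  if (n < 1L) stopf("model has no points")
  N <- ncol(points)
  if (!N %in% c(2L, 3L)) stopf("dimensionality must be 2 or 3, got %d", N)
  bad <- which(!apply(points, 1L, function(r) all(is.finite(r))))
  if (length(bad)) stopf("non-finite coordinate at record %d", bad[1L])
  radii <- as.numeric(radii)
  if (length(radii) != n) stopf("need one radius per point (%d points, %d radii)", n, length(radii))
  if (any(!is.finite(radii)) || any(radii <= 0)) stopf("radius must be positive")
  if (is.null(polylines)) polylines <- list(seq_len(n))
  for (pl in polylines) {
    if (any(pl < 1L | pl > n)) stopf("polyline index out of range")
  }
  structure(list(points = points, radii = radii, N = N,
                 polylines = lapply(polylines, as.integer),
                 graph = NULL, name = name,
                 start_index = start_index, goal_index = goal_index,
                 curvature_limit = curvature_limit),
            class = "centerline_model")
}

#' @export
print.centerline_model <- function(x, ...) {
  cat(sprintf("<centerline_model>%s %d points (N = %d), %d polyline(s), radii %.2f-%.2f mm%s\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              nrow(x$points), x$N, length(x$polylines),
              min(x$radii), max(x$radii),
              if (is.null(x$graph)) "" else sprintf(", k-NN graph (k = %d)", attr(x$graph, "k"))))
  invisible(x)
}

#' Arc-chord tortuosity of a polyline
#'
#' Cumulative arc length divided by the straight-line distance between the
#' endpoints.  A straight vessel has tortuosity 1; the ratio grows with
#' winding.
#'
#' @param polyline numeric matrix of ordered points (rows).
#' @return scalar tortuosity, always >= 1 up to floating-point error.
#' @examples
#' tortuosity(cbind(0:2, c(0, 0, 0)))  # 1
#' @export
tortuosity <- function(polyline) {
  pts <- as.matrix(polyline)
  if (nrow(pts) < 2L) stopf("tortuosity needs at least 2 points")
  chord <- sqrt(sum((pts[nrow(pts), ] - pts[1L, ])^2))
  if (chord == 0) stopf("tortuosity undefined: coincident endpoints")
  polyline_length(pts) / chord
}

#' Perturb planning endpoints with Gaussian noise and snap to the centerline
#'
#' Adds independent per-coordinate noise \eqn{N(0, \sigma^2)} to the start
#' and goal points (benchmark trials use \eqn{\sigma = 10} model units to
#' vary the task), then snaps each perturbed point to its nearest centerline
#' point so that graph search stays well-posed.
#'
#' @param model a \code{centerline_model}.
#' @param p0,pG numeric start/goal positions (length-N vectors).
#' @param sigma noise standard deviation per coordinate (model units, >= 0).
#' @param seed integer seed; the draw is deterministic given it.
#' @return list with perturbed-and-snapped positions \code{p0}, \code{pG}
#'   and the corresponding point indices \code{i0}, \code{iG}.
#' @export
perturb_endpoints <- function(model, p0, pG, sigma, seed = 1L) {
  stopifnot(inherits(model, "centerline_model"))
  if (sigma < 0) stopf("sigma must be non-negative")
  N <- model$N
  p0 <- as.numeric(p0); pG <- as.numeric(pG)
  if (length(p0) != N || length(pG) != N) stopf("endpoints must have %d coordinates", N)
  eps <- if (sigma > 0) {
    with_seed(seed, matrix(stats::rnorm(2L * N, 0, sigma), nrow = 2L))
  } else matrix(0, 2L, N)
  q0 <- p0 + eps[1L, ]
  qG <- pG + eps[2L, ]
  i0 <- which.min(row_norms(sweep(model$points, 2L, q0)))
  iG <- which.min(row_norms(sweep(model$points, 2L, qG)))
  list(p0 = model$points[i0, ], pG = model$points[iG, ], i0 = i0, iG = iG)
}
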