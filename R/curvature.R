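#' Curvature profile of a sampled B-spline curve
#'
#' Curvature at each dense sample from the analytic first and second
#' parametric derivatives, using the generic N-dimensional expression
#' \deqn{s = \sqrt{\tfrac12 \sum_{j,k} (\dot x_j \ddot x_k - \dot x_k
#' \ddot x_j)^2} \; / \; \|\dot x\|^3,}
#' evaluated through the Lagrange identity
#' \eqn{\frac12\sum_{j,k}(\dot x_j\ddot x_k-\dot x_k\ddot x_j)^2 =
#' \|\dot x\|^2\|\ddot x\|^2-(\dot x\cdot\ddot x)^2}.  For N = 3 this
#' equals the familiar cross-product formula, and for N = 2 it reduces to
#' \eqn{|\dot x_0\ddot x_1 - \dot x_1\ddot x_0| / \|\dot x\|^3}.  The value
#' is independent of the curve's parameterization.
#'
#' @param curve a \code{path_curve} carrying dense derivative samples.
#' @param S optional device curvature limit (mm^-1); when given, a
#'   per-sample violation mask (\code{s > S}) is attached.
#' @return object of class \code{curvature_profile}: \code{values}
#'   (non-negative, mm^-1), \code{limit}, \code{violated} (logical mask or
#'   NULL).
#' @export
curvature_profile <- function(curve, S = NULL) {
  stopifnot(inherits(curve, "path_curve"))
  curvature_from_derivs(curve$d1, curve$d2, S)
}

curvature_from_derivs <- function(d1, d2, S = NULL) {
  speed2 <- rowSums(d1^2)
  cusp <- which(speed2 < 1e-20)
  if (length(cusp))
    stopf("vanishing first derivative (cusp) at sample %d", cusp[1L])
  num2 <- speed2 * rowSums(d2^2) - rowSums(d1 * d2)^2
  num2[num2 < 0] <- 0
  values <- sqrt(num2) / speed2^1.5
  structure(list(values = values, limit = S,
                 violated = if (is.null(S)) NULL else values > S),
            class = "curvature_profile")
}

#' @export
print.curvature_profile <- function(x, ...) {
  cat(sprintf("<curvature_profile> %d samples, max %.4g mm^-1%s\n",
              length(x$values), max(x$values),
              if (is.null(x$limit)) "" else
                sprintf(", limit %.4g (%d violating)", x$limit, sum(x$violated))))
  invisible(x)
}

#' Extract the curve segments whose curvature exceeds the device limit
#'
#' Finds maximal runs of consecutive samples with \eqn{s_i > S}, expands
#' each run by the margin \eqn{\Delta} on both sides (clamped to the curve),
#' and merges windows whose expanded ranges overlap or touch, so that the
#' per-window optimizations never share samples.  An empty list means the
#' constraint holds everywhere and the tentative curve is already final.
#'
#' @param profile a \code{curvature_profile} with a limit set.
#' @param delta margin in dense samples (\eqn{\Delta \ge 0}); the planner
#'   default is 5\% of the total sample count.
#' @return list of \code{segment_window} objects with fields \code{i0},
#'   \code{iF} (first/last violating sample), \code{lo}, \code{hi}
#'   (expanded, clamped bounds) and \code{delta}; all indices 1-based.
#' @export
find_violation_windows <- function(profile, delta) {
  stopifnot(inherits(profile, "curvature_profile"))
  if (is.null(profile$violated)) stopf("profile has no curvature limit set")
  delta <- as.integer(delta)
  if (delta < 0L) stopf("delta must be non-negative")
  n <- length(profile$values)
  r <- rle(profile$violated)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs)) return(list())

  wins <- lapply(runs, function(j) {
    list(i0 = starts[j], iF = ends[j],
         lo = max(1L, starts[j] - delta), hi = min(n, ends[j] + delta),
         delta = delta)
  })
  # merge expanded windows that overlap or touch
  merged <- list(wins[[1L]])
  for (w in wins[-1L]) {
    last <- merged[[length(merged)]]
    if (w$lo <= last$hi + 1L) {
      last$iF <- w$iF; last$hi <- w$hi
      merged[[length(merged)]] <- last
    } else {
      merged[[length(merged) + 1L]] <- w
    }
  }
  lapply(merged, function(w) structure(w, class = "segment_window"))
}

#' @export
print.segment_window <- function(x, ...) {
  cat(sprintf("<segment_window> violating samples %d-%d, window %d-%d (delta %d)\n",
              x$i0, x$iF, x$lo, x$hi, x$delta))
  invisible(x)
}

#' Distance from sampled path points to the vascular centerline
#'
#' For each sample, the minimum Euclidean distance over all centerline
#' points, paired with the index and maximal-inscribed-sphere radius of the
#' nearest centerline point.  A sample lies inside the vessel exactly when
#' its distance does not exceed that radius.
#'
#' @param points numeric matrix of sampled positions (rows).
#' @param model a \code{\link{centerline_model}}.
#' @return list with numeric \code{dist} (\eqn{d_{ci}}), integer
#'   \code{nearest}, numeric \code{radius} (radius at the nearest point).
#' @export
distance_to_centerline <- function(points, model) {
  stopifnot(inherits(model, "centerline_model"))
  D <- cross_dist(as.matrix(points), model$points)
  nearest <- max.col(-D, ties.method = "first")
  idx <- cbind(seq_len(nrow(D)), nearest)
  list(dist = D[idx], nearest = nearest, radius = model$radii[nearest])
}
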