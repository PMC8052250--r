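#' B-spline machinery: Cox-de Boor basis, interpolation, smoothing fits
#'
#' The planner represents every path as a cubic (degree M = 3) B-spline.
#' Basis functions are evaluated with the Cox-de Boor recursion; curves are
#' fitted either by exact interpolation (global tentative curve) or by a
#' penalized smoothing fit (local re-interpolation inside the genetic
#' optimizer).  All evaluation is done on the analytic spline, including
#' first and second parametric derivatives, so curvature never relies on
#' finite differencing of positions.
#'
#' @name bspline
#' @keywords internal
NULL

#' Evaluate B-spline basis functions by the Cox-de Boor recursion
#'
#' Computes the matrix of basis function values (or parametric derivatives)
#' for a given knot vector and degree.  The recursion starts from the
#' degree-0 indicator functions on the knot intervals and raises the degree
#' one step at a time; terms with a zero-width support are taken as 0
#' (the usual 0/0 := 0 convention).
#'
#' @param u numeric vector of evaluation parameters.
#' @param knots non-decreasing knot vector of length \code{nbasis + degree + 1}.
#' @param degree spline degree (cubic, 3, throughout the planner).
#' @param deriv derivative order (0, 1 or 2).
#' @return numeric matrix, \code{length(u)} rows by \code{nbasis} columns;
#'   row sums are exactly 1 for \code{deriv = 0} (partition of unity) at any
#'   parameter inside the knot range.
#' @examples
#' kn <- c(0, 0, 0, 0, 0.5, 1, 1, 1, 1)
#' B <- bspline_basis(seq(0, 1, 0.1), kn, 3)
#' stopifnot(max(abs(rowSums(B) - 1)) < 1e-12)
#' @export
bspline_basis <- function(u, knots, degree, deriv = 0L) {
  if (is.unsorted(knots)) stopf("knot vector must be non-decreasing")
  if (deriv < 0L || deriv > degree) stopf("deriv must be in 0..degree")
  m <- length(knots)
  nb <- m - degree - 1L
  if (nb < 1L) stopf("too few knots for degree %d", degree)
  u <- as.numeric(u)

  # degree-0 indicators on half-open intervals [t_i, t_{i+1})
  B <- matrix(0, length(u), m - 1L)
  for (i in seq_len(m - 1L)) {
    if (knots[i] < knots[i + 1L]) B[u >= knots[i] & u < knots[i + 1L], i] <- 1
  }
  # close the right end: the curve domain includes its last parameter
  nonempty <- which(knots[-m] < knots[-1L])
  if (length(nonempty)) B[u == knots[m], nonempty[length(nonempty)]] <- 1

  p_lo <- degree - deriv   # raise plain basis to this degree first
  if (p_lo > 0L) {
    for (p in seq_len(p_lo)) {
      nb_p <- m - p - 1L
      Bn <- matrix(0, length(u), nb_p)
      for (i in seq_len(nb_p)) {
        den1 <- knots[i + p] - knots[i]
        den2 <- knots[i + p + 1L] - knots[i + 1L]
        acc <- 0
        if (den1 > 0) acc <- acc + (u - knots[i]) / den1 * B[, i]
        if (den2 > 0) acc <- acc + (knots[i + p + 1L] - u) / den2 * B[, i + 1L]
        Bn[, i] <- acc
      }
      B <- Bn
    }
  }
  # derivative relation, applied `deriv` times while raising the degree
  if (deriv > 0L) {
    for (d in seq_len(deriv)) {
      p <- p_lo + d
      nb_p <- m - p - 1L
      Bn <- matrix(0, length(u), nb_p)
      for (i in seq_len(nb_p)) {
        den1 <- knots[i + p] - knots[i]
        den2 <- knots[i + p + 1L] - knots[i + 1L]
        acc <- 0
        if (den1 > 0) acc <- acc + p / den1 * B[, i]
        if (den2 > 0) acc <- acc - p / den2 * B[, i + 1L]
        Bn[, i] <- acc
      }
      B <- Bn
    }
  }
  B[, seq_len(nb), drop = FALSE]
}

# Clamped knot vector for interpolation at parameters u (de Boor averaging).
averaged_knots <- function(u, degree) {
  n <- length(u)
  interior <- if (n > degree + 1L) {
    vapply(seq_len(n - degree - 1L),
           function(i) mean(u[(i + 1L):(i + degree)]), numeric(1))
  } else numeric(0)
  c(rep(u[1L], degree + 1L), interior, rep(u[n], degree + 1L))
}

# Chord-length parameters in [0, 1] for a matrix of ordered points.
chord_params <- function(pts) {
  seg <- row_norms(diff(pts))
  if (any(seg == 0)) stopf("consecutive waypoints coincide; deduplicate first")
  u <- c(0, cumsum(seg))
  u / u[length(u)]
}

new_path_curve <- function(waypoints, degree, knots, control,
                           params, pos, d1, d2, pieces = NULL) {
  structure(list(waypoints = waypoints, degree = degree, knots = knots,
                 control = control, params = params, pos = pos,
                 d1 = d1, d2 = d2, pieces = pieces),
            class = "path_curve")
}

#' Fit an interpolating cubic B-spline through ordered waypoints
#'
#' Chord-length parameterization, clamped (averaged) knot vector, and an
#' exact interpolation solve: the curve passes through every waypoint.  The
#' curve is then sampled densely, together with its first and second
#' parametric derivatives, which downstream modules use for curvature and
#' collision checking.  With fewer than 4 waypoints the degree is lowered
#' to \code{n - 1} with a warning (degenerate but plannable input).
#'
#' @param waypoints numeric matrix (rows = ordered points, columns = 2 or 3
#'   coordinates, millimetres).  Consecutive duplicate rows are dropped.
#' @param dense_n number of dense samples; default 10 per waypoint, so that
#'   curvature extrema between waypoints are resolved.
#' @return a \code{path_curve}: waypoints, degree, knots, control points and
#'   dense samples \code{pos}, \code{d1}, \code{d2} at parameters
#'   \code{params}.
#' @export
fit_bspline <- function(waypoints, dense_n = NULL) {
  waypoints <- as.matrix(waypoints)
  if (nrow(waypoints) > 1L) {
    keep <- c(TRUE, row_norms(diff(waypoints)) > 0)
    waypoints <- waypoints[keep, , drop = FALSE]
  }
  n <- nrow(waypoints)
  if (n < 2L) stopf("need at least 2 distinct waypoints")
  degree <- 3L
  if (n < 4L) {
    degree <- n - 1L
    warning(sprintf("only %d waypoints: lowering spline degree to %d", n, degree),
            call. = FALSE)
  }
  if (is.null(dense_n)) dense_n <- 10L * n
  if (dense_n < n) stopf("dense_n must be at least the waypoint count")

  u <- chord_params(waypoints)
  knots <- averaged_knots(u, degree)
  Bmat <- bspline_basis(u, knots, degree)
  control <- solve(Bmat, waypoints)

  w <- seq(u[1L], u[n], length.out = dense_n)
  pos <- bspline_basis(w, knots, degree) %*% control
  d1 <- bspline_basis(w, knots, degree, 1L) %*% control
  d2 <- if (degree >= 2L) bspline_basis(w, knots, degree, 2L) %*% control
        else matrix(0, dense_n, ncol(waypoints))
  new_path_curve(waypoints, degree, knots, control, w, pos, d1, d2)
}

#' Evaluate a fitted B-spline curve at arbitrary parameters
#'
#' @param curve a \code{path_curve} with spline coefficients.
#' @param u parameters inside the knot range.
#' @param deriv derivative order (0, 1 or 2).
#' @return matrix of positions (or parametric derivatives), one row per u.
#' @export
eval_bspline <- function(curve, u, deriv = 0L) {
  if (is.null(curve$control)) stopf("composite curve has no single spline form")
  bspline_basis(u, curve$knots, curve$degree, deriv) %*% curve$control
}

#' @export
print.path_curve <- function(x, ...) {
  cat(sprintf("<path_curve> degree %d, %d waypoints, %d dense samples, N = %d\n",
              x$degree,
              if (is.null(x$waypoints)) NA_integer_ else nrow(x$waypoints),
              length(x$params), ncol(x$pos)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Penalized smoothing fit (the local optimizer's re-interpolation engine)
# ---------------------------------------------------------------------------

# Precomputed fitting context for repeated smoothing fits of the same
# ordered point set (the GA evaluates hundreds of candidate fits per
# window; everything that depends only on the data geometry is computed
# once here).  `fix_head`/`fix_tail` are lists (pos = position, tan = unit
# tangent) pinning the segment ends to the surrounding curve; the pinned
# second/penultimate control points are placed at the natural clamped-end
# derivative scale (total chord length over the unit parameter interval),
# so pinning does not distort the parameterization.
smoothing_context <- function(points, fix_head = NULL, fix_tail = NULL) {
  y <- as.matrix(points)
  n <- nrow(y)
  if (n < 5L) stopf("smoothing fit needs at least 5 points")
  degree <- 3L
  seg <- row_norms(diff(y))
  L <- sum(seg)
  u <- chord_params(y)
  knots <- averaged_knots(u, degree)
  B <- bspline_basis(u, knots, degree)
  B1 <- bspline_basis(u, knots, degree, 1L)
  B2 <- bspline_basis(u, knots, degree, 2L)
  nc <- ncol(B)
  m <- length(knots)

  fixed_idx <- integer(0)
  fixed_val <- NULL
  if (!is.null(fix_head)) {
    c1 <- fix_head$pos
    c2 <- c1 + fix_head$tan * L * (knots[degree + 2L] - knots[2L]) / degree
    fixed_idx <- c(fixed_idx, 1L, 2L)
    fixed_val <- rbind(fixed_val, c1, c2)
  }
  if (!is.null(fix_tail)) {
    cn <- fix_tail$pos
    cm <- cn - fix_tail$tan * L * (knots[m - 1L] - knots[m - degree - 1L]) / degree
    fixed_idx <- c(fixed_idx, nc - 1L, nc)
    fixed_val <- rbind(fixed_val, cm, cn)
  }
  D2 <- diff(diag(nc), differences = 2L)
  list(y = y, n = n, degree = degree, u = u, knots = knots,
       B = B, B1 = B1, B2 = B2, nc = nc, DtD = crossprod(D2),
       fixed_idx = fixed_idx, fixed_val = fixed_val,
       free_idx = setdiff(seq_len(nc), fixed_idx),
       cache = new.env(parent = emptyenv()))
}

# Weighted penalized least-squares B-spline fit within a prepared context.
#
# Minimizes  sum_i w_i ||B(u_i) c - y_i||^2 + lambda ||D2 c||^2  over the
# free control points, where D2 is the second-order difference operator on
# the control polygon (a P-spline roughness penalty).  `smooth_bound` is
# the upper bound g2 on the weighted residual sum of squares: lambda is
# chosen by bisection on the largest penalty whose residual still respects
# the bound, so g2 = 0 reproduces the (weighted) interpolating fit and
# growing g2 trades displacement for smoothness.  A relative ridge of
# 1e-10 keeps the unpenalized system well-posed when zero-weighted points
# leave basis functions without data support.
smoothing_fit <- function(ctx, weights = NULL, smooth_bound = 0) {
  n <- ctx$n
  if (is.null(weights)) weights <- rep(1, n)
  if (sum(weights > 0) < 4L) stopf("too few positively weighted points for a cubic fit")

  key <- paste0("w", paste(which(weights == 0), collapse = "."))
  pre <- ctx$cache[[key]]
  if (is.null(pre)) {
    Wb <- ctx$B * weights
    BtWB <- crossprod(Wb, ctx$B)
    # roughness floor: keeps the system well-posed when zero-weighted
    # points leave basis functions without data support, bridging such
    # gaps smoothly (the floor's null space is the linear polynomials, so
    # it is rigid-motion invariant, unlike a plain ridge)
    floor_l <- 1e-8 * mean(diag(BtWB)) / max(mean(diag(ctx$DtD)), .Machine$double.eps)
    pre <- list(BtWB = BtWB, rhs = crossprod(Wb, ctx$y), floor_l = floor_l)
    ctx$cache[[key]] <- pre
  }
  fixed_idx <- ctx$fixed_idx; free_idx <- ctx$free_idx
  fixed_val <- ctx$fixed_val

  solve_for <- function(lambda) {
    A <- pre$BtWB + (lambda + pre$floor_l) * ctx$DtD
    if (length(fixed_idx)) {
      ctrl <- matrix(0, ctx$nc, ncol(ctx$y))
      ctrl[fixed_idx, ] <- fixed_val
      rhs <- pre$rhs[free_idx, , drop = FALSE] -
        A[free_idx, fixed_idx, drop = FALSE] %*% fixed_val
      ctrl[free_idx, ] <- solve(A[free_idx, free_idx, drop = FALSE], rhs)
      ctrl
    } else {
      solve(A, pre$rhs)
    }
  }
  rss_of <- function(ctrl) {
    r <- ctx$B %*% ctrl - ctx$y
    sum(weights * rowSums(r^2))
  }

  ctrl <- solve_for(0)
  rss0 <- rss_of(ctrl)
  if (smooth_bound > 0 && rss0 < smooth_bound) {
    scale0 <- mean(diag(pre$BtWB)) / max(mean(diag(ctx$DtD)), .Machine$double.eps)
    lo <- 0; hi <- scale0 * 1e-6
    c_hi <- NULL
    repeat {
      c_hi <- solve_for(hi)
      if (rss_of(c_hi) >= smooth_bound || hi > scale0 * 1e12) break
      lo <- hi; hi <- hi * 10
    }
    if (rss_of(c_hi) < smooth_bound) {
      ctrl <- c_hi                        # bound never reached: max smoothing
    } else {
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        c_mid <- solve_for(mid)
        r_mid <- rss_of(c_mid)
        if (r_mid <= smooth_bound) { lo <- mid; ctrl <- c_mid } else hi <- mid
        if (r_mid > 0.98 * smooth_bound && r_mid <= smooth_bound) break
        if ((hi - lo) < 1e-12 * max(hi, 1)) break
      }
    }
  }
  list(knots = ctx$knots, control = ctrl, degree = ctx$degree, u = ctx$u,
       rss = rss_of(ctrl))
}
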