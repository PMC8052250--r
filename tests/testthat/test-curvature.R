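test_that("curvature of a circle is 1/R and of a line is 0", {
  ang <- seq(0, 1.8 * pi, length.out = 150)
  cv <- fit_bspline(circle_points(10, ang), dense_n = 600)
  prof <- curvature_profile(cv)
  inner <- prof$values[30:570]          # away from the clamped ends
  expect_true(all(abs(inner - 0.1) < 1e-3))

  line <- fit_bspline(cbind(seq(0, 20), 2 * seq(0, 20)))
  expect_lt(max(curvature_profile(line)$values), 1e-12)
})

test_that("the generic curvature formula matches its literal double-sum form", {
  set.seed(13)
  for (N in 2:3) {
    d1 <- matrix(rnorm(30 * N), ncol = N)
    d2 <- matrix(rnorm(30 * N), ncol = N)
    ours <- vesselpath:::curvature_from_derivs(d1, d2)$values
    literal <- vapply(seq_len(30), function(i) {
      acc <- 0
      for (j in seq_len(N)) for (k in seq_len(N)) {
        acc <- acc + (d1[i, j] * d2[i, k] - d1[i, k] * d2[i, j])^2
      }
      sqrt(acc / 2) / sum(d1[i, ]^2)^1.5
    }, numeric(1))
    expect_equal(ours, literal, tolerance = 1e-12)
    if (N == 3) {
      crossf <- vapply(seq_len(30), function(i) {
        cx <- c(d1[i, 2] * d2[i, 3] - d1[i, 3] * d2[i, 2],
                d1[i, 3] * d2[i, 1] - d1[i, 1] * d2[i, 3],
                d1[i, 1] * d2[i, 2] - d1[i, 2] * d2[i, 1])
        sqrt(sum(cx^2)) / sum(d1[i, ]^2)^1.5
      }, numeric(1))
      expect_equal(ours, crossf, tolerance = 1e-12)
    }
  }
})

test_that("spline curvature agrees with a finite-difference oracle", {
  set.seed(17)
  wp <- cbind(cumsum(runif(12, 2, 4)), 3 * rnorm(12), 3 * rnorm(12))
  cv <- fit_bspline(wp, dense_n = 120)
  u0 <- cv$params[10:110]
  prof <- vesselpath:::curvature_from_derivs(
    eval_bspline(cv, u0, 1L), eval_bspline(cv, u0, 2L))$values
  h <- 1e-5
  pm <- eval_bspline(cv, u0 - h); p0 <- eval_bspline(cv, u0); pp <- eval_bspline(cv, u0 + h)
  d1 <- (pp - pm) / (2 * h)
  d2 <- (pp - 2 * p0 + pm) / h^2
  fd <- vesselpath:::curvature_from_derivs(d1, d2)$values
  expect_lt(max(abs(prof - fd) / pmax(abs(prof), 1e-6)), 1e-4)
})

test_that("curvature scales inversely with coordinates and ignores rigid motion", {
  set.seed(23)
  wp <- cbind(cumsum(runif(10, 1, 2)), rnorm(10))
  base <- curvature_profile(fit_bspline(wp))$values
  for (c_scale in c(0.5, 3)) {
    scaled <- curvature_profile(fit_bspline(wp * c_scale))$values
    expect_equal(scaled, base / c_scale, tolerance = 1e-9)
  }
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- curvature_profile(fit_bspline(sweep(wp %*% R, 2, c(5, -3), "+")))$values
  expect_equal(moved, base, tolerance = 1e-9)
})

test_that("a vanishing first derivative is reported with its sample index", {
  d1 <- rbind(c(1, 0), c(0, 0), c(1, 0))
  d2 <- matrix(1, 3, 2)
  expect_error(vesselpath:::curvature_from_derivs(d1, d2), "cusp.*2")
})

test_that("violation windows are maximal runs, expanded, clamped and merged", {
  fake_profile <- function(mask, S = 1) {
    structure(list(values = ifelse(mask, 2, 0.5), limit = S, violated = mask),
              class = "curvature_profile")
  }
  mask <- rep(FALSE, 200); mask[40:45] <- TRUE
  w <- find_violation_windows(fake_profile(mask), delta = 5)
  expect_length(w, 1)
  expect_equal(c(w[[1]]$lo, w[[1]]$i0, w[[1]]$iF, w[[1]]$hi), c(35, 40, 45, 50))

  mask[52:55] <- TRUE                      # expanded ranges overlap: merge
  w <- find_violation_windows(fake_profile(mask), delta = 5)
  expect_length(w, 1)
  expect_equal(c(w[[1]]$lo, w[[1]]$hi), c(35, 60))

  expect_length(find_violation_windows(fake_profile(rep(FALSE, 50)), 5), 0)

  mask2 <- rep(FALSE, 30); mask2[1:2] <- TRUE; mask2[29] <- TRUE
  w <- find_violation_windows(fake_profile(mask2), delta = 4)
  expect_equal(w[[1]]$lo, 1)               # clamped at the curve start
  expect_equal(w[[2]]$hi, 30)              # clamped at the curve end

  # property: every violating sample covered, windows disjoint
  set.seed(29)
  for (rep in 1:25) {
    mask <- runif(120) < 0.1
    if (!any(mask)) next
    delta <- sample(0:8, 1)
    ws <- find_violation_windows(fake_profile(mask), delta)
    covered <- unlist(lapply(ws, function(w) w$lo:w$hi))
    expect_true(all(which(mask) %in% covered))
    expect_false(any(duplicated(covered)))
  }
})

test_that("distance to centerline matches the brute-force double loop", {
  set.seed(37)
  m <- centerline_model(matrix(runif(60, 0, 30), ncol = 2), runif(30, 1, 3))
  q <- matrix(runif(40, 0, 30), ncol = 2)
  dc <- distance_to_centerline(q, m)
  for (i in seq_len(20)) {
    d <- apply(m$points, 1, function(p) sqrt(sum((q[i, ] - p)^2)))
    expect_equal(dc$dist[i], min(d), tolerance = 1e-12)
    expect_equal(dc$nearest[i], which.min(d))
    expect_equal(dc$radius[i], m$radii[which.min(d)])
  }
  on_point <- distance_to_centerline(m$points[5, , drop = FALSE], m)
  expect_equal(on_point$dist, 0)
})
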