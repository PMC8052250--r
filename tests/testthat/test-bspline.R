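test_that("basis functions form a partition of unity", {
  kn <- c(0, 0, 0, 0, 0.15, 0.4, 0.55, 0.8, 1, 1, 1, 1)
  set.seed(42)
  u <- c(0, sort(runif(100)), 1)
  B <- bspline_basis(u, kn, 3)
  expect_lt(max(abs(rowSums(B) - 1)), 1e-12)
  expect_true(all(B >= 0))
})

test_that("vectorized basis agrees with the naive Cox-de Boor recursion", {
  kn <- c(0, 0, 0, 0, 0.2, 0.2, 0.5, 0.77, 1, 1, 1, 1)
  nb <- length(kn) - 4L
  set.seed(7)
  u <- c(0, sort(runif(25)), 1)
  B <- bspline_basis(u, kn, 3)
  for (j in seq_along(u)) {
    for (i in seq_len(nb)) {
      expect_lt(abs(B[j, i] - naive_cox_de_boor(u[j], i, 3, kn)), 1e-9)
    }
  }
})

test_that("basis derivatives match splines::splineDesign", {
  kn <- c(0, 0, 0, 0, 0.3, 0.6, 1, 1, 1, 1)
  set.seed(3)
  u <- sort(runif(40))
  for (d in 0:2) {
    ours <- bspline_basis(u, kn, 3, d)
    ref <- splines::splineDesign(kn, u, ord = 4, derivs = rep(d, length(u)))
    expect_lt(max(abs(ours - ref)), 1e-10)
  }
})

test_that("interpolating fit passes through waypoints and preserves endpoints", {
  set.seed(11)
  wp <- cbind(sort(runif(12, 0, 100)), rnorm(12, sd = 5))
  cv <- fit_bspline(wp, dense_n = 200)
  u <- vesselpath:::chord_params(wp)
  expect_lt(max(abs(eval_bspline(cv, u) - wp)), 1e-9)
  expect_identical(cv$pos[1, ], wp[1, ])
  expect_identical(cv$pos[nrow(cv$pos), ], wp[12, ])
})

test_that("collinear waypoints give an exactly straight curve", {
  wp <- cbind(0:9, 2 * (0:9))
  cv <- fit_bspline(wp)
  cross <- cv$d1[, 1] * cv$d2[, 2] - cv$d1[, 2] * cv$d2[, 1]
  expect_lt(max(abs(cross)), 1e-9)
})

test_that("spline derivatives agree with finite differences of positions", {
  set.seed(5)
  wp <- cbind(cumsum(runif(10, 1, 3)), rnorm(10), rnorm(10))
  cv <- fit_bspline(wp)
  h <- 1e-6
  u0 <- seq(0.1, 0.9, length.out = 21)
  d1_fd <- (eval_bspline(cv, u0 + h) - eval_bspline(cv, u0 - h)) / (2 * h)
  d1 <- eval_bspline(cv, u0, 1L)
  expect_lt(max(abs(d1 - d1_fd)) / max(abs(d1)), 1e-6)
  d2_fd <- (eval_bspline(cv, u0 + h) - 2 * eval_bspline(cv, u0) +
              eval_bspline(cv, u0 - h)) / h^2
  d2 <- eval_bspline(cv, u0, 2L)
  expect_lt(max(abs(d2 - d2_fd)) / max(abs(d2)), 1e-3)
})

test_that("fewer than 4 waypoints lowers the degree with a warning", {
  wp <- cbind(c(0, 1, 2), c(0, 1, 0))
  expect_warning(cv <- fit_bspline(wp, dense_n = 30), "degree")
  expect_equal(cv$degree, 2L)
  expect_equal(cv$pos[1, ], wp[1, ])
})

test_that("smoothing fit at g2 = 0 reproduces the data", {
  set.seed(9)
  wp <- cbind(seq(0, 60, length.out = 40), 4 * sin(seq(0, 5, length.out = 40)))
  seg <- refit_segment(wp, list(g1 = 0, g2 = 0))
  expect_lt(max(sqrt(rowSums((seg$pos - wp)^2))), 1e-6)
})

test_that("growing the smoothness bound reduces maximum curvature", {
  set.seed(2)
  x <- seq(0, 40, length.out = 45)
  wp <- cbind(x, 2 * sin(x * 1.2) + rnorm(45, sd = 0.15))
  maxcurv <- vapply(c(0, 0.5, 5, 50, 500), function(g2) {
    seg <- refit_segment(wp, list(g1 = 0, g2 = g2))
    max(curvature_profile(seg)$values)
  }, numeric(1))
  expect_lt(maxcurv[length(maxcurv)], 0.05 * maxcurv[1])
  expect_true(all(diff(maxcurv) < 0.05 * maxcurv[1]))
})

test_that("the fit survives the boundary case g1 = window size - 5", {
  set.seed(4)
  wp <- cbind(seq_len(12), rnorm(12))
  seg <- refit_segment(wp, list(g1 = 7, g2 = 0))
  expect_equal(nrow(seg$pos), 12L)
  expect_true(all(is.finite(seg$pos)))
  expect_error(refit_segment(wp, list(g1 = 8, g2 = 0)), "g1")
})
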