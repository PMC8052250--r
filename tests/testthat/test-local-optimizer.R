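# A reusable sharp-bend planning instance: straight legs meeting at 60
# degrees inside a wide vessel, violating S = 0.1 at the corner by ~2x.
bend_instance <- function() {
  m <- sharp_bend_model(leg = 40, spacing = 1, turn = pi / 3, radius = 10)
  a_s <- plan_global(m, 1, nrow(m$points), k = 2)
  S <- 0.1
  prof <- curvature_profile(a_s, S)
  # the margin must leave room for the repair arc: R / tan((pi - turn)/2)
  # ~ 5.8 mm on each side of the corner at S = 0.1
  wins <- find_violation_windows(prof, delta = round(0.18 * nrow(a_s$pos)))
  list(model = m, curve = a_s, S = S, windows = wins, profile = prof)
}

test_that("the sharp-bend fixture violates the limit by at least 2x", {
  bi <- bend_instance()
  expect_length(bi$windows, 1)
  expect_gt(max(bi$profile$values), 2 * bi$S)
})

test_that("segment cost reproduces direct arithmetic on a known candidate", {
  # centerline and candidate on the same circle of radius 2/S: d_c ~ 0,
  # s ~ S/2, l = l(a0), so with unit soft weights f = 0 + 0.5 + 1 = 1.5
  S <- 0.1
  ang <- seq(0, pi / 2, length.out = 200)
  circ <- circle_points(2 / S, ang)
  m <- centerline_model(circ, rep(5, nrow(circ)))
  cand <- fit_bspline(circ[seq(1, 200, 4), ], dense_n = 300)
  f <- segment_cost(cand, m, S, cost_weights(),
                    ref_length = polyline_length(cand$pos))
  expect_equal(as.numeric(f), 1.5, tolerance = 0.02)
  comp <- attr(f, "components")
  expect_equal(comp[["penalty_s"]], 0)
  expect_equal(comp[["penalty_d"]], 0)
})

test_that("hard-constraint violations dominate the cost", {
  # candidate running 1 mm outside a radius-1 vessel: d_c - r = 1
  m <- straight_model(n = 80, spacing = 1, radius = 1)
  off <- cbind(seq(10, 60, length.out = 40), rep(2, 40))
  cand <- fit_bspline(off)
  f <- segment_cost(cand, m, S = 0.1, cost_weights(),
                    ref_length = polyline_length(cand$pos))
  expect_gte(as.numeric(f), 1000)

  # curvature excess is priced at w4 per unit excess
  bi <- bend_instance()
  w <- bi$windows[[1]]
  pts <- bi$curve$pos[w$lo:w$hi, ]
  ident <- refit_segment(pts, list(g1 = 0, g2 = 0))
  f2 <- segment_cost(ident, bi$model, bi$S, cost_weights(),
                     ref_length = polyline_length(pts))
  excess <- max(curvature_profile(ident)$values) - bi$S
  expect_gte(as.numeric(f2), 1000 * excess)

  # and a violating candidate is never preferred to a feasible one
  rep_ga <- ga_optimize(w, bi$curve, bi$model, bi$S, ga_config(seed = 3))
  expect_true(rep_ga$clean)
  expect_lt(rep_ga$cost, as.numeric(f2))
})

test_that("an already-feasible window returns a near-identity refit quickly", {
  m <- straight_model(n = 60, spacing = 1, radius = 5)
  a_s <- plan_global(m, 1, 60)
  fake_win <- structure(list(i0 = 200, iF = 210, lo = 190, hi = 240, delta = 10),
                        class = "segment_window")
  r <- ga_optimize(fake_win, a_s, m, S = 0.1, ga_config(seed = 1, n_g = 1))
  expect_true(r$feasible && r$clean)
  expect_lt(r$cost, 1000)
})

test_that("the GA repairs a sharp bend across seeds", {
  bi <- bend_instance()
  w <- bi$windows[[1]]
  ok <- 0L
  for (s in 1:20) {
    r <- ga_optimize(w, bi$curve, bi$model, bi$S,
                     ga_config(seed = s, time_limit = 5))
    seg_prof <- curvature_profile(r$segment)$values
    dc <- distance_to_centerline(r$segment$pos, bi$model)
    if (max(seg_prof) <= bi$S && all(dc$dist <= dc$radius)) ok <- ok + 1L
  }
  expect_gte(ok, 19L)
})

test_that("GA best cost is within 5% of an exhaustive two-gene grid search", {
  bi <- bend_instance()
  w <- bi$windows[[1]]
  lo <- w$lo; hi <- w$hi
  pts <- bi$curve$pos[lo:hi, ]
  lc <- vesselpath:::curvature_from_derivs(bi$curve$d1[lo:hi, ],
                                           bi$curve$d2[lo:hi, ])$values
  pins <- vesselpath:::window_pins(bi$curve$pos, bi$curve$d1, lo, hi,
                                   nrow(bi$curve$pos))
  refl <- polyline_length(pts)
  wts <- cost_weights()
  grid_best <- Inf
  for (g1 in 0:6) {
    for (g2 in 10^seq(-4, 4, length.out = 20)) {
      seg <- tryCatch(
        refit_segment(pts, list(g1 = g1, g2 = g2), lc, pins$head, pins$tail),
        error = function(e) NULL)
      if (is.null(seg)) next
      f <- as.numeric(segment_cost(seg, bi$model, bi$S, wts, refl))
      grid_best <- min(grid_best, f)
    }
  }
  r <- ga_optimize(w, bi$curve, bi$model, bi$S, ga_config(seed = 11))
  expect_lte(r$cost, 1.05 * grid_best)
})

test_that("best-in-population cost is non-increasing across generations", {
  bi <- bend_instance()
  r <- ga_optimize(bi$windows[[1]], bi$curve, bi$model, bi$S,
                   ga_config(seed = 2))
  expect_true(all(diff(r$trace) <= 1e-9))
})

test_that("full plans are reproducible and windows are order-independent", {
  m <- generate_synthetic_tree("femoral2d", seed = 2)
  res1 <- plan(m, config = ga_config(seed = 5))
  res2 <- plan(m, config = ga_config(seed = 5))
  expect_identical(res1$final_curve$pos, res2$final_curve$pos)
  expect_identical(res1$metrics$max_curvature, res2$metrics$max_curvature)

  # each window's result equals its isolated recomputation with the same
  # child seed: execution order cannot matter
  a_s <- res1$tentative_curve
  n <- nrow(a_s$pos)
  prof <- curvature_profile(a_s, res1$S)
  wins <- find_violation_windows(prof, max(1L, round(0.05 * n)))
  for (j in rev(seq_along(wins))) {
    cfg <- ga_config(seed = vesselpath:::child_seed(5, j))
    iso <- ga_optimize(wins[[j]], a_s, m, res1$S, cfg)
    expect_identical(iso$segment$pos, res1$segment_reports[[j]]$segment$pos)
  }
})

test_that("splices are C1-continuous and success implies verified feasibility", {
  m <- generate_synthetic_tree("femoral2d", seed = 6)
  res <- plan(m, config = ga_config(seed = 9))
  expect_true(res$success)
  fc <- res$final_curve

  # independent re-verification, not the planner's own flag
  prof <- curvature_profile(fc)
  dc <- distance_to_centerline(fc$pos, m)
  expect_lte(max(prof$values), res$S + 1e-12)
  expect_true(all(dc$dist <= dc$radius))

  # joint continuity at every window boundary
  for (w in res$windows) {
    for (idx in c(w$lo, w$hi)) {
      if (idx <= 1 || idx >= nrow(fc$pos)) next
      gap <- sqrt(sum((fc$pos[idx, ] - fc$pos[idx - 1L, ])^2))
      expect_lt(gap, 3 * max(sqrt(rowSums(diff(fc$pos)^2))))
      t1 <- fc$d1[idx - 1L, ] / sqrt(sum(fc$d1[idx - 1L, ]^2))
      t2 <- fc$d1[idx, ] / sqrt(sum(fc$d1[idx, ]^2))
      expect_lt(acos(min(1, sum(t1 * t2))), 0.1)
    }
  }
})

test_that("a straight vessel needs no optimization at all", {
  m <- generate_synthetic_tree("straight2d", seed = 0)
  res <- plan(m)
  expect_true(res$success)
  expect_length(res$windows, 0)
  expect_equal(res$reason, "tentative curve already feasible")
  dc <- distance_to_centerline(res$final_curve$pos, m)
  # within half the point spacing of the discrete centerline
  expect_lte(max(dc$dist), synth_preset("straight2d")$point_spacing / 2 + 1e-9)
})

test_that("planning failures are reported as results, not conditions", {
  pts <- rbind(cbind(0:5, 0), cbind(0:5, 500))
  m <- centerline_model(pts, rep(2, 12))
  res <- plan(m, 1, 12, S = 0.1, k = 2)
  expect_false(res$success)
  expect_match(res$reason, "no path")
})
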