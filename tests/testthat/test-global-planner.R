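test_that("k-NN graph construction matches the hand-checkable cases", {
  m <- centerline_model(cbind(c(0, 1, 2), c(0, 0, 0)), rep(1, 3))
  g <- build_knn_graph(m, k = 1)
  expect_equal(g$graph[[1]], 2L)
  expect_equal(g$graph[[2]], c(1L, 3L))   # symmetrized: 1 and 3 both chose 2
  expect_equal(g$graph[[3]], 2L)

  chain <- straight_model(n = 100, spacing = 1)
  g <- build_knn_graph(chain, k = 2)
  path <- bfs_path(g, 1, 100)
  expect_gt(length(path), 0)                     # chain graph is connected
  for (j in seq_len(length(path) - 1L)) {
    expect_true(path[j + 1L] %in% g$graph[[path[j]]])
  }

  expect_error(build_knn_graph(m, k = 3), "smaller than the point count")
  expect_error(build_knn_graph(m, k = 0), "k must be")
})

test_that("k-NN adjacency equals a brute-force all-pairs distance sort", {
  set.seed(20)
  pts <- matrix(runif(100, 0, 50), ncol = 2)
  m <- centerline_model(pts, rep(1, 50))
  g <- build_knn_graph(m, k = 4)
  # independent oracle: per-node sort of the full distance vector
  sel <- lapply(seq_len(50), function(i) {
    d <- sqrt(colSums((t(pts) - pts[i, ])^2))
    d[i] <- Inf
    sort(order(d)[1:4])
  })
  for (i in seq_len(50)) {
    expected <- sort(unique(c(sel[[i]], which(vapply(sel, function(s) i %in% s, logical(1))))))
    expect_equal(g$graph[[i]], expected)
  }
})

test_that("BFS returns minimum-hop paths with deterministic tie-breaking", {
  m <- straight_model(n = 4, spacing = 1)
  g <- build_knn_graph(m, k = 1)
  expect_equal(bfs_path(g, 1, 4), 1:4)
  expect_equal(bfs_path(g, 2, 2), 2L)

  # unreachable goal: two separated components
  pts <- rbind(cbind(0:3, 0), cbind(0:3, 1000))
  m2 <- build_knn_graph(centerline_model(pts, rep(1, 8)), k = 1)
  expect_length(bfs_path(m2, 1, 8), 0)
  expect_s3_class(plan_global(m2, 1, 8), "plan_failure")
})

test_that("BFS hop count equals exhaustive enumeration on small graphs", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(5:15, 1)
    pts <- matrix(runif(2 * n, 0, 10), ncol = 2)
    m <- centerline_model(pts, rep(1, n))
    k <- sample(2:3, 1)
    g <- build_knn_graph(m, k = k)
    from <- 1L; to <- n
    path <- bfs_path(g, from, to)
    oracle <- brute_min_hops(g$graph, from, to)
    if (length(path) == 0) {
      expect_identical(oracle, Inf)
    } else {
      expect_equal(length(path) - 1L, oracle)
      # returned sequence is a real path through the graph
      for (j in seq_len(length(path) - 1L)) {
        expect_true(path[j + 1L] %in% g$graph[[path[j]]])
      }
    }
  }
})

test_that("the tentative curve follows a straight vessel and reaches the goal branch", {
  m <- straight_model(n = 60, spacing = 1, radius = 4)
  cv <- plan_global(m, 1, 60)
  dc <- distance_to_centerline(cv$pos, m)
  expect_lt(max(dc$dist), 0.5)                   # within half the spacing
  expect_equal(cv$pos[1, ], m$points[1, ])
  expect_equal(cv$pos[nrow(cv$pos), ], m$points[60, ])

  tree <- generate_synthetic_tree("femoral2d", seed = 4)
  cv2 <- plan_global(tree, tree$start_index, tree$goal_index)
  wp <- attr(cv2, "waypoint_indices")
  goal_branch <- setdiff(attr(tree, "main_path"), tree$polylines[[2]])
  expect_gt(length(intersect(wp, goal_branch)), 0)
  expect_equal(wp[length(wp)], tree$goal_index)
})
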