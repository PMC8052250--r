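#' Evaluation metrics and benchmark harness
#'
#' The planner and its baselines are compared on: normalized path length
#' (cumulative sample-to-sample length over the straight start-goal
#' distance), minimum distance to the vascular wall (radius at the nearest
#' centerline point minus distance to it — the safety margin; positive iff
#' the whole sampled path stays inside the vessel), curvature statistics,
#' planning time (recorded for information only), and the success rate
#' \eqn{\delta = n_s / n}.  Method differences are tested with the
#' rank-based Kruskal-Wallis test at \eqn{\alpha = 0.05}.
#'
#' @name evaluation
NULL

#' Normalized path length
#'
#' @param curve a \code{path_curve}.
#' @param p0,pG start and goal positions.
#' @return \eqn{l(a) / \|pG - p0\|}, at least 1 up to discretization.
#' @export
normalized_path_length <- function(curve, p0, pG) {
  chord <- sqrt(sum((as.numeric(pG) - as.numeric(p0))^2))
  if (chord == 0) stopf("normalized length undefined: coincident endpoints")
  polyline_length(curve$pos) / chord
}

#' Minimum distance to the vascular wall along a path
#'
#' @param curve a \code{path_curve}.
#' @param model a \code{\link{centerline_model}}.
#' @return min over samples of (radius at nearest centerline point - distance
#'   to it), millimetres.
#' @export
min_wall_distance <- function(curve, model) {
  dc <- distance_to_centerline(curve$pos, model)
  min(dc$radius - dc$dist)
}

#' Success rate over a series of planning attempts
#'
#' @param outcomes logical vector (TRUE = a feasible path was returned).
#' @return \eqn{n_s / n} in [0, 1].
#' @export
success_rate <- function(outcomes) {
  if (!length(outcomes)) stopf("no outcomes given")
  mean(as.logical(outcomes))
}

#' Rank-based comparison of metric distributions between methods
#'
#' Kruskal-Wallis H with tie correction and the chi-square p-value
#' (nonparametric; no normality assumed).  When every value is identical
#' the convention H = 0, p = 1 is returned.
#'
#' @param groups list of >= 2 numeric vectors, one per method.
#' @return list with \code{H}, \code{p}, \code{df}, and
#'   \code{significant} at the 0.05 level.
#' @export
rank_group_test <- function(groups) {
  if (length(groups) < 2L) stopf("need at least two groups")
  if (any(!vapply(groups, length, integer(1)))) stopf("each group needs >= 1 value")
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3L) stopf("need at least 3 values in total")
  if (length(unique(x)) == 1L) {
    return(list(H = 0, p = 1, df = length(groups) - 1L, significant = FALSE))
  }
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), significant = kt$p.value < 0.05)
}

#' Run a reproducible benchmark over synthetic presets
#'
#' For each trial a fresh model is generated from the preset with a child
#' seed, the endpoints (trunk root and branch tip, i.e. terminal nodes of
#' distinct branches) are perturbed with Gaussian noise and snapped back to
#' the centerline, and every method plans on the identical instance.  The
#' result table is a pure function of its arguments.
#'
#' @param methods character subset of \code{c("bfs-ga", "rrt", "rrt-star")}.
#' @param presets character vector of preset names.
#' @param trials trials per preset.
#' @param seed master seed; trial and planner seeds are derived from it.
#' @param sigma endpoint perturbation sd (model units; 10 matches the
#'   benchmark convention, 0 disables perturbation).
#' @param config a \code{\link{ga_config}} for the BFS-GA runs (its seed is
#'   replaced per-trial).
#' @param rrt a \code{\link{rrt_config}} for the baseline runs (same).
#' @return object of class \code{benchmark_table}: \code{$table} with one
#'   row per method x preset x trial and the metric columns, and
#'   \code{$summary} with per-method-x-preset medians, IQRs and success
#'   rates.
#' @export
run_benchmark <- function(methods = c("bfs-ga", "rrt", "rrt-star"),
                          presets = "femoral2d", trials = 10L, seed = 1L,
                          sigma = 10, config = ga_config(),
                          rrt = rrt_config()) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (preset in presets) {
    for (tr in seq_len(trials)) {
      tseed <- child_seed(seed, match(preset, presets) * 10000L + tr)
      m <- generate_synthetic_tree(preset, tseed)
      m <- build_knn_graph(m)
      ep <- perturb_endpoints(m, m$points[m$start_index, ],
                              m$points[m$goal_index, ], sigma,
                              seed = child_seed(tseed, 1L))
      for (method in methods) {
        rec <- run_one(method, m, ep$i0, ep$iG, config, rrt,
                       child_seed(tseed, 2L + match(method, methods)))
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(method = method, preset = preset, trial = tr,
                           seed = tseed), rec)
      }
    }
  }
  table <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(table, list(table$method, table$preset), drop = TRUE),
    function(d) data.frame(
      method = d$method[1L], preset = d$preset[1L],
      n = nrow(d),
      success_rate = success_rate(d$success),
      median_norm_length = stats::median(d$norm_length, na.rm = TRUE),
      iqr_norm_length = stats::IQR(d$norm_length, na.rm = TRUE),
      median_min_wall = stats::median(d$min_wall_distance, na.rm = TRUE),
      median_max_curv = stats::median(d$max_curvature, na.rm = TRUE))))
  rownames(summary) <- NULL
  structure(list(table = table, summary = summary), class = "benchmark_table")
}

run_one <- function(method, model, i0, iG, config, rrt, seed) {
  if (method == "bfs-ga") {
    cfg <- config; cfg$seed <- seed
    res <- plan(model, i0, iG, config = cfg)
    return(res$metrics)
  }
  rcfg <- rrt; rcfg$seed <- seed
  if (method == "rrt") rcfg$rewire_count <- 0L
  t0 <- proc.time()[["elapsed"]]
  res <- rrt_star_plan(model, i0, iG, rcfg)
  elapsed <- proc.time()[["elapsed"]] - t0
  if (inherits(res, "plan_failure")) {
    return(data.frame(plan_time_s = elapsed, norm_length = NA_real_,
                      min_wall_distance = NA_real_, max_curvature = NA_real_,
                      mean_curvature = NA_real_, success = FALSE))
  }
  prof <- curvature_profile(res)
  data.frame(plan_time_s = elapsed,
             norm_length = normalized_path_length(res, model$points[i0, ],
                                                  model$points[iG, ]),
             min_wall_distance = min_wall_distance(res, model),
             max_curvature = max(prof$values),
             mean_curvature = mean(prof$values),
             success = TRUE)
}

#' @export
print.benchmark_table <- function(x, ...) {
  cat("<benchmark_table>\n")
  print(x$summary)
  invisible(x)
}
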