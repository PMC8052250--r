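#' Genetic-algorithm local optimization of curvature-violating segments
#'
#' Phase two of the planner.  Each violating segment window of the
#' tentative curve is re-fitted as a smoothing cubic B-spline governed by a
#' two-gene chromosome: \code{g1}, the number of points given weight 0 in
#' the fit (the samples driving the curvature violation), and \code{g2},
#' the smoothness bound — the upper limit on the weighted error sum of
#' squared displacements.  Candidates are scored by a penalty cost that
#' trades wall clearance, curvature and length against two heavily
#' weighted hard-constraint terms, and a small generational GA searches the
#' gene space.  Optimized segments are spliced back into the curve with
#' position and tangent continuity.
#'
#' @name local_optimizer
NULL

#' GA configuration
#'
#' @param population_size chromosomes per generation (8).
#' @param parents_kept chromosomes surviving truncation selection (4); the
#'   single best additionally survives unchanged (elitism), which makes the
#'   best cost non-increasing across generations.
#' @param n_g iterations per round; multiplied by \code{escalation_factor}
#'   whenever a round ends without a feasible candidate.
#' @param escalation_factor see above.
#' @param max_rounds escalation rounds before the window is declared
#'   unrepairable (a deterministic budget: with the defaults, up to
#'   30 + 60 + 120 + 240 generations).
#' @param time_limit hard per-window wall-clock ceiling in seconds, a
#'   safety net that rarely intervenes at the default; results are
#'   bit-reproducible whenever it does not.
#' @param mutation_mu Gaussian mutation mean for both genes (0).
#' @param mutation_sd_g1 mutation sd for the integer gene g1 (rounded and
#'   clamped to validity); NULL (default) scales it with the window size
#'   (4\% of the window point count, at least 1), so that the number of
#'   zero-weighted points can traverse its full useful range within a
#'   round.
#' @param mutation_sd_g2_frac mutation sd for g2, as a fraction of the
#'   current population's g2 span.
#' @param seed integer seed; each window receives a deterministic child
#'   seed, so results are independent of the order in which windows are
#'   optimized.
#' @return object of class \code{ga_config}.
#' @export
ga_config <- function(population_size = 8L, parents_kept = 4L, n_g = 30L,
                      escalation_factor = 2, max_rounds = 4L, time_limit = 60,
                      mutation_mu = 0, mutation_sd_g1 = NULL,
                      mutation_sd_g2_frac = 0.2, seed = 1L) {
  stopifnot(parents_kept < population_size, n_g >= 1, time_limit > 0,
            escalation_factor >= 1, max_rounds >= 1)
  structure(list(population_size = as.integer(population_size),
                 parents_kept = as.integer(parents_kept),
                 n_g = as.integer(n_g),
                 escalation_factor = escalation_factor,
                 max_rounds = as.integer(max_rounds),
                 time_limit = time_limit, mutation_mu = mutation_mu,
                 mutation_sd_g1 = mutation_sd_g1,
                 mutation_sd_g2_frac = mutation_sd_g2_frac,
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Cost weights and feasibility threshold for the penalty cost
#'
#' Soft terms (mean normalized wall distance, mean normalized curvature,
#' normalized length) carry unit weights; the two hard-constraint penalty
#' terms (curvature excess over S, protrusion beyond the vessel radius)
#' carry weights large enough that any violation pushes the cost past the
#' feasibility threshold.
#'
#' @param w1,w2,w3 soft-term weights (defaults 1).
#' @param w4,w5 hard-constraint penalty weights (defaults 1000).
#' @param feasibility_threshold cost above which a candidate counts as
#'   infeasible (default 1000).
#' @param penalty_agg how pointwise constraint excesses are aggregated into
#'   the penalty terms: \code{"max"} (default: one violating sample trips
#'   the threshold), \code{"mean"} or \code{"sum"}.
#' @return object of class \code{cost_weights}.
#' @export
cost_weights <- function(w1 = 1, w2 = 1, w3 = 1, w4 = 1000, w5 = 1000,
                         feasibility_threshold = 1000,
                         penalty_agg = c("max", "mean", "sum")) {
  stopifnot(w1 > 0, w2 > 0, w3 > 0, w4 > 0, w5 > 0)
  structure(list(w1 = w1, w2 = w2, w3 = w3, w4 = w4, w5 = w5,
                 feasibility_threshold = feasibility_threshold,
                 penalty_agg = match.arg(penalty_agg)),
            class = "cost_weights")
}

#' Re-fit one curve segment under a two-gene chromosome
#'
#' Fits a smoothing cubic B-spline through the window's sample points in
#' which the \code{g1} points of highest local curvature receive weight 0
#' (they no longer pull the fit into the tight turn) and the weighted sum
#' of squared displacements of the remaining points is bounded by
#' \code{g2}.  When pinning frames are supplied, the segment's end
#' positions and end tangent directions are held to the surrounding curve
#' so that splicing is C1-continuous; at a curve boundary (start or goal
#' inside the window) the corresponding end is left free and its pose is
#' optimized along with the rest of the segment.
#'
#' @param window_points matrix of the window's sampled positions (>= 5 rows).
#' @param chromosome list with integer \code{g1 >= 0}
#'   (\code{g1 < nrow(window_points) - 4}) and scalar \code{g2 >= 0}.
#' @param local_curv per-point curvature used to rank candidates for
#'   zero-weighting; discrete three-point curvature is used when missing.
#' @param fix_head,fix_tail boundary pins, each a list with \code{pos}
#'   (position) and \code{tan} (unit tangent), or NULL for a free end.
#' @return a \code{path_curve} for the candidate segment, sampled at the
#'   window's own chord parameters (one sample per window point, keeping
#'   splicing index-aligned).
#' @export
refit_segment <- function(window_points, chromosome, local_curv = NULL,
                          fix_head = NULL, fix_tail = NULL) {
  ctx <- smoothing_context(window_points, fix_head, fix_tail)
  refit_in_context(ctx, chromosome, local_curv)
}

refit_in_context <- function(ctx, chromosome, local_curv = NULL) {
  n <- ctx$n
  g1 <- as.integer(round(chromosome$g1))
  g2 <- as.numeric(chromosome$g2)
  if (g1 < 0L || g2 < 0) stopf("invalid chromosome: g1 and g2 must be non-negative")
  if (g1 >= n - 4L) stopf("invalid chromosome: g1 must be < window size - 4")
  if (is.null(local_curv)) local_curv <- discrete_curvature(ctx$y)

  weights <- rep(1, n)
  if (g1 > 0L) {
    interior <- 3:(n - 2L)
    drop <- interior[order(local_curv[interior], decreasing = TRUE)][seq_len(min(g1, length(interior)))]
    weights[drop] <- 0
  }
  fit <- smoothing_fit(ctx, weights, smooth_bound = g2)
  seg <- new_path_curve(ctx$y, fit$degree, fit$knots, fit$control, ctx$u,
                        ctx$B %*% fit$control,
                        ctx$B1 %*% fit$control,
                        ctx$B2 %*% fit$control)
  attr(seg, "chromosome") <- list(g1 = g1, g2 = g2)
  attr(seg, "rss") <- fit$rss
  seg
}

# Discrete (circumscribed-circle) curvature of a polyline, used only to
# rank points for zero-weighting when no analytic profile is available.
discrete_curvature <- function(pts) {
  n <- nrow(pts)
  k <- numeric(n)
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      a <- pts[i - 1L, ]; b <- pts[i, ]; d <- pts[i + 1L, ]
      ab <- sqrt(sum((b - a)^2)); bd <- sqrt(sum((d - b)^2)); ad <- sqrt(sum((d - a)^2))
      cr <- sum((b - a) * (d - b)) / (ab * bd)
      k[i] <- if (ad > 0) 2 * sqrt(max(0, 1 - cr^2)) / ad else 0
    }
  }
  k
}

#' Penalty cost of a candidate curve segment
#'
#' Implements the unconstrained form of the segment optimization problem:
#' \deqn{f(a) = w_1\,\mathrm{mean}(d_c/r) + w_2\,\mathrm{mean}(s)/S +
#'   w_3\,l(a)/l(a_0) + w_4\,P[\max(0, s - S)] + w_5\,P[\max(0, d_c - r)]}
#' where \eqn{d_c} is the distance to the nearest centerline point, r the
#' radius at that point, s the sampled curvature, \eqn{l(a_0)} the
#' reference (original window) length, and P the configured pointwise-excess
#' aggregator (maximum by default).  A candidate that violates either hard
#' constraint anywhere scores at least \eqn{\min(w_4, w_5)} times the
#' violation magnitude and is never preferred to a fully feasible one under
#' default weights.
#'
#' @param candidate a \code{path_curve} segment (from
#'   \code{\link{refit_segment}}).
#' @param model the \code{\link{centerline_model}}.
#' @param S curvature limit (mm^-1).
#' @param weights a \code{\link{cost_weights}}.
#' @param ref_length reference length \eqn{l(a_0)} of the original window.
#' @return scalar cost with attribute \code{components}.
#' @export
segment_cost <- function(candidate, model, S, weights, ref_length) {
  stopifnot(inherits(weights, "cost_weights"), ref_length > 0, S > 0)
  prof <- tryCatch(curvature_profile(candidate), error = function(e) NULL)
  if (is.null(prof)) return(Inf)
  s <- prof$values
  dc <- distance_to_centerline(candidate$pos, model)
  g_d <- mean(dc$dist / dc$radius)
  g_s <- mean(s) / S
  g_l <- polyline_length(candidate$pos) / ref_length
  agg <- switch(weights$penalty_agg,
                max = function(x) max(x, 0),
                mean = mean, sum = sum)
  pen_s <- agg(pmax(0, s - S))
  pen_d <- agg(pmax(0, dc$dist - dc$radius))
  f <- weights$w1 * g_d + weights$w2 * g_s + weights$w3 * g_l +
    weights$w4 * pen_s + weights$w5 * pen_d
  attr(f, "components") <- c(g_d = g_d, g_s = g_s, g_l = g_l,
                             penalty_s = pen_s, penalty_d = pen_d)
  f
}

# Pinning frames for a window: end positions and unit tangent directions
# taken from the surrounding curve (NULL at a curve boundary, where the
# endpoint pose is optimized together with the segment).
window_pins <- function(pos, d1, lo, hi, n_total) {
  fix_head <- fix_tail <- NULL
  if (lo > 1L) {
    fix_head <- list(pos = pos[lo, ], tan = d1[lo, ] / sqrt(sum(d1[lo, ]^2)))
  }
  if (hi < n_total) {
    fix_tail <- list(pos = pos[hi, ], tan = d1[hi, ] / sqrt(sum(d1[hi, ]^2)))
  }
  list(head = fix_head, tail = fix_tail)
}

#' Optimize one violation window with the genetic algorithm
#'
#' Follows the generational scheme: 8 chromosomes are initialized
#' (\code{g1} small, \code{g2} log-uniform over a data-scaled range from
#' near-interpolation to chord-level smoothing), scored via
#' \code{\link{refit_segment}} + \code{\link{segment_cost}}, the best 4
#' kept as parents (with the single best surviving unchanged), offspring
#' formed by per-gene exchange between parent pairs, and genes mutated
#' with Gaussian noise.  After \code{n_g} iterations the best candidate is
#' accepted if its cost is below the feasibility threshold; otherwise
#' \code{n_g} is escalated and search continues until the per-window time
#' limit, after which the window is reported infeasible.
#'
#' @param window a \code{segment_window}.
#' @param curve the curve being repaired (supplies window samples and
#'   boundary tangents).
#' @param model the \code{\link{centerline_model}}.
#' @param S curvature limit (mm^-1).
#' @param config a \code{\link{ga_config}}; \code{config$seed} fully
#'   determines the stochastic search.
#' @param weights a \code{\link{cost_weights}}.
#' @return list: \code{segment} (best candidate \code{path_curve}),
#'   \code{best} chromosome, \code{cost}, \code{feasible}, \code{generations},
#'   \code{trace} (best cost per generation).
#' @export
ga_optimize <- function(window, curve, model, S, config = ga_config(),
                        weights = cost_weights()) {
  stopifnot(inherits(config, "ga_config"))
  lo <- window$lo; hi <- window$hi
  n_total <- nrow(curve$pos)
  pts <- curve$pos[lo:hi, , drop = FALSE]
  n_w <- nrow(pts)
  if (n_w < 5L) stopf("window too small to optimize")
  local_curv <- curvature_from_derivs(curve$d1[lo:hi, , drop = FALSE],
                                      curve$d2[lo:hi, , drop = FALSE])$values
  pins <- window_pins(curve$pos, curve$d1, lo, hi, n_total)
  ref_length <- polyline_length(pts)
  g1_max <- n_w - 5L

  # smoothing scale: residual of the straight chord through the window,
  # the largest displacement budget that could ever be useful
  chord <- pts[1L, ] + outer(seq(0, 1, length.out = n_w), pts[n_w, ] - pts[1L, ])
  g2_scale <- max(sum((pts - chord)^2), 1e-8)

  ctx <- smoothing_context(pts, pins$head, pins$tail)
  evaluate <- function(chr) {
    seg <- tryCatch(
      refit_in_context(ctx, chr, local_curv = local_curv),
      error = function(e) NULL)
    if (is.null(seg)) return(list(cost = Inf, segment = NULL, clean = FALSE))
    f <- segment_cost(seg, model, S, weights, ref_length)
    comp <- attr(f, "components")
    list(cost = as.numeric(f), segment = seg,
         clean = comp[["penalty_s"]] == 0 && comp[["penalty_d"]] == 0)
  }

  g1_init_cap <- min(g1_max, as.integer(ceiling(n_w / 3)))
  sd_g1 <- config$mutation_sd_g1
  if (is.null(sd_g1)) sd_g1 <- max(1, round(0.04 * n_w))

  # data-driven prior for g1: the number of window samples actually
  # violating the limit is about how many points must stop pulling the fit
  n_hot <- sum(local_curv > S)

  random_chromosome <- function() {
    list(g1 = sample(0:g1_init_cap, 1L),
         g2 = 10^stats::runif(1L, log10(g2_scale) - 6, log10(g2_scale)))
  }

  with_seed(config$seed, {
    pop <- lapply(seq_len(config$population_size), function(j) {
      chr <- random_chromosome()
      if (j <= 2L && n_hot > 0L) {
        chr$g1 <- min(g1_max, n_hot + (j - 1L) * max(1L, n_hot %/% 2L))
      }
      chr
    })
    evals <- lapply(pop, evaluate)
    trace <- numeric(0)
    start <- proc.time()[["elapsed"]]
    n_g <- config$n_g
    gen_total <- 0L
    rounds <- 0L
    repeat {
      for (g in seq_len(n_g)) {
        ord <- order(vapply(evals, `[[`, numeric(1), "cost"))
        pop <- pop[ord]; evals <- evals[ord]
        parents <- pop[seq_len(config$parents_kept)]
        pairs <- list(c(1L, 2L), c(3L, 4L), c(1L, 3L), c(2L, 4L))
        offspring <- lapply(pairs, function(pr) {
          a <- parents[[min(pr[1L], length(parents))]]
          b <- parents[[min(pr[2L], length(parents))]]
          if (stats::runif(1L) < 0.5) list(g1 = a$g1, g2 = b$g2)
          else list(g1 = b$g1, g2 = a$g2)
        })
        newpop <- c(parents, offspring)[seq_len(config$population_size)]
        span <- diff(range(vapply(newpop, `[[`, numeric(1), "g2")))
        if (span <= 0) span <- g2_scale * 1e-3
        mutated <- lapply(seq_along(newpop), function(j) {
          chr <- newpop[[j]]
          if (j == 1L) return(chr)      # elite passes through unchanged
          g1 <- chr$g1 + round(stats::rnorm(1L, config$mutation_mu, sd_g1))
          g2 <- chr$g2 + stats::rnorm(1L, config$mutation_mu,
                                      config$mutation_sd_g2_frac * span)
          list(g1 = max(0L, min(g1_max, g1)), g2 = max(0, g2))
        })
        # steady immigration: the last slot is refilled with a fresh random
        # chromosome each generation, preventing premature convergence
        mutated[[length(mutated)]] <- random_chromosome()
        same <- vapply(seq_along(mutated), function(j) {
          j <= length(pop) && identical(mutated[[j]], pop[[j]])
        }, logical(1))
        evals <- lapply(seq_along(mutated), function(j) {
          if (same[j]) evals[[j]] else evaluate(mutated[[j]])
        })
        pop <- mutated
        gen_total <- gen_total + 1L
        trace <- c(trace, min(vapply(evals, `[[`, numeric(1), "cost")))
        if (proc.time()[["elapsed"]] - start >= config$time_limit) break
      }
      best_i <- which.min(vapply(evals, `[[`, numeric(1), "cost"))
      # escalate while constraints are not fully satisfied: the threshold
      # rule flags gross infeasibility, the hard-penalty check catches
      # candidates whose residual excess is small in absolute terms
      done <- evals[[best_i]]$cost < weights$feasibility_threshold &&
        evals[[best_i]]$clean
      rounds <- rounds + 1L
      if (done || rounds >= config$max_rounds) break
      if (proc.time()[["elapsed"]] - start >= config$time_limit) break
      n_g <- ceiling(n_g * config$escalation_factor)
    }
    best_i <- which.min(vapply(evals, `[[`, numeric(1), "cost"))
    list(segment = evals[[best_i]]$segment, best = pop[[best_i]],
         cost = evals[[best_i]]$cost,
         feasible = evals[[best_i]]$cost < weights$feasibility_threshold,
         clean = evals[[best_i]]$clean,
         generations = gen_total, trace = trace)
  })
}

# Splice optimized segment samples into the curve, returning a composite
# path_curve that carries per-sample positions and derivatives.
splice_segments <- function(curve, windows, reports) {
  pos <- curve$pos; d1 <- curve$d1; d2 <- curve$d2
  for (j in seq_along(windows)) {
    seg <- reports[[j]]$segment
    if (is.null(seg)) next
    idx <- windows[[j]]$lo:windows[[j]]$hi
    pos[idx, ] <- seg$pos
    d1[idx, ] <- seg$d1
    d2[idx, ] <- seg$d2
  }
  out <- new_path_curve(curve$waypoints, curve$degree, NULL, NULL,
                        curve$params, pos, d1, d2,
                        pieces = list(base = curve, windows = windows,
                                      reports = reports))
  out
}

#' Two-phase curvature-constrained path planning (BFS + GA)
#'
#' The full pipeline: global BFS planning of the tentative curve along the
#' centerline graph, curvature evaluation against the device limit S,
#' genetic-algorithm repair of every violating window (each window an
#' independent task with its own deterministic child seed, so results do
#' not depend on execution order), C1 splicing of the optimized segments,
#' and an independent full-path constraint re-check.  If splicing
#' re-introduces a violation near a joint, the affected region is
#' re-windowed once and re-optimized; a second failure fails the plan.
#'
#' @param model a \code{\link{centerline_model}}.
#' @param p0_index,pG_index 1-based start/goal point indices (defaults:
#'   the model's stored endpoints).
#' @param S maximum allowed curvature (mm^-1); defaults to the model's
#'   stored limit.
#' @param config a \code{\link{ga_config}} (its \code{seed} drives all
#'   stochastic steps).
#' @param weights a \code{\link{cost_weights}}.
#' @param k,dense_n graph/sampling controls, see \code{\link{plan_global}}.
#' @param delta_frac window margin \eqn{\Delta} as a fraction of the dense
#'   sample count (default 0.05).
#' @return object of class \code{plan_result}: \code{final_curve},
#'   \code{tentative_curve}, \code{success}, \code{reason},
#'   \code{segment_reports}, \code{windows} and \code{metrics} (a one-row
#'   data frame: plan time, normalized length, minimum wall distance, max
#'   and mean curvature, success flag).
#' @examples
#' \donttest{
#' m <- generate_synthetic_tree("femoral2d", seed = 1)
#' res <- plan(m, config = ga_config(seed = 1))
#' res$success
#' }
#' @export
plan <- function(model, p0_index = model$start_index,
                 pG_index = model$goal_index, S = model$curvature_limit,
                 config = ga_config(), weights = cost_weights(),
                 k = NULL, dense_n = NULL, delta_frac = 0.05) {
  stopifnot(inherits(model, "centerline_model"))
  if (is.null(S) || S <= 0) stopf("a positive curvature limit S is required")
  if (is.null(p0_index) || is.null(pG_index)) stopf("start and goal indices are required")
  t0 <- proc.time()[["elapsed"]]

  a_s <- plan_global(model, p0_index, pG_index, k = k, dense_n = dense_n)
  if (inherits(a_s, "plan_failure")) {
    return(new_plan_result(NULL, a_s, FALSE, a_s$reason, list(), list(),
                           model, p0_index, pG_index, S, t0))
  }

  n <- nrow(a_s$pos)
  delta <- max(1L, as.integer(round(delta_frac * n)))
  prof <- curvature_profile(a_s, S)
  windows <- find_violation_windows(prof, delta)

  if (!length(windows)) {
    return(new_plan_result(a_s, a_s, TRUE, "tentative curve already feasible",
                           list(), list(), model, p0_index, pG_index, S, t0))
  }

  reports <- lapply(seq_along(windows), function(j) {
    cfg <- config
    cfg$seed <- child_seed(config$seed, j)
    ga_optimize(windows[[j]], a_s, model, S, cfg, weights)
  })
  final <- splice_segments(a_s, windows, reports)

  # joint effects: one re-windowing pass on the spliced curve
  prof2 <- curvature_profile(final, S)
  if (any(prof2$violated)) {
    windows2 <- find_violation_windows(prof2, delta)
    reports2 <- lapply(seq_along(windows2), function(j) {
      cfg <- config
      cfg$seed <- child_seed(config$seed, 1000L + j)
      ga_optimize(windows2[[j]], final, model, S, cfg, weights)
    })
    final <- splice_segments(final, windows2, reports2)
    windows <- c(windows, windows2)
    reports <- c(reports, reports2)
  }

  ok <- verify_constraints(final, model, S)
  reason <- if (ok) "all constraints satisfied" else {
    if (all(vapply(reports, `[[`, logical(1), "feasible")))
      "constraint violation persists after splicing"
    else "local optimization failed to repair a segment within its limits"
  }
  new_plan_result(final, a_s, ok, reason, windows, reports,
                  model, p0_index, pG_index, S, t0)
}

# Independent feasibility checker (not the optimizer's own bookkeeping).
verify_constraints <- function(curve, model, S) {
  prof <- tryCatch(curvature_profile(curve, S), error = function(e) NULL)
  if (is.null(prof)) return(FALSE)
  dc <- distance_to_centerline(curve$pos, model)
  all(prof$values <= S) && all(dc$dist <= dc$radius)
}

new_plan_result <- function(final, tentative, success, reason, windows,
                            reports, model, p0_index, pG_index, S, t0) {
  elapsed <- proc.time()[["elapsed"]] - t0
  metrics <- if (!is.null(final) && inherits(final, "path_curve")) {
    p0 <- model$points[p0_index, ]; pG <- model$points[pG_index, ]
    prof <- curvature_profile(final)
    data.frame(plan_time_s = elapsed,
               norm_length = normalized_path_length(final, p0, pG),
               min_wall_distance = min_wall_distance(final, model),
               max_curvature = max(prof$values),
               mean_curvature = mean(prof$values),
               success = success)
  } else {
    data.frame(plan_time_s = elapsed, norm_length = NA_real_,
               min_wall_distance = NA_real_, max_curvature = NA_real_,
               mean_curvature = NA_real_, success = success)
  }
  structure(list(final_curve = final, tentative_curve = tentative,
                 success = success, reason = reason, windows = windows,
                 segment_reports = reports, S = S, metrics = metrics),
            class = "plan_result")
}

#' @export
print.plan_result <- function(x, ...) {
  cat(sprintf("<plan_result> %s (%s)\n",
              if (x$success) "success" else "FAILURE", x$reason))
  if (!is.null(x$final_curve) && inherits(x$final_curve, "path_curve")) {
    cat(sprintf("  windows optimized: %d; max curvature %.4f (limit %.4f); min wall distance %.2f mm\n",
                length(x$windows), x$metrics$max_curvature, x$S,
                x$metrics$min_wall_distance))
  }
  invisible(x)
}
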