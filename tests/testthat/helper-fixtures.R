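# Geometric fixtures built in code.

# Points on a circular arc of given radius (2D), angles in radians.
circle_points <- function(radius, angles, center = c(0, 0)) {
  cbind(center[1] + radius * cos(angles), center[2] + radius * sin(angles))
}

# A straight 2D centerline model along +x with constant radius.
straight_model <- function(n = 50, spacing = 1, radius = 5) {
  pts <- cbind(seq(0, by = spacing, length.out = n), rep(0, n))
  centerline_model(pts, rep(radius, n))
}

# A 2D model with one sharp bend of the given turn angle between two
# straight legs, inside a wide vessel: the local optimizer's canonical
# repair problem.
sharp_bend_model <- function(leg = 40, spacing = 1, turn = pi / 3,
                             radius = 10) {
  n1 <- round(leg / spacing)
  leg1 <- cbind(seq(-leg, -spacing, by = spacing), 0)
  dir2 <- c(cos(turn), sin(turn))
  leg2 <- outer(seq(0, leg, by = spacing), dir2)
  pts <- rbind(leg1, leg2)
  centerline_model(pts, rep(radius, nrow(pts)))
}

# Naive Cox-de Boor recursion, transcribed literally (0/0 := 0), used as
# the independent oracle for the vectorized basis implementation.
naive_cox_de_boor <- function(w, i, p, knots) {
  if (p == 0) {
    inside <- knots[i] <= w && w < knots[i + 1]
    # closed right end of the domain
    if (!inside && w == knots[length(knots)] && knots[i] < knots[i + 1] &&
        knots[i + 1] == knots[length(knots)]) inside <- TRUE
    return(as.numeric(inside))
  }
  a <- 0
  if (knots[i + p] > knots[i]) {
    a <- (w - knots[i]) / (knots[i + p] - knots[i]) *
      naive_cox_de_boor(w, i, p - 1, knots)
  }
  b <- 0
  if (knots[i + p + 1] > knots[i + 1]) {
    b <- (knots[i + p + 1] - w) / (knots[i + p + 1] - knots[i + 1]) *
      naive_cox_de_boor(w, i + 1, p - 1, knots)
  }
  a + b
}

# Exhaustive minimum-hop search by enumerating all simple paths (oracle
# for BFS on small graphs).
brute_min_hops <- function(adj, from, to) {
  best <- Inf
  walk <- function(v, seen, hops) {
    if (v == to) { best <<- min(best, hops); return(invisible()) }
    if (hops >= best) return(invisible())
    for (u in adj[[v]]) if (!seen[u]) {
      seen[u] <- TRUE
      walk(u, seen, hops + 1L)
      seen[u] <- FALSE
    }
  }
  seen <- rep(FALSE, length(adj)); seen[from] <- TRUE
  walk(from, seen, 0L)
  best
}

# Textbook Kruskal-Wallis H with tie correction (oracle).
kw_H_formula <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  splits <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, splits, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}
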