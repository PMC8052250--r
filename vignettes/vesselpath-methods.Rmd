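---
title: "Curvature-constrained vascular path planning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature-constrained vascular path planning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The planning problem

A steerable catheter navigating the vasculature cannot bend arbitrarily
tightly: each device has a minimum bending radius, equivalently a maximum
curvature $S$ (mm$^{-1}$). A path that simply follows the vascular
centerline is the safest route — it maximizes clearance from the wall —
but at bifurcations the centerline itself can turn with a bending radius
below a millimetre, far beyond any catheter's capability. The planner in
this package resolves that tension in two phases:

1. **Global phase.** The centerline points $p_i$ (with their
   maximal-inscribed-sphere radii $r_i$, the local distance to the vessel
   wall) are connected into a $k$-nearest-neighbour graph. Breadth-first
   search finds a minimum-hop waypoint sequence from start to goal, and a
   cubic B-spline interpolation of those waypoints gives the *tentative
   curve* $a_s$.
2. **Local phase.** Curvature is evaluated along $a_s$; wherever $s_i > S$,
   the violating stretch — expanded by a margin $\Delta$ on both sides —
   becomes a *segment window*, and a small genetic algorithm re-fits just
   that window as a smoothing B-spline, scored by a penalty cost trading
   wall clearance, curvature and length against hard-constraint penalties.
   Repaired segments are spliced back with positional and tangential
   continuity, giving the final curve $a_f$.

The device is abstracted entirely by the scalar $S$; no kinematics, contact
mechanics or deformation modelling is attempted.

## Geometry engine

All curves are cubic ($M = 3$) B-splines over clamped, chord-length
parameterized knot vectors, evaluated with the Cox–de Boor recursion
implemented in `bspline_basis()`. Curvature comes from the analytic first
and second parametric derivatives of the spline, never from differencing
sampled positions, via the generic $N$-dimensional expression

$$ s \;=\; \frac{\sqrt{\tfrac12 \sum_{j,k}(\dot x_j \ddot x_k - \dot x_k
\ddot x_j)^2}}{\lVert \dot x \rVert^3}, $$

computed through the algebraically identical Lagrange form
$\sqrt{\lVert\dot x\rVert^2 \lVert\ddot x\rVert^2 - (\dot x \cdot \ddot
x)^2} / \lVert\dot x\rVert^3$ (tests verify the literal double sum, the
$N = 3$ cross-product form, and a finite-difference oracle agree). The
value is invariant to the parameterization, to rigid motions, and scales
as $1/c$ under uniform scaling by $c$ — all property-tested.

The tentative curve is sampled densely, 10 samples per waypoint by
default, because collision and curvature are checked only at samples:
the density bounds how much can hide between checks.

## The two genes of the local re-fit

Each GA chromosome is a pair $(g_1, g_2)$ controlling one candidate re-fit
of a window:

- $g_1$ (non-negative integer): the number of window points given **weight
  zero** in the fit. The $g_1$ points of highest local curvature are
  chosen — they are the ones pulling the fit into the tight turn. With the
  corner points silenced, the fit bridges the gap smoothly.
- $g_2$ (non-negative scalar, mm$^2$): the **smoothness bound**, an upper
  limit on the weighted error sum of squared displacements. Internally the
  fit minimizes $\sum_i w_i\lVert B(u_i)c - y_i\rVert^2 +
  \lambda\lVert D_2 c\rVert^2$ (a P-spline second-difference penalty on the
  control polygon), with $\lambda$ found by bisection as the largest
  penalty whose residual still respects $g_2$. So $g_2 = 0$ reproduces the
  interpolating fit, and growing $g_2$ trades displacement for smoothness.

A numerical subtlety matters here: when $g_1$ zero-weights a run of
points, the basis functions over that run lose data support. We keep the
system well-posed with a tiny *roughness floor* ($10^{-8}$ relative)
rather than a ridge: a ridge shrinks the unsupported control points toward
the coordinate origin, which is translation-variant and produced visible
artifacts; the roughness floor's null space is the linear polynomials, so
unsupported stretches are bridged by a smooth, rigid-motion-invariant
extension. Interpolation accuracy at $g_2 = 0$ remains well below the
$10^{-6}$ mm documented tolerance.

Window ends are pinned: the first/last control points reproduce the
surrounding curve's end positions, and the second/penultimate ones are
placed along the end tangents at the natural clamped-end derivative scale
(total chord length over the unit parameter interval). Pinning at the
natural scale is essential — pins placed a sample-spacing away distort the
parameterization and create curvature spikes at the joins. When the
window reaches the curve's start or goal, that end is left free and its
pose is optimized with the segment.

## Cost and penalties

A candidate segment $a$ is scored by

$$ f(a) = w_1\,\mathrm{mean}(d_c/r) + w_2\,\mathrm{mean}(s)/S +
w_3\,l(a)/l(a_0) + w_4\,P[\max(0, s-S)] + w_5\,P[\max(0, d_c-r)], $$

with defaults $w_{1..3} = 1$, $w_4 = w_5 = 1000$: $d_c$ is the distance
from each sample to its nearest centerline point, $r$ the radius stored at
that point (a sample is inside the vessel exactly when $d_c \le r$), and
$l(a_0)$ the original window length. $P$ aggregates pointwise excesses;
the default is the maximum (configurable to mean or sum), so a single
violating sample already contributes $w_4$ times its excess and a
violating candidate is never preferred to a feasible one.

The feasibility threshold (default 1000) flags gross infeasibility, but a
*small* residual excess — say $0.004$ mm$^{-1}$ over $S$ — costs only a
few units and would pass a literal threshold test while still violating
the constraint. The escalation logic therefore continues (doubling $n_g$)
while the best candidate has **any** positive hard-constraint excess, not
only while its cost exceeds the threshold. Success of a whole plan is
decided by an independent re-check of $\max(s) \le S$ and $d_c \le r$ at
every sample of the spliced curve, never by the optimizer's bookkeeping.

## The genetic algorithm

Population 8, truncation selection of the best 4, single-elite survival
(making the best cost provably non-increasing), per-gene exchange
crossover between the four parent pairings, and Gaussian mutation.
Three choices were left open by the scheme and are fixed here as package
design decisions:

- **Initialization.** $g_1$ uniform up to a third of the window size, with
  two chromosomes seeded at the count of currently violating samples — a
  data-driven prior for how many points must stop pulling the fit. (A
  narrow $\{0..3\}$ initialization was tried first and could not reach the
  useful range, routinely 20–40 on realistic windows, within a round.)
  $g_2$ is log-uniform between $10^{-6}\times$ and $1\times$ the squared
  residual of the window's straight chord — the largest displacement
  budget that could ever be useful.
- **Mutation scales.** $\sigma_{g_1}$ is 4% of the window point count (at
  least 1); $\sigma_{g_2}$ is 20% of the population's current $g_2$ span.
- **Immigration.** Each generation the worst slot is refilled with a fresh
  random chromosome. An 8-individual population otherwise converges
  prematurely on a small fraction of seeds, stalling short of a feasible
  repair; steady immigration removed every such stall in testing while
  leaving the monotone elite untouched.

Escalation multiplies $n_g$ (default 30) by 2 for at most 4 rounds — a
deterministic budget of up to 450 generations — with a 60 s per-window
wall-clock ceiling as a safety net. Results are bit-reproducible from the
seed whenever the wall clock does not intervene, which at these sizes it
does not; an earlier design that stopped on wall-clock alone was
measurably load-dependent and abandoned. Windows never share samples
(overlapping windows are merged upstream), each window gets a child seed
derived from the global seed by a fixed formula, and window results are
therefore independent of execution order — asserted by re-running windows
in reverse order in the tests.

After splicing, the full path is re-checked; if the joins re-introduce a
violation the affected region is re-windowed and optimized once more, and
a second failure fails the plan honestly.

## Synthetic vasculature

Real centerline datasets cannot ship with the package, so a generator
produces the study conditions. Trees are assembled from circular-arc
serpentines (arcs of radius $R$ alternating left/right through angles
drawn around a preset turn angle $\theta$), a bifurcation where a short
stub continues the trunk heading, and a goal branch leaving through a
small fillet at the preset's junction angle. Radii taper linearly with a
smooth widening around the junction, as maximal-inscribed-sphere radii do
at real bifurcations. In 3D the arc planes tilt randomly between arcs.

Four presets emulate recognisable anatomy at benchmark scale:

| preset | N | tortuosity (target) | S (mm$^{-1}$) | radii (mm) |
|---|---|---|---|---|
| femoral2d | 2 | 2.365 ± 0.100 | 0.08 | 3.5 → 2.4 |
| lowerlimb2d | 2 | 1.067 ± 0.015 | 0.10 | 3.2 → 2.0 |
| aorta3d | 3 | 1.075 ± 0.045 | 0.08 | 11 → 6 |
| coronary3d | 3 | 1.501 ± 0.120 | 0.20 | 2.0 → 1.3 |

The turn angles were calibrated once, numerically, so that the mean
arc-chord tortuosity of the start-to-goal path over hundreds of seeds
lands on the target mean (for an ideal alternating serpentine the ratio is
$\theta / (2\sin(\theta/2))$; the junction kink shifts it, hence the
numerical calibration). The per-arc jitter sd sets the between-seed
spread. For the aorta preset the spread achievable from arc jitter alone
(≈0.03) is narrower than the target band's sd; the mean is the calibrated
quantity.

Two presets are deliberately *sharp*: femoral2d and coronary3d join the
goal branch through a sub-millimetre fillet (bending radius < 1 mm), so a
centerline-following curve always violates $S$ there and the local
optimizer is always exercised. Both also straighten into the bifurcation
over a short leg (20 mm / 8 mm), and their serpentine arcs use only ~70%
of the curvature budget ($R = 18$ mm against $1/S = 12.5$ mm for
femoral2d). Both features are anatomically sensible and geometrically
necessary: the corner-cut excursion of the repair needs headroom below
$S$ on the legs it lands on, and an earlier preset whose arcs consumed
84% of the budget made sharp-corner repairs infeasible inside the vessel.

What the generator does **not** emulate: non-circular cross-sections,
stenoses, imaging noise in the centerline positions or radii, deformation
over the cardiac cycle, and n-furcations beyond simple bifurcations.
Passing tests on these models show the planner's geometric and
algorithmic contracts hold; they do not certify performance on any
clinical dataset.

## Baselines and evaluation

The comparison planners are centerline-sampling RRT and RRT*: samples are
drawn uniformly from centerline points (max 4048 per trial), straight
extensions are accepted if interpolated test points — every quarter of the
smallest local radius, so a segment cannot tunnel through a wall — stay
inside the vessel, goal connection is attempted with probability 0.1, and
RRT* chooses parents among / rewires its 32 nearest tree nodes. The
baselines do not enforce the curvature limit; their curvature is measured,
which is the contrast the benchmark exists to show.

Metrics: normalized path length $l(a)/\lVert p_G - p_0 \rVert$, minimum
wall distance $\min_i (r_i - d_{ci})$, curvature statistics, wall-clock
planning time (recorded for information only, never asserted), and the
success rate $\delta = n_s/n$. Method differences are compared with the
Kruskal–Wallis rank test at $\alpha = 0.05$ (`stats::kruskal.test` behind
the `rank_group_test()` surface, with $H = 0, p = 1$ by convention when
all values tie). Benchmarks perturb the endpoints with per-coordinate
Gaussian noise ($\sigma = 10$ model units by default, configurable — the
appropriate units depend on whether the source images were pixel- or
mm-scaled) and snap them to the nearest centerline point, keeping the
graph search well-posed.

## Numerical choices and degenerate inputs

- Chord-length parameterization throughout; consecutive duplicate
  waypoints are dropped before fitting, and coincident endpoints make
  tortuosity and normalized length error out explicitly.
- Fewer than 4 waypoints lower the spline degree with a warning rather
  than failing: degenerate but plannable.
- A vanishing first derivative (cusp) raises an error naming the sample.
- $\Delta$ defaults to 5% of the dense sample count; windows are counted
  in dense samples (the same index space as the curvature profile). The
  margin must leave room for the repair arc ($\approx R/\tan((\pi -
  \delta_{turn})/2)$ on each side of a corner), which the defaults do at
  the presets' scales.
- BFS minimizes hop count, not arc length; over a symmetrized k-NN graph
  it takes stride-$k/2$ hops where it can. The two coincide only for
  uniform spacing — the planner implements literal BFS and documents the
  distinction rather than silently substituting a metric search.
- Problem sizes used in the shipped tests and benchmark defaults (models
  of ~150–300 points, dense sampling ~10× waypoints, 50-trial benchmark
  units) were chosen as desk-scale analogues of the study conditions.

## Known limitations

- The smoothing-fit family displaces points toward smoothness, not
  radially; windows spanning a full high-curvature arc are repairable only
  when the surrounding corridor leaves room, and the planner reports an
  honest failure otherwise.
- Success depends on the margin $\Delta$ making windows wide enough to
  contain the repair arc; pathological $S$ close to the vessel's own
  curvature regime degrades to frequent failures (correctly reported).
- Wall-clock time is hardware-dependent and intentionally outside every
  assertion.
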