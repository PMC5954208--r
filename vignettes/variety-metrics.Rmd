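---
title: "Quantifying walking-path variety and building walk-training courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying walking-path variety and building walk-training courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varietywalk)
```

## The problem

Toddlers learning to walk do not practice steady-state, straight-line gait.
During free play they produce short, curving, omnidirectional bouts of
walking punctuated by frequent stops — a strikingly *varied* practice
regimen. Whether that variety helps or hinders the acquisition of
functional walking can be probed with humanoid-robot walk optimization:
train a simulated robot's walk engine by replaying walking paths of
different variety, then score the resulting teams against each other in
round-robin soccer tournaments. This package implements the desk-scale
analysis around that experiment:

1. **Path metrics** — segment raw step streams into walking bouts and
   quantify four dimensions of variety per walker.
2. **Balanced clustering** — partition walkers into equal-size groups by
   variety profile.
3. **Course construction** — turn recorded (or synthetic) sessions into
   walk/stop training schedules, plus geometric baseline courses.
4. **Tournament analytics** — aggregate per-game ledgers into league
   tables, win matrices, and goal-difference statistics.
5. **Synthetic sessions** — a correlated-random-walk generator so every
   stage is testable without access to video-coded infant data.

The physics simulation, the robot walk engine, and the soccer gameplay are
out of scope: the package produces and consumes their tabular inputs and
outputs.

## Walking bouts and the variety profile

A *session* is an ordered table of foot placements $(t_i, x_i, y_i)$ in a
6 × 9 m playroom, 20 minutes of free play at the defaults. A *walking
bout* is a maximal run of steps with every inter-step interval below the
stationary threshold (500 ms by default): a pause of at least 500 ms ends
the bout, matching the behavioral-coding convention that a walker
stationary for half a second has stopped. `segment_bouts()` implements
this as a single linear scan, so every step belongs to exactly one bout.

Per bout, two path-shape quantities are computed:

* **Path curvature** (a straightness index). For a bout of at least 4
  steps, the *overall* ratio is chord over arc,
  $d(p_1, p_n) / \sum_i d(p_i, p_{i+1})$, and the *step-to-step* ratio is
  the same chord/arc ratio averaged over every consecutive triple
  $(p_i, p_{i+1}, p_{i+2})$ (sliding window, stride 1). The bout's
  curvature is the equal-weight mean of the two. It lies in $(0, 1]$: 1
  for a perfectly straight path, values near 0 for maximally tortuous
  ones. Bouts of fewer than 4 steps, or with zero traveled distance, are
  flagged undefined rather than zeroed.
* **Heading changes**. For consecutive displacement vectors
  $v_i = p_{i+1} - p_i$, the turning angle at each interior step is the
  plane angle between $v_i$ and $v_{i+1}$, reported in degrees. The
  default is the absolute angle in $[0, 180]$ — the conservative reading
  of "change in degrees" — with signed angles (counter-clockwise
  positive) available via `signed = TRUE`. Zero-length displacements
  (re-digitized identical positions) are skipped and counted.

`variety_profile()` reduces a session to four numbers, each a measure of
*dispersion*, not level:

| dimension | definition |
|---|---|
| `shape_variety` | SE of per-bout curvature (eligible bouts only) |
| `direction_variety` | SE of absolute heading change, pooled over all step pairs |
| `length_variety` | SE of steps-per-bout, over all bouts |
| `n_bouts` | number of bouts (starts and stops) |

All standard errors use the sample standard deviation ($n-1$ denominator)
divided by $\sqrt{n}$, the convention of behavioral reporting. A
dispersion with fewer than two contributing units is `NA`, never silently
zero, and the contributing counts are returned alongside. Two open
choices are exposed as arguments: heading changes are pooled across bouts
(attributing the statistic to step pairs) rather than aggregated per bout
(`pool_direction = FALSE` gives the per-bout variant), and bouts of 1–3
steps do count toward `length_variety` — they are bouts — while being
ineligible for curvature.

## Equal-cardinality k-means

Walkers are grouped by variety profile with k-means under an exact
equal-size constraint: every cluster holds exactly $n/k$ members
(`balanced_kmeans()`, default $k = 5$; $n$ must be divisible by $k$).
The alternation is Lloyd's, but the assignment step is a balanced
transportation problem — each cluster a sink of capacity $n/k$, cost the
squared Euclidean distance to the centroid — solved exactly by successive
shortest augmenting paths (min-cost flow, implemented in C++). Because
each assignment is optimal under the constraint and each centroid update
is a mean, the within-cluster sum of squares never increases, so the
iteration terminates at a stable assignment.

Numerical and design choices, all of which the underlying literature
leaves open:

* **Feature scaling**: z-scores by default, so all four dimensions weigh
  equally in squared distance; min–max scaling is reserved for display
  (`standardize_features(method = "minmax")`). Zero-variance columns are
  centered and left unscaled, with a warning.
* **Initialization**: k-means++ seeding; best of `n_restarts = 32`
  restarts by objective, all driven by one integer seed.
* **Determinism and ties**: the computation runs in a canonical row order
  (rows sorted by feature values, then id), so the returned partition is
  identical for any permutation of the input rows, distance ties resolve
  toward the lowest-sorting walker, and cluster labels are numbered by
  first appearance. Strict objective improvement (beyond $10^{-12}$) is
  required to replace the incumbent restart, so restart ties keep the
  earliest.
* **Exactness**: on instances small enough to enumerate ($n \le 8$,
  $k = 2$), the solver is tested against the exhaustive minimum over all
  balanced partitions; at every iteration the cardinality constraint
  holds exactly.

The greedy capacity-filling heuristic sometimes used for balanced
clustering is deliberately *not* the default assignment: it can violate
optimality of the assignment step, which is cheap to solve exactly at
these problem sizes.

## Training courses

`session_to_timeline()` replays a session as a schedule in field
coordinates (room center mapped to field center, meters preserved 1:1 —
the 1 m grid convention; `grid_cell` rescales if needed): each bout
becomes a run of walk-to-waypoint elements timed by the walker's own
inter-step intervals, and each inter-bout pause becomes a stop element of
duration $\min(\text{pause}, 2\,\mathrm{s})$. The 2 s cap reflects robot
stabilization: a humanoid is fully settled after about two seconds of
standing, so longer stationary periods add no training information.

`build_infant_course()` samples one contiguous 4-minute block per walker
(uniform start over feasible positions; timelines shorter than a block
are cycled end-to-start until the duration accumulates) and concatenates
15 of them into an exactly 3600 s course. Three invariants are enforced
simultaneously: exact total duration, no stop above the cap, and no two
adjacent stops. Where a block boundary would abut two stops, they are
merged, capped at 2 s, and the trimmed time is recovered by extending
that block within its own timeline — so duration is conserved exactly
rather than approximately. A block boundary that bisects a walk segment
splits it at the position interpolated along the segment.

The geometric baselines follow fixed structures: the line course is 10
repetitions of 7 s forward walking plus a 2 s stop (90 s); the circle
course updates the target heading every second for 20 s around a fixed
circle (radius 1.5 m by default) and then stops for 2 s, repeated 7 times
(154 s); the square course alternates an end-stop lap with a
corner-stop lap (5 s of walking per side, 20 s per lap), the pair
repeated 7 times. "Repeated 7 times" is read as 7 repetitions of the
alternating *pair* — the natural unit of the alternation. Spatial sizes
derive from a nominal walk speed (0.4 m/s by default, a steady humanoid
walk), since the source procedure sizes shapes by walking time, not
distance.

## Tournament analytics

`build_league()` scores a per-game ledger with the standard league rule
(3 points a win, 1 a tie, 0 a loss), reporting per-team W/L/T, per-game
goals scored and conceded as mean ± SE, and the average goal difference —
points measure *consistency* of success, goal difference its *magnitude*.
Ranking ties break by average goal difference, then name.
`goal_difference_anova()` runs a one-way ANOVA over per-game goal
differences grouped by team (the per-game unit is what the degrees of
freedom in published tables of this design imply), followed by all
pairwise two-sample t tests with Bonferroni correction. Pooled-variance
tests are the default — matching the classical post-hoc presentation —
with Welch available (`var_equal = FALSE`). Pairs are ordered so the
higher-scoring team comes first and mean differences are positive. A
ledger with no within-group variance anywhere is flagged `degenerate`
rather than silently producing infinite statistics.

Two bundled scoring tables (`tournament_scoring(1)` and `(2)`) record the
published results of the two tournaments this design comes from — five
and six teams, 1,000 head-to-head matches per pair. They serve as
arithmetic fixtures: every row satisfies
$\text{points} = 3W + T$ and $W + L + T$ equals the scheduled 4,000 or
5,000 games.

## The synthetic generator

`generate_session()` draws sessions from a bout-structured correlated
random walk. Per bout: a step count
$1 + \mathrm{NB}(\mu - 1, \text{size})$, a persistent turning bias drawn
from $\mathcal{N}(0, \sigma_{\text{drift}})$, and a fresh uniform initial
heading. Per step: a heading change
$\mathcal{N}(\text{bias}, \sigma_{\text{heading}})$ and a truncated-normal
step length (mean 0.25 m). Steps fall at a fixed 0.3 s cadence — about
three steps per second, a brisk toddler pace chosen safely below the
0.5 s stationary threshold (an exactly 0.5 s cadence would make every
step its own bout, so the two constants cannot coincide). Pauses between
bouts are truncated at 0.6 s so segmentation recovers the generated bout
count exactly.

Walls are handled by *minimal deflection*: when a proposed step would
leave the room (keeping a 0.3 m clearance), the heading is rotated by the
smallest angle — in 5° increments, alternating sides — that keeps the
step inside. Walkers therefore graze walls rather than U-turn at them.
An earlier center-steering rule was rejected because its near-reversals
injected heavy-tailed turning angles that swamped the direction-variety
signal at low heading dispersion, destroying the monotone relationship
between $\sigma_{\text{heading}}$ and measured direction variety that
makes the generator useful for parameter-recovery testing. Deflection is
deterministic, so the random stream is identical whether or not a wall is
ever touched.

The generator maps cleanly onto the four variety dimensions:
$\sigma_{\text{heading}}$ drives direction variety, the drift SD spreads
per-bout tortuosity (shape variety), the negative-binomial size controls
length variety, and `n_bouts` is the start/stop count. The five presets
(`variety_presets()`, named by conventional team colors) encode only the
*ordinal* pattern of high/low features across the five published
path-variety groups; their numeric values are this package's design,
chosen for clear between-group separation, and were frozen before the
test suite asserted anything about them. Two compressions limit how far
the dimensions can be pushed: absolute turning angles saturate toward the
uniform distribution as $\sigma_{\text{heading}}$ grows, and with short
bouts the curvature SE is dominated by within-bout sampling noise. In
cohorts, per-session bout counts are jittered ($\mathrm{Poisson}$ around
the preset) so the start/stop dimension carries walker-to-walker
variation.

What the generator does *not* emulate: biomechanics (no feet, no gait
cycle), goal-directed locomotion toward toys or caregivers, room
furniture, or the joint distribution of real infant path features — that
distribution is unpublished, and passing recovery tests on synthetic
cohorts shows the pipeline recovers *designed* structure, not that real
cohorts cluster this cleanly.

## Problem sizes and tolerances in the test suite

The suite exercises: segmentation and profile oracles on randomized
sessions (agreement to $10^{-9}$); the curvature worked example
$(1/3 + \sqrt{2}/2)/2$ against an independently coded oracle
($10^{-9}$); balanced k-means against exhaustive enumeration on 100
random instances with $n \le 8$; cohort recovery over 10 seeds of the
full 75-session pipeline (mean adjusted Rand index at least 0.9); and
direction-variety monotonicity across a five-point heading-dispersion
grid at 200 bouts per setting, three seeds. These sizes keep the default
run in tens of seconds while leaving the statistical assertions
well-powered; all randomness is seeded.

## Known limitations

* Curvature and heading statistics treat digitized steps as exact;
  digitization noise propagates directly into the variety metrics.
* The balanced assignment is exact, but the overall balanced-k-means
  objective is still a local optimum over restarts, as for any Lloyd-type
  scheme; the exhaustive guarantee is only tested at enumerable sizes.
* Course construction reads time, not dynamics: the robot is assumed to
  reach each waypoint on the walker's schedule.
* The ANOVA treats games as independent observations, as the published
  design does; scores within a match pairing are plainly not independent
  samples of a common population, so the F statistic is descriptive.
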