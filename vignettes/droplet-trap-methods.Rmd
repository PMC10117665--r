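---
title: "Methods: flow-trap mechanics and mobility scoring in dropletTrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flow-trap mechanics and mobility scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropletTrap)
```

# The physical picture

A millimetre-scale water droplet on a vibrating substrate develops
steady recirculating flow cells; the number of cells (one, two or four)
is set by the driving frequency, which this package treats purely as
metadata — the vibration physics itself is not modelled. A zebrafish
larva confined in the droplet is prevented from migrating, and in the
four-cell pattern it sits at a central stagnation point where the local
flow is well approximated by the planar straining field
$(u, v) = (\dot\epsilon x, -\dot\epsilon y)$. Everything the package
computes flows from that configuration: the torque a slender body feels
there, the resulting orientation equilibria, and the statistics that
turn recorded headings into a mobility score.

# Flow fields

`flowField()` provides the straining simplification plus three bounded
fields on the droplet disk of radius $R$, defined by streamfunctions
($u = \partial\psi/\partial y$, $v = -\partial\psi/\partial x$):

| pattern | $\psi$ | cells |
|---|---|---|
| `four_cell_bounded` | $\dot\epsilon\, x y (1 - r^2/R^2)$ | 4 |
| `two_cell` | $\dot\epsilon\, R y (1 - r^2/R^2)$ | 2 |
| `one_cell` | $(\dot\epsilon/2)(R^2 - r^2)$ | 1 |

The bounded fields are the simplest smooth fields that satisfy
no-penetration on $r = R$ and have the observed cell counts; the
four-cell one reduces exactly to the straining flow as $r/R \to 0$,
which ties the bounded geometry to the torque analysis. For the one-cell
pattern we use rigid rotation ($u_\theta = \dot\epsilon r$, uniform
vorticity $2\dot\epsilon$). A polynomial alternative with
$u_\theta(R) = 0$ was rejected: any field whose tangential velocity
returns to zero at the rim necessarily has ring-shaped streamfunction
extrema and sign-changing vorticity, which breaks the one-extremum-
per-cell correspondence that the pattern classifier relies on. The
droplet surface is free, so tangential slip at the boundary is
physically acceptable.

The magnitude $\dot\epsilon$ is a free parameter (the droplet-internal
flow speed is not constrained by the experiments this emulates); all
defaults use $\dot\epsilon = 1\,\mathrm{s^{-1}}$, and every derived
threshold scales with it explicitly.

## Pattern classification

`classifyPattern()` reconstructs the streamfunction from a sampled grid
by trapezoidal path integration (averaging the two integration orders
for robustness), smooths it with a Gaussian of `smoothSigma` grid cells,
and counts streamfunction extrema inside the mask — one per
recirculation cell. Three numerical details matter:

* **Plateau-tolerant extrema.** On even grids a vortex centre falls
  exactly between four equal-valued nodes; a strict local-maximum test
  finds nothing. A candidate node must tie the extreme of its
  8-neighbourhood and strictly beat at least one neighbour; adjacent
  candidates are merged (8-connected components) and counted once.
  Constant plateaus beat no neighbour and are ignored.
* **Hole filling.** Velocity grids binned from tracer tracks leave
  empty cells wherever no particle passed. Empty cells inside the disk
  hull spanned by the data are filled by repeated neighbour averaging
  before integration; the grid object itself keeps empty cells masked,
  so filling is internal to classification.
* **Smoothing width.** `smoothSigma = 1.5` cells suppresses the
  bin-to-bin noise of tracer-derived grids; analytic fields classify
  identically at 1 and 1.5, so the wider default costs nothing.

A near-zero field (speeds below `degenerateTol`) is reported as
`random` with 0 cells rather than classified.

# Slender-body torque and equilibria

With drag correction $c = 2\ln(L/a) - 1$ and perpendicular coefficient
$c_\perp = 8\pi\mu/c$, the torque about the pivot for a rod along
$s \in [0, L]$ at heading $\theta$ is

$$T = \int_0^L s\, c_\perp\, u_\theta'(s)\, ds, \qquad
  u_\theta'(s) = u_\theta(s) - \dot\theta s,$$

which on the straining flow evaluates to
$T(\theta) = -(8\pi\mu\dot\epsilon/c)(L^3/3)\sin 2\theta$. The $L^3/3$
prefactor corresponds to the rod extending from the pivot ($s \in
[0, L]$), not straddling it ($s \in [-L/2, L/2]$ would give $L^3/12$);
we adopt $[0, L]$ throughout — including the rotational drag
$\zeta_\mathrm{rot} = c_\perp L^3/3$ used for the dynamics — so the
closed form, the quadrature and the relaxation law are mutually
consistent. The choice affects only the time scale, not the
$\sin 2\theta$ structure, the zero set, or anything dimensionless.

Geometries with $L/a \le e$ are rejected (the correction $c$ would drop
to or below 1, outside the validity of resistive-force theory as adopted
here). The rod is rigid: bending-driven migration in the one-cell flow
is a real phenomenon but only a qualitative one, and gravity is
neglected because vertical motion is suppressed in a droplet of
fish-comparable depth.

`torqueNumeric()` integrates with `stats::integrate` at a relative
tolerance of $10^{-11}$; the absolute tolerance is floored at
$10^{-13} c_\perp U L^2$ (the natural torque scale, with $U$ the largest
relative speed along the rod) so the quadrature remains convergent at
exact torque balance, where the integrand is pure roundoff.

`equilibria()` reports the two zeros per half-turn, modulo the rod's
head–tail symmetry: for $\dot\epsilon > 0$, 90° is unstable (the slope
of $T$ is positive there, so a deviation grows) and 180° stable. The
angles are independent of $|\dot\epsilon|$; reversing the flow direction
swaps the labels.

# The active swimmer

The core behavioural observation — untreated fish fight to face upstream,
anesthetised fish are swept to the sink heading — is modelled by the
minimal smooth self-righting term:

$$\dot\theta = -\dot\epsilon \sin 2\theta + A \sin(\theta_g - \theta)
  + \sqrt{2 D_r}\,\xi(t).$$

* $A \ge 0$ (1/s) is the **activity**: $A = 0$ reproduces the passive
  rod exactly; large $A$ pins the fish at the goal $\theta_g$.
* Linearising at $\theta_g = 90°$ gives the decay rate $A -
  2\dot\epsilon$, hence the critical activity $A_c = 2\dot\epsilon$
  (`criticalActivity()`), verified in the tests by bisection on
  noiseless simulations.
* $D_r$ is rotational diffusivity. The default $0.05\,\mathrm{rad^2/s}$
  makes a strongly active fish ($A = 5\dot\epsilon$) fluctuate with a
  stationary spread of $\sqrt{D_r/(A - 2\dot\epsilon)} \approx 7°$
  around the goal — a band of roughly 80–100°, the width reported for
  wild-type fish. Noise enters orientation only; the trap itself holds
  the centroid, so translational diffusion is omitted from the core
  model.
* Whether a fish targets 90° or 270° is set by its initial heading
  (both upstream headings occur in practice); the folded statistics
  treat them identically.

`simulateSwimmer()` uses Euler–Maruyama with wrap-around, refuses steps
with $\Delta t \cdot \max|\mathrm{drift}| > 0.2$ rad, and is bitwise
reproducible given a seed (the global RNG state is saved and restored).
The default $\Delta t = 0.02$ s resolves the fastest default dynamics
($|\dot\epsilon| + A = 6\,\mathrm{s^{-1}}$) with margin.

`estimateActivity()` regresses finite-difference angular rates on
$\sin(\theta_g - \theta)$ with the passive term subtracted (or
co-estimated). Because the simulator is explicit Euler, finite
differences invert the update exactly on noiseless data, and with noise
the drift is evaluated at the left endpoint, so the estimator is
unbiased by construction. Estimates are clipped at zero — the amplitude
is a rate — and the unclipped standard error is reported; a fish pinned
exactly at the goal makes the regressor degenerate and raises an
identifiability error rather than returning noise.

# Tracking

Detection is deliberately classical: global threshold at a fraction of
the frame maximum (hence intensity-scale invariant), 8-connected
components (EBImage's 4-connected labelling plus a diagonal union-find
merge), minimum-area filter, intensity-weighted centroids, and
principal-axis orientation from second central moments, reported modulo
180°. Head–tail disambiguation, where needed, uses the intensity
asymmetry along the axis (synthetic fish are rendered brighter at the
head) and is off by default.

Pixel coordinates have the origin at the top-left pixel centre with y
down; conversion to physical coordinates recentres on the image and
flips y so angles agree with the flow-model convention.

Linking solves optimal bipartite assignment per frame pair
(`clue::solve_LSAP`) on Euclidean cost, excludes pairs beyond
`maxDispPx`, starts new tracks for unmatched detections, and does not
close gaps — a one-frame dropout splits a track, which biases nothing
downstream because velocities come from consecutive-frame steps only.
Detections are sorted by position before matching so the result cannot
depend on input order.

`velocityGridFromTracks()` is particle-tracking velocimetry, not
correlation PIV: each consecutive-frame displacement contributes one
velocity sample at the step midpoint, samples are averaged per grid
cell, and empty cells are masked. At the seeding densities of the
synthetic scenes PTV is accurate and directly testable against ground
truth; correlation PIV would add machinery without testable benefit.

# Synthetic data

The generators define the study conditions:

* **Cohorts** (`cohortSpec()`): three classes of five fish by default.
  Type I (untreated) has $A = 5\dot\epsilon$; type II (anesthetised, or
  motor-deficient — parameterised identically) has $A = 0$; type III
  (recovering) ramps $A$ linearly from 0 to the type-I level over 20
  simulated minutes, starting within ±10° of the sink axis. The ramp
  shape is the simplest monotone choice; nothing downstream assumes
  linearity. Observation windows are 5 min for types I/II (the reported
  stabilisation window) and the full 20 min ramp for type III.
  Per-fish seeds derive deterministically from the cohort seed.
* **Scenes** (`sceneSpec()`): tracers advected by midpoint Runge–Kutta
  substeps, rendered as Gaussian spots of width ~1.2 px with additive
  Gaussian sensor noise (default SNR 50); geometry defaults follow the
  experiments (12 mm droplet, 20 µm pixels, 30 fps tracer / 20 fps fish
  imaging). Seeding enforces a minimum tracer separation (default 6 px)
  because two sub-resolution tracers genuinely merge into one blob.
* **Pool walks** (`generatePoolWalk()`): seeded Gaussian random walks,
  optionally with a reflecting circular wall, for exercising the MSD
  estimator against its closed forms (ballistic $|v|^2\tau^2$, diffusive
  $4D\tau$, saturation under confinement).

What the generators do *not* emulate: burst-and-coast swimming,
dwell/freeze intermittency, inter-fish variability of $A$ beyond seed
noise, body flexibility, occlusions, illumination drift, and droplet
shape oscillation. Tests passing on these synthetics therefore validate
the *pipeline* — geometry, estimators, statistics — not the behavioural
realism of any particular fish.

# Mobility statistics

Headings are summarised by the circular mean and resultant length
(vector averaging; an arithmetic mean of degrees is wrong under
wrap-around, e.g. {350°, 10°}). The folded **source deviation** — the
minimal angular distance to {90°, 270°} — lives in [0°, 90°] and
treats both upstream headings as equivalent; the sink deviation is its
complement (they sum to 90° for every angle).

Classification applies the observed angle windows as a decision rule:
intact if the mean heading is within 10° of the source axis with
resultant ≥ 0.9; disrupted if within 20° of the sink axis with
resultant ≥ 0.9; recovering if within 40° of the source with resultant
≥ 0.5; otherwise indeterminate. The windows come straight from the
reported bands (80–100°, ~0 ± 10° with its 180–220° mirror, ~90 ± 40°);
the resultant thresholds encode "narrow region" vs "relatively broader
region" and are exposed in the configuration because the underlying
experiments report windows, not a rule.

The chance-alignment probability generalises the printed 5-fish case:
for a partition of the circle into $360/w$ windows,
$p = (w/360)^n (360/w)$, capped at 1 (it is a union bound). For
$n = 5$, $w = 30°$ this is $12^{-4} \approx 4.8 \times 10^{-5}$, and a
$10^6$-cohort Monte-Carlo under the same fixed partition agrees within
binomial error (this is one of the acceptance checks). For observed
cohorts, `cohortTable()` attaches the p-value when the minimal
enclosing arc of the per-fish means fits in one window — the "all fish
within one 30° window" reading — rather than requiring them to share a
fixed partition bin, which would fail a cohort straddling a bin edge at
89°/91°.

`recoveryTrend()` folds per-time-bin circular means onto the sink
deviation scale (0 = sink-aligned, 90 = source-aligned) and reports the
first and last bins plus the interpolated first crossing of 45°;
non-monotone series are flagged but still reported.

The MSD uses the standard time-averaged definition over all overlapping
origins, requires uniform sampling, and drops lags beyond the track
duration with a warning.

# Problem sizes and runtimes

The test-suite and acceptance runs use deliberately modest sizes chosen
as adequate for their statistical resolution: 181-point torque sweeps;
20-iteration bisection for the critical activity (resolution
$\sim 10^{-4}$ on $A$); 20-seed recovery cohorts of 2 000 steps; scenes
of 50 tracers over 60–90 frames at 20 µm/px in a 6 mm droplet
(criterion-level recovery needs only a few thousand truth positions);
100-seed random walks for the MSD calibration; $10^6$ Monte-Carlo
cohorts for the alignment probability (binomial SE
$\approx 7 \times 10^{-6}$ at $p \approx 4.8 \times 10^{-5}$); and the
default 5 + 5 + 5 cohort with the full 20-minute type-III ramp.

# Known limitations

* The activity model is phenomenological; $A$ is identifiable and
  interpretable, but no claim is made that real fish implement a
  $\sin(\theta_g - \theta)$ controller.
* The flow fields are steady idealisations; real droplet flows
  fluctuate and are three-dimensional near the contact line.
* PTV binning needs adequate seeding; very sparse scenes classify as
  `random` rather than guessing.
* Orientation from image moments is inherently 180°-ambiguous; head
  disambiguation relies on a rendered intensity asymmetry that real
  imagery may not provide.
* The chance-alignment formula is a union bound over a window
  partition; it is exact only in the regime where double counting is
  negligible (always the case at the sizes used here).
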