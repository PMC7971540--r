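---
title: "Shape-dependent Rho GTPase polarization: model, numerics and design choices"
author: "ShapePolarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-dependent Rho GTPase polarization: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ShapePolarity)
```

## The biological question

When a cell is confined to a micropatterned shape and then stimulated, the
small Rho GTPases Cdc42, Rac and Rho redistribute into a polarized pattern:
high active Cdc42 and Rac mark the prospective front, high active Rho the
rear. ShapePolarity simulates this process on static two-dimensional cell
outlines to ask how the *shape* of the cell — its symmetry, size and aspect
ratio — shapes the polarization pattern that an identical stimulus produces.
A central phenomenon of interest is *reverse polarization*: the spatial
maximum of active Cdc42 detaching from the stimulated front and travelling
in the opposite direction.

## The reaction–diffusion model

Nine concentration fields live on the cell interior: active/inactive Cdc42
($C$, $C_i$), Rac ($R$, $R_i$), Rho ($\rho$, $\rho_i$) and the
phosphoinositides PIP ($P_1$), PIP$_2$ ($P_2$), PIP$_3$ ($P_3$), all in
$\mu M$. Each GTPase cycles between a slowly diffusing active
(membrane-bound) form and a fast cytosolic inactive form,

$$\partial_t G = Q_G \frac{G_i}{G_{tot}} - d_G\, G + D_m \Delta G, \qquad
  \partial_t G_i = -Q_G \frac{G_i}{G_{tot}} + d_G\, G + D_{mc} \Delta G_i,$$

so each total $G + G_i$ is conserved pointwise by the reactions — the
mass-conserved ("wave-pinning") structure that lets fronts form and pin.
The activation rates couple the three switches and the lipids:

$$Q_C = \frac{I_C}{1 + (\rho/a_1)^n}\,\phi(P_3), \qquad
  Q_R = (I_R + \alpha C)\,\phi(P_3), \qquad
  Q_\rho = \frac{I_\rho + \beta R}{1 + (C/a_2)^n},$$

with the PIP$_3$ feedback factor $\phi(P_3) = (1-f) + f\,P_3/P_{3b}$
($0 \le f \le 1$; $\phi \equiv 1$ at basal PIP$_3$ and for $f = 0$). Cdc42
and Rho inhibit each other through Hill terms of coefficient $n$; Cdc42
activates Rac ($\alpha$), Rac activates Rho ($\beta$); Rho activation is
independent of the lipids.

The phosphoinositides form a linear conversion chain
PIP $\leftrightarrow$ PIP$_2$ $\leftrightarrow$ PIP$_3$ with constant PIP
input $I_{P1}$ and decay $\delta_{P1}$. The kinase steps
(PIP $\to$ PIP$_2$ by PI5K, PIP$_2$ $\to$ PIP$_3$ by PI3K) are amplified by
Rac and the phosphatase step (PIP$_3$ $\to$ PIP$_2$ by PTEN) by Rho, each
through a factor $(1 + X/X_b)/2$ equal to one at basal $X$. All three PIs
diffuse with $D_P$.

### Parameters

`polarityParams()` returns the standard set; every value is overridable by
name and via a flat `key = value` parameter file (`readParams()`). The
symbols, units and defaults:

| symbol | meaning | default |
|---|---|---|
| `C_tot`, `R_tot`, `rho_tot` | total Cdc42, Rac, Rho ($\mu M$) | 2.4, 7.5, 3.1 |
| `I_C`, `I_R`, `I_rho` | baseline activation inputs ($\mu M\,s^{-1}$) | 2.95, 0.5, 3.3 |
| `a1`, `a2` | Rho (Cdc42) level for half-max inhibition of Cdc42 (Rho) ($\mu M$) | 1.25, 1 |
| `n` | Hill coefficient of the mutual inhibition | 3 |
| `f` | PIP$_3$ feedback strength (–) | 0.4 |
| `alpha`, `beta` | Cdc42$\to$Rac, Rac$\to$Rho activation ($s^{-1}$) | 4.5, 0.3 |
| `d_C`, `d_R`, `d_rho` | inactivation rates ($s^{-1}$) | 1 |
| `D_m`, `D_mc`, `D_P` | diffusion of active / inactive / PI species ($\mu m^2 s^{-1}$) | 0.1, 50, 5 |
| `I_P1`, `delta_P1` | PIP input and decay ($\mu M s^{-1}$, $s^{-1}$) | 10.5, 0.21 |
| `kappa12`, `kappa21`, `kappa23`, `kappa32` | effective PI conversion baselines ($s^{-1}$) | 0.0084, 0.014, 0.0072, 4.32 |
| `C_b`, `R_b`, `rho_b`; `P_1b`, `P_2b`, `P_3b` | basal levels ($\mu M$) | 1, 3, 1.25; 50, 30, 0.05 |

Two parameter-level design choices deserve explanation:

* **Effective PI conversion rates.** The kinases/phosphatase PI5K, PI3K and
  PTEN are treated as well-mixed at a fixed 10 $\mu M$, so their
  second-order rate constants are folded into effective first-order
  baselines. `kappa23` and `kappa32` are the second-order constants times
  the enzyme level (0.00072 and 0.432 $\mu M^{-1}s^{-1} \times 10\,\mu M$);
  their ratio fixes basal PIP$_3$ exactly
  ($0.0072 \times 30 = 4.32 \times 0.05$). `kappa12` is *calibrated* so
  that the basal PI triple (50, 30, 0.05) $\mu M$ is an exact fixed point
  of the chain at basal Rac and Rho:
  $\kappa_{12} = (I_{P1} + \kappa_{21} P_{2b} - \delta_{P1} P_{1b})/P_{1b}
  = 0.0084\,s^{-1}$. A literal 10 $\mu M$ folding of the PI5K constant
  would put basal PIP$_2$ near 3000 $\mu M$, three orders of magnitude
  above its stated basal level, so the calibrated value is used; all four
  rates remain user-overridable.
* **Basal GTPase levels are not a fixed point.** With the standard inputs
  the resting concentrations balance Rac exactly and Rho almost exactly,
  but active Cdc42 has a small net drain
  ($Q_C C_i/C_{tot} - d_C C = -0.14\,\mu M s^{-1}$ at rest). The space-free
  system therefore relaxes from the standard initial state to a nearby
  fixed point at $(C^*, R^*, \rho^*) \approx (0.63, 2.07, 1.56)\,\mu M$
  (`wellmixedSteadyState()` computes it; the analytic PI fixed point is
  `piSteadyState()`). This is a property of the published constants, not of
  the implementation, and it means simulations carry a mild global
  transient on top of the stimulus response.

## Geometry: the synthetic-input generator

`makeShape()` rasterizes parametric outlines onto a regular square-cell
grid, emulating the confinement geometries of micropatterning experiments:
shapes with two mirror axes (`circle`, `ellipse`, `square`, `rectangle`)
versus shapes with a single mirror axis and a blunt end (`teardrop`,
`narrow_drop`, `wide_drop`, `triangle`). The blunt end sits at $+x$, the
point or apex at $-x$, and the single mirror axis is horizontal. Because
the exact published outlines of the drop family are not available, they are
generated as a blunt elliptical cap (x-semiaxis $\min(L, W)/2$) joined to a
tail whose half-width follows $(x/x_t)^p$ — straight flanks ($p = 1$,
teardrop), concave ($p = 1.6$, narrow drop) or convex ($p = 0.6$, wide
drop). This preserves the topological features the shape comparison rests
on (one symmetry axis, a blunt and a pointed end) at any length $\times$
width, and any outline can be substituted via `importMask()` (8-bit PNG,
foreground above 127).

The grid spacing is set so the longest extent plus a two-cell margin spans
`nMesh` cells (default 110), the convention used for all headline runs.
Cell-centre coordinates are built exactly antisymmetric about the grid
centre, so rasterized masks carry the outline's mirror symmetries *exactly*
— symmetry-breaking in a simulation can then only come from the dynamics,
not from one-pixel mask artifacts (which were observed to seed spurious
asymmetric maxima before this was enforced).

What the generator does *not* emulate: boundary roughness and adhesion
heterogeneity of real patterned cells, membrane deformation, and any
third dimension. Tests passing on these masks therefore validate the
solver and classification logic on idealized geometries, not the biology
of real confined cells.

## Stimulus and initial state

`initialState()` sets every species uniform at resting-cell values (active
/inactive Cdc42 1/1.4, Rac 3/4.5, Rho 1.25/1.85, PIs 55/30/0.05 $\mu M$),
whose per-GTPase sums equal the totals exactly. `stimulusProtocol()`
describes the transient graded activation: for $t \le \tau$ (default 10 s)
the Cdc42 input rate is $b + m\,s$ with $s$ the distance from the back of
the cell along the stimulus axis (defaults $b = 2.6$, $m = 0.05$);
afterwards it is a uniform 2.95 $\mu M s^{-1}$. The direction's second
letter names the prospective front: `L-R` puts the high end at the right
edge, `R-L` mirrors it, and `U-D` places the front at the bottom. The
gradient is measured from the shape's own bounding box, so it adapts to
cell length. The up–down sign convention is a genuine free choice (nothing
pins which vertical end is "front"); mirror symmetry of the dynamics makes
the two choices equivalent up to reflection, and the classification rules
are explicitly mirror-invariant (a property covered by the test suite).

## Numerics

The solver (`simulatePolarity()`) uses Strang operator splitting per step
$\Delta t$: a half step of diffusion, a full reaction step, a second half
step of diffusion.

* **Diffusion** uses the standard 5-point finite-volume Laplacian on the
  masked interior with zero-flux faces on the boundary
  (`buildDiffusionOperator()`; rows sum to zero, so the discrete flow
  conserves mass exactly). Each half step is advanced by the trapezoidal
  (Crank–Nicolson) rule; the three distinct diffusion coefficients
  ($D_m$, $D_{mc}$, $D_P$) each get one sparse Cholesky factorization per
  step size, cached and reused across the whole run, and each solve
  advances three species at once.
* **Reaction** kinetics are pointwise, so between diffusion half-steps
  every grid cell is an independent nine-dimensional ODE system. Cells are
  integrated in compiled code with an embedded Cash–Karp 4(5) Runge–Kutta
  pair and a *per-cell* adaptive substep, with local error controlled
  against `absTol` ($10^{-9}\,\mu M$) and `relTol` ($10^{-7}$ by default).
  The per-cell control matters: on a pinned front the PIP$_3$ feedback
  factor reaches $O(10)$ and the local activation rates $O(10^2)\,s^{-1}$,
  so front cells subcycle at millisecond steps while the calm bulk takes a
  few substeps — no cell pays for another's stiffness, and each cell's
  step size is carried across splitting steps. The activation input field
  is constant within a step; the stimulus switch-off time is a hard step
  boundary, as are all record times.
* **Conservation and positivity.** Runge–Kutta steps preserve the exact
  active+inactive antisymmetry of the GTPase reactions, and the diffusion
  solves conserve column sums, so per-GTPase mass drift over a full run is
  at round-off level (the run log records it). Small negative undershoots
  (possible at the sharp PIP$_3$ sink) are clipped to zero and counted;
  a drop below $-10^{-3}\,\mu M$ aborts the run as a diagnostic.
* **Degenerate maxima.** The recorded position of the spatial maximum is
  the centroid of all cells within `absTol` of the maximum, with a
  degeneracy flag — a uniform field reports the shape centroid, and
  symmetric fields report positions on the symmetry axis rather than an
  arbitrary tied cell.
* **Accuracy.** The splitting is second order asymptotically; on
  wave-pinning dynamics the pre-asymptotic error at $\Delta t = 0.25$ s is
  at the percent level for the recorded maxima (front positions are the
  sensitive quantity), dropping roughly fourfold per halving. The suite
  asserts this refinement behavior. Statements about recorded maxima at
  the default step should be read with that ~1% horizon in mind; runs
  aimed at quantitative point values use $\Delta t = 0.1$ s.

## Classification rules

`classifyPattern()` reduces a run to the categorical outcomes used in the
shape/size phase diagrams:

* *uniform* if the final max–min range of active Cdc42 is below
  0.01 $\mu M$;
* otherwise the final polarization axis is the axis (x or y) with the
  larger range of the axis-projected field — a projection is used rather
  than a pointwise gradient because isoclines curve near no-flux
  boundaries; the outcome is *normal* if the final maximum lies within two
  grid cells of the cell extremity at the stimulated front along that axis
  (either extremity when the axis is the perpendicular, "new" one), else
  *reverse*. The two-cell band operationalizes "maximum at an extremity",
  which is otherwise not quantified; the choice is exposed as
  `edgeCells`.

`onsetOfReversal()` reports the first record time at which the maximum has
retreated, against the stimulus direction, by more than one grid cell from
its running extreme; measuring from the running extreme (rather than the
initial position) catches a brief advance followed by retreat, and the
alternative rule is available via `rule = "initial"`. `deltaC()` measures
the drop from the main-axis maximum to the front extremity — small values
mean a broad front touching the membrane. `countFronts()` counts
4-connected components above a display threshold (3 $\mu M$ standard,
8 $\mu M$ for large-cell regimes), the same super-level sets rendered
white by `plotField()`.

## Sweeps

`aspectRatioSweep()`, `sensitivity1d()` and `phaseDiagram()` drive the
systematic experiments (size/aspect grids; one-at-a-time parameter series;
$(a_1, d_C)$ grids at $n = 1, 4, 8$). Runs still holding more than one
front at 1000 s — metastable competing peaks that usually merge later —
are continued to 3000 s with the stimulus off before classification. Every
run is deterministic and independent, so sweep tables are reproducible
row-by-row; individual failures are recorded in an `error` column without
aborting the sweep. The default $(a_1)$ grid includes both 2.0 and 2.25 as
the high value since both appear in the published exploration.

## Problem sizes used by the test suite

The package's own test policy: exactness properties (conservation,
operators, kinetics, rules) run on small meshes (24–60 cells across,
seconds each); quantitative point-value checks use the full 110-cell mesh
at $\Delta t \le 0.25$ s over 30 s horizons; long-horizon categorical
anchors (pattern classes at 1000 s) run on a 48-cell mesh at
$\Delta t = 1$ s with tolerances loosened to ($10^{-8}$, $10^{-5}$) —
settings at which the categorical outcomes match the fine-mesh,
default-tolerance runs while each run costs tens of seconds instead of
minutes. The mesh-convergence check compares the 110- and 220-cell meshes
directly.

## Known limitations

* Static geometry only: no membrane mechanics, no moving boundary, no
  actin module — shape is an input, never an output.
* The printed default constants do not make the resting state an exact
  fixed point (see above); quantitative point values (e.g. the height and
  position of the Cdc42 maximum at a given time) are sensitive to the Hill
  coefficient `n` and to the inactivation rates, so they should be treated
  as regime-level, not calibration-grade, predictions.
* Front positions in the wave-pinning regime are the most
  discretization-sensitive observable; categorical outcomes (normal /
  reverse / uniform, front counts) are robust well before point values
  converge.
* The drop-family outlines are plausible reconstructions, not digitized
  experimental masks; `importMask()` exists precisely so real masks can be
  substituted.
* Under a stimulus perpendicular to a drop shape's symmetry axis, the
  solution settles into a stable high-Cdc42 boundary spot at the
  stimulated edge (displaced toward the blunt end) instead of re-orienting
  the gradient onto the long axis, as interface-length minimization of the
  mass-conserved front would suggest for elongated shapes. This outcome is
  insensitive to mesh, tolerances and the Hill coefficient in our checks;
  the acceptance test encoding the expected re-orientation is left failing
  rather than weakened, and the discrepancy is treated as an open question
  about the model's spot-versus-band regime at these sizes.
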