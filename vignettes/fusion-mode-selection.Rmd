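---
title: "Fusion-mode selection on free-energy landscapes: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusion-mode selection on free-energy landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(endofuse)
```

## The problem

Late endosomes in the mouse visceral endoderm fuse in two visually distinct
modes.  In *explosive* fusion the fusion pore between two like vesicles
widens within tens of seconds and the pair rounds up into a single sphere.
In *bridge* fusion the pore stays narrow and the smaller compartment slowly
drains into its partner (here, a lysosome) over minutes until it vanishes
from the focal plane.  `endofuse` implements (i) the thermodynamic model
that explains which mode a vesicle pair selects, and (ii) the measurement
pipeline used to quantify fusion kinetics and actin turnover (FRAP) in
live-imaging data, exercised against a seeded synthetic-data generator.

## Free-energy model

A closed membrane of fixed area connected through a constricted neck is
described by two shape coordinates: the dimensionless neck width $w$ (waist
radius over $R_{\mathrm{eq}} = \sqrt{S/4\pi}$, the radius of the
area-equivalent sphere) and the area fraction $a \in (0, 0.5]$ of the
smaller lobe.  Membrane size is parameterised by the projected area $A_p$
(the microscopy size metric); the membrane area is fixed at $S = 4A_p$
(sphere equivalence).  The free energy combines Helfrich bending and
osmotic work,

$$F = b - \Delta p \, V, \qquad
  b = \frac{\kappa}{2} \oint (2H)^2 \, dS ,$$

with zero spontaneous curvature and the Gaussian term dropped (fixed
topology).  A sphere has $b = 8\pi\kappa$; the bending energy depends only
on shape, while the osmotic term scales with volume, so membrane size sets
the balance between the two.  Defaults follow the biological estimates:
$\kappa = 10\,k_BT$, minimum bending radius $R_0 = 100$ nm,
$\Delta p \simeq 2.5\text{–}25$ Pa (from an assumed 1–10 mM ion
difference), $T = 298$ K.  Note the deliberate inconsistency kept visible
in the API: an ideal van't Hoff conversion of 1–10 mM gives kPa-scale
pressures; the package exposes `vant_hoff_pressure()` alongside the Pa-scale
working range `default_osmotic_range()` and never reconciles them, treating
the working range as an effective input.

### Shape family

Minimum-energy shapes at fixed $(w, a, S)$ are built from an analytic
family: two spherical caps joined tangentially by an axisymmetric collar.

* **Toroidal collar** — a torus arc of tube radius $\rho$ (free variable of
  the constrained minimisation).  Closed forms exist for all areas, volumes
  and bending integrals, which is what makes landscape grids affordable.
* **Catenoid collar** — a patch of the zero-mean-curvature catenoid
  $r = c\cosh(z/c)$, whose waist radius pins $c = wR_{\mathrm{eq}}$.  It
  contributes *no* bending energy.

The scale-free minimisation (used for the bending-only landscape) takes the
cheaper of the two branches.  This matters: with the torus branch alone,
shrinking necks retain an $O(\kappa)$ residual collar energy, which
manufactures a spurious barrier at $w \to 0$ and would stall every orbit at
the post-pore initial condition.  The catenoid branch removes the artifact:
$b(w)$ decreases monotonically from the two-sphere value $16\pi\kappa$
toward the single-sphere value as the neck opens, which is exactly the
descent that drives explosive fusion.

For *large* vesicles the osmotic term dominates but the neck's bending
energy remains important, so the large-size landscape is
$F \simeq B_{\mathrm{neck}} - \Delta p\,V$.  Here the $R_0$ floor is
essential — an unconstrained narrow neck could always relax into a cheap
catenoid.  Physically, a catenoid waist of radius $wR_{\mathrm{eq}} < R_0$
bends the membrane below its minimum bending radius, so the floored family
is torus-only with $\rho \ge R_0$ and an effective waist radius
$\max(wR_{\mathrm{eq}}, R_0)$.  At $w = 0$ the neck energy is by convention
the limit value computed with waist radius $R_0$ (never a division by
zero).  Because the floor is an absolute length it breaks scale invariance;
it is therefore applied only in the large-size mode, keeping the
bending-only landscape exactly identical across vesicle sizes (the model's
own statement that $b$ depends on shape alone).

Shapes minimise *bending* energy only; the osmotic term is evaluated on the
minimiser afterwards.  This makes the large-mode free energy exactly linear
in $\Delta p$ with slope $-V(w,a)$, and landscapes at different pressures
share one geometry computation.

A discretised-meridian relaxation (`relax_shape()`, tangent-angle
parameterisation, 81 nodes, penalty constraints) provides a
family-independent check: across spot checks in the working region it finds
energies at most ~1% below the analytic family, well within the 5%
agreement the package tests enforce.

## Landscapes, orbits and the phase diagram

`compute_landscape()` evaluates $F$ on a rectilinear $(w,a)$ grid — by
default 31 × 25 nodes over $[0,0.6] \times [0.02,0.5]$, densified to 0.01
spacing over the corridor $w \le 0.15$, $a \in [0.25, 0.35]$ where mode
selection happens.  Geometrically infeasible nodes ($w^2 \ge 2a$: the neck
would outgrow the smaller lobe's cap) are masked, never interpolated;
stencils touching the mask reuse the nearest feasible value in the same
column, and queries inside the masked region raise errors.  Interpolation
is tensor-product 4-point Lagrange cubic: exact at nodes, smooth within
cells, with the analytic in-cell gradient.

Deformation follows overdamped dynamics on the landscape,
$x_{k+1} = x_k - M \nabla F \, \delta\tau + \sqrt{2 M E_{\mathrm{fluct}}
\delta\tau}\,\xi_k$, mobility $M = 1$, dimensionless time (the model fixes
no physical time scale).  With $F$ in $k_BT$, $E_{\mathrm{fluct}} = 1\,k_BT$
is thermal noise at room temperature.  The step starts at
$\delta\tau = 10^{-3}$ and is halved whenever the drift move would exceed
0.01 in either coordinate or (deterministic case) raise $F$, with a
1.5-fold recovery per accepted step; the zero-noise limit reproduces the
deterministic gradient orbit bitwise.  Boundaries reflect, except that a
proposal crossing a classification threshold is accepted as the terminal
state: the absorption boundary $a \le a_{\mathrm{abs}}$ coincides with the
default grid edge, and reflecting there first would let noisy orbits hover
above the threshold indefinitely.

Orbits are classified from first crossings: *explosive* if $w$ reaches
$w_{\mathrm{dev}} = 0.2$ strictly before $a$ falls to
$a_{\mathrm{abs}} = 0.02$, *bridge* in the opposite order (ties resolve as
bridge), *undetermined* otherwise.  The thresholds operationalise "the
orbit deviates from the narrow-neck path": $w_{\mathrm{dev}}$ sits just
above the $w \le 0.15$ corridor, and both are configurable (including the
side of the $a$ threshold, since the verbal description of bridge fusion as
absorption of the smaller lobe fixes the direction we adopt:
$a$ decreases).  `explosive_probability()` and `phase_diagram()` run seeded
orbit ensembles (per-orbit seeds derived deterministically from the master
seed) and report Wilson 95% intervals, with undetermined orbits kept in the
denominator.  The diagnostic scale
$\Gamma = 2\pi\kappa\sqrt{A_p/\pi}/R_0$ (an energy, with $\kappa$ in
$k_BT$) is reported per row but never used to rescale $F$.

On the default large-vesicle landscape ($A_p = 10\ \mu m^2$,
$\Delta p = 10$ Pa) the explosive fraction stays at zero for fluctuation
energies up to $\sim 10^2\,k_BT$ and rises through $\sim 10^3\,k_BT$ —
the order of $\Gamma$ — reaching a majority by $10^4\,k_BT$.  Thermal
noise alone therefore predicts bridge fusion for late-endosome-sized
vesicles across the whole working pressure range, while
cytoskeleton-scale forcing far above thermal can rescue explosive fusion;
both statements are asserted by the test suite with paired seeds.

## Crossover size

For a spherical vesicle, $V(A_p) = (4A_p/3)\sqrt{A_p/\pi}$.  Setting
$\Delta p \, V(A^*) = b$ with the typical bending energy
$b = 2 \times 10^{-18}$ J gives
$A^* = (3 b \sqrt{\pi} / 4 \Delta p)^{2/3}$: 0.22 $\mu m^2$ at 25 Pa and
1.0 $\mu m^2$ at 2.5 Pa.  Observed late endosomes (5–20 $\mu m^2$) sit far
above this switching range, which is why their homotypic explosive fusion
requires the fluctuation argument above.

## Synthetic data: what it emulates, and what it does not

The generator (`fusion_generator_config()` and `simulate_*`) encodes the
study conditions:

* **Sizes** are log-normal (positive, right-skewed, matching the shape of
  the published histograms), moment-matched to the reported mean ± SD per
  labeling time point (5.7 ± 6.4 $\mu m^2$ at 5 min, n = 265-scale;
  10.1 ± 8.1 at 15 min).  The sample-size labels reported for the 5- and
  15-min size distributions are ambiguous; the defaults follow the values
  quoted here.
* **Fusion durations**: homotypic 31.9 s, heterotypic 154.8 s.  The
  reported ±0.2 s and ±1.4 s are read as SEMs, so single-event SDs default
  to $0.2\sqrt{37} \approx 1.2$ s and $1.4\sqrt{25} = 7$ s; a
  "range-calibrated" preset (SD 7 s and 40 s, matching the quoted 20–50 s
  and 90–250 s completion ranges) ships alongside.  Durations are
  truncated positive.
* **Size–duration coupling** uses a Gaussian copula with the latent
  correlation calibrated analytically so the *Pearson* correlation between
  the log-normal size and the duration equals the target (0.60 homotypic,
  0 heterotypic) — only a Pearson r is reported for the real data, and a
  rank-preserving copula is the least-committal joint model consistent
  with it.
* **Tracks** (frame interval 5 s by default, 400 s recordings, ~tens of
  vesicles per field): homotypic events appear as two adjacent tracks
  replaced by a child whose projected area starts at the parents' sum and
  relaxes linearly to the volume-conserving single-sphere area over the
  drawn duration; heterotypic events as a linear shrink to disappearance
  (5% detection floor).  Event counts are Poisson at configurable
  per-vesicle rates (defaults 0.03 and 0.02 min⁻¹, chosen as realistic
  order-of-magnitude rates; tail draws are clamped to the participant
  capacity, and configurations infeasible in expectation raise errors).
  Ground truth travels with the table for scoring.
* **FRAP** curves recover mono-exponentially from a bleach floor of 0.25
  towards a plateau of 0.92 (pre-bleach = 1) with per-condition half-times
  (cell surface 29.0 s, apical 11.5 s, basal 18.9 s, S3 10.9 s, RV
  18.3 s), 1 s sampling, 5 s of pre-bleach and 180 s of recovery, a
  constant background channel, a shared acquisition-photobleaching decay
  (0.002 s⁻¹) on ROI and whole-cell channels, and 2% multiplicative noise.

The generator does *not* emulate segmentation or tracking failures, focal
drift, vesicle motility coupling to fusion, partial occlusions, or drug
treatments beyond preset parameter shifts.  Passing recovery tests
therefore demonstrates that the pipeline's estimators are calibrated and
unbiased on clean track-level data — not that they would survive raw-image
segmentation artefacts, which are outside the pipeline interface.

## Quantification choices

* **Homotypic completion** ("single round vesicle") is proxied by the area
  plateau of the child track; the end time is the intersection of a line
  fit through the decaying ramp with the final plateau level, giving
  sub-frame resolution (frame-level thresholding alone would quantise
  31.9 s to 5 s bins and bias the mean).
* **Shrink onset** uses a two-pass change-point: a conservative terminal
  run of significant frame-to-frame declines establishes a rough
  pre-shrink level; flat frames are then separated from the ramp at 3
  noise SDs below that level, the final level is the median of flat frames
  only, and onset/disappearance are line-fit intersections with the level
  and zero.  The single-pass variant absorbs early-ramp frames into the
  level estimate and dates onsets ~2–3 s late.
* **Fusion frequency** divides event counts by vesicles present at
  recording start (the denominator stated for the real measurements) times
  minutes recorded.
* **Mann–Whitney** comparisons use full enumeration of group assignments
  (tie-safe, two-sided as the symmetric sum of both tails) for combined
  n ≤ 12 and the tie-corrected normal approximation with continuity
  correction otherwise; a zero null variance (all observations tied)
  returns p = 1.
* **FRAP** correction: background subtraction, division by the same-frame
  whole-cell channel normalised to its pre-bleach mean, then normalisation
  to the pre-bleach ROI mean.  The primary half-time estimator is
  model-free (first crossing of half recovery on a lightly smoothed curve
  — 3-frame window, which damps the early-triggering bias of a first
  passage through noise) because no fit model is stated for the original
  measurements; the mono-exponential fit is reported alongside.  Recovery
  amplitudes below 5% of the bleach depth are flagged as undefined rather
  than fitted.  No multiple-testing correction is applied anywhere, since
  each comparison is reported singly.

## Numerical choices and degenerate inputs

Energies are handled in $k_BT$ at 298 K ($1\,k_BT = 4.11\times10^{-21}$ J,
1 Pa·$\mu m^3$ = $10^{-18}$ J ≈ 243 $k_BT$); lengths in $\mu$m; all
conversions live in one constants table.  The collar minimisation uses a
25-point log-spaced scan plus golden-section refinement; lobe radii come
from bracketed root finding at $10^{-12}$ tolerance.  Profiles default to
~400 meridian samples, at which the finite-difference bending quadrature
reproduces $8\pi\kappa$ on a sphere to $<10^{-4}$ relative.  The w = 0
column of the bending landscape is the exact two-sphere closed form; in the
floored family the whole region $wR_{\mathrm{eq}} < R_0$ shares the limit
geometry, including the volume (using the two-sphere volume at $w = 0$
would put a spurious kink into the osmotic term).  Orbit stagnation
(gradient below $10^{-10}$) terminates deterministic orbits as
undetermined, which is what a constant landscape produces.

Problem sizes used by the tests and the acceptance script — landscape
grids of ~1200 nodes, 200-orbit ensembles, 37/25-event kinetic samples,
50-seed FRAP medians, 30-vesicle 400 s track fields — are the study-scale
conditions the generator encodes; moment-convergence checks use $10^4$ to
$10^5$ draws.

## Known limitations

* The shape family is axisymmetric and two-lobed; no spontaneous
  curvature, area-difference elasticity, or composition-dependent moduli.
* The dynamics carry no physical time scale, so orbit durations cannot be
  compared to measured fusion times — only the mode classification and its
  probabilities are meaningful.
* The corridor definition behind "deviating orbits" is an explicit
  operationalisation (the thresholds above); the exact corridor used for
  the original measurements is not specified anywhere, so the thresholds
  are configurable and their ±50% sensitivity is covered by regression
  tests.
* In-vivo quantities (per-condition fusion frequencies, apical/basal FRAP
  differences as biological facts) enter only as generator presets; the
  package reproduces the measurement procedure, not the biology.
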