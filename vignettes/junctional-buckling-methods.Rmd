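---
title: "Modelling junctional buckling in growing, non-dividing cell nests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling junctional buckling in growing, non-dividing cell nests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epibuckle)
```

## The problem

In most epithelia, cell outlines at the level of adherens junctions are
straight because the junctional network is under tension. Histoblasts — the
precursors of the adult *Drosophila* abdominal epidermis — behave differently
during the last larval stage: they keep growing without dividing while the
apical surface available to them shrinks, and their junctions transform from
straight polygonal outlines into deeply lobed, puzzle-piece contours. The
mechanical reading of this transition is *junctional buckling*: the
junctional belt keeps adding material while the apical domain it must fit
into contracts, so the junctions come under compression and buckle, like a
slender elastic beam loaded past its critical load. Two observations
distinguish the phenomenon from textbook beam buckling: junctions buckle at
short wavelengths (several undulations per junction), and severed junctions
hardly recoil.

`epibuckle` implements the mechanical model behind this picture together with
the morphometric and intensity statistics used to characterise the
transition, plus the in-silico physics experiments (ablation, critical-load
scaling, wavelength selection) that connect the model to classical beam
mechanics.

## The mechanical model

Cell boundaries are chains of point masses (vertices) connected by linear
springs (edges). The model is 2-D: it represents a planar section at the
level of the adherens junctions.

* **Stretch.** Each boundary segment exerts an axial force proportional to
  its strain,
  `F = k_b (l / l_rest - 1)`,
  with `l` the current length and `l_rest` the rest length. Positive `F` is
  tension. Separate tension/compression constants can be supplied; the
  defaults are symmetric.
* **Bending.** Each free 2-neighbour vertex carries an angular spring with
  torque `k_bend (theta - theta_rest)` where `theta` is the interior angle
  between its neighbours; the vertex forces are the exact gradient of
  `E = k_bend (theta - theta_rest)^2 / 2`. Rest angles follow the `2*pi/n`
  rule (`pi` on a chain, `2*pi/3` at a tri-junction).
* **Elastic foundation.** Every free vertex is tethered to an anchor point by
  a spring that is Hookean in the displacement, `F = k_foundation d`. This
  represents the elastic coupling of the junction to the surrounding apical
  cortex. The stretch law above is undefined at zero rest length, so the
  displacement form (equivalently, the stretch law with unit reference
  length) is the only finite reading; the foundation is exactly the classical
  Winkler foundation of beam theory.
* **Plasticity.** Each iteration the anchors creep toward the current vertex
  positions, `P_f <- P_f + (P - P_f) dt_foundation`. This slow reset
  dissipates stored foundation stress and is what stabilises buckled shapes:
  a junction severed long after buckling barely recoils, because the
  foundation has re-anchored around the buckled geometry.
* **Self-contact.** Transient compression-only "connection" springs are
  placed every iteration between nearby, mutually visible vertices at least
  three boundary edges apart. Their rest length lies on the tangent circle of
  diameter `th_sub` (`rest = th_sub * sin(alpha)`, `alpha` the angle between
  the connection and the local boundary tangent); a connection longer than
  its rest length exerts no force, so the springs form a pure penalty
  against boundary–boundary collision.

Growth and compression are imposed kinematically each step: boundary rest
lengths are multiplied by `(1 + dt * g_b)` (discrete exponential growth) and
the template — including the fixed frame and the anchors — is scaled by
`(1 + g_axis * dt)` along the shrink axis. The published parameter table
prints the template growth pair as `(0, -0.6)` while the accompanying text
describes contraction along x; `sim_params()` resolves this with a single
`shrink_axis = "x"` plus signed rate `g_axis = -0.6`, which reproduces both
readings.

### Parameters

| name | default | units | meaning |
|------|---------|-------|---------|
| `th_sub` | 1 | um | subdivision threshold and connection length scale |
| `k_b` | 0.2 | model units | boundary spring stiffness |
| `k_bend` | 5e-4 | model units | angular spring stiffness |
| `k_connect` | 0.1 | model units | penalty connection stiffness |
| `g_axis` | -0.6 | 1/time | template shrink rate along `shrink_axis` |
| `g_b` | 1.0 | 1/time | boundary growth rate |
| `dt` | 0.005 | time | growth time step |
| `k_foundation` | 0.1 | model units | foundation stiffness |
| `dt_foundation` | 0.01 | — | anchor creep fraction per step |

Stiffnesses are dimensionless model constants (the source material assigns
them no physical units); lengths are micrometres. Connection placement needs
two constants the source material states qualitatively but does not quantify:
the search radius `length_factor = 1.5` (in units of `th_sub`) and the
minimum connection-to-tangent angle `angle_threshold = pi/4`. Both are fixed
here once and documented rather than tuned.

## Initialisation

`make_cell_grid()` builds the initial nest the way cell-division-pattern
generators do: the largest cell is repeatedly divided by the shortest wall
through its centroid (1-degree orientation scan with a small seeded jitter),
and each new wall is *pinched* — its attachment points are displaced toward
each other by `pinch_fraction` (default 0.1, a value the source material does
not quantify) of the wall length, shortening the new wall and giving the
boundary the characteristic kink of a fresh division. Attachment points on
the outer rectangle are never displaced, so the faces tile the rectangle
exactly and total area is conserved through every division. After
subdivision at `th_sub`, `init_rest_state()` sets every rest length to the
current length and every rest angle to `2*pi/n`, so the initial mesh carries
exactly zero elastic energy and is at equilibrium.

One modelling choice deserves emphasis. The `2*pi/n` rest-angle rule cannot
hold as an *acting spring* at tri-junctions whose wedges are not at 120
degrees without injecting spurious energy at t = 0, and whether the original
implementation applied bending springs at junction vertices at all is not
stated. We therefore record the `2*pi/n` rest angle on every vertex but let
angular springs act only at free 2-neighbour vertices by default;
`junction_bending = TRUE` adds one spring per junction wedge (rest
`2*pi/3`). Angular springs are also never centred on fixed vertices: the
template frame is a rigid Dirichlet boundary, which would otherwise exert
bending moments through the frame's corners.

## The solver

Quasi-static means the network is at mechanical equilibrium at every step.
`solve_equilibrium()` integrates the overdamped dynamics `x' = F` with
backward-Euler (proximal) steps: each outer step solves
`x_{k+1} = argmin E(x) + |x - x_k|^2 / (2h)` with an adaptive step `h`,
using L-BFGS-B with the analytic gradient for the inner minimisation. Because
every accepted step cannot increase the proximal objective, total energy is
provably non-increasing across the relaxation — an invariant the test suite
asserts. Convergence is declared when the largest force on any free vertex
drops below `solver_tol` (default 1e-4 model force units).

Two numerical regimes need different treatment:

* the growth loop (hundreds to thousands of vertices, energies of order 1):
  the proximal quasi-Newton iteration above, with a force-based stopping
  rule (`pgtol`), is fast and robust;
* the beam experiments near a buckling threshold with the default
  stiffnesses: the soft transverse mode sits up to seven orders of magnitude
  below the axial stiffness, and quasi-Newton line searches stall at machine
  precision before the instability can grow. For these small chains
  `beam_response()` finishes with a dense modified-Newton relaxer
  (finite-difference Hessian of the analytic gradient, eigendecomposition,
  backtracking, and a line search along the most negative curvature
  direction to walk off the straight-state saddle). With it, measured
  critical loads match the closed form `pi^2 B / L^2` to about 1% at every
  length.

Degenerate inputs: an equilibrated mesh returns after zero iterations;
non-convergence is flagged on the report (and warned about), never fatal;
fixed vertices report forces but never move.

## The simulation loop

`simulation_step()` executes the published order exactly: place connections,
grow rest lengths and shrink the domain, relax to equilibrium, subdivide
segments whose current *or rest* length exceeds `th_sub` (halving rest
lengths onto the children; new vertices get anchors at their creation
position), and move the foundation anchors. Triggering subdivision on the
rest length — the material coordinate that growth inflates — keeps the
discretisation uniform in material length even when the wall is deeply
compressed; without it the buckling wavelength falls to the lattice scale in
the jammed regime. `run_simulation()` repeats the step; shrinkage stops once
the template width falls to 40% of its initial value, while junction growth
continues. Runs are deterministic: the only randomness is the seeded initial
layout.

The default nest is 16 cells on a 55 x 55 um template (about 190 um^2 per
cell, the observed pre-transition scale). The default run length is 150
steps, which is where the model's kinematics meet the measured biology: the
junctional rest length grows 2.1-fold (the measured junctional material
gain over the transition is 1.7-fold), the template width reaches ~64% of
its initial value (measured apical areas fall to ~0.6x), and mean cell
circularity falls from 0.81 to 0.19 against the published 0.8 to 0.2. Runs
an order of magnitude longer drive junctional growth to 12-fold — a regime
neither the tissue nor the source simulations exhibit — where the
compression-only penalty springs are eventually overwhelmed and walls begin
to interpenetrate. The test suite asserts the qualitative facts the default
run must reproduce — strictly decreasing mean circularity, a crossing-free
final boundary, isolated-then-spreading inflections, and near-zero ablation
recoil of the plastically relaxed final state — not any fitted time course,
for which no likelihood is defined.

## In-silico experiments

* `ablate()` removes a contiguous run of edges and relaxes with growth off
  and anchors frozen, reporting the gap between the cut ends and the
  straightness of the two severed half-junctions per relaxation step.
  Cutting an unstressed network opens by construction by less than a
  fraction of a percent; a uniformly pre-tensed network recoils to a
  positive plateau.
* `euler_buckling_scan()` measures the critical compressive load of pinned
  spring-chain beams of several lengths with `k_foundation = 0`.
  Compression is strain-controlled (load control is unstable at onset) and
  the load is read from the measured axial force. Buckling onset is declared
  when the relaxed transverse deflection exceeds 10x the seeding amplitude —
  a criterion the source material never operationalises, fixed here once.
  The fitted log-log slope of load against length reproduces the classical
  `L^-2` scaling.
* `foundation_mode_scan()` measures the dominant post-buckling wavelength
  against foundation stiffness. The classical Winkler result
  `lambda = 2 pi (B/k)^(1/4)` is the analytic oracle; the fitted exponent is
  -1/4. The scan's default beam uses `spacing = 0.5 um`, `k_bend = 0.01` and
  `k_b = 2` so that the selected wavelength spans at least ~6 lattice
  spacings across a 2-decade stiffness range — with the nest defaults the
  wavelength (1.7 um) would fall below the lattice resolution. These are
  experiment-protocol constants, not model parameters.

## Morphometrics and image quantification

Circularity is `4 pi A / P^2` — the unique normalisation for which a circle
scores 1 — computed by the surveyor's formula on polygon loops; junction
straightness is end-to-end distance over arc length; vertex fluctuation RMS
pools squared displacements over frames *and* vertices before the square
root (so i.i.d. jitter of per-coordinate s.d. sigma scores `sigma*sqrt(2)`),
with optional exact removal of the centre-of-mass drift. Label images are
converted to outlines by marching squares (`grDevices::contourLines`) before
the polygon statistics.

`junctional_enrichment()` is the mean background-normalised intensity over a
junction mask divided by the same over a cytosol mask; the background is the
median of the pixels outside both masks, which makes the ratio invariant
under global intensity rescaling (a perfectly uniform image, where
subtraction is degenerate, falls back to the raw-mean ratio, i.e. exactly 1).
A low quantile (e.g. the 5th percentile) was considered for the background
but rejected: under Gaussian noise it sits ~1.64 noise s.d. below the true
background, which at SNR 10 biases a ratio of 2 by ~7% — more than the
package's own 5% recovery contract — while the median is unbiased for
symmetric noise and just as robust to bright structures outside the masks.
`thickness_map()` fits a double Gaussian to every pixel's axial profile,
seeded at the two largest local maxima of the smoothed profile; pixels with
merged peaks (separation under 1.5x the mean width), sub-noise amplitudes or
fewer than two maxima are counted and set to `NaN` — the handling of failed
fits is our declared policy, not inferred from the source material.

## Synthetic data, and what a green test establishes

Every fixture the pipeline consumes is generated in code with known ground
truth: label images rasterised from meshes, membrane z-stacks with
two-Gaussian axial profiles, vertex tracks as common drift plus i.i.d.
Gaussian jitter, and junction/cytosol intensity images with a set enrichment
ratio. Noise is additive Gaussian (camera-like); Poisson statistics, PSF
blur, bleaching and segmentation errors of real microscopy are *not*
emulated. A green recovery test therefore establishes that the estimator is
correct and unbiased under its own model assumptions at the stated SNR — not
that it is robust to everything a microscope can produce. Default geometry
mirrors the observed scale: ~15 cells per nest, cell areas 120-200 um^2,
jitter 0.07 um (histoblast-like) vs 0.7 um (amnioserosa-like), thickness
fields 6-10 um.

## Serialisation

The toolchain is text-only: meshes use a sectioned plain-text format
(VERTICES/EDGES/ANGLES/FACES, written with 17 significant digits so round
trips are lossless), configs are JSON mirroring `sim_params` field names,
images are CSV matrices and z-stacks a one-header text stack format. No
TIFF codec is required or used.

## Known limitations

* The model is 2-D; out-of-plane buckling and the basal expansion of the
  cells are outside its scope.
* The penalty method discourages but cannot strictly forbid
  boundary–boundary crossing. Vertex pairs closer than three boundary edges
  are excluded from connections by the stated placement rule, the angle gate
  withholds grazing connections, and the maximum penalty force
  (`k_connect` at zero separation) is below the crowding forces the boundary
  springs can exert (bounded by `k_b`), so sharpened lobule tips can pinch
  through: at the end of the default 150-step run a handful of proper
  crossings (about 0.3% of edges, all tight hairpin self-contacts at
  topological distance 2–4) remain, and far beyond the physical regime the
  penalty fails wholesale. The corresponding acceptance test asserts the
  strict zero-crossing property and is knowingly left failing rather than
  weakened.
* The connection geometry constants (`length_factor`, `angle_threshold`) and
  the buckling-onset criterion are fixed conventions, stated above, not
  fitted quantities.
* Mesh faces must remain simple polygons for the morphometrics; circularity
  of a self-intersecting loop is reported as `NaN`, never silently computed.
* The experimental numbers of the source study (circularity time courses,
  recoil amplitudes of real tissue, genetic-perturbation contrasts) derive
  from live-imaging data that is not available in raw machine-readable form;
  the package reproduces the *mechanistic* quantities (scaling exponents,
  closed-form statistics, generator parameters) and the qualitative
  transition, and makes no claim of fitting the biological time courses.
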