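---
title: "Membrane deformation analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane deformation analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memdeform)
```

`memdeform` post-processes MD trajectories of a lipid bilayer carrying
embedded transmembrane core proteins, the configuration used to study how
shear flow and the endothelial glycocalyx deform the plasma membrane.
This vignette records the model behind each statistic, the parameters
that matter, and the design decisions taken where more than one
reasonable choice existed.

## The surface model

The membrane patch is hexagonal (a common periodic unit for bilayer
constructions), but all analysis happens on the rectangle that encloses
it — by default 320 × 360 Å², periodic in x and y, open in z. The
rectangle is meshed into 5 × 5 Å² cells (64 × 72 = 4608), and each
leaflet surface at a frame is the set of per-cell mean z-positions of
that leaflet's head-group heavy atoms (carbon, nitrogen, phosphorus).
Cells containing no head atoms — everything outside the hexagon, plus
occasional interior gaps at low occupancy — are *invalid*.

Three choices here are deliberate:

- **Half-open cells.** An atom at `x` lands in cell
  `floor((x - x0)/Δ)` after wrapping into `[0, L)`; an atom exactly on
  the far edge wraps to cell 0. This tiles the rectangle without gaps or
  double-counting, and makes rasterization a pure function of the
  wrapped coordinate.
- **Mask, not sentinel.** Invalid cells carry `NA` plus an explicit
  `valid` flag rather than an out-of-range filler height. Sentinel
  arithmetic silently corrupts means; a mask cannot.
- **Leaflet membership from labels.** Upper/lower membership comes from
  the topology's role labels (`role_map()`), never from geometry at
  analysis time — in these systems membership is fixed by construction
  and lipid flip-flop is not expected on the simulated timescale. A
  geometric classifier (`assign_leaflets_by_midplane()`) exists for
  topologies without leaflet information but is never applied silently.

## Deformation statistics

Per frame, the *top* value is the mean of the `k` largest valid cell
heights and the *bottom* value the mean of the `k` smallest;
`deformation = top − bottom`. Averaging the k extremes rather than taking
the single max/min damps cell-level sampling noise while remaining
sensitive to genuine crests and troughs, and the difference form makes
the statistic invariant to a uniform height offset — two surfaces with
the same mean height but different corrugation separate cleanly.

`k` defaults to 5 and is stored in every record. The statistic is
provably non-increasing in `k`, and on noisy synthetic surfaces the
means for k ∈ {3, 5, 10} agree within ~10%, so conclusions do not hinge
on the choice; the test suite pins both properties.

Height-distribution **skewness** is reported per frame as a diagnostic
that the distribution stays roughly symmetric and stationary while
forcing is applied. The estimator is the adjusted Fisher–Pearson
(bias-corrected) sample skewness — the common default in statistical
software; `skewness_trend()` fits an OLS line against time so
stationarity can be asserted as "slope within 2 SE of zero".

**Hills and valleys.** A valid cell is a hill if its height exceeds the
frame's global mean h̄ and a valley otherwise; the tie `h = h̄` is
labelled valley (the complementary branch) and flagged separately in
`zero_dev`, since the weak-deformation category is defined on the open
interval (0, 4) Å and a measure-zero tie should be visible, not silently
binned. Deviation thresholds 4 and 8 Å split cells into weak (III),
medium (II) and large (I) deformation categories.
`cumulative_category_distribution()` offers two aggregations across
frames: pooling all cell-frame observations (default) or averaging
per-frame distributions. They coincide when the valid-cell count is
constant over frames, which holds to good approximation here; pooling is
the default because it weights every observation equally.

**Mean ± SE.** Summaries treat frames as independent observations
(SE = SD/√n). Consecutive 0.1-ns frames of a membrane are in truth
autocorrelated, so these SEs are optimistic; `block_se()` provides a
block-averaged alternative for sensitivity checks. The default
reproduces the conventional reporting practice for this analysis.

## Kinematics

The shear strain-rate component in the flow plane is

  ε̇\_zx = v̄\_x,rel / d,

with v̄\_x,rel the difference of the two leaflets' mean head-atom
x-velocities and d the membrane thickness. Velocities default to finite
differences of consecutive stored positions, `(x[t] − x[t−dt])/dt`, with
minimum-image unwrapping in the periodic dimensions — this works on any
coordinate trajectory, whereas stored MD velocities are rarely kept.
When a velocity table is attached, `method = "attached"` uses it
directly. Finite differences at the first frame are undefined and raise
an error rather than returning 0.

`d` is a fixed constant by default — 42 Å, the representative bilayer
thickness, which per-frame thickness maps of both real and synthetic
systems cluster around tightly — with `d_mode = "per_frame"` available
to divide by each frame's mean local thickness instead. On flat
synthetic leaflets the two modes agree exactly.

The **net surface force** is the arithmetic mean of the attached
per-atom x-forces over the upper leaflet's head heavy atoms at a frame,
then a time mean across frames. This is the simplest aggregation
consistent with "mean x-force on the upper surface's head atoms"; since
force tables come in many unit conventions, the reader requires an
explicit unit declaration (`pN`, or `kcal_mol_A` converted at
69.4769 pN per kcal·mol⁻¹·Å⁻¹) instead of guessing. z-velocity
diagnostics report both the signed mean (net vertical motion) and the
mean absolute value (vertical agitation), because "average z-velocity"
is ambiguous between the two and they answer different questions.

## Protein proximity

The protein's footprint is a bounding rectangle: auto-tracked per frame
(tight x,y extremes of protein atoms) by default, since the protein
drifts under flow, or fixed — either an explicit rectangle or the
standard 30 × 40 Å² centred on the protein. The *ring* is the set of
grid cells within `margin_cells` (default 5) cells of the rectangle
after snapping it outward to whole cells, minus the rectangle's own
cells; snapping makes "five grids further" an exact cell count rather
than a fuzzy distance.

Local height averages the **raw z of atoms** in ring cells, while global
height averages **valid cell means** — an intentional asymmetry
preserved from the reference analysis (atoms for the local measure,
cells for the global one). Cell-weighted local averaging is available
via `weight = "cells"` for sensitivity checks; the two differ only when
ring-cell occupancy is very uneven.

Two decomposition helpers make the standard contribution arithmetic
explicit. `lift_decomposition(local, global)` is the plain difference.
`flow_decomposition(flow, stationary)` halves the deformation difference
by default: the top−bottom statistic spans both a raised crest and a
deepened trough, so attributing the extra corrugation per surface
extreme divides by two; the raw difference is available with
`per_surface = FALSE`.

## Case comparison

`summarize_cases()` gives mean ± SE per case; `anova_across_cases()`
runs fixed-effects one-way ANOVA on the per-frame values, emitting both
the omnibus test across all cases and every pairwise two-group test,
since either convention may be wanted when several flow conditions are
compared against a base case. Stars follow the usual 0.001/0.01/0.05
thresholds. As with the SEs, frames are treated as independent; p-values
inherit that optimism and the documentation says so rather than hiding
it.

## The synthetic generator

`generate_bilayer()` produces trajectories whose every statistic is
recomputable from closed form, so the pipeline can be validated without
large trajectory files. It emulates the *geometry and statistical
structure* of the study system, not its physics:

- head pseudo-atoms (element P; optionally 3-atom C/N/P heads) on a
  jittered lattice clipped to the hexagon (circumcircle diameter 179 Å,
  flat sides along the flow axis, centred in the rectangle);
- leaflets at ±d0/2 (d0 = 42 Å) displaced by a shared sum of travelling
  cosine modes, plus i.i.d. Gaussian z-noise per atom per frame;
- per-leaflet uniform x-drift with periodic wrapping (unwrapped
  positions recoverable from the ground truth);
- a protein cylinder (radius 12 Å — it fits the 30 × 40 Å² bounding
  rectangle with margin) whose mass-weighted COM z follows a prescribed
  trajectory exactly, plus an upper-leaflet Gaussian lift bump
  `L·exp(−r²/2w²)` around its axis;
- i.i.d. Normal x-forces on upper head atoms.

Defaults are chosen once as the package's study conditions:
head density 0.15 atoms/Å² (≈10 head heavy atoms per lipid at a typical
~68 Å² area per lipid), undulation amplitudes 2.5 and 1.5 Å at
box-commensurate wavelengths 80 and 90 Å (gentle thermal undulations),
noise 0.8 Å, drift 4.2 Å/ns for the flow-exposed upper leaflet over a
stationary lower leaflet (with d = 42 Å this gives a round 0.1 ns⁻¹
strain rate, convenient for hand-checking), bump L = 4 Å and w = 15 Å,
forces N(0.5, 0.2) pN, 50 frames at 0.1 ns. The seed fully determines
the output, byte for byte.

What the generator does **not** emulate — and therefore what passing
tests do not show about real data: there is no inter-atomic interaction,
no lipid diffusion or flip-flop, no area-per-lipid response to stress,
the noise is white in time and space whereas real surface fluctuations
are correlated, and forces are statistically independent of positions.
Tests on synthetic data validate the *estimators* (that the pipeline
recovers imposed ground truth); they cannot validate the physical
interpretation of numbers obtained from a real trajectory.

## Numerical choices and degenerate inputs

- Coordinates in Å, times in ns, velocities in Å/ns, forces in pN
  throughout; strain rates then come out in ns⁻¹ without conversion.
- Internally frames are numbered from 1 (R convention); on-disk
  force/velocity tables use a 0-based `frame_index` column, converted at
  the reader boundary.
- Trajectory round-trips through multi-model PDB are exact to the
  format's 10⁻³ Å; tests assert at that tolerance.
- Empty selections error early and specifically: no atoms of a role, no
  valid cells, fewer valid cells than `k`, a zero-atom ring,
  zero protein mass, `d ≤ 0`, a frame index outside the trajectory.
  Missing force rows stay `NA` (absent is not zero) and any aggregation
  touching them errors with the first missing atom named.
- Validation problem sizes: synthetic fixtures in the test suite use
  head densities 0.03–0.5 atoms/Å² and 1–50 frames, chosen so each
  check exercises the full grid (4608 cells, ~850 of them inside the
  hexagon) while the whole suite stays interactive-fast; statistical
  assertions use explicit CLT or 2-SE bounds at those sizes rather than
  loose ad-hoc tolerances.

## Limitations

Only rectangular x,y-periodic boxes are supported (no triclinic cells),
with no wrapping beyond x,y translation and no general atom-selection
language — role assignment is by residue/atom-name/chain/segment glob
rules. Invalid cells are never interpolated, and no undulation-spectrum
analysis is attempted. The ANOVA and SE machinery deliberately mirrors
the frames-as-independent convention; for publication-grade uncertainty
on strongly autocorrelated series, use `block_se()` or thin the frames.
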