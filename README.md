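# memdeform

Post-processing toolkit for molecular-dynamics trajectories of lipid
bilayers carrying embedded transmembrane core proteins — the kind of
system used to study how shear flow and the endothelial glycocalyx
(syndecan-4 core proteins with their glycosaminoglycan chains) deform the
plasma membrane. The trajectories themselves come from an MD engine;
`memdeform` takes over afterwards: it turns head-group coordinates into
surface height maps and extracts deformation, strain-rate, force and
protein-proximity statistics that can be compared across simulation
cases.

## What it computes

Each leaflet surface is represented on a fixed rectangular mesh
(default 320 × 360 Å² at 5 × 5 Å², i.e. 64 × 72 = 4608 cells). A cell's
height *hᵢ* is the mean z-position of the leaflet's head-group heavy
atoms (C, N, P) falling in it; empty cells are masked, and the global
mean height is h̄ = Σhᵢ/n over the n valid cells. From there:

- **Deformation** per frame: the mean of the five largest *hᵢ* (the *top*
  value) minus the mean of the five smallest (the *bottom* value), an
  offset-invariant measure of surface corrugation; reported with
  height-distribution skewness as a diagnostic.
- **Hill/valley categories**: cells with *hᵢ* > h̄ are hills, the rest
  valleys, binned by |*hᵢ* − h̄| into Category I (≥ 8 Å), II (4–8 Å) and
  III (< 4 Å), with cumulative category distributions across frames.
- **Kinematics**: the shear strain rate ε̇\_zx = v̄\_x,rel / d, where
  v̄\_x,rel is the relative x-velocity of the two leaflets (finite
  differences of the head atoms with periodic unwrapping, or attached
  velocities) and d the membrane thickness (fixed 42 Å or per-frame from
  the thickness map); plus the mean net x-force on the upper surface's
  head atoms.
- **Protein proximity**: the local membrane height in a five-cell ring
  around the protein's bounding rectangle (30 × 40 Å² or auto-tracked)
  versus the global height, and the mass-weighted protein COM height —
  together with the two decomposition helpers
  `flow_decomposition()` ((flow − stationary)/2 per surface) and
  `lift_decomposition()` (local − global).
- **Case comparison**: mean ± SE per case over frames and one-way ANOVA
  (omnibus and pairwise) with the usual significance stars.

A fully ground-truthed synthetic bilayer generator
(`generate_bilayer()`) emulates the study geometry — a hexagonal membrane
patch of 179 Å circumdiameter inside the periodic rectangle, two leaflets
42 Å apart, travelling undulations, leaflet drift, an embedded protein
cylinder with a Gaussian membrane-lift bump, per-atom forces — so every
stage of the pipeline can be exercised and validated without trajectory
files.

## Worked example

```r
library(memdeform)

gen <- generate_bilayer(synthetic_params(n_frames = 20, seed = 3))
up  <- height_map_series(gen$trajectory, "upper")

glance(deformation_series(up, k = 5))
#>   n_frames mean_deformation se_deformation mean_top mean_bottom mean_skewness
#> 1       20             9.85          0.252     26.4        16.6        0.0766

glance(kinematics_series(gen$trajectory, d = 42))
#>   n_frames mean_strain_rate se_strain_rate mean_v_x_rel mean_f_x_net
#> 1       19           0.1000       5.92e-16         4.20        0.500

glance(proximity_series(gen$trajectory))
#>   n_frames mean_local mean_global mean_lift mean_com_z
#> 1       20       21.4        21.3     0.110         25
```

Reading the numbers: the default synthetic surface carries ~4 Å of
undulation plus 0.8 Å atom noise, so the top-five/bottom-five deformation
fluctuates around 9.9 ± 0.3 Å. The imposed 4.2 Å/ns drift of the upper
leaflet over the stationary lower one, divided by the 42 Å thickness,
gives the strain rate 0.100 ns⁻¹ exactly; the per-atom x-forces drawn
from N(0.5, 0.2) pN average to 0.500 pN. The Gaussian lift bump around
the protein raises the five-cell ring ~0.11 Å above the global mean, and
the protein COM sits at its prescribed 25 Å.

The same analyses run on real data via `read_topology()` (PDB plus a
`role_map()` describing which atoms are upper/lower head heavy atoms and
protein), `read_trajectory()` (DCD, multi-model PDB, or coordinate CSV)
and `attach_forces()`; `run_pipeline()` drives everything from a single
YAML config and writes the per-case and cross-case CSV tables:

```r
run_pipeline("pipeline.yaml")   # see ?read_pipeline_config for the format
```

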