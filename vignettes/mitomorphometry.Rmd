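---
title: "Quantifying 3D mitochondrial morphology in labeled EM volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D mitochondrial morphology in labeled EM volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomorph)
```

## The measurement problem

Serial block-face scanning electron microscopy produces aligned 3D image
stacks in which neuronal compartments (myelinated axons, dendritic shafts,
somata) and their mitochondria can be segmented as labeled voxel volumes.
The voxels are strongly anisotropic — a typical acquisition has 10 nm pixels
in-plane but 50 nm section thickness — so every geometric quantity must be
computed in physical units, not voxel counts of a notional cube.

`mitomorph` computes, per organelle: volume $V$ (µm³), surface area $SA$
(µm²), the **mitochondrial complexity index**

$$\mathrm{MCI} = \frac{SA^3}{16\pi^2 V^2},$$

and the surface **genus** (a genus ≥ 1 organelle is a "donut", a
mitochondrion that has looped and fused onto itself). Per compartment it
computes the **mitochondrial volume density** (fraction of intracellular
volume occupied by mitochondria), the tube **diameter** of axons and
dendrites, and the soma decomposition into nucleus, cytoplasm and
mitochondria. A comparison layer provides the nonparametric test battery
used for such data: Kruskal-Wallis omnibus tests, pairwise Mann-Whitney
contrasts, two-way ANOVA for cell-level volumes, and the two-stage
Benjamini-Krieger-Yekutieli (BKY) FDR step-up.

The MCI is a three-dimensional analog of the form factor: dimensionless,
scale invariant, minimized by the sphere at $9/(4\pi) \approx 0.7162$, and
equal to $R/r$ for a torus with ring radius $R$ and tube radius $r$ — which
is why voxelized tori double as an exact MCI oracle across the whole
observed range of complexities.

## Why phantoms with closed-form ground truth

Segmented tissue stacks come with no ground truth: there is no independent
measurement of a real mitochondrion's surface area. Every estimator in this
package is therefore validated against **synthetic phantoms** whose volume
and area are known in closed form — spheres, capsules
($V = \pi r^2 L + \tfrac43\pi r^3$, $SA = 2\pi r L + 4\pi r^2$) and tori
($V = 2\pi^2 R r^2$, $SA = 4\pi^2 R r$) — plus a branched tube (trunk with
one side branch) whose volume is known only numerically. Voxelization uses
center-point inclusion: a voxel belongs to a shape iff its center lies
inside the implicit solid, the natural analog of binary manual
segmentation, and convergent as spacing shrinks.

The generator also builds whole **compartment scenes**: a tubular axon or
dendrite, or an ellipsoidal soma containing an ellipsoidal nucleus, packed
with a sampled organelle population by rejection sampling (non-overlapping,
fully interior, never touching a stack face — mirroring the exclusion of
structures that are not completely inside the imaged region). Each scene
ships a manifest of per-object ground truth, so pipeline outputs can be
checked row by row.

## The synthetic population model

Organelle volumes are lognormal, parameterized by their arithmetic mean (in
µm³, e.g. the reported group means 0.12/0.27/0.19 for young dentate-gyrus
axons/dendrites/somata) and a coefficient of variation defaulting to 0.8.
The lognormal reproduces the right-skewed distributions seen in tissue,
including the rare organelles above 1 µm³. Morphology kinds are drawn from
a configurable mix (default: 60% spheres, 30% capsules, 5% tori, 5%
branched tubes); capsule elongation $L/r$ is uniform on $[2, 8]$ and torus
aspect $R/r$ uniform on $[2, 10]$, so donut phantoms span the MCI range
observed in tissue (≈ 2.8–9).

Several placement rules are the package's own design choices, made for
geometric feasibility and biological plausibility, and they matter when
interpreting scene statistics:

* **Confinement.** An organelle wider than its compartment can accommodate
  is re-solved as a volume-preserving capsule at the maximal feasible
  radius. This mirrors reality — large axonal mitochondria are elongated
  because the axon constrains them — and it is why tube scenes contain more
  capsules than the nominal mix.
* **Orientation.** Tube organelles lie near-axially; somatic capsules lie
  tangential to the nucleus (wrapping it), and somatic tori lie flat
  against the shell (ring plane tangent).
* **Somatic truncation.** The soma volume law is truncated at 1.2 µm³ in
  the pipeline defaults: a straight capsule of larger volume cannot fit the
  curved cytoplasmic shell at the default soma size. The truncated mass is
  below ~2% of the mean, well inside the sampling noise of any group of 60.
* **Axis placement.** Tube axes and soma centers sit on voxel centers, which
  keeps the distance-transform caliper (below) free of an avoidable
  half-voxel quantization bias.

What the generator deliberately does **not** emulate: raw EM grayscale,
membranes and cristae, myelin texture, segmentation errors, spines, or
fission/fusion dynamics. Passing tests therefore demonstrate that the
*measurement* chain is accurate on clean labels of known geometry — not
that segmentation of real tissue is accurate.

## Surface estimation and its calibration

Surface area is the step where naive approaches fail: summing exposed voxel
faces overestimates the area of a smooth organelle by up to ~50%, and any
bias enters the MCI **cubed**. The package:

1. Gaussian-smooths the binary field (σ in voxels per axis, anisotropy
   respected; default **1.5 voxels per axis**);
2. extracts the 0.5 iso-surface by **marching tetrahedra** on the
   Freudenthal 6-tetrahedron cube decomposition, with physical spacing
   applied and vertices welded on shared grid edges, so closed surfaces are
   watertight and carry a well-defined Euler characteristic;
3. sums triangle areas.

σ = 1.5 was chosen on phantoms: at σ = 1 the residual staircase corrugation
leaves ~+4–5% area error (+12–14% MCI); at σ = 1.5 the sphere's area is
recovered to ~1% and tori to ~1.6%. Smoothing is a flag (`smooth = FALSE`
gives the raw binary iso-surface, which is what the box-phantom area test
uses), and σ is a config knob.

Measured MCI pairs the mesh area with the **mesh-enclosed volume**
(divergence theorem) rather than the voxel-count volume. The two volumes
agree within ~3% on well-resolved phantoms, but on organelles only a few
voxels across, smoothing shrinks the iso-surface; because the MCI is scale
invariant, using the mesh pair cancels that shrinkage and keeps every
measured organelle above the spherical bound. The reported `V_um3` column
remains the voxel-count volume — it is unbiased and definitionally what
"volume of the segmented object" means. For organelles so small that
smoothing erases the 0.5 level set entirely, σ is halved until a surface
reappears (ultimately the raw binary surface).

Accuracy on the 10×10×50 nm acquisition grid, frozen into the test suite:
sphere $r$ = 0.5 µm — volume within 2%, area within 5%, MCI within 10%;
tori with $R/r \in \{2, 5, 8\}$ — MCI within 10% of $R/r$ with genus 1;
doubling all spacings leaves MCI unchanged.

## Diameter: a caliper on the centerline

The diameter protocol measures the tube at 10 equally spaced points along
the structure and averages them. The package implements this as:

1. centerline = geodesic between the two mutually farthest foreground
   voxels (26-neighborhood Dijkstra with physical step lengths), with node
   costs penalized away from the medial axis so the path hugs the tube
   center;
2. local diameter = 2 × the anisotropic Euclidean distance-transform value,
   i.e. the maximal inscribed ball, sampled at the neighborhood maximum
   around each path voxel (the discrete path zigzags within a voxel of the
   true axis);
3. the centerline is trimmed where the inscribed ball becomes limited by
   the end caps rather than the wall, and the 10 sampling points are spread
   over the trimmed length.

A deliberate design deviation: the centerline is a penalized geodesic, not
an iterative-thinning skeleton. On strongly anisotropic grids,
topology-preserving 3D thinning is fragile and needs large case tables; the
geodesic centerline yields the same measured quantity (the caliper
diameter), is rotation invariant, and degrades gracefully. Structures that
are not elongated — the trimmed centerline shorter than twice the local
width, e.g. a sphere — raise an insufficient-length error rather than a
meaningless number. Recovery on voxelized cylinders of radius 0.3–0.6 µm is
within one coarsest voxel (50 nm), rotation invariant in-plane.

## Statistics

* `kruskal_wallis()` / `mann_whitney()` wrap the standard R implementations
  behind the package's interface; the Mann-Whitney switches to the exact
  null distribution when the combined sample is ≤ 12 with no ties
  (enumeration stays under ~1,000 cases) and otherwise uses the
  tie-corrected normal approximation with continuity correction. The exact
  path is verified against a brute-force enumeration oracle in the tests.
* `bky_two_stage()` implements the two-stage linear step-up: BH at
  $q' = q/(1+q)$ estimates the number of true nulls; a second BH pass runs
  at $q' m/(m - r_1)$. Adjusted q-values are obtained by bisection on the
  smallest q at which each hypothesis is rejected. The reject set is always
  a prefix of the p-sorted list and contains the plain-BH set whenever
  stage 1 rejects anything; both properties are tested, and the reject sets
  match an independently coded transcription on 1,000 random p-vectors.
* `two_way_anova()` uses Type II sums of squares (via `car::Anova`), the
  appropriate choice for the unbalanced cell counts that arise when somata
  are reconstructed opportunistically; empty design cells are refused by
  name.
* `median_ci()` gives the distribution-free binomial order-statistic
  interval ("median with 95% CI"); below n = 6 no such interval achieves
  95% and the range is returned with an under-coverage warning.
* FDR families follow the per-panel convention: each (region × age, metric)
  set of pairwise contrasts is corrected as one family.

## The pipeline and its problem sizes

`run_pipeline()` goes from config to tables: generate (or read) stacks →
measure organelles → summarize compartments → compare groups → write
per-organelle, per-compartment, comparison and mitotype CSVs plus a JSON
manifest. One master seed drives everything; child seeds (one per group,
drawn from the master-seeded stream in listed order) are logged in the
manifest, and identical configs and seeds give byte-identical outputs.

Two grid scales are used deliberately. Single-phantom accuracy is
demonstrated on the acquisition grid (10×10×50 nm). Whole-compartment
scenes in the pipeline default to 100 nm isotropic voxels: a 60-organelle
dendrite then fits in a ~350k-voxel stack, organelle shape fidelity at that
scale is not the claim being tested (it is tested on the fine grid), and
group-level quantities — measured mean volumes, volume density, contrast
rejection — are insensitive to the residual per-object discretization,
which is shared across groups. With the reported young-DG group means
(0.12/0.27/0.19 µm³, n = 60 per compartment), the dendrite-vs-axon volume
contrast is rejected at q < 0.05 in essentially every seeded run, and
pooled measured means recover the configuration within a few percent.

## Known limitations

* Area estimation is calibrated for smooth organelles a dozen or more
  voxels across; on 2–4-voxel objects the MCI remains bounded and sane (the
  mesh-pair construction) but carries +5–15% bias, and genus calls on such
  objects are unreliable.
* The diameter caliper reports the inscribed-ball diameter; on strongly
  elliptical cross-sections this is the minor axis, not an average width.
* The generator's branched tubes have no closed-form area; their nominal
  volume (used for volume-law targeting) approximates the trunk–branch
  union, so their voxel volumes deviate from the target by the junction
  overlap (a few percent, on ~5% of objects).
* Exact Mann-Whitney p-values under ties are out of scope; ties always take
  the corrected normal approximation.
* Compartment scenes use one compartment per stack; multi-compartment
  fields of view are not modeled.
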