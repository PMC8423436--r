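# mitomorph

3D morphometry of neuronal mitochondria in labeled electron-microscopy
volumes.

Serial block-face scanning electron microscopy yields aligned image stacks
in which neuronal compartments (myelinated axons, dendrites, somata) and
their mitochondria are segmented as integer-labeled voxel volumes, with
strongly anisotropic voxels (typically 10 × 10 × 50 nm). `mitomorph` turns
such label stacks into the quantities a mitochondrial-morphology study
reports, and ships a synthetic phantom generator with closed-form ground
truth so every estimator is validated against known geometry.

Per organelle it measures volume *V* (µm³), surface area *SA* (µm²), the
**mitochondrial complexity index**

```
MCI = SA³ / (16 π² V²)
```

— a scale-invariant 3D form factor, minimal for a sphere at 9/(4π) ≈ 0.7162
and equal to R/r for a torus — plus the surface genus (genus ≥ 1 flags
"donut" mitochondria). Per compartment it computes mitochondrial volume
density (the fraction of intracellular volume occupied by mitochondria),
the tube diameter of axons/dendrites (10-point distance-transform caliper
along a centerline), and the voxel-exact soma decomposition into nucleus,
cytoplasm and mitochondria. The comparison layer provides Kruskal-Wallis,
exact/approximate Mann-Whitney, two-way ANOVA (Type II), distribution-free
median confidence intervals, ECDFs, threshold fractions, mitotype
summaries, and the two-stage Benjamini-Krieger-Yekutieli FDR step-up.

For the scientific details — surface estimation and its calibration,
the diameter protocol, the synthetic population model and what it does and
does not emulate — see the methods vignette,
`vignettes/mitomorphometry.Rmd`.

## Worked example

Measure a voxelized sphere phantom (radius 0.5 µm) on the acquisition grid:

```r
library(mitomorph)
g   <- voxel_grid(c(10, 10, 50), c(120, 120, 26))     # spacing in nm
vol <- voxelize_shape(shape_sphere(r = 0.5, center = c(0.6, 0.6, 0.65)), g)
measure_stack(vol)[, c("label", "V_um3", "SA_um2", "MCI", "genus")]
#>   label  V_um3 SA_um2    MCI genus
#> 1     1 0.5249  3.172 0.7511     0
```

The closed forms are V = 0.5236 µm³, SA = 3.1416 µm² and MCI = 0.7162: the
voxel-count volume is 0.25% high, the mesh area 1% high, and the measured
MCI sits 4.9% above the spherical minimum — the discretization envelope the
test suite pins down. `genus = 0` says the surface is a topological sphere;
a torus phantom returns `genus = 1`.

A two-group synthetic run through the pipeline (axon vs dendrite at the
young dentate-gyrus group means):

```r
cfg <- list(seed = 42, groups = list(
  list(region = "DG", age = "young", compartment = "axon",
       n_mito = 30, mean_volume_um3 = 0.12),
  list(region = "DG", age = "young", compartment = "dendrite",
       n_mito = 30, mean_volume_um3 = 0.27)))
res <- run_pipeline(cfg)
subset(res$comparisons, metric == "V_um3")
#>   region   age metric           test         contrast statistic        p    q_adj reject
#> 1     DG young  V_um3 kruskal_wallis          omnibus      16.7 4.35e-05       NA     NA
#> 2     DG young  V_um3   mann_whitney axon vs dendrite     173.5 4.49e-05 4.49e-05   TRUE

res$mitotypes[, c("compartment", "n", "mean_V_um3", "sem_V_um3", "mean_MCI")]
#>   compartment  n mean_V_um3 sem_V_um3 mean_MCI
#> 1        axon 30      0.137    0.0213     1.00
#> 2    dendrite 30      0.293    0.0359     1.08
```

The Mann-Whitney contrast (U = 173.5) is rejected after two-stage FDR
correction (`q_adj` < 0.05): the generated dendritic mitochondria are
measurably larger than the axonal ones, as configured. The mitotype table
gives each group's (mean MCI, mean volume) point with SEM — the summary
used to plot populations in complexity-volume space.

`run_pipeline(cfg, output_dir = "out")` additionally writes
`organelles.csv`, `compartments.csv`, `comparisons.csv`, `mitotypes.csv`
and a JSON run manifest with the master and per-group child seeds. The same
run is available from a shell via the installed script:

```sh
Rscript exec/mitomorph run --config inst/extdata/example_run.yaml --out out
```

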