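# myomap3d

3D **structure-tensor myomapping** and **regional collagen quantification**
for tomographic volumes of transmural myocardial tissue, with a synthetic
phantom generator so the whole pipeline is testable against known ground
truth.

## Who this is for

Groups analysing high-resolution tomographic scans (synchrotron X-ray
phase-contrast imaging, micro-CT) of myocardial tissue blocks — e.g.
apical cores from assist-device implantation or transmural samples from
explanted hearts — who want quantitative microarchitecture readouts
instead of purely visual histopathology.

## What it computes

At every voxel the 3D structure tensor — the windowed average of gradient
outer products, `J = w_ρ * (∇I_σ ∇I_σᵀ)` — is eigendecomposed; the
eigenvector of the smallest eigenvalue `λ₃` estimates the local
myocyte-aggregate direction (intensity varies least along the fiber).
Against a local wall frame (circumferential `c`, longitudinal `l`, radial
`r`) the package reports, per voxel:

- **Helical angle** `HA = atan2(v·l, v·c)` in (−90°, 90°] — the classical
  transmural ramp runs from ≈+60° (sub-epicardium) to ≈−60°
  (sub-endocardium);
- **Intrusion angle** `IA = asin(v·r)` — the elevation of the fiber out of
  the wall-tangent plane (0° in-plane, ±90° radial);
- **Fractional anisotropy**
  `FA = sqrt(3/2)·sqrt(Σ(λᵢ−λ̄)²)/sqrt(Σλᵢ²)` ∈ [0,1] — a
  coherence/disorganisation index.

plus transmural profiles (axial angle-doubling statistics per depth bin),
region-mean FA, and collagen volume fractions
(`100·n_collagen/n_voxels`, exact counting) in labelled transmural ROIs
with their unweighted average.

The default integration window is **123.5 µm** (isotropic, interpreted as
the FWHM of a Gaussian), i.e. ≈21.3 voxels at the 5.8 µm scan scale; both
the size and its interpretation (`fwhm`/`sigma`/`box`) are parameters.

## Worked example

```r
library(myomap3d)

# a 128^3 transmural slab phantom: HA ramps +60 -> -60 deg, 5.8 um voxels
spec <- fiber_phantom_spec(dims = c(128, 128, 128), voxel_size_um = 5.8, seed = 42)
ph <- generate_fiber_phantom(spec)

map <- compute_myomap(ph$volume, tissue_mask = "all")   # 123.5 um window
print(map)
#> <myo_map> 128 x 128 x 128 voxels, 592704 valid (28.3%)
#>   window 123.5 um, IA convention 'elevation'
#>   mean FA (valid): 0.7126

prof <- transmural_profile(map$HA, map$frame, n_bins = 10)
head(subset(as.data.frame(prof), !empty), 8)
#>   bin_center mean_angle_deg dispersion_deg     n empty
#> 2       0.15          39.06           1.41 28224 FALSE
#> 3       0.25          30.42           4.12 91728 FALSE
#> 4       0.35          18.41           3.21 84672 FALSE
#> 5       0.45           6.84           4.19 91728 FALSE
#> 6       0.55          -7.01           3.87 91728 FALSE
#> 7       0.65         -19.15           3.39 84672 FALSE
#> 8       0.75         -29.86           3.18 91728 FALSE
#> 9       0.85         -37.58           1.47 28224 FALSE

m <- mean_fa(map$FA, roi_box(c(32, 32, 32), c(96, 96, 96), "selected-area"),
             valid = map$valid)
sprintf("mean FA in selected area: %.4f over %d voxels", m, attr(m, "n_voxels"))
#> "mean FA in selected area: 0.7116 over 262144 voxels"
```

Reading the output: only 28.3% of voxels are "valid" because one full
window width at every lattice boundary is excluded (replicated-edge
smoothing biases orientations there). The per-bin means track the linear
ground-truth ramp (+60·(1−2d)°: e.g. +42° at depth 0.15, −42° at 0.85) to
within a few degrees; the residual flattening is the expected averaging of
the ramp over the 123.5 µm window. High FA (≈0.71) reflects perfectly
coherent, noise-free tube texture — real tissue sits lower.

Collagen, from a binary segmentation mask:

```r
cph <- generate_collagen_phantom(collagen_phantom_spec(
  dims = c(128, 128, 128), target_fraction = 0.10, seed = 42))
rois <- list(roi_box(c(0, 0, 0),  c(42, 128, 128),  "sub-epicardium"),
             roi_box(c(42, 0, 0), c(86, 128, 128),  "mid-myocardium"),
             roi_box(c(86, 0, 0), c(128, 128, 128), "sub-endocardium"))
regional_collagen_report(cph$mask, rois, sample_id = "PH")
#> <collagen_report> sample 'PH'
#>   sub-epicardium    10.10%  (69480 / 688128 voxels)
#>   mid-myocardium    10.71%  (77222 / 720896 voxels)
#>   sub-endocardium    9.16%  (63013 / 688128 voxels)
#>   Average            9.99%
```

## Command line

A single entry point with subcommands (installed at
`system.file("cli/myomap3d", package = "myomap3d")`, or call
`myomap3d_cli()` directly):

```sh
myomap3d phantom  --kind fiber --seed 1 --outdir runs/ph
myomap3d myomap   --input runs/ph/phantom.nrrd --window-um 123.5 \
                  --roi-config rois.json --outdir runs/map
myomap3d collagen --input mask.nrrd --roi-config rois.json --outdir runs/col
myomap3d slices   --input scan.tif --outdir runs/cuts
```

JSON configs (`--config cfg.json`) provide defaults; explicit flags win.
Every run directory gets the resolved `config.json` and a `run.log`;
identical config + seed reproduces byte-identical CSV/JSON outputs.

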