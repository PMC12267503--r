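---
title: "Structure-tensor myomapping of transmural myocardium: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-tensor myomapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(myomap3d)
```

## The problem

High-resolution tomographic scans (e.g. synchrotron X-ray phase-contrast
imaging) of transmural myocardial tissue blocks resolve the texture of
myocyte aggregates in 3D. Two quantitative readouts summarise the
microarchitecture of such a block:

* **Myomapping** — the voxelwise orientation of myocyte aggregates,
  expressed as the helical angle (HA) and intrusion angle (IA) in a local
  ventricular-wall frame, together with fractional anisotropy (FA) as a
  coherence/disorganisation index. Healthy compact myocardium shows the
  classical smooth transmural HA ramp from roughly +60° at the
  sub-epicardium to −60° at the sub-endocardium; disease can blunt or
  disrupt that transition, and disorganised (e.g. trabecular) tissue shows
  lower FA and higher |IA|.
* **Collagen volume fraction** — the percentage of collagen voxels inside
  named transmural regions (sub-epicardium, mid-myocardium,
  sub-endocardium) of a binary segmentation mask, plus their unweighted
  average, as a regional fibrosis summary.

The package implements both readouts plus a synthetic phantom generator
with known ground truth, so that every stage is testable without access to
scanner data.

## The structure-tensor model

For an intensity volume $I$ the structure tensor at a voxel is

$$ J = w_\rho * \left( \nabla I_\sigma \, \nabla I_\sigma^{T} \right), $$

where $I_\sigma$ is the volume pre-smoothed with a small Gaussian of scale
$\sigma$ (the *gradient scale*), the gradient is taken by central
differences, and $w_\rho$ is an *integration window* averaging the gradient
outer products over a physical neighbourhood. $J$ is symmetric positive
semi-definite; its eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3 \ge 0$
describe how strongly intensity varies along the corresponding
eigenvectors. For fibrous texture, intensity varies *least* along the
fiber, so the eigenvector of $\lambda_3$ estimates the local
myocyte-aggregate direction. That estimate is **axial**: $v$ and $-v$ are
the same physical orientation, which shapes everything downstream (sign
normalisation before angle computation, angle-doubling statistics).

Fractional anisotropy is the normalised eigenvalue dispersion

$$ \mathrm{FA} = \sqrt{\tfrac{3}{2}} \;
   \frac{\sqrt{\sum_i (\lambda_i - \bar\lambda)^2}}{\sqrt{\sum_i \lambda_i^2}}
   \in [0, 1], $$

defined as 0 when all eigenvalues vanish. FA is computed from the **raw**
structure-tensor eigenvalues; no eigenvalue transform (inversion,
sharpening) is applied. This choice is documented rather than arbitrated:
published regional mean-FA values in the 0.33–0.55 range are compatible
with several conventions, and without the original scan data the raw-
eigenvalue definition is the defensible default.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `window_size_um` | 123.5 µm | physical extent of the integration window; the scale at which orientation is defined. 123.5 µm at 5.8 µm/voxel ≈ 21.3 voxels. |
| `window_kind` | `"fwhm"` | how the size is interpreted: FWHM of a Gaussian (σ = size/2.355), Gaussian σ directly, or a box width. The FWHM-of-Gaussian reading is the default because a Gaussian window is rotation-invariant and FWHM is the natural "filter size" reading; the enum keeps the other interpretations one flag away. |
| `gradient_scale_um` | 1 voxel/axis | pre-smoothing before differentiation; just enough to regularise central differences without eroding texture. |
| `eps` | 1e−6 | degeneracy threshold: voxels with `trace(J) ≤ eps·max trace` (no texture) or `λ2 − λ3 ≤ eps·λ1` (direction not unique) are flagged and excluded from statistics, never silently dropped. |

All kernel widths are converted from micrometres to voxels **per axis**, so
anisotropic voxel sizes are honoured. Boundary handling is edge
replication; because replicated edges bias orientation, one full window
width at each lattice boundary is excluded from the valid mask of
`compute_myomap()` (configurable).

## Wall frame and angles

Angles need a local frame: circumferential $c$, longitudinal $l$, radial
$r$, orthonormal with $c \times l = r$, plus a normalised transmural depth
(0 = epicardium, 1 = endocardium).

* **slab_axes** (default): for block samples cut roughly parallel to the
  wall, $r$ is a designated lattice axis (epicardial face at low index),
  $l$ a second axis, $c = l \times r$. Depth is computed per transmural
  column between the first and last tissue voxel, so a warped slab surface
  does not bias depth binning.
* **surface_normal**: for curved samples with labelled epicardial and
  endocardial faces, depth is $d_{epi}/(d_{epi}+d_{endo})$ from Euclidean
  distance transforms, and $r$ is the normalised gradient of the
  transmural field $d_{epi} - d_{endo}$, smoothed at σ = 2 voxels. Using
  the *difference* of the two distance fields rather than $d_{epi}$ alone
  gives the identical normal for parallel surfaces but suppresses surface-
  voxelisation noise (on a discretised spherical shell the 95th-percentile
  angular error of the recovered normal drops from ≈5.6° to ≈0.8°).

With the fiber vector sign-normalised so that $v \cdot c \ge 0$ (ties
broken by $v \cdot l \ge 0$, then $v \cdot r \ge 0$):

* $\mathrm{HA} = \operatorname{atan2}(v \cdot l,\, v \cdot c)$ in degrees,
  range (−90°, 90°]. Voxels whose fiber is essentially radial (tangential
  component < 1e−6) have no defined HA and are invalidated.
* $\mathrm{IA} = \arcsin(v \cdot r)$ — the *elevation* of the fiber out of
  the wall-tangent plane: 0° for in-plane fibers, ±90° for radial ones.
  A literal "angle to the radial direction" convention would assign 90° to
  every in-plane fiber, which contradicts the way intrusion is used as a
  disorganisation marker (disorganised tissue shows *higher* IA); the
  elevation convention matches that usage and is the default, with
  `ia_convention = "to_radial"` (= 90° − |elevation|) available.
* The HA sign convention (which helix handedness is positive) is not
  externally fixed; the package's default — positive toward $+l$ from $+c$
  after sign normalisation — is documented and consistent across all
  outputs, which is what matters for transmural *transitions*.

Transmural profiles bin valid voxels by depth into equal-width bins; the
per-bin mean and dispersion use angle doubling
($\bar\theta = \tfrac12 \operatorname{atan2}(\sum \sin 2\theta, \sum \cos 2\theta)$,
dispersion = half the circular SD of $2\theta$), the correct statistics for
axial data near the ±90° wrap. Empty bins are reported as empty, never as
zero.

## Collagen quantification

Collagen percentages are exact integer counting — `100 · n_collagen /
n_voxels` inside each 0-based half-open ROI box, optionally restricted to a
tissue mask — with division only at the end, and the regional average is
the *unweighted* mean of the three regional percentages (this is the
convention that reproduces published regional tables from their printed
regional values). Whether the denominator is all ROI voxels or tissue-only
voxels is an explicit argument; the default (all ROI voxels) reproduces
plain mask-fraction arithmetic. Segmentation itself is an input: pixel
classification is deliberately out of scope. `extract_cube()` crops
physically cube-shaped sub-volumes (odd-rounded voxel counts per axis) for
external 3D rendering of the collagen network.

## The synthetic world

`generate_fiber_phantom()` renders a transmural slab whose texture is a sum
of Gaussian-profile tubes laid along the depth-dependent fiber direction:
HA ramps linearly from `ha_epi_deg` (+60° default) to `ha_endo_deg` (−60°)
at constant IA (0°), at 5.8 µm voxels on a 128³ lattice by default.
Choices a reader should know:

* **Tubes, not gratings.** A plane-wave grating leaves the structure
  tensor's smallest eigenvalue degenerate in a whole plane; tubes make the
  fiber direction unique, which is the property the estimator relies on.
* **Tubes span the lattice** (half-length 2·max(dims)). A tube end-cap
  inside the volume adds gradients *along* the fiber axis and measurably
  biases recovered directions; with spanning tubes the parallel-tube
  phantom recovers the tube axis within 2° at >99% of interior tissue
  voxels.
* **Density** = tubes per 100 voxel² of transmural cross-section
  (N = density·dims₁·dims₂/100); the default 4 gives dense but resolvable
  texture. Tube radius defaults to 2 voxels, amplitude 1 — plausible
  values, stated as such, since no quantitative texture statistics of real
  scans are available to calibrate against.
* **Disorganisation** is modelled as per-tube Gaussian angular jitter
  (`dispersion_deg`), a simple seedable stand-in, not a calibrated
  myocardial dispersion model.
* **Artefacts**: additive white Gaussian noise and additive concentric
  sinusoidal rings (random phase per seed, default period 8 voxels) about a
  chosen axis — enough to test robustness claims, not a physical detector
  model. Phase retrieval, reconstruction physics and realistic
  cardiomyocyte geometry are out of scope.
* All randomness flows from a single integer seed; phantom metadata (spec +
  seed) is echoed as a JSON sidecar, and re-ingesting the sidecar
  regenerates the identical phantom.

`generate_collagen_phantom()` builds a soft structure field (scattered
thin streaks, one compact ellipsoidal patch, or a mix) and thresholds it at
**exactly** the voxel count matching the target fraction, so the achieved
fraction is correct to one voxel and the collagen-recovery test is a
counting identity plus geometry, not a tuning exercise.

What a green phantom test does *not* establish: the phantoms have piecewise
ideal tube texture, no adipose or vessel structure, no contrast drift, no
reconstruction artefacts beyond the two injected kinds. Recovery numbers on
phantoms are upper bounds on what identical settings achieve on real
scans.

## Numerical choices and degenerate inputs

* Eigendecomposition is a batched symmetric 3×3 solve; eigenvalues are
  sorted descending and the triad kept orthonormal to 1e−8. Zero tensors
  yield eigenvalues (0,0,0), a degeneracy flag, and a null fiber direction.
* FA is clipped to [0,1] against rounding; eigenvalues below −1e−8·‖λ‖ are
  a validation error rather than silently clamped.
* The Euclidean distance transform uses the separable lower-envelope
  algorithm with a large finite sentinel instead of Inf (Inf−Inf in the
  parabola intersection would poison the scan).
* Ties in the axial sign normalisation ($v\cdot c = 0$) are broken by
  $v \cdot l$, then $v \cdot r$, making HA/IA jointly well defined,
  including the purely radial fiber (IA = +90° by convention).
* TIFF carries no reliable physical spacing, so voxel size for TIFF inputs
  must come from the caller (defaulting to 1 µm with a warning); NRRD
  `spacings` are authoritative unless overridden. Masks read with
  `as_mask = TRUE` coerce any nonzero value (e.g. 255) to 1 with a warning.

## Known limitations

* No phase retrieval, denoising or ring-artefact *correction* — artefacts
  are only simulated, and the estimator is knowingly sensitive to them.
* No whole-ventricle coordinate systems (Laplace/universal ventricular
  coordinates) or tractography; samples are local transmural blocks.
* The CLI uses JSON configs (no YAML dependency in the supported stack) and
  exports slices as TIFF rather than PNG.
* Orientation output is axial; applications needing signed fiber fields
  (e.g. electrophysiology meshes) must impose their own sign field.
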