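---
title: "Continuous 3D ultrasound volumes from rotational B-mode sweeps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous 3D ultrasound volumes from rotational B-mode sweeps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usinr)
```

## The problem

Volumetric ultrasound with 2D matrix arrays is expensive; a far cheaper
route is to rotate an ordinary 1D array with a programmable motor and
collect 2D B-mode slices at known angles. Because every frame's pose is
known exactly, the slices can be fused into a 3D volume. Classical fusion
interpolates a discrete voxel grid from the scattered slice pixels, which
scales poorly: doubling the resolution of a voxel grid costs 8x the
memory, and a nearest-neighbour query over a dataset of D pixels costs
O(log D) per voxel, growing with the data.

`usinr` instead fits an *implicit neural representation* (INR): a
coordinate network `F(x, y, z) -> (I, S)` trained so that evaluating it at
any 3D position returns the B-mode intensity `I` and a segmentation
probability `S` there. One network is fitted per acquired volume (there is
no generalization across scans). Once fitted, the volume is continuous:
arbitrary planes, resolutions and voxel grids are plain function
evaluations whose cost never depends on the dataset size.

## Acquisition geometry

A `scan_geometry` describes the sweep: a frame raster of `rows x cols`
pixels spanning `axial_extent_mm x lateral_extent_mm`, rotated about the
depth line through the lateral center (`axis_col`). At angle 0 the frame
lies in the x-y plane; a pixel with signed lateral offset `l` maps to
`(x, l cos(theta), l sin(theta))`. Angles follow the half-open sequence
`0, step, ..., sweep - step`: for a 180-degree sweep the closing plane
duplicates the opening one, so a 1.25-degree step yields exactly 144
frames, a 5-degree step 36, a 10-degree step 18.

Two consequences of this cylindrical sampling matter for everything below.
First, the azimuthal distance between consecutive frames grows linearly
with the distance from the rotation axis (`r * step` in radians), so
off-axis structures are sampled more sparsely. Second, pixel centers carry
the coordinates (`spacing = extent / (n - 1)`), which puts corner pixels
exactly on the field-of-view bounds and makes the normalization to
`[-1, 1]^3` exactly invertible.

## The synthetic phantom

No public datasets exist for this acquisition, so the package ships a
simulator that emulates the reference phantom study: `n_spheres` spheres
(default 6) with radii uniform in 4-15 mm and contrasts uniform in -2 to
+8 dB over background (or fully anechoic), placed uniformly inside the
swept cylinder by rejection sampling. Placement enforces a
surface-to-surface clearance of `min_gap_mm` (default 3 mm, roughly the
azimuthal sampling distance of a 5-degree sweep at mid-field radius):
per-object volumetry labels connected components, and targets closer than
the sampling distance are not separable by *any* reconstruction at the
studied angular resolutions, so without a clearance the per-object metric
structure is ill-posed. Setting `min_gap_mm = 0` restores unconstrained
non-overlapping packing.

Frames are rendered geometrically: the noise-free amplitude of a pixel is
`background_level * 10^(contrast_db / 20)` inside a sphere (0 for
anechoic targets) and `background_level` outside, multiplied by unit-mean
Rayleigh speckle and clipped to `[0, 1]`. Masks are rendered noise-free
from geometry, playing the role of exact expert segmentations; this
deliberately isolates INR error from segmentation error.

Speckle deserves care. In a real (or acoustically simulated) acquisition
the speckle pattern is produced by scatterers frozen in the tissue, so the
same world position shows the same speckle in every frame that crosses it
-- which is why a sufficiently large INR can and does learn the speckle
texture itself. The default `speckle_mode = "frozen"` reproduces this: a
fixed 3D complex Gaussian random field (a sum of 192 random plane waves
with wavelengths of one to two `speckle_grain_mm`) is attached to the
phantom and its Rayleigh envelope multiplies every rendered pixel.
`speckle_mode = "frame"` instead draws independent noise per frame
(decorrelated speckle, as caused by out-of-plane motion); that noise is
unlearnable by construction, and the fitted volume converges to the
denoised echogenicity map.

What the simulator does *not* model: wave propagation, beamforming,
attenuation, shadowing, refraction, and the elevation beam width
(partial-volume blur). Passing tests on this phantom therefore shows that
the reconstruction machinery is correct and accurate under ideal imaging
physics, not that the pipeline is robust to the artifacts of real scans.

## Network and objectives

Coordinates normalized to `[-1, 1]^3` are expanded by a harmonic
positional encoding: each coordinate contributes its raw value plus
sine/cosine pairs at frequencies `2^j`, `j = 0..pe_bands-1`. With the
default 15 pairs the input has `3 * (1 + 2*15) = 93` features. The trunk
is a SIREN multilayer perceptron -- linear layers with `sin(omega0 * z)`
activations, first layer initialized uniform `+-1/fan_in`, later layers
`+-sqrt(6/fan_in)/omega0` so scaled pre-activations have unit variance --
of `n_layers = 10` layers of width 256 by default, with additive skip
connections between same-width hidden activations every second layer. The
output head is linear with two units: raw intensity (clamped to `[0, 1]`
only at rendering time) and the segmentation logit (sigmoid). The sine
activation is evaluated by a range-reduced odd polynomial accurate to
about 3e-7, identical in training and inference.

Training minimizes `w_image * (1 - SSIM) + w_seg * L_seg` over whole
frames (the SSIM needs spatial windows, so batches are `frames_per_step`
whole frames rather than random pixels). SSIM uses an 11x11 uniform
window over all complete windows, constants `(0.01)^2` and `(0.03)^2` at
dynamic range 1. The segmentation loss is binary cross-entropy (computed
through the logits, so its gradient `(x - y)/n` survives sigmoid
saturation) plus a soft Dice complement and a pixel-wise false-positive
penalty. All three terms are non-negative and vanish as the prediction
approaches the mask.

The optimizer is Adam under a cosine annealing schedule from `lr_init` to
`lr_min = 1e-6`, with gradient EMA filtering: `ema <- alpha*ema +
(1-alpha)*grad`, `filtered <- grad + lambda*ema` (defaults `alpha = 0.98`,
`lambda = 2`). Note that for a slowly varying gradient the filter
multiplies the effective step by `(1 + lambda)`; the nominal rate of
`1e-3` therefore corresponds to a base `lr_init` of about `3e-4` when the
filter is active, and the reduced-scale experiments below use exactly
that. With the unscaled combination (base 1e-3 *and* lambda = 2) we
observed a characteristic failure on small networks: the intensity head
orbits at high effective step and settles into a flat, structure-free
solution that the SSIM objective then locks in.

## Reconstruction and volumetry

`sample_volume` evaluates the model on an axis-aligned voxel grid (tiled
to bound memory) and thresholds the mask probability at 0.5 (the
conventional operating point; exposed as a parameter). `reslice` renders
arbitrary axis-aligned planes at any resolution, including resolutions
and positions never acquired; oblique planes are available through
`reslice_oblique` with an orthonormal in-plane frame. The baseline the
INR is compared against is exact nearest-neighbour interpolation over all
frame pixels, implemented as a k-d tree whose ties break toward the
lowest datum index so results are fully deterministic.

Sampled masks are labelled by 26-connected components (6/18/26
configurable) in deterministic raster order. Each object's volume is
reported two ways: voxel count times voxel volume, and the volume of the
convex hull of the component's voxel centers (computed by incremental
hull construction and the divergence theorem over the watertight mesh).
The hull is taken over voxel centers, which slightly under-estimates a
smooth convex body (about half a voxel at the surface); both estimates
are first-class outputs because count-based errors suit the simulation
study while hull volumes suit bead- and tumor-like targets. Metrics
follow the standard definitions: per-object Dice and IoU (with
`IoU = Dice/(2 - Dice)` for binary masks, and the both-empty case defined
as 1), relative volume error in percent, and per-frame target contrast as
the difference of mean dB intensity between the target region and the
background.

When a predicted component must be attributed to a ground-truth sphere
(`volume_metrics`), each sphere takes the component with maximal overlap;
spheres with no overlapping component score Dice 0 and a 100% volume
error. Components smaller than `min_voxels` (default 2) are dropped as
speckle islands before hull extraction.

## Reduced-scale experiments

The package's acceptance experiments re-run the two simulation studies at
a scale one CPU handles in minutes; all sizes are stated here as the
package's own reproduction conditions.

*Volumetric accuracy.* A seed-fixed anechoic 6-sphere phantom is swept at
5-degree steps (36 frames) and rendered noise-free at 96^2 (the suite's
single-seed check uses 128^2); the INR is reduced to 6 layers of width 48
with 10 encoding bands and trained 150 epochs with 9 frames per step
(larger whole-frame batches average the windowed objective and keep the
per-epoch loss trend monotone). The volume is sampled at
1 mm, labelled, and scored per sphere; the headline number is
`100 - mean(voxel-count error %)` across spheres, averaged over 3 seeds.
In our runs this sits between 94% and 99% depending on the seed, well
above the 93% the full-scale system reports at this angular resolution.

*Contrast fidelity.* A 6-sphere phantom with contrasts in -2..+8 dB is
swept at 2.5-degree steps (72 frames) at 96^2 under mild frozen speckle
(`speckle_scale = 0.3`). The grain of the frozen field is set to 8 mm so
that the texture's degrees of freedom (about (FOV/grain)^3) are within
reach of the reduced network, preserving the full-scale regime in which
the network fits the speckle rather than averaging it; with per-frame
decorrelated noise the SSIM objective provably rewards contrast
exaggeration (the prediction's local variance is pulled toward the total
target variance, noise included), which is an artifact of under-modelled
noise, not of the method. Training uses width 64 for 150 epochs. For
every frame and every sphere with at least 30 in-plane pixels, the
contrast (region mean minus background mean on the 20*log10 amplitude
image) of the original frame is compared with that of the INR-resampled
frame; the mean absolute deviation over pairs and 3 seeds is the headline
number, 0.08-0.15 dB per seed in our runs.

The angle-resolution comparison (10 vs 1.25 degrees) and the training
sanity checks (mean training-frame SSIM, non-increasing loss trend) run
on a smaller 4-sphere scene at 64^2, where the coarse sweep visibly
under-estimates the smallest sphere -- the same failure mode the
full-scale study reports when the rotation step is inadequate.

## Numerical choices and edge cases

- Sweep angles are validated to divide the sweep evenly (tolerance 1e-9);
  the closing angle is excluded.
- Coordinate normalization is exactly affine and invertible; points
  outside `[-1, 1]^3` are permitted (extrapolation) and simply evaluated.
- SSIM is averaged over complete windows only, so images must be at least
  the window size; the analytic gradient is validated against finite
  differences in the test suite.
- Probabilities are clamped to `[eps, 1 - eps]` (default 1e-6) inside
  logarithms; the Dice ratio carries a 1e-6 additive smoothing so empty
  masks are well-defined.
- Training is bit-reproducible given the master seed on a single-threaded
  BLAS: the seed fans out to phantom placement, speckle, initialization
  and frame shuffling, and all heavy arithmetic is single precision with
  a fixed reduction order.
- Convex hulls of fewer than 4 points, or of collinear/coplanar sets,
  return volume 0 with a degeneracy flag instead of a mesh.
- Checkpoints store doubles with a JSON sidecar; loading validates the
  parameter count against the architecture and refuses mismatches.

## Known limitations

The simulator's ideal-physics assumptions are listed above. Beyond them:
the INR is scene-specific (one model per acquisition, no transfer);
training cost grows linearly with frames x pixels; volumetry by convex
hull is only meaningful for convex or near-convex objects; and angular
under-sampling far from the rotation axis remains the dominant error
source for small off-axis targets, which no amount of training can
recover once the gaps exceed the target size.
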