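---
title: "Localizing ultrasound planes in fetal brain volumes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing ultrasound planes in fetal brain volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planepose)
```

## The problem

Fetal biometry is measured on standard planes (SPs): anatomically defined 2D
sections of the fetal head mandated by clinical guidelines. The
transventricular (TV) plane, for instance, must show the skull outline, the
cavum septum pellucidum (CSP), and the posterior horn of the lateral
ventricle. Finding these planes freehand in a 3D volume is hard and
operator-dependent. `planepose` implements the computational core of a
regression approach: given a single 2D ultrasound image sliced from a 3D
volume, predict the 6D pose (3D translation + 3D rotation) of that slice
relative to a normalized, brain-centred coordinate frame.

The package covers the full loop needed to study this problem without any
clinical data:

1. **Phantoms** — synthetic fetal-brain-like volumes with exact ground truth
   (`make_phantom()`);
2. **Slicing and dataset generation** — arbitrary-pose plane extraction and
   supervised datasets (`extract_slice()`, `generate_dataset()`);
3. **Registration** — closed-form 7-DOF fiducial alignment between volumes
   plus quality metrics (`fit_similarity()`, `fiducial_rms()`,
   `intensity_rms()`);
4. **Pose regression** — a convolutional network with a 9-parameter head and
   the continuous 6D rotation representation (`build_model()`, `train()`);
5. **Evaluation** — translation/geodesic error summaries,
   annotation-variance statistics, and leave-one-out cross-validation
   (`summarize_errors()`, `annotation_variance_report()`, `run_loocv()`).

## Coordinate conventions

All pose mathematics uses a right-handed frame with axes x (lateral),
y (anterior–posterior), z (inferior–superior). A volume's *normalized frame*
maps the bounding box of its brain mask to $[-1, 1]$ per axis: the box centre
is the origin and the half-extents (`mm_per_unit`, one value per axis) convert
normalized units to millimetres. Working in this frame makes pose regression
independent of physical brain size; errors are converted back to mm for
reporting.

A plane pose `pose6d(t, R)` places a square sampling grid at normalized
translation $t$: pixel $(u, v)$ (image x → columns, image y → rows, both in
$[-\mathrm{extent}, \mathrm{extent}]$ at half-pixel centres) maps to
$t + u\,R_{\cdot 1} + v\,R_{\cdot 2}$, with $R_{\cdot 3}$ the plane normal.
Intensities are trilinearly interpolated; out-of-volume samples take a fill
value. Any left-handed (game-engine style) annotations must be converted to
this convention at I/O time.

Angles are radians internally and degrees in every user-facing value.
Quaternions are scalar-first $(s, x, y, z)$; $q$ and $-q$ denote the same
rotation and every comparison accounts for that sign ambiguity.

## The 6D rotation representation

Euler angles and quaternions are discontinuous as regression targets. The
package therefore trains on the continuous 6D encoding: the first two columns
of the rotation matrix, unnormalized. Decoding is Gram–Schmidt
(`rot6d_to_matrix()`): normalize the first 3-vector, orthogonalize and
normalize the second, complete with the cross product. Decoded outputs are
*always* valid rotations — no projection step — and the map is smooth, so an
analytic gradient (`rot6d_backward()`, verified against numerical
differentiation in the tests) backs the training loss.

Two numerical choices matter:

* **Trace clamping.** The geodesic distance
  $\arccos((\mathrm{tr}(R''^{})-1)/2)$, $R'' = R_{pred}^{-1} R_{gt}$, clamps
  the arccos argument to $[-1,1]$; floating-point drift otherwise produces
  NaN at 0° and 180°. Note that near 0° the arccos amplifies rounding error
  to about $10^{-6}$ degrees, which is why exact-recovery tests compare
  matrix entries rather than angles.
* **Head initialization.** The zero 6-vector is the singular point of the
  Gram–Schmidt decode, and it is also the unconditional MSE optimum when
  rotation targets are spread over the whole group (their mean matrix is
  near zero). An untrained network whose output head starts near zero
  therefore sits exactly on the degenerate region and cannot learn. The
  regression head's bias is initialized to the identity encoding
  $(1,0,0,0,1,0)$ and its weights are scaled down, which keeps the decode
  well-conditioned from the first step.

Rotation averaging uses the chordal L2 mean (`chordal_mean()`): the
arithmetic mean of the matrices projected onto SO(3) by SVD, with the
standard determinant correction `diag(1, 1, det)` applied to guarantee a
proper rotation. Antipodal inputs make the mean singular and raise an
explicit error rather than returning an arbitrary branch. The
annotation-variance statistics combine this with per-element geodesic
residuals: RMS distance of translations to their centroid (in mm) and RMS
residual angle about the chordal mean (in degrees).

## The phantom

`make_phantom()` builds a deterministic, seed-reproducible volume on an
isotropic 0.5 mm grid (the default, matching isotropically resampled fetal
volumes):

* a bright ellipsoidal **skull shell** (1.5 mm thick) around darker brain
  tissue — the mask is the full skull ellipsoid;
* an echogenic **falx midline** slab (1 mm) in the x = 0 plane;
* two hypoechoic **lateral-ventricle** ellipsoids (the left 15% larger);
* a small anechoic **CSP** box anterior on the midline;
* an echogenic **cerebellum-like** mass posterior–inferior;
* a smooth multiplicative **parenchymal texture** (a fixed, seed-determined
  sum of 3D sinusoids with 3–8 mm wavelengths);
* two photometric ramps — **lateral attenuation** across the midline (the
  probe sits lateral to the fetal head, so the distal hemisphere is darker)
  and a milder **axial gain ramp** along z;
* multiplicative uniform **speckle** (default amplitude 0.15).

All structure sizes scale with `ga_scale`, a gestational-age-like parameter,
so a set of phantoms with different `ga_scale` emulates a cohort of fetuses
of different ages. `ga_scale = 1` gives a ~36 mm brain; the tests use
0.40–0.55 on 48–64 voxel grids to keep runtimes at desk scale. These are far
smaller than real mid-trimester brains; nothing in the method depends on
absolute size because poses live in the normalized frame.

The texture and the two shading ramps deserve a note, because they are what
makes the pose *identifiable*. A plain ellipsoid-with-midline phantom is
nearly mirror-symmetric, and several 180° rotations map it almost onto
itself; a regressor trained on such a phantom provably cannot resolve those
modes (we observed exactly the bimodal ~180° error distribution the symmetry
predicts). Real ultrasound is not symmetric in this way — attenuation,
shadowing and tissue texture break it — and the phantom mimics that: the
lateral ramp breaks left–right symmetry, the axial ramp breaks the remaining
180° mode about the attenuation axis, and the texture provides
position-dependent appearance everywhere. What the phantom does **not**
emulate: ray-based physics (shadowing, reverberation, angle-dependent
speckle), probe geometry, or inter-subject anatomical variability beyond
uniform scaling. Passing tests on phantoms therefore demonstrate the
*pipeline and the estimator*, not clinical performance.

The designated standard plane is a transventricular-like section: an axial
plane tilted 8° about the lateral axis passing through the ventricle bodies
and the CSP. Each phantom carries six named fiducials (CSP, both ventricles,
cerebellum, anterior/posterior midline) placed analytically, so registration
can be evaluated against exact ground truth.

## Dataset generation

The emulated acquisition protocol collects, per volume, 20699 planes at
random orientations and 1330 in a dense cloud around the annotated SP —
22029 images per volume — and the package defaults reproduce those counts
exactly. Near-SP sampling perturbs the annotation by at most 0.001
normalized units per translation axis and a rotation of at most 1.9° about a
random axis (both uniform); these are the protocol's fine sampling steps.
The coarse steps of the random acquisition (0.1 units, 7.9°) are retained as
reference values in the configuration, but random poses are drawn
continuously: translations uniform per axis, rotations uniform on SO(3) via
random unit quaternions (uniform Euler ranges would bias orientation). The
protocol's unquantified "fixed range … to avoid slices with poor overlap" is
realized as a translation range of 0.35 normalized units per axis plus a
rejection rule requiring at least 50% of the sample grid inside the brain
mask. Whether the near-SP steps bound each axis separately or the total
magnitude is not specified by the protocol; the package implements per-axis
translation bounds and a total rotation-angle bound, which the property
tests pin down.

Datasets are written as 8-bit grayscale PNGs plus a CSV manifest
(`path, tag, tx, ty, tz, r00..r22`, rotation row-major), reproducible
byte-for-byte from the seed; `make_pose_dataset()` produces the identical
draws in memory for training runs that do not need files.

## Registration

Volumes from different subjects are aligned with a 7-degree-of-freedom
similarity transform (rotation + translation + uniform scale) fitted in
closed form to matched fiducials: centroids, cross-covariance SVD with
determinant correction, variance-ratio scale — the standard least-squares
construction. Iterative intensity-based refinement (e.g. mutual-information
optimizers) is deliberately out of scope: the fiducial stage is the
verifiable core, and the quality metrics are decoupled from the fit so any
external registration can be scored. Quality is reported as fiducial RMS
(mm) and masked intensity RMS on the 0–255 scale; the mask restriction
exists so the score reflects brain anatomy rather than the shape of the
ultrasound cone. The closed-loop property — perturb a phantom by a known
transform, fit on fiducials, recover the inverse to machine precision — is
tested exactly, and with noisy fiducials registration must reduce the
fiducial RMS across 20 seeds.

## The pose regressor

The network maps a single-channel image in $[0,1]$ to 9 numbers: 3
translation components and the 6D rotation encoding, decoded to a rotation
matrix in the forward pass. Two backbones are provided:

* `"small"` — four stride-2 3×3 conv + batch-norm + ReLU blocks
  (16/32/64/64 channels) and a single linear head; the desk-scale default.
* `"resnet18"` — an 18-weight-layer residual network (stem + eight
  two-conv residual blocks with batch norm and projection shortcuts) of the
  classic topology at reduced width. No pretrained weights are used or
  downloaded.

The loss is `MSE(translation) + rot_weight * MSE(rotation matrix)`, each
term averaged over its components. `rot_weight` defaults to 0.5: rotation
matrix entries are $O(1)$ while normalized translations live well inside the
unit cube, so an unweighted sum lets the rotation term dominate early
training. The optimizer is Adam (defaults: learning rate $10^{-4}$, betas
0.9/0.999, batch 64, 50 epochs, 20% validation split) with
best-on-validation checkpointing. The engine (im2col convolutions, exact
adjoint backward pass, batch norm with running inference statistics, Adam)
is implemented in R with C++ kernels and is verified against numerical
differentiation in the tests; inference is deterministic and
batch-independent.

Augmentation is photometric only — brightness and contrast factors drawn
uniformly from $[0.5, 1.5]$, applied on the fly to training batches with
labels untouched. A saturation knob exists for API symmetry but is an exact
no-op on single-channel images (an image is its own grayscale) and only acts
in an opt-in 3-channel mode. The protocol this emulates jittered
"brightness, contrast and saturation to a value between 0 and 1", a phrase
whose mapping onto jitter factors is ambiguous; the $[0.5, 1.5]$ range is
the package's reading of moderate jitter and is configurable per call.

### Desk-scale training recipe

The reference experiment trains the small backbone on 2000 slices of a
64³-voxel phantom (64×64-pixel slices) for 20 epochs at learning rate
$10^{-3}$ — about five minutes on one CPU core. Against a Monte-Carlo
baseline for uninformed rotation prediction (median geodesic distance
between independent uniform rotations, ≈126°), this recipe reaches a median
test geodesic error of roughly 30–45° and a median translation error around
0.1–0.2 normalized units across seeds. The parameter-recovery test asserts
the halved-baseline and 0.25-unit bars. These numbers characterize the
desk-scale phantom task only; full-scale training (tens of thousands of
128×128 images, 50 epochs, GPU) is architecturally supported but outside the
test budget.

## Evaluation

`summarize_errors()` reports median, mean, SD, min and max of the per-pair
Euclidean translation error (mm) and geodesic rotation error (degrees); the
median is the standard middle-order statistic. `run_loocv()` drives
leave-one-out cross-validation with one fold per volume — train on the
others, test on the held-out volume — and reports per-fold summaries, their
statistic-wise average, and a pooled summary. The average row averages each
statistic across folds (the cross-validated test-error average); pooling raw
samples instead is also provided because the choice is a reporting
convention, not a property of the estimator. The statistic-wise average is
the default as it matches the usual per-fold presentation of
cross-validation tables.

`annotation_variance_report()` turns a set of SP annotations (one per
volume, in a common frame) into the RMS translation and rotation spreads,
the quantity that bounds achievable ground-truth accuracy from below.

## Problem sizes used in the tests

Module tests run on 48³ phantoms with 32-pixel slices and minutes-scale
training stubs. The acceptance-style end-to-end checks use a 64³ phantom:
the full 22029-image dataset generation runs in about a minute, and the
parameter-recovery training takes around five minutes on one CPU. These
sizes were chosen as the smallest at which every pipeline property is
non-trivially exercised.

## Known limitations

* The phantom's speckle is i.i.d. multiplicative noise, not a coherent
  imaging artifact; interpolation therefore cannot reproduce it pointwise,
  and resampling-fidelity tests use noise-free phantoms with tolerances set
  by the voxel-scale structures (falx, shell).
* Trilinear sampling of 1–3-voxel-wide structures dominates interpolation
  residuals; tolerances in the equivariance and round-trip tests reflect
  that floor and are an order of magnitude below what misaligned planes
  produce.
* Training determinism holds for a fixed seed on a given BLAS; bitwise
  reproducibility across numerics libraries is not guaranteed.
* `"resnet18"` is the topology, not the torchvision artifact: no pretrained
  weights, batch norm without learned affine freezing, reduced width.
* The LOOCV driver regenerates per-volume datasets in memory; at full
  protocol scale (22029 images × N volumes) it should be pointed at on-disk
  datasets instead.
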