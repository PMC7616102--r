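# planepose

Plane-pose regression and registration for fetal-brain ultrasound volumes.

## The problem

Fetal biometry relies on *standard planes*: anatomically defined 2D sections
of the fetal head (the transventricular plane must show the skull, the cavum
septum pellucidum and the posterior ventricle horn). Locating a standard
plane freehand inside a 3D ultrasound volume is slow and operator-dependent.
`planepose` implements the computational machinery to study the regression
alternative — predict, from a single 2D slice `I`, its full 6D pose

```
θ = (t_x, t_y, t_z, R),   t ∈ [-1, 1]³ (normalized brain frame),  R ∈ SO(3)
```

relative to the centre of the brain, using a CNN whose 9-parameter output
`(t₁, t₂, t₃, r₁, …, r₆)` carries the translation plus the continuous 6D
rotation representation, decoded to a rotation matrix by Gram–Schmidt in the
forward pass. Everything runs on synthetic fetal-brain phantoms with exact
ground truth, so the whole pipeline is testable without clinical data.

The package provides:

* **Rotation mathematics** — 6D encoding/decoding with analytic gradients,
  geodesic and quaternion angular distances
  (`arccos((tr R'' − 1)/2)`, `2 arccos|s|`), chordal L2 rotation averaging by
  polar decomposition, and RMS pose-spread statistics for annotation
  variance.
* **Phantoms** — seed-reproducible skull/midline/ventricle/CSP/cerebellum
  anatomy with gestational-age-like scaling, speckle, attenuation, named
  fiducials, a brain mask and an annotated standard plane.
* **Slicing & datasets** — trilinear plane extraction at arbitrary poses;
  protocol-default dataset generation (20699 random + 1330 near-SP = 22029
  images per volume) as PNGs + CSV manifest.
* **Registration** — closed-form 7-DOF similarity fit on matched fiducials
  (Umeyama/Horn construction) with fiducial-RMS and masked intensity-RMS
  quality metrics.
* **Pose regression** — compact conv/batch-norm backbones (a 4-block
  "small" net and an 18-layer residual topology) trained with Adam on
  `MSE(t) + w·MSE(R)`, best-on-validation checkpointing.
* **Evaluation** — error summaries (median / mean ± SD / min / max in mm and
  degrees), leave-one-out cross-validation with per-fold and fold-averaged
  reporting, annotation-variance reports.

## Worked example

```r
library(planepose)

# a 64³-voxel phantom (0.5 mm isotropic) with annotated standard plane
v <- make_phantom(phantom_spec(ga_scale = 0.55, grid_shape = c(64, 64, 64),
                               seed = 1))
v
#> <us_volume> 64x64x64 voxels @ 0.5x0.5x0.5 mm, 6 fiducials, mask 6.4%, SP annotated
v$sp_pose
#> <pose6d> t = (0.0000, 0.0000, 0.0440), euler zyx deg = (0.00, -0.00, 8.00)

# slice the annotated plane: 64×64 image in [0, 1]
img <- extract_slice(v, v$sp_pose, slice_spec(size_px = 64))

# misalign a copy by a known 7-DOF similarity transform, then register back
truth <- compose_transforms(
  similarity_transform(1, diag(3), v$center_mm),
  compose_transforms(similarity_transform(1.08, rot_z(9), c(1, -0.5, 0.3)),
                     similarity_transform(1, diag(3), -v$center_mm)))
moved <- perturb_phantom(v, truth)
reg <- register_volumes(moved, v)
round(reg$report, 4)
#>  fiducial_rms_pre  fiducial_rms_post  intensity_rms_pre intensity_rms_post
#>            1.6623             0.0000            59.8004            21.3096
#>           fit_rms
#>            0.0000
```

The fiducial RMS (mm) drops to machine zero because noiseless landmarks
determine the similarity transform exactly; the masked intensity RMS
(0–255 scale) drops from 59.8 to the interpolation floor. Annotation
variability over six simulated standard-plane picks:

```r
set.seed(2)
ann <- lapply(1:6, function(i)
  pose6d(v$sp_pose$translation + rnorm(3, sd = 0.01),
         v$sp_pose$rotation %*% rot_axis_angle(rnorm(3), rnorm(1, sd = 2))))
str(annotation_variance_report(ann, mm_per_unit = v$mm_per_unit)[1:2])
#> List of 2
#>  $ rms_translation_mm: num 0.182
#>  $ rms_rotation_deg  : num 2.51
```

i.e. the simulated annotators agree to 0.18 mm RMS about their centroid and
2.5° RMS about their chordal-mean orientation — the ground-truth
uncertainty floor for any regressor trained on those annotations.

Training the desk-scale regressor end to end (≈5 min on one CPU):

```r
ds  <- make_pose_dataset(v, sampling_config(n_random = 2200, n_near_sp = 200,
                                            seed = 11),
                         slice_spec(size_px = 64))
cfg <- train_config(epochs = 20, learning_rate = 1e-3, seed = 7)
fit <- train(build_model(cfg, input_px = 64),
             list(images = ds$images[, , 1:2000], poses = ds$poses[1:2000]),
             cfg)
summarize_errors(predict(fit, ds$images[, , 2001:2400]),
                 ds$poses[2001:2400], mm_per_unit = v$mm_per_unit)
```

which prints a median geodesic error far below the ≈126° chance level of
uniform rotation guessing (typically 30–45°) and a median translation error
of roughly 1–2 mm on this phantom.

A thin CLI over the same functions lives at `inst/cli/planepose.R`
(`phantom`, `generate`, `register`, `train`, `evaluate` subcommands).

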