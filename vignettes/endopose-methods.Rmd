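---
title: "Methods: monocular 6D pose estimation for endoscopic model overlay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: monocular 6D pose estimation for endoscopic model overlay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

During robot-assisted laparoscopic surgery the surgeon sees the operative
field only through a monocular endoscope. Augmented-reality support overlays
the patient's preoperative 3D model (prostate, kidney, or an inserted rigid
instrument such as a catheter) on the live video, which requires knowing the
target's 6D pose — image-plane position, apparent scale (a proxy for camera
distance), and three rotations — in every frame, from RGB pixels alone.

`endopose` implements a full registration-and-tracking pipeline for this
setting:

1. **Semantic segmentation** of each frame into background / tool / target
   (a trainable convolutional encoder-decoder);
2. **Localization**: the target mask's largest connected component is
   summarised by its moment-equivalent ellipse, whose centre anchors the
   model and whose area yields the scale factor;
3. **Rotation**, by one of three case-study modes:
   - *rigid-instrument*: a discretized-angle classification network predicts
     the one unknown rotation per frame; the in-plane angle comes from the
     mask ellipse; the spin about the instrument's symmetry axis is
     irrelevant;
   - *organ-auto*: the rotation network registers an initial well-framed
     frame, then masked dense optical flow tracks rotation increments;
   - *organ-manual*: the initial pose is supplied explicitly (a pose literal
     on the command line stands in for interactive registration), then flow
     tracking proceeds as above;
4. **Overlay**: the mesh is rasterized at the estimated pose and
   alpha-blended over the frame, with a per-frame pose log tagging the
   source of every field.

Because no deposited surgical videos or patient models exist for this kind
of study, the package includes a first-class **scene simulator** that stands
in for a rendering pipeline built on a 3D engine: every stage can be
trained, calibrated and evaluated against exact ground truth.

# Geometry and conventions

One convention is fixed and used everywhere (the choice is documented
because conventions of this kind are rarely stated in the surgical-AR
literature and cannot be inferred from results tables):

- Rotations are **intrinsic, X then Y then Z** about the model's own axes;
  the world rotation matrix is `Rx %*% Ry %*% Rz`. Angles are degrees.
- The camera sits at the origin looking along **-Z**; image x points right,
  image y points **down**; pixel centres are at integer coordinates with the
  origin at the top-left pixel.
- `scale` multiplies projected linear size: the object is placed at distance
  `cam_distance / scale`, so silhouette area goes as `scale^2`. The scale
  factor is dimensionless with 1 = the registration distance.
- The instrument cylinder is built with its long axis along model Z, so
  rotation about Z is its symmetry spin and carries no visual information
  (the cylinder texture is rotationally symmetric by construction — axial
  bands only). The catheter scenario fixes the sitting tilt `ry` (default
  50°, configurable as `mask_axis_base`) and draws the network-predicted
  `rx` from its configured range; `rx` then drives both the silhouette's
  in-plane angle and its foreshortening, which is exactly the cue structure
  the rotation network learns.

Under this convention the in-plane major-axis angle of the rendered
instrument is `theta = atan2(sin rx cos ry, sin ry)`. The mask-derived
"Y rotation" of the rigid-instrument mode is implemented as a calibrated
linear map `sign * theta + offset` of that ellipse angle (wrapped to
(-90, 90]), with the calibration fixed once per target on a registered
frame. This is an interpretation: the premise that the in-plane angle is
recoverable from the semantic map is well founded, but no published mapping
exists, so the package states its own.

# The scene simulator

`render_scene()` is a deterministic software rasterizer: pinhole projection,
z-buffer hidden-surface removal, per-face Lambertian shading, and procedural
value-noise texture anchored to model-space coordinates (so texture moves
rigidly with the target — the property optical flow depends on). Image
output is 8-bit RGB with a fixed per-pixel dither applied at quantisation;
without it, sub-pixel inter-frame motion of low-contrast texture is
swallowed by the quantisation deadzone and any motion estimator is biased
toward zero.

The organ texture is **chromatic**: two independent noise fields modulate
the red and green channels (their mean modulates blue). Real tissue varies
in colour (vascularity), not only in brightness, and this matters
downstream: Lambertian shading is a smooth pattern anchored to the *light*,
not the object, so a brightness-only texture would make much of the image
content appear stationary under target rotation. The log-chromaticity
channel `log(1+R) - log(1+G)` cancels shading exactly and is what the flow
heuristic operates on.

Scene nuisance factors emulate the variability of rendered training data:
per-frame lighting direction and intensity jitter, random texture phase,
target pose jitter (position, scale), and 0–2 rod-shaped tools entering from
outside the frame. Tool placements that would occlude more than
`occlusion_cap` (default 40%) of the target silhouette are redrawn — usable
intraoperative frames keep the target well framed. The label mask is the
exact rasterized visibility: occluding tool pixels are class 1, visible
target pixels class 2.

A **domain-shift variant** (`domain_shift = TRUE`) emulates the gap to real
intraoperative frames for fine-tuning experiments: doubled lighting jitter,
specular highlights, and mild stochastic flips of mask boundary pixels
(annotation noise). It is a caricature of the synthetic-to-real gap, not a
claim of realism: passing fine-tuning tests on it demonstrates the
*mechanism* (accuracy on shifted data improves after fine-tuning on 100
shifted frames), not performance on actual surgical video.

What the simulator does *not* model: tissue deformation, smoke, blood,
motion blur, rolling shutter, specular wetness of real organs, and
patient-specific anatomy. Results on it bound what the pipeline can do under
rigid motion with clean labels; they do not transfer numerically to real
scenes.

## Default study conditions

The reference desk-scale conditions, used by the test suite and the
acceptance script, are: organ scenes at 96×96 (ellipsoid with semi-axes
(1, 0.8, 0.7), 6% seeded bump irregularity, up to 2 tools, kidney-style
rotation ranges (−10, 10)° per axis, scale 0.85–1.15); catheter scenes at
64×64 (cylinder r = 0.18, L = 2.6 model units, ry fixed at 50°,
rx ∈ (−40, 10)°, no extra tools — the instrument *is* the tool); 500 scenes
for segmentation and 4000 train + 3000 test frames for rotation, split
70/15/15 where applicable. Problem sizes were chosen so the whole
train-and-evaluate cycle runs in minutes on one CPU core while leaving the
learning problems non-trivial.

# Segmentation

The network is an encoder-decoder with skip connections and a residual-block
encoder: three resolution levels (channel widths `w, 2w, 4w`, default
`w = 8` for the desk profile, 2×2 max pooling), nearest-neighbour upsampling
with skip concatenation in the decoder, and a 1×1 classification head over
three classes. The loss is plain pixel-wise cross-entropy; optimisation is
Adam at the reference hyper-parameters (batch 4, learning rate 1e-4, up to
50 epochs). The checkpoint with the best validation mean IoU is returned,
with early stopping at patience 5; the desk-scale reference run caps at 18
epochs, well past the point where validation mean IoU exceeds 0.9 (it keeps
creeping upward to ≈0.98 by epoch 50, so the cap trades a little accuracy
for a several-fold shorter run).
Everything — initialisation, shuffling, updates — is seeded, and training is
bit-reproducible.

IoU conventions: per-class scores are **pooled** over the evaluation set
(summed intersections over summed unions); per-image scores are retained in
the report. A class absent from both prediction and truth has an undefined
IoU and is excluded from means rather than scored 0, so tool-free frames do
not distort the tool class. The report header states that pooling is used.

# Rotation network

Angles are discretized into 1° half-open bins over the per-axis range
(`[lo + kw, lo + (k+1)w)`, decoded at bin centres), making the catheter head
a 50-way classification. The architecture is a shared residual convolutional
backbone (stride-2 stem plus two stride-2 residual blocks; base width 16 in
the desk profile) and one branch per predicted axis: dense layer → batch
normalisation → dropout (rate 0.5) → dense(N) → softmax. The paper-profile
constants (4096-unit branch dense layer, learning rate 1e-5, batch 32,
~15 epochs) are preserved as the `"paper"` profile of `rot_config()`; the
desk profile trains from scratch, so it uses a larger initial rate (1e-3)
with per-epoch decay 0.93 over 30 epochs.

Two desk-scale regularisers matter at 4000 training images:

- **Soft ordinal targets**: the one-hot class target is replaced by a
  Gaussian over neighbouring bins (σ = 1.5 bins). The loss remains
  cross-entropy; neighbouring-bin confusions stop being penalised as hard as
  gross errors, which is the correct inductive bias for a discretized
  continuous quantity.
- **Translation augmentation**: random integer shifts of up to ±3 px.
  Rotation labels are translation-invariant, so this augments without
  relabelling.

Decoding is argmax per head (ties to the lower class index) at bin centres.
Checkpoint selection uses validation ±5° tolerance accuracy with ±1°
accuracy as tie-break, because the 5° band saturates early on clean
synthetic data. Tolerance accuracy (the fraction of predictions within ±5°
or ±10°) is the evaluation metric throughout; 5° is visually negligible for
overlay purposes and 10° is the clinically accepted bound.

`fine_tune()` clones the model and continues optimisation at one tenth of
the learning rate, leaving the original untouched so before/after
comparisons are honest.

# Optical-flow rotation tracking

The premise: an organ in situ is anatomically constrained, so inter-frame
pixel displacements on the organ contain rotation information — the
magnitude relating to the rotation angle and the direction pattern to the
axis. The literature states this premise and that a (unpublished) heuristic
quantifies it; this package therefore fixes its own concrete, calibratable
heuristic and documents it as an interpretation:

1. `dense_flow()` — coarse-to-fine iterative Lucas–Kanade (3 pyramid
   levels, 3 iterations per level, 9×9 box integration window, Tikhonov
   regulariser 1e-4). The estimator is contractual, not canonical: any
   dense method with median error well under 0.2 px on unit translations
   would serve.
2. `masked_flow()` — restrict to pixels labelled target in both frames.
3. `decompose_motion()` — least-squares affine fit
   `d(p) = A (p − c) + t` about the ellipse centre `c`, split into curl
   `ω = (A21 − A12)/2`, divergence `s = (A11 + A22)/2`, and residual slip
   `r = t − Δc` (texture motion at the centre minus silhouette-centre
   motion — the signature of out-of-plane rotation, because the silhouette
   of a turning convex body stays put while its surface texture slides).
4. `flow_to_rotation()` — `δrz = −deg(ω)` (the sign follows from the
   y-down image convention), `δry = ky · r_x`, `δrx = kx · r_y`, with a
   dead-band (ε = 0.05 px median slip; the curl uses the equivalent rim
   displacement `|ω|·a` with `a` the semi-major axis) so static scenes
   produce exactly zero increments.
5. `calibrate_flow()` — `kx`, `ky` are per-target constants, estimated as
   the mean ratio of true increment to measured slip on one single-axis
   synthetic sequence each. They absorb the geometry factor relating
   surface slip to rotation angle (≈ the mean depth of the visible surface
   relative to its radius), which depends on target shape.

Increments are computed on **consecutive** frames and summed — never on
frames 10 apart; the 10-frame step is only the evaluation sampling grid.

Two implementation details determine whether this works at 0.5°/frame
(rim displacement ≈ 0.2 px):

- The affine fit on raw Lucas–Kanade output seeds a **parametric
  Gauss–Newton refinement** of the same affine model directly on brightness
  constancy over the target pixels. Pixel-wise flow at that amplitude is
  noise-limited; the 6-parameter fit over ~2000 pixels is not.
- Estimation runs on the **log-chromaticity channel** after a mild
  high-pass, with the target region eroded 5 px past the silhouette.
  Shading (light-anchored, hence stationary) and the silhouette edge
  (stationary under rotation in place) otherwise contaminate the fit and
  bias every rotation estimate toward zero by 20–60%. This attenuation is a
  real physical effect — it would affect real endoscopic footage equally —
  and the chromaticity trick is the package's answer to it.

Error handling: frame pairs whose target intersection is empty hold the last
pose and flag the frame; a sequence is trackable again as soon as the target
reappears (no re-localization of orientation is attempted).

# Pipeline and evaluation

`run_video()` applies, per frame: mask prediction → ellipse localization
(position, scale; the scale reference is registered on the first successful
frame) → rotation per mode → overlay → pose-log record with a source tag
(`network`, `mask`, `flow`, `fixed`, `manual-init`, `held`) on every field.
When the elongation gate rejects the mask angle (`axis-ambiguous`,
major/minor < 1.2) the last valid value is held and the frame flagged.
Frame rate is reported, not guaranteed: real-time performance is
hardware-dependent and is treated as a contract target only.

`evaluate_pipeline()` aggregates pooled segmentation IoU, median position
and scale errors, per-axis tolerance accuracies for the axes the mode
actually estimated, and 10-frame-step trajectory accuracies into one report.

# Numerical choices and degenerate inputs

- Ellipse fitting uses image moments (centre = centroid, axes
  `4·sqrt(eigenvalues)` of the second-central-moment matrix,
  `theta = ½·atan2(2μ11, μ20−μ02)`), robust to ragged mask boundaries and
  deterministic. Isotropic regions report `theta = 0` by tie-break;
  degenerate (collinear) regions floor the minor axis at 1 px with a
  warning; regions under 5 px are errors.
- Whether the scale factor should be proportional to linear size or to area
  is genuinely open; the square-root-of-area law is chosen (projected
  linear size ∝ 1/distance ⇒ area ∝ scale²) and used consistently by the
  simulator and the estimator.
- Connected components are 8-connected; ties between equal-sized components
  break toward the earliest first pixel in row-major order.
- The 70/15/15 split takes `floor(0.70 n)` and `floor(0.15 n)` with the
  remainder as test, on a seeded shuffle.
- Trajectories that would leave the configured rotation range are clamped
  with a warning. Accumulated tracking is continuous across sample frames
  (no resetting — whether the original evaluation reset at sample frames is
  unstated; continuous accumulation is the stricter reading).
- All training loops, the simulator, and the flow estimator are exactly
  seeded; fixed seed ⇒ bit-identical images, manifests, checkpoints and
  metrics.

# Known limitations

- The stand-in meshes (bumped ellipsoid, capped cylinder) make no claim of
  anatomical shape realism; a patient-specific preoperative model would be
  dropped in as a `"custom"` mesh.
- The flow heuristic's X/Y calibration constants are shape-dependent; they
  must be recalibrated per target, and they degrade when the visible
  surface departs strongly from the convex assumption.
- The rotation network's accuracy on the simulator does not predict
  real-video accuracy; the domain-shift variant demonstrates the
  fine-tuning mechanism only.
- Deformable tissue, full occlusion recovery and depth in metric units are
  out of scope.
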