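---
title: "Surface-guided motion tracking: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-guided motion tracking: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgrtrack)
```

## The problem

Head-and-neck radiotherapy delivered without a closed thermoplastic mask
needs continuous, markerless verification that the patient has not moved.
Surface-guided radiotherapy (SGRT) does this by registering a live surface
image of the face against a reference surface and converting the result
into a couch-correctable 6-DoF motion estimate. `sgrtrack` implements the
full chain — registration, sequential tracking, sensor calibration — plus a
virtual depth-camera testbed so that the whole pipeline can be benchmarked
in software, with exact ground truth, before any hardware exists.

All coordinates are in a right-handed room frame: +x toward the patient's
left (LR), +y superior (SI), +z anterior (AP); millimeters and degrees
throughout.

## Registration model

The tracker estimates the rigid transform $T$ minimising the robust
weighted point-to-plane cost

$$\mathrm{Cost}(T) \;=\; \sum_{(p,q)\in\mathrm{Corr}} w_{pq}\,
\big((p - Tq)\cdot n_p\big)^2,$$

where $p$ are points of the current (target) surface with normals $n_p$,
$q$ their nearest counterparts on the reference surface, and $w_{pq}$
per-pair robust weights. $T$ maps reference coordinates toward the target,
so $T$ *is* the motion estimate.

Minimisation alternates three steps (`icp()`):

1. **Correspondence.** Each valid target point is matched to its nearest
   reference point through a KD-tree, with pairs beyond a gating distance
   rejected. The search runs in the reference frame (targets moved by
   $T^{-1}$), so the reference tree is built once per pyramid level and
   reused across iterations and frames.
2. **Reweighting (IRLS).** Weights come from the derivative of Barron's
   generalised adaptive loss, normalised to $w(0)=1$:
   $w(r) = \big((r/c)^2/|\alpha-2| + 1\big)^{\alpha/2-1}$ for
   $\alpha \neq 2$, and $w \equiv 1$ in the quadratic limit $\alpha = 2$
   (handled exactly, not as a division by zero). Weights are recomputed
   every iteration from the current residuals; the scale is held fixed
   within a level.
3. **Increment.** The cost is linearised in the 6 pose parameters
   ($a_i = [q_i \times n_i;\, n_i]$) and the weighted $6\times 6$ normal
   equations solved; the rotation vector is exponentiated to an exact
   rotation and step-halving guarantees the increment never increases the
   cost on the current correspondence set. Rank deficiency (e.g. all
   normals parallel, or a single flat plane, which leaves in-plane sliding
   unconstrained) raises an explicit degenerate-geometry error.

Iteration stops when the increment drops below 0.01 mm and 0.01 deg, or
after 30 iterations per level.

### Multiscale schedule

Registration runs rough-to-fine over five levels. The surface density at
the coarsest level is 0.2 points/cm² and at the finest 100 points/cm²; the
intermediate levels are log-spaced (0.2, 0.94, 4.5, 21, 100), a choice made
here since only the endpoints are externally meaningful. Each level voxel-
downsamples both clouds to its density (voxel edge $\sqrt{1/\rho}$, one
centroid with averaged re-normalised normal per occupied voxel — an
order-independent, deterministic reduction) and chains its pose into the
next level.

Per level the correspondence gate is $4\times$ the voxel edge — wide at
coarse levels, which must absorb the initial error, tightening to 4 mm at
the finest — and the Barron scale is $\max(2 \times \text{voxel edge},
1\,\mathrm{mm})$ with $\alpha = 1$ (the pseudo-Huber regime) by default.
Tying $c$ to resolution keeps the weight profile meaningful across the
pyramid; $\alpha$ and $c$ are user-configurable because no canonical values
exist for this application.

Target normals are estimated once on the full-resolution cropped frame
(k-NN PCA, $k = 30$, sign-oriented toward a configurable viewpoint between
the cameras) and carried through downsampling by averaging, never
re-estimated on coarse clouds where the neighborhood PCA would be biased.
The squared point-to-plane residual is sign-invariant, so normal
orientation consistency is cosmetic rather than load-bearing.

## Sequential tracking

`track()` processes a frame sequence against a reference surface (the
first, resting frame of the session by default; an imported PLY — e.g. a
planning-CT surface in room coordinates — is equally valid):

- the incoming frame is cropped with the ROI propagated from the previous
  estimate; the user-drawn ROI is used as given only for the first frame;
- registration is warm-started from the previous frame's pose;
- the next ROI is `shift_roi(roi0, T_k)` — always derived from the
  *initial* ROI and the *current total* estimate, never incrementally
  chained, so numerical error cannot accumulate in the box pose;
- a frame whose crop is empty or whose registration fails is flagged
  (`converged = FALSE`), carries the previous estimate, and tracking
  continues with the last good ROI. This lost-frame policy is a design
  choice of this package; it favours continuity over alarm.

The ROI is an oriented box rather than an axis-aligned one so that
rotation propagation is exact. Adaptive propagation is not cosmetic: the
test suite includes an A/B ablation in which a contoured static neck
support sits below the chin — with a frozen ROI, support points
progressively replace the face as the head slides superior and drag the
estimate toward zero, while the propagated ROI escapes them.

## Calibration

Each sensor is mapped into the room frame by a closed-form least-squares
rigid fit (SVD/Kabsch with the determinant correction) on ordered
fiducial pairs; `calibrate()` verifies the RMS residual against a 0.5 mm
threshold — half the sub-millimeter accuracy the tracker targets — and
names the worst fiducial on failure. `fuse()` concatenates the calibrated
clouds with optional voxel thinning at the finest schedule density (1 mm)
to remove duplicate coverage where the two views overlap. The fiducial
protocol (known labels, ordered correspondence) is this package's own
design; it assumes a labelled calibration jig rather than automatic marker
matching.

## The virtual benchmark

`make_phantom()` builds a head-like triangulated surface: a superellipsoid
cranium (semi-axes 75/105/88 mm, exponent 2.5) with angular-Gaussian
radial features — a 25 mm nose ridge, 6 mm brow, 10 mm chin, 4 mm cheeks —
plus a seeded ~1 mm smooth perturbation standing in for individual surface
texture, about 39,000 triangles with per-vertex anatomical labels.

`default_cameras()` places two 848×480 pinhole depth cameras (65°×40°
field of view) flanking the head at ≈450 mm range, ≈30 cm above the torso
plane, aimed at the head center — the couch-mounted geometry that keeps
the face visible regardless of gantry angle and gives each camera one
cheek, with forehead and nose seen by both. `render_depth()` rasterises
the mesh with a z-buffer (per-pixel visibility honours self-occlusion: the
nose genuinely shadows a cheek from the contralateral camera), perturbs
each pixel's range along its viewing ray with Gaussian noise of
$\sigma(z) = \sigma_0 (z/450\,\mathrm{mm})^2$ — the quadratic depth
dependence characteristic of stereo depth sensing, $\sigma_0 = 1$ mm by
default — quantises the depth (0.25 mm) and applies optional dropout
before back-projecting into a room-frame cloud. All noise is seeded;
per-frame sub-seeds derive deterministically from the session seed as
`(seed·1000003 + frame·7919 + camera) mod (2³¹−1)`, so a session is
bit-reproducible.

Motion comes from two generators. `single_axis_protocol()` replays the
robot benchmarking program — 1 mm steps from −5 to +5 mm and 1 deg steps
from −5 to +5 deg, one axis at a time, 66 commanded poses, with a
configurable dwell. `smooth_trace()` is a statistical stand-in for
recorded head-and-neck motion: per-axis sums of random sinusoids below
0.35 Hz, zero at $t=0$, scaled to a requested peak. It reproduces the
amplitude and bandwidth of resting head motion but *not* its temporal
correlations, drifts, or coupling between axes — benchmark results on it
bound sensor-noise-driven error, not physiological realism.

`facial_deformation()` adds non-rigid perturbations (yawn, smile, frown,
swallow, shake residual) as cosine-windowed displacement fields confined
to labelled regions, with hinge-like ramps so the field is not a pure
windowed translation. The least-squares rigid component is removed by
corrections proportional to the window — Newton iterations on the Kabsch
fit — so the deformation carries no net rigid motion (best-fit transform
identity to ~1e−9) while points outside the region stay exactly fixed,
and the field is rescaled to its requested peak afterwards. These are
geometric caricatures: they localise and scale like the named actions but
are not biomechanical models, which is sufficient for studying *whether*
deformation degrades rigid tracking, not *how much* a specific action
does.

## Evaluation

The tracking error is measured − truth per axis, with ground truth
linearly interpolated to the (sparser) measurement timestamps. Rotation
errors are component-wise Euler differences — valid in the ≤5 deg regime —
with the geodesic angle carried as a diagnostic column. `summarize_errors()`
reports mean, sample SD, linear-interpolation quartiles and 1.5×IQR
whiskers clipped to the data range; `benchmark_report()` adds pass/fail
verdicts against accuracy gates of 1 mm / 1 deg mean absolute error and
separates rigid from deformation segments.

## Numerical choices and degenerate inputs

- Rotations are validated orthonormal (det +1) to 1e−9 and
  re-orthonormalised by SVD projection after every composition.
- Euler extraction refuses gimbal lock (|ry| = 90°) with an explicit
  error; the convention is extrinsic x-y-z about fixed room axes.
- Collinear normal-estimation neighborhoods flag the point invalid rather
  than fabricating a normal; invalid points are excluded from
  registration.
- Empty ROI crops warn and return an empty cloud; the tracker treats the
  frame as lost. Zero correspondences and rank-deficient normal systems
  are errors that name the level and gate.
- Voxel downsampling keys voxels off the cloud minimum, so results are
  translation-consistent within a session but two globally shifted copies
  of a cloud reduce identically.

## Problem sizes used in validation

The package's own test battery runs the full-scale benchmark: the 66-pose
staircase with 5-frame dwell plus three 12 s smooth traces at 2 fps
(~400 frames at 848×480 × two cameras), tracked end-to-end with default
settings. The noise-free exactness check uses a 1-frame dwell — without
noise, dwell frames are byte-identical, so repetition adds cost but no
information. The deformation-sensitivity property is asserted as a trend
over 10 seeded sessions (18 frames each, half rigid, half with an 8 mm
yawn). Unit tests use a reduced phantom (~11,000 triangles) and
quarter-resolution cameras; all tolerances on those are correspondingly
looser and stated per test.

## Known limitations

- Rigid-motion estimates only; deformation is simulated to *stress* the
  tracker, and the robust loss contains the damage, but no non-rigid
  motion model is fitted.
- The virtual sensor models axial noise, quantisation and dropout, not
  lateral noise, motion blur, rolling exposure, emitter interference
  between the two sensors, or temperature drift.
- Translational and rotational accuracy are not fully separable: the
  registration returns one rigid transform, and with the origin away from
  the head's rotation center a small angular error leaks into
  translation.
- The couch-mounted geometry means couch motion itself is invisible to
  the system by construction; the simulator inherits this.
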