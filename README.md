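# sgrtrack

Markerless 6-DoF head-motion tracking from surface imaging for
surface-guided radiotherapy (SGRT), with a fully software-based
depth-camera benchmark.

Head-and-neck radiotherapy without a closed immobilisation mask needs
continuous verification that the patient has not moved. SGRT systems do
this optically: a live surface image of the face is registered to a
reference surface and the result converted into a translation vector and
Euler angles suitable for couch correction. `sgrtrack` is aimed at medical
physicists and algorithm developers who want a complete, inspectable
implementation of that chain — and a virtual treatment room to benchmark
it in, with exact ground truth, before touching hardware.

## What is inside

The registration engine minimises the robust weighted point-to-plane ICP
cost

```
Cost(T) = sum over corresponding pairs (p, q) of  w_pq ((p − T q) · n_p)²
```

where `p`/`n_p` are target-surface points and normals, `q` reference
points, `T` the 6-DoF rigid transform (the motion estimate), and `w_pq`
IRLS weights from Barron's generalised adaptive loss. Optimisation is a
five-level rough-to-fine pyramid: surfaces voxel-downsampled from 0.2 to
100 points/cm², each level warm-starting the next.

Around it:

- **Tracking** (`track`) — sequential frames, adaptive region-of-interest
  propagation (the ROI follows the current motion estimate so it stays
  fixed with respect to the patient), warm starts from the previous pose,
  explicit lost-frame policy.
- **Calibration** (`calibrate`, `fuse`) — closed-form Kabsch fit of
  sensor-to-room transforms from surveyed fiducials, residual
  verification, two-sensor cloud fusion.
- **Simulator** (`make_phantom`, `render_depth`, `simulate_session`) — a
  parametric head phantom, two virtual couch-mounted depth cameras with
  z-buffer self-occlusion and depth-dependent axial noise, the robot-style
  single-axis staircase protocol, smooth seeded head-motion traces, and
  region-confined facial deformations (yawn, smile, frown, swallow).
- **Evaluation** (`align_and_diff`, `summarize_errors`,
  `benchmark_report`) — tracking error versus ground truth, per-axis
  mean ± SD, quartiles and 1.5×IQR whiskers, accuracy-gate verdicts.
- **I/O** — PLY point clouds (ASCII and binary), motion-trace CSV, 16-bit
  depth PNG with camera sidecar, fiducial CSV, calibration JSON, YAML
  tracker configs.

## Worked example

Simulate a short staircase experiment (±5 mm and ±5 deg in 2.5 mm/deg
steps, one axis at a time, 1 mm sensor noise), track it, and summarise the
error:

```r
library(sgrtrack)

phantom <- make_phantom(seed = 1)
phantom
#> <head_phantom> 19796 vertices, 39200 triangles, area 1174 cm^2

trace <- prepend_rest(single_axis_protocol(step_mm = 2.5, range_mm = 5,
                                           step_deg = 2.5, range_deg = 5))
session <- simulate_session(phantom, trace, default_cameras(),
                            noise_model(sigma_mm = 1), seed = 7)
session
#> <sgrt_session> 31 frames, 2 cameras, noise sigma 1 mm

motion <- track(session$frames, session$frames$clouds[[1]], default_roi())
head(motion[, 1:4], 4)
#>    t_s         tx_mm        ty_mm        tz_mm
#> 1 -0.2  6.642555e-05 -0.003119617  0.019626367
#> 2  0.0 -5.020412e+00  0.002345784 -0.016552271
#> 3  0.2 -2.517419e+00 -0.038917720  0.017828252
#> 4  0.4 -2.355631e-02 -0.017581952 -0.008057759

err <- align_and_diff(motion, session$truth)
summarize_errors(err)[, c("axis", "mean", "sd", "mean_abs")]
#>      axis    mean    sd mean_abs
#> 1   ex_mm -0.0134 0.014    0.014
#> 2   ey_mm -0.0139 0.015    0.016
#> 3   ez_mm  0.0088 0.016    0.015
#> 4 erx_deg -0.0182 0.027    0.027
#> 5 ery_deg  0.0116 0.015    0.016
#> 6 erz_deg -0.0039 0.017    0.013
```

The first frame is the rest pose (the reference), so its estimate is
≈ zero; the second row shows the commanded −5 mm LR step recovered as
−5.02 mm. Per-axis tracking errors on this noisy sequence are in the
10–30 µm / millidegree range, far inside the 1 mm / 1 deg clinical
accuracy gates:

```r
rep <- benchmark_report(list(staircase = list(measured = motion,
                                              truth = session$truth)))
all(rep$passed)
#> [1] TRUE
```

## Documentation

The methods vignette (`vignettes/surface-tracking-methods.Rmd`) describes
the registration model and its assumptions, the multiscale and robust-loss
parameter choices, what the simulator does and does not emulate, numerical
edge cases, and known limitations.
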