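#' Single-axis staircase motion protocol
#'
#' Replicates the robot benchmarking protocol: the phantom is moved one
#' axis at a time at fixed intervals of `step_mm` from `-range_mm` to
#' `+range_mm` (and `step_deg` likewise for each rotation axis), dwelling
#' `dwell_frames` frames at each commanded pose. With the defaults this
#' yields (2 * 5 + 1) poses x 6 axes = 66 commanded poses.
#'
#' @param step_mm,range_mm translation step and range (mm).
#' @param step_deg,range_deg rotation step and range (deg).
#' @param dwell_frames frames per commanded pose.
#' @param dt frame interval (s).
#' @return A motion-trace data frame (trace dialect) with an extra
#'   `pose_id` column identifying the commanded pose of each frame.
#' @export
single_axis_protocol <- function(step_mm = 1, range_mm = 5,
                                 step_deg = 1, range_deg = 5,
                                 dwell_frames = 1, dt = 0.2) {
  if (step_mm <= 0 || step_deg <= 0 || range_mm < 0 || range_deg < 0)
    stop("steps must be positive and ranges non-negative")
  vals_t <- seq(-range_mm, range_mm, by = step_mm)
  vals_r <- seq(-range_deg, range_deg, by = step_deg)
  poses <- matrix(0, 0, 6)
  for (ax in 1:3) {
    m <- matrix(0, length(vals_t), 6)
    m[, ax] <- vals_t
    poses <- rbind(poses, m)
  }
  for (ax in 4:6) {
    m <- matrix(0, length(vals_r), 6)
    m[, ax] <- vals_r
    poses <- rbind(poses, m)
  }
  idx <- rep(seq_len(nrow(poses)), each = dwell_frames)
  tr <- as.data.frame(poses[idx, , drop = FALSE])
  names(tr) <- trace_cols()[-1]
  cbind(t_s = (seq_along(idx) - 1) * dt, tr, pose_id = idx)
}

#' Smooth band-limited head-motion trace
#'
#' A statistical stand-in for recorded head-and-neck motion: each of the
#' six axes is a sum of sinusoids with random frequencies below 0.35 Hz
#' and random phases, shifted to start at zero and scaled so the per-axis
#' peak equals the requested amplitude (translations `amplitude_mm`,
#' rotations `amplitude_deg`). Deterministic per seed; more than 99% of
#' the signal power lies below 0.5 Hz.
#'
#' @param duration_s trace length (s).
#' @param amplitude_mm,amplitude_deg per-axis peak amplitudes.
#' @param seed RNG seed.
#' @param fps frame rate (Hz).
#' @return A motion-trace data frame (trace dialect).
#' @export
smooth_trace <- function(duration_s, amplitude_mm = 5, amplitude_deg = 5,
                         seed = 1, fps = 5) {
  if (duration_s <= 0) stop("duration must be positive")
  t <- seq(0, duration_s, by = 1 / fps)
  amp <- c(rep(amplitude_mm, 3), rep(amplitude_deg, 3))
  cols <- with_seed(seed, {
    lapply(amp, function(a) {
      if (a == 0) return(rep(0, length(t)))
      f <- stats::runif(5, 0.03, 0.35)
      A <- stats::runif(5, 0.3, 1)
      p <- stats::runif(5, 0, 2 * pi)
      s <- drop(sin(outer(2 * pi * t, f) +
                    matrix(p, length(t), 5, byrow = TRUE)) %*% A)
      s <- s - s[1]
      pk <- max(abs(s))
      if (pk > 0) s * (a / pk) else s
    })
  })
  out <- data.frame(t, cols[[1]], cols[[2]], cols[[3]],
                    cols[[4]], cols[[5]], cols[[6]])
  names(out) <- trace_cols()
  out
}

#' Prepend rest frames to a motion trace
#'
#' Inserts `n_frames` zero-pose frames before a trace so that the session
#' starts at the pose of the reference surface (the tracker's reference is
#' normally the first, resting frame). Lead-in timestamps continue the
#' trace's frame interval backwards.
#'
#' @param trace motion-trace data frame.
#' @param n_frames number of rest frames to prepend.
#' @return The extended trace.
#' @export
prepend_rest <- function(trace, n_frames = 1) {
  dt <- if (nrow(trace) > 1L) stats::median(diff(trace$t_s)) else 1
  zero <- trace[rep(1L, n_frames), , drop = FALSE]
  zero[, trace_cols()[-1]] <- 0
  if ("pose_id" %in% names(zero)) zero$pose_id <- 0L
  zero$t_s <- trace$t_s[1] - dt * (n_frames:1)
  out <- rbind(zero, trace)
  rownames(out) <- NULL
  out
}

#' Non-rigid facial deformation fields
#'
#' Displaces a labelled phantom-local cloud with a smooth, cosine-windowed
#' displacement field confined to the anatomical region of the requested
#' mode (`yawn`/`jaw`, `smile`/cheeks, `frown`/brow, `swallow`/larynx,
#' `shake_free`/jaw+larynx lateral residual). The least-squares rigid
#' component of the field is removed -- by corrections themselves confined
#' to the windowed region -- so the deformation carries no net rigid
#' motion: the best-fit rigid transform between input and output is
#' identity to machine-level tolerance, and points outside the region do
#' not move.
#'
#' @param cloud a `surface_cloud` in phantom-local coordinates carrying a
#'   `labels` attribute (factor per point), as produced by
#'   [phantom_cloud()].
#' @param mode one of `"yawn"`, `"smile"`, `"shake_free"`, `"frown"`,
#'   `"swallow"` (hyphens accepted).
#' @param amplitude peak displacement (mm).
#' @param phase scalar in \[0, 1\] scaling the field (temporal envelope).
#' @return The deformed `surface_cloud` (labels preserved).
#' @export
facial_deformation <- function(cloud, mode, amplitude, phase = 1) {
  stopifnot(inherits(cloud, "surface_cloud"))
  mode <- gsub("-", "_", mode)
  spec <- switch(mode,
    yawn = list(regions = c("jaw"), dir = c(0, -0.85, -0.53)),
    smile = list(regions = c("cheek_l", "cheek_r"), dir = NULL),  # outward
    frown = list(regions = c("brow"), dir = c(0, -0.3, -0.95)),
    swallow = list(regions = c("larynx"), dir = c(0, 0, 1)),
    shake_free = list(regions = c("jaw", "larynx"), dir = c(1, 0, 0)),
    stop("unknown deformation mode: ", mode))
  labels <- attr(cloud, "labels")
  if (is.null(labels)) stop("cloud must carry a 'labels' attribute")
  x <- cloud$points
  n <- nrow(x)
  in_reg <- labels %in% spec$regions
  if (amplitude == 0 || phase == 0 || !any(in_reg)) return(cloud)

  # cosine window: 1 at the region centroid, 0 at its boundary and outside
  w <- numeric(n)
  ctr <- colMeans(x[in_reg, , drop = FALSE])
  dctr <- sqrt(rowSums(sweep(x[in_reg, , drop = FALSE], 2, ctr)^2))
  dmax <- max(dctr)
  w[in_reg] <- 0.5 * (1 + cos(pi * pmin(dctr / dmax, 1)))

  if (is.null(spec$dir)) {            # smile: outward from region centroid
    dirs <- sweep(x, 2, ctr)
    dirs[, 2] <- dirs[, 2] + 20       # slight superior pull at mouth corners
    len <- sqrt(rowSums(dirs^2))
    dirs <- dirs / pmax(len, 1e-9)
    mag <- w
  } else {
    dirv <- spec$dir / sqrt(sum(spec$dir^2))
    dirs <- matrix(dirv, n, 3, byrow = TRUE)
    # hinge-like ramp along SI: inferior tissue displaces most (a windowed
    # uniform push would be a pure windowed translation and would vanish
    # entirely under rigid-component removal)
    yr <- range(x[in_reg, 2])
    ramp <- pmin(pmax((yr[2] - x[, 2]) / max(yr[2] - yr[1], 1e-9), 0), 1)
    mag <- w * (0.2 + 0.8 * ramp)
  }
  f <- remove_rigid_component(x, dirs * mag, w)
  peak <- max(sqrt(rowSums(f^2)))
  if (peak < 1e-12) stop("deformation field degenerated to zero")
  f <- f * (amplitude * phase / peak)
  out <- surface_cloud(x + f, cloud$normals, cloud$valid)
  attr(out, "labels") <- labels
  out
}

# Subtract the least-squares rigid component of displacement field f,
# using corrections proportional to the window w (so the support of the
# field is preserved). Newton iteration on the Kabsch fit of (x, x + f).
remove_rigid_component <- function(x, f, w) {
  ctr <- colMeans(x)
  d <- sweep(x, 2, ctr)
  # linearized rigid modes at each point: omega x d + t
  modes <- cbind(  # columns: omega_x, omega_y, omega_z, tx, ty, tz
    rbind(cbind(0 * d[, 1], d[, 3], -d[, 2]),
          cbind(-d[, 3], 0 * d[, 1], d[, 1]),
          cbind(d[, 2], -d[, 1], 0 * d[, 1])),
    rbind(cbind(1 + 0 * d[, 1], 0 * d[, 1], 0 * d[, 1]),
          cbind(0 * d[, 1], 1 + 0 * d[, 1], 0 * d[, 1]),
          cbind(0 * d[, 1], 0 * d[, 1], 1 + 0 * d[, 1])))
  # linear least-squares rigid-fit operator L(field) -> 6 coefficients
  N <- crossprod(modes)
  Lfit <- function(field) solve(N, crossprod(modes, as.vector(field)))
  # windowed modes and their fitted coefficients (6x6 response matrix)
  wmodes <- modes * rep(w, 3)
  G <- matrix(0, 6, 6)
  for (k in 1:6) G[, k] <- Lfit(matrix(wmodes[, k], ncol = 3))
  for (it in 1:8) {
    T <- fit_rigid(x, x + f)
    g <- apply_transform(T, x) - x   # exact field of the fitted rigid part
    coef <- Lfit(g)
    if (max(abs(coef)) < 1e-12) break
    cc <- solve(G, coef)
    f <- f - matrix(wmodes %*% cc, ncol = 3)
  }
  f
}

#' Labelled phantom-local vertex cloud
#'
#' @param phantom a `head_phantom`.
#' @return A `surface_cloud` of the mesh vertices with the anatomical
#'   `labels` attribute required by [facial_deformation()].
#' @export
phantom_cloud <- function(phantom) {
  out <- surface_cloud(phantom$vertices)
  attr(out, "labels") <- phantom$labels
  out
}

#' Simulate a full tracking session
#'
#' Replays a motion trace on the head phantom in software: for every trace
#' sample the phantom is posed (and optionally deformed), rendered by each
#' virtual camera with seeded sensor noise, and the per-sensor clouds are
#' fused into a room-frame frame. Per-frame noise seeds are derived
#' deterministically from the session seed
#' (`(seed * 1000003 + frame * 7919 + camera) mod 2^31 - 1`), so a session
#' is bit-reproducible.
#'
#' @param phantom a `head_phantom`.
#' @param trace motion-trace data frame (trace dialect); also the exact
#'   ground truth of the session.
#' @param cameras list of `depth_camera`s.
#' @param noise a `noise_model` (its seed is overridden per frame).
#' @param deformation `NULL`, or a list with `mode`, `amplitude` (mm) and
#'   `frames` (indices of deformed frames); the temporal envelope is
#'   `sin(pi * u)` over each contiguous block, so deformation ramps in and
#'   out smoothly.
#' @param calibs optional per-camera `rigid_transform`s standing in for
#'   sensor calibrations (identity by default; inject an error here to
#'   study mis-calibration).
#' @param static_meshes optional list of meshes (`vertices`/`faces`) that
#'   do not move with the phantom -- couch, headrest or neck support.
#'   They take part in z-buffer occlusion and appear in the rendered
#'   clouds, which is what makes region-of-interest handling matter.
#' @param seed session seed.
#' @param thin_voxel fusion duplicate-thinning voxel (mm); 1 mm matches
#'   the finest registration level.
#' @return A list of class `sgrt_session`: `frames` (a `frame_sequence`),
#'   `truth` (the input trace), `deformed` (logical per frame), plus the
#'   generating `phantom`, `cameras`, `noise`, `seed`.
#' @export
simulate_session <- function(phantom, trace, cameras = default_cameras(),
                             noise = noise_model(), deformation = NULL,
                             calibs = NULL, static_meshes = NULL,
                             seed = 1, thin_voxel = 1) {
  stopifnot(inherits(phantom, "head_phantom"))
  nf <- nrow(trace)
  if (is.null(calibs))
    calibs <- rep(list(rt_identity()), length(cameras))
  deformed <- rep(FALSE, nf)
  phase <- rep(0, nf)
  if (!is.null(deformation)) {
    idx <- deformation$frames
    deformed[idx] <- TRUE
    u <- (seq_along(idx) - 0.5) / length(idx)
    phase[idx] <- sin(pi * u)
  }
  base_cloud <- phantom_cloud(phantom)
  clouds <- vector("list", nf)
  for (i in seq_len(nf)) {
    rendered <- render_session_frame(phantom, base_cloud, trace, cameras,
                                     noise, deformation, deformed, phase,
                                     static_meshes, seed, i)
    clouds[[i]] <- fuse(rendered$views, calibs, thin_voxel = thin_voxel)
  }
  structure(list(frames = frame_sequence(clouds, trace$t_s),
                 truth = trace, deformed = deformed, phantom = phantom,
                 cameras = cameras, noise = noise, seed = seed,
                 deformation = deformation, static_meshes = static_meshes,
                 calibs = calibs, thin_voxel = thin_voxel),
            class = "sgrt_session")
}

# one frame of a session: pose + (optional) deformation + static scene,
# rendered from every camera with the frame's derived noise seed
render_session_frame <- function(phantom, base_cloud, trace, cameras,
                                 noise, deformation, deformed, phase,
                                 static_meshes, seed, i,
                                 return_image = FALSE) {
  pose <- from_sixdof(as.numeric(trace[i, trace_cols()[-1]]))
  verts <- phantom$vertices
  if (deformed[i]) {
    defc <- facial_deformation(base_cloud, deformation$mode,
                               deformation$amplitude, phase[i])
    verts <- defc$points
  }
  # pose the phantom, then merge the static scene so occlusion between
  # patient and room structure is resolved in one z-buffer pass
  scene <- list(vertices = apply_transform(pose, verts),
                faces = phantom$faces)
  for (sm in static_meshes) {
    off <- nrow(scene$vertices)
    scene$vertices <- rbind(scene$vertices, sm$vertices)
    scene$faces <- rbind(scene$faces, sm$faces + off)
  }
  views <- lapply(seq_along(cameras), function(j) {
    nj <- noise
    nj$seed <- (seed * 1000003 + i * 7919 + j) %% (2^31 - 1)
    render_depth(scene, rt_identity(), cameras[[j]], nj,
                 return_image = return_image)
  })
  list(views = if (return_image) lapply(views, `[[`, "cloud") else views,
       depths = if (return_image) lapply(views, `[[`, "depth"))
}

#' Write a simulated session to disk
#'
#' Emits the session in the on-disk layout the tracker's command-line
#' tools consume: `frames/` with one fused room-frame PLY per frame (and
#' per-camera PLYs), `depth/` with 16-bit depth PNGs (0.1 mm per unit)
#' plus JSON intrinsics sidecars, `truth.csv` and `manifest.csv` (frame
#' file to timestamp), and `session.json` echoing the full configuration.
#' Per-camera views are re-rendered from the session's stored seed, which
#' reproduces them bit-exactly.
#'
#' @param session an `sgrt_session` from [simulate_session()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "sgrt_session"))
  dir.create(file.path(dir, "frames"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "depth"), showWarnings = FALSE)
  nf <- n_frames(session$frames)
  phase <- attr(session$deformed, "phase")
  if (is.null(phase)) {
    phase <- rep(0, nf)
    if (!is.null(session$deformation)) {
      idx <- session$deformation$frames
      phase[idx] <- sin(pi * (seq_along(idx) - 0.5) / length(idx))
    }
  }
  base_cloud <- phantom_cloud(session$phantom)
  manifest <- data.frame(frame = seq_len(nf),
                         file = sprintf("frames/frame_%04d.ply", seq_len(nf)),
                         t_s = session$frames$timestamps)
  for (i in seq_len(nf)) {
    write_ply(session$frames$clouds[[i]],
              file.path(dir, manifest$file[i]))
    rendered <- render_session_frame(session$phantom, base_cloud,
                                     session$truth, session$cameras,
                                     session$noise, session$deformation,
                                     session$deformed, phase,
                                     session$static_meshes, session$seed,
                                     i, return_image = TRUE)
    for (j in seq_along(session$cameras)) {
      write_ply(rendered$views[[j]],
                file.path(dir, sprintf("frames/frame_%04d_cam%d.ply", i, j)))
      write_depth_png(rendered$depths[[j]],
                      file.path(dir, sprintf("depth/frame_%04d_cam%d.png",
                                             i, j)),
                      camera = session$cameras[[j]])
    }
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  write_trace_csv(session$truth, file.path(dir, "truth.csv"))
  cam_json <- lapply(session$cameras, function(cm)
    list(fx = cm$fx, fy = cm$fy, cx = cm$cx, cy = cm$cy,
         width = cm$width, height = cm$height,
         pose_row_major = as.numeric(t(rbind(cbind(cm$pose$rotation,
                                                   cm$pose$translation),
                                             c(0, 0, 0, 1))))))
  jsonlite::write_json(
    list(seed = session$seed,
         n_frames = nf,
         noise = unclass(session$noise),
         thin_voxel_mm = session$thin_voxel,
         phantom_params = unclass(session$phantom$params),
         phantom_seed = session$phantom$seed,
         deformation = if (!is.null(session$deformation))
           session$deformation[c("mode", "amplitude", "frames")],
         cameras = cam_json),
    file.path(dir, "session.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a frame directory into a frame sequence
#'
#' Consumes the layout written by [write_session()] (or any directory of
#' per-frame PLY files with a `manifest.csv` mapping `file` to `t_s`).
#'
#' @param dir directory containing `manifest.csv`.
#' @return A `frame_sequence`.
#' @export
read_frame_dir <- function(dir) {
  mf <- utils::read.csv(file.path(dir, "manifest.csv"))
  if (!all(c("file", "t_s") %in% names(mf)))
    stop("manifest.csv must contain 'file' and 't_s' columns")
  frame_sequence(lapply(file.path(dir, mf$file), read_ply), mf$t_s)
}

#' @export
print.sgrt_session <- function(x, ...) {
  cat("<sgrt_session> ", n_frames(x$frames), " frames, ",
      length(x$cameras), " cameras, noise sigma ",
      x$noise$sigma_mm, " mm", if (any(x$deformed))
        paste0(", ", sum(x$deformed), " deformed frames"), "\n", sep = "")
  invisible(x)
}
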