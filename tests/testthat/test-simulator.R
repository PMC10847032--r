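test_that("the phantom is deterministic, bounded and plausibly sized", {
  p1 <- make_phantom(seed = 7)
  p2 <- make_phantom(seed = 7)
  expect_identical(p1$vertices, p2$vertices)
  expect_identical(p1$faces, p2$faces)
  p3 <- make_phantom(seed = 8)
  expect_gt(max(abs(p3$vertices - p1$vertices)), 0)

  expect_true(all(sqrt(rowSums(p1$vertices^2)) < 250))
  area_cm2 <- phantom_area(p1) / 100
  expect_gt(area_cm2, 400)
  expect_lt(area_cm2, 1200)
  expect_setequal(levels(p1$labels),
                  c("nose", "brow", "cheek_l", "cheek_r", "jaw", "larynx",
                    "cranium"))
  expect_error(phantom_params(nose_mm = 60), "amplitude")
})

test_that("with all features off, the anterior extent is the analytic semi-axis", {
  prm <- phantom_params(nose_mm = 0, brow_mm = 0, chin_mm = 0, cheek_mm = 0,
                        texture_mm = 0)
  ph <- make_phantom(prm)
  expect_equal(max(ph$vertices[, 3]), prm$c, tolerance = 1e-9)
  # the default nose raises the anterior extent above the bare cranium
  expect_gt(max(make_phantom()$vertices[, 3]), prm$c + 10)
})

test_that("a fronto-parallel plane renders at its exact depth", {
  cam <- depth_camera(fx = 200, fy = 200, cx = 79.5, cy = 59.5,
                      width = 160, height = 120)
  s <- 400
  plane <- list(vertices = rbind(c(-s, -s, 500), c(s, -s, 500),
                                 c(s, s, 500), c(-s, s, 500)),
                faces = rbind(c(1, 2, 3), c(1, 3, 4)))
  out <- render_depth(plane, rt_identity(), cam, zero_noise(),
                      return_image = TRUE)
  expect_true(all(is.finite(out$depth)))
  expect_lt(max(abs(out$depth - 500)), 1e-9)
  # back-projection: z of every room point is exactly 500
  expect_lt(max(abs(out$cloud$points[, 3] - 500)), 1e-9)
})

test_that("sphere rendering matches the analytic projected-disk pixel count", {
  cam <- depth_camera(fx = 600, fy = 600, cx = 319.5, cy = 239.5,
                      width = 640, height = 480)
  r <- 60; d <- 500
  sp <- sphere_mesh(c(0, 0, d), r, n_theta = 161, n_phi = 240)
  out <- render_depth(sp, rt_identity(), cam, zero_noise(),
                      return_image = TRUE)
  got <- sum(is.finite(out$depth))
  # a sphere of angular radius asin(r/d) projects to ~pi * fx * fy * tan^2
  expected <- pi * cam$fx * cam$fy * tan(asin(r / d))^2
  expect_lt(abs(got - expected) / expected, 0.01)
  # the far hemisphere is occluded: every surface point is on the near side
  expect_true(all(out$cloud$points[, 3] <= d + 1e-6))
  radii <- sqrt(rowSums(sweep(out$cloud$points, 2, c(0, 0, d))^2))
  expect_lt(max(abs(radii - r)), 0.02)   # chordal error of the facet mesh
})

test_that("no rendered point lies beyond another surface intersection (ray audit)", {
  ph <- small_phantom()
  cam <- small_cameras()$left
  out <- render_depth(ph, rt_identity(), cam, zero_noise(),
                      return_image = TRUE)
  hit <- which(is.finite(out$depth))
  set.seed(61)
  sample_px <- sample(hit, 500)
  rc <- arrayInd(sample_px, dim(out$depth))
  V <- apply_transform(rt_inverse(cam$pose), ph$vertices)
  F <- ph$faces
  v0 <- V[F[, 1], ]; e1 <- V[F[, 2], ] - v0; e2 <- V[F[, 3], ] - v0
  for (s in seq_along(sample_px)) {
    dir <- c((rc[s, 2] - 1 - cam$cx) / cam$fx,
             (rc[s, 1] - 1 - cam$cy) / cam$fy, 1)
    # Moller-Trumbore over all triangles, vectorised
    pv <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
                dir[3] * e2[, 1] - dir[1] * e2[, 3],
                dir[1] * e2[, 2] - dir[2] * e2[, 1])
    det <- rowSums(e1 * pv)
    ok <- abs(det) > 1e-12
    u <- rowSums(-v0 * pv) / det
    qv <- cbind(-v0[, 2] * e1[, 3] + v0[, 3] * e1[, 2],   # (-v0) x e1
                -v0[, 3] * e1[, 1] + v0[, 1] * e1[, 3],
                -v0[, 1] * e1[, 2] + v0[, 2] * e1[, 1])
    v <- (dir[1] * qv[, 1] + dir[2] * qv[, 2] + dir[3] * qv[, 3]) / det
    tt <- rowSums(e2 * qv) / det
    valid <- ok & u >= -1e-9 & v >= -1e-9 & (u + v) <= 1 + 1e-9 & tt > 0
    t_min <- min(tt[valid])
    expect_lt(abs(out$depth[sample_px[s]] - t_min), 0.05)
  }
})

test_that("the noise model is unbiased, correctly scaled and reproducible", {
  cam <- depth_camera(fx = 300, fy = 300, cx = 199.5, cy = 199.5,
                      width = 400, height = 400)
  s <- 900
  plane <- list(vertices = rbind(c(-s, -s, 600), c(s, -s, 600),
                                 c(s, s, 600), c(-s, s, 600)),
                faces = rbind(c(1, 2, 3), c(1, 3, 4)))
  nm <- noise_model(sigma_mm = 1, ref_depth_mm = 450, quant_mm = 0,
                    dropout = 0, seed = 99)
  ideal <- render_depth(plane, rt_identity(), cam, zero_noise(),
                        return_image = TRUE)
  noisy <- render_depth(plane, rt_identity(), cam, nm, return_image = TRUE)
  # per-pixel depth error measured along the ray
  rc <- arrayInd(seq_along(ideal$depth), dim(ideal$depth))
  ray_norm <- sqrt(((rc[, 2] - 1 - cam$cx) / cam$fx)^2 +
                   ((rc[, 1] - 1 - cam$cy) / cam$fy)^2 + 1)
  err <- (as.vector(noisy$depth) - as.vector(ideal$depth)) * ray_norm
  sigma_true <- 1 * (600 / 450)^2
  n <- length(err)
  expect_gt(n, 1e5)
  expect_lt(abs(mean(err)), 3 * sigma_true / sqrt(n))
  expect_lt(abs(stats::sd(err) - sigma_true) / sigma_true, 0.05)

  again <- render_depth(plane, rt_identity(), cam, nm, return_image = TRUE)
  expect_identical(noisy$depth, again$depth)

  quant <- noise_model(sigma_mm = 0.5, quant_mm = 0.25, seed = 5)
  q <- render_depth(plane, rt_identity(), cam, quant, return_image = TRUE)
  expect_true(all(abs(q$depth / 0.25 - round(q$depth / 0.25)) < 1e-9))

  drop <- noise_model(sigma_mm = 0, quant_mm = 0, dropout = 0.3, seed = 6)
  d <- render_depth(plane, rt_identity(), cam, drop, return_image = TRUE)
  frac <- 1 - sum(is.finite(d$depth)) / n
  expect_equal(frac, 0.3, tolerance = 0.02)
})

test_that("the staircase protocol emits the commanded poses of the benchmark", {
  tr <- single_axis_protocol()
  poses <- unique(tr[, trace_cols_test()[-1]])
  expect_equal(nrow(tr), 66L)
  expect_equal(nrow(poses), 61L)          # 66 poses, zero repeated per axis
  expect_equal(length(unique(tr$pose_id)), 66L)
  expect_equal(range(tr$tx_mm), c(-5, 5))
  expect_equal(range(tr$ry_deg), c(-5, 5))
  expect_true(all(rowSums(as.matrix(tr[, trace_cols_test()[-1]]) != 0) <= 1))

  dwell <- single_axis_protocol(dwell_frames = 5)
  expect_equal(nrow(dwell), 330L)
  expect_equal(unname(table(dwell$pose_id)[1]), 5L)

  flat <- single_axis_protocol(range_mm = 0, range_deg = 0)
  expect_equal(nrow(unique(flat[, trace_cols_test()[-1]])), 1L)
  expect_true(all(flat[, trace_cols_test()[-1]] == 0))
})

test_that("smooth traces are bounded, band-limited and seeded", {
  tr <- smooth_trace(30, amplitude_mm = 3, amplitude_deg = 2, seed = 4,
                     fps = 10)
  expect_lte(max(abs(tr$tx_mm)), 3 + 1e-12)
  expect_lte(max(abs(tr$rz_deg)), 2 + 1e-12)
  expect_equal(tr$tx_mm[1], 0)
  expect_identical(tr, smooth_trace(30, 3, 2, seed = 4, fps = 10))

  zero <- smooth_trace(10, 0, 0, seed = 1)
  expect_true(all(zero[, trace_cols_test()[-1]] == 0))

  # spectral check: over 99% of power below 0.5 Hz
  x <- tr$ty_mm - mean(tr$ty_mm)
  sp <- Mod(stats::fft(x))^2
  freq <- (seq_along(x) - 1) * 10 / length(x)
  half <- freq <= 5                      # keep one side of the spectrum
  low <- freq <= 0.5
  expect_gt(sum(sp[half & low]) / sum(sp[half]), 0.99)
})

test_that("facial deformations are region-confined and rigid-motion-free", {
  ph <- small_phantom()
  cl <- phantom_cloud(ph)
  for (mode in c("yawn", "smile", "shake-free", "frown", "swallow")) {
    def <- facial_deformation(cl, mode, amplitude = 5)
    disp <- sqrt(rowSums((def$points - cl$points)^2))
    moved <- disp > 1e-9
    expect_gt(sum(moved), 10)
    expect_lte(max(disp), 5 * 1.05)
    fit <- fit_rigid(cl$points, def$points)
    expect_lt(unname(rt_magnitude(fit)["trans_mm"]), 1e-6)
    expect_lt(unname(rt_magnitude(fit)["rot_deg"]), 1e-6)
  }
  smile <- facial_deformation(cl, "smile", 5)
  moved <- sqrt(rowSums((smile$points - cl$points)^2)) > 1e-9
  expect_true(all(attr(cl, "labels")[moved] %in% c("cheek_l", "cheek_r")))

  expect_identical(facial_deformation(cl, "yawn", 0)$points, cl$points)
  expect_error(facial_deformation(cl, "grimace", 5), "unknown")
  expect_error(facial_deformation(surface_cloud(diag(3)), "yawn", 5),
               "labels")
})

test_that("a session round-trips through its on-disk layout", {
  ph <- small_phantom()
  tr <- smooth_trace(1, 2, 1, seed = 5, fps = 2)
  ses <- simulate_session(ph, tr, small_cameras(), noise_model(), seed = 11)
  d <- withr::local_tempdir()
  write_session(ses, d)
  expect_true(file.exists(file.path(d, "truth.csv")))
  expect_true(file.exists(file.path(d, "session.json")))
  expect_true(file.exists(file.path(d, "depth", "frame_0001_cam2.png.json")))
  back <- read_frame_dir(d)
  expect_equal(n_frames(back), nrow(tr))
  expect_equal(back$timestamps, tr$t_s)
  # PLY storage is float32: sub-micrometer agreement on ~100 mm coordinates
  expect_lt(max(abs(back$clouds[[2]]$points -
                    ses$frames$clouds[[2]]$points)), 1e-3)
  truth <- read_trace_csv(file.path(d, "truth.csv"))
  expect_equal(truth$ty_mm, tr$ty_mm, tolerance = 1e-12)
  # per-camera depth images re-rendered from the stored seed are consistent
  dp <- read_depth_png(file.path(d, "depth", "frame_0001_cam1.png"))
  expect_equal(dp$camera$width, small_cameras()$left$width)
  expect_gt(sum(is.finite(dp$depth)), 1000)
  expect_true(all(dp$depth[is.finite(dp$depth)] > 300))
})

test_that("sessions are deterministic and carry exact ground truth", {
  ph <- small_phantom()
  cams <- small_cameras()
  tr <- single_axis_protocol(range_mm = 2, range_deg = 2, dwell_frames = 1)
  tr <- tr[c(1, 3, 5), ]
  tr$t_s <- c(0, 0.2, 0.4)
  s1 <- simulate_session(ph, tr, cams, noise_model(), seed = 3)
  s2 <- simulate_session(ph, tr, cams, noise_model(), seed = 3)
  expect_identical(s1$frames$clouds[[2]]$points, s2$frames$clouds[[2]]$points)
  expect_identical(s1$truth, tr)          # commanded trace passes through

  # zero motion + zero noise: every frame is identical
  tr0 <- tr; tr0[, trace_cols_test()[-1]] <- 0
  s0 <- simulate_session(ph, tr0, cams, zero_noise(), seed = 1)
  expect_identical(s0$frames$clouds[[1]]$points, s0$frames$clouds[[3]]$points)

  # different seeds give different noise
  s3 <- simulate_session(ph, tr, cams, noise_model(), seed = 4)
  expect_gt(max(abs(s3$frames$clouds[[1]]$points[1, ] -
                    s1$frames$clouds[[1]]$points[1, ])), 0)
})
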