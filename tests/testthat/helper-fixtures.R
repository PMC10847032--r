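# Shared fixtures and independent oracles. Everything is generated in code;
# smaller phantom/camera variants keep unit tests fast while the acceptance
# tests use the full defaults.

small_phantom <- function(seed = 1)
  make_phantom(seed = seed, n_theta = 61, n_phi = 96)

# quarter-resolution cameras with the same field of view and geometry
small_cameras <- function() {
  full <- default_cameras()
  lapply(full, function(cm)
    depth_camera(fx = cm$fx / 4, fy = cm$fy / 4,
                 cx = (cm$cx + 0.5) / 4 - 0.5, cy = (cm$cy + 0.5) / 4 - 0.5,
                 width = cm$width / 4, height = cm$height / 4,
                 pose = cm$pose, near = cm$near, far = cm$far))
}

render_fused <- function(phantom, pose, cameras, noise = zero_noise(),
                         seeds = NULL, thin_voxel = 1) {
  views <- lapply(seq_along(cameras), function(j) {
    nj <- noise
    if (!is.null(seeds)) nj$seed <- seeds[j]
    render_depth(phantom, pose, cameras[[j]], nj)
  })
  fuse(views, rep(list(rt_identity()), length(cameras)),
       thin_voxel = thin_voxel)
}

random_rigid <- function(max_mm = 50, max_deg = 90) {
  ax <- stats::rnorm(3)
  from_sixdof(c(stats::runif(3, -max_mm, max_mm), 0, 0, 0)) |>
    compose(rigid_transform(rot_axis_angle(ax, stats::runif(1, -max_deg, max_deg))))
}

# dense flat rectangular patch in the z = z0 plane (spacing in mm)
flat_patch <- function(lx = 100, ly = 100, spacing = 1, z0 = 0) {
  g <- expand.grid(x = seq(0, lx, by = spacing), y = seq(0, ly, by = spacing))
  surface_cloud(cbind(g$x, g$y, z0))
}

# latitude/longitude sphere mesh for renderer tests
sphere_mesh <- function(center, radius, n_theta = 81, n_phi = 120) {
  theta <- seq(0, pi, length.out = n_theta)
  phi <- seq(-pi, pi, length.out = n_phi + 1)[seq_len(n_phi)]
  g <- expand.grid(theta = theta, phi = phi)
  V <- cbind(sin(g$theta) * sin(g$phi), cos(g$theta),
             sin(g$theta) * cos(g$phi)) * radius
  V <- sweep(V, 2, -center)
  idx <- function(i, j) (j - 1L) * n_theta + i
  faces <- NULL
  for (j in seq_len(n_phi)) {
    jn <- if (j == n_phi) 1L else j + 1L
    i <- seq_len(n_theta - 1L)
    faces <- rbind(faces,
                   cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, jn)),
                   cbind(idx(i, j), idx(i + 1L, jn), idx(i, jn)))
  }
  list(vertices = V, faces = faces)
}

# brute-force voxel occupancy count (oracle for downsample)
voxel_occupancy <- function(points, voxel) {
  ijk <- floor(sweep(points, 2, apply(points, 2, min)) / voxel)
  nrow(unique(ijk))
}

# direct numerical minimisation of the weighted point-to-plane cost over
# the 6 pose parameters (independent oracle for the ICP solver)
optim_pp_cost <- function(p, n, q, w, start = rep(0, 6)) {
  fn <- function(par) {
    T <- from_sixdof(par)
    q2 <- apply_transform(T, q)
    sum(w * rowSums((p - q2) * n)^2)
  }
  o1 <- stats::optim(start, fn, method = "Nelder-Mead",
                     control = list(maxit = 4000, reltol = 1e-14))
  o2 <- stats::optim(o1$par, fn, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-14))
  min(o1$value, o2$value, fn(o2$par))
}

trace_cols_test <- function()
  c("t_s", "tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg", "rz_deg")
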