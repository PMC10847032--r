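# Barron's rho, written independently of the package's weight formula and
# used as a finite-difference oracle: w(r) proportional to rho'(r)/r.
barron_rho <- function(r, alpha, c) {
  if (alpha == 0) return(log(0.5 * (r / c)^2 + 1))
  abs(alpha - 2) / alpha * (((r / c)^2 / abs(alpha - 2) + 1)^(alpha / 2) - 1)
}

test_that("barron weights match the finite-difference IRLS oracle", {
  h <- 1e-6
  for (alpha in c(1, 0.5, -2)) {
    for (cc in c(0.5, 1, 3)) {
      loss <- robust_loss(alpha, cc)
      for (r in c(0.3, 1, 2.7)) {
        drho <- (barron_rho(r + h, alpha, cc) -
                 barron_rho(r - h, alpha, cc)) / (2 * h)
        w_raw <- drho / r
        w0 <- 1 / cc^2                        # analytic limit of rho'(r)/r at 0
        expect_equal(barron_weight(r, loss), w_raw / w0, tolerance = 1e-6)
      }
    }
  }
})

test_that("barron weight normalisation, quadratic limit and monotonicity", {
  expect_equal(barron_weight(0, robust_loss(1, 2)), 1)
  expect_equal(barron_weight(0, robust_loss(-5, 0.3)), 1)
  expect_equal(barron_weight(17, robust_loss(2, 1)), 1)   # alpha = 2: unweighted
  expect_equal(barron_weight(c(-4, 0, 100), robust_loss(2, 5)), rep(1, 3))
  # Cauchy special case alpha = 0: w = 1 / (1 + (r/c)^2 / 2)
  r <- seq(-5, 5, by = 0.5)
  expect_equal(barron_weight(r, robust_loss(0, 1)), 1 / (1 + r^2 / 2),
               tolerance = 1e-12)
  for (alpha in c(1.5, 1, 0, -2)) {
    w <- barron_weight(seq(0, 10, by = 0.1), robust_loss(alpha, 1))
    expect_true(all(diff(w) <= 1e-12))
    expect_true(all(w > 0 & w <= 1))
  }
})

test_that("barron weight is continuous in alpha across the quadratic limit", {
  r <- c(0.5, 1, 5)
  for (cc in c(0.7, 2)) {
    below <- barron_weight(r, robust_loss(2 - 1e-7, cc))
    above <- barron_weight(r, robust_loss(2 + 1e-7, cc))
    expect_lt(max(abs(below - 1)), 1e-5)
    expect_lt(max(abs(above - 1)), 1e-5)
  }
  expect_error(robust_loss(Inf, 1), "finite")
  expect_error(robust_loss(1, 0), "positive")
})

make_wavy_cloud <- function(n = 400, seed = 1) {
  set.seed(seed)
  x <- stats::runif(n, -60, 60)
  y <- stats::runif(n, -60, 60)
  z <- 8 * sin(x / 15) + 6 * cos(y / 18)
  estimate_normals(surface_cloud(cbind(x, y, z)), k = 12,
                   viewpoint = c(0, 0, 500))
}

test_that("correspondence search matches the exhaustive nearest-neighbor oracle", {
  set.seed(41)
  ref <- surface_cloud(matrix(stats::rnorm(300, sd = 40), 100, 3))
  tgt_pts <- matrix(stats::rnorm(300, sd = 40), 100, 3)
  nrm <- matrix(stats::rnorm(300), 100, 3)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  tgt <- surface_cloud(tgt_pts, nrm)
  T1 <- from_sixdof(c(3, -2, 5, 4, -6, 2))
  corr <- find_correspondences(tgt, ref, T1, max_dist = 100)
  # brute-force O(N^2) oracle in the reference frame
  p_ref <- apply_transform(rt_inverse(T1), tgt_pts)
  for (i in seq_len(nrow(corr))) {
    d2 <- rowSums(sweep(ref$points, 2, p_ref[corr$target_idx[i], ])^2)
    expect_equal(corr$ref_idx[i], which.min(d2))
  }
  # residual definition: (p - T q) . n_p
  q_cur <- apply_transform(T1, ref$points[corr$ref_idx, ])
  r_expect <- rowSums((tgt_pts[corr$target_idx, ] - q_cur) *
                      nrm[corr$target_idx, ])
  expect_lt(max(abs(corr$residual - r_expect)), 1e-9)
})

test_that("correspondences: self-match, gating, and failure modes", {
  cl <- make_wavy_cloud(200, seed = 42)
  corr <- find_correspondences(cl, cl, rt_identity(), max_dist = 5)
  expect_equal(corr$ref_idx, corr$target_idx)
  expect_true(all(abs(corr$residual) < 1e-12))

  # sparse grid offset by 1 mm: nothing within a 0.5 mm gate
  grid <- flat_patch(40, 40, spacing = 5)
  grid_n <- surface_cloud(grid$points,
                          matrix(c(0, 0, 1), n_points(grid), 3, byrow = TRUE))
  shifted <- transform_cloud(rigid_transform(diag(3), c(1, 0, 0)), grid_n)
  expect_error(find_correspondences(shifted, grid, rt_identity(),
                                    max_dist = 0.5), "max_dist")
  expect_error(find_correspondences(surface_cloud(diag(3)), cl), "normals")
})

test_that("solve_increment recovers an exact translation from 3 orthogonal planes", {
  g <- as.matrix(expand.grid(seq(-20, 20, 5), seq(-20, 20, 5)))
  p <- rbind(cbind(g, 30), cbind(30, g), cbind(g[, 1], 30, g[, 2]))
  n <- rbind(matrix(c(0, 0, 1), nrow(g), 3, byrow = TRUE),
             matrix(c(1, 0, 0), nrow(g), 3, byrow = TRUE),
             matrix(c(0, 1, 0), nrow(g), 3, byrow = TRUE))
  q <- sweep(p, 2, c(1, 2, 3))   # reference shifted by -(1,2,3)
  corr <- data.frame(px = p[, 1], py = p[, 2], pz = p[, 3],
                     nx = n[, 1], ny = n[, 2], nz = n[, 3],
                     qx = q[, 1], qy = q[, 2], qz = q[, 3],
                     residual = rowSums((p - q) * n), weight = 1)
  inc <- solve_increment(corr)
  expect_lt(max(abs(inc$translation - c(1, 2, 3))), 1e-6)
  expect_lt(max(abs(inc$rotation - diag(3))), 1e-6)

  # zero residuals: identity increment
  corr0 <- corr
  corr0[, c("qx", "qy", "qz")] <- p
  corr0$residual <- 0
  inc0 <- solve_increment(corr0)
  expect_lt(unname(rt_magnitude(inc0)["trans_mm"]), 1e-9)
})

test_that("solve_increment rejects rank-deficient normal geometry", {
  n <- matrix(c(0, 0, 1), 50, 3, byrow = TRUE)   # all normals parallel
  p <- cbind(stats::runif(50), stats::runif(50), 1)
  corr <- data.frame(px = p[, 1], py = p[, 2], pz = p[, 3],
                     nx = n[, 1], ny = n[, 2], nz = n[, 3],
                     qx = p[, 1], qy = p[, 2], qz = p[, 3] - 1,
                     residual = 1, weight = 1)
  expect_error(solve_increment(corr), "degenerate")
  expect_error(solve_increment(corr[1:3, ]), "at least 6")
})

test_that("icp is exact on constructed rigid pairs and idempotent when warm", {
  ref <- make_wavy_cloud(500, seed = 43)
  res_self <- icp(ref, ref, max_dist = 10)
  expect_lt(unname(rt_magnitude(res_self$transform)["trans_mm"]), 1e-6)
  expect_lt(unname(rt_magnitude(res_self$transform)["rot_deg"]), 1e-6)
  expect_lt(res_self$final_cost, 1e-12)

  T_true <- from_sixdof(c(2, -1.5, 1, 1.2, -0.8, 1.5))  # |t| ~ 3 mm, ~2 deg
  tgt <- transform_cloud(T_true, ref)
  res <- icp(tgt, ref, max_dist = 15, max_iter = 50)
  err <- compose(res$transform, rt_inverse(T_true))
  expect_lt(unname(rt_magnitude(err)["trans_mm"]), 0.01)
  expect_lt(unname(rt_magnitude(err)["rot_deg"]), 0.01)

  warm <- icp(tgt, ref, init = T_true, max_dist = 15)
  expect_lte(warm$iterations_used, 2L)
  expect_true(warm$converged)
})

test_that("self-registration returns identity for any loss shape", {
  cl <- make_wavy_cloud(300, seed = 44)
  for (alpha in c(2, 1, 0)) {
    res <- icp(cl, cl, loss = robust_loss(alpha, 2), max_dist = 8)
    expect_lt(unname(rt_magnitude(res$transform)["trans_mm"]), 1e-6)
    expect_lt(unname(rt_magnitude(res$transform)["rot_deg"]), 1e-6)
  }
})

test_that("icp cost matches direct nonlinear minimisation within 1%", {
  set.seed(45)
  for (i in 1:5) {
    ref <- make_wavy_cloud(300, seed = 100 + i)
    T_true <- from_sixdof(c(stats::runif(3, -2, 2), stats::runif(3, -1.5, 1.5)))
    tgt_pts <- apply_transform(T_true, ref$points)
    tgt_pts <- tgt_pts + matrix(stats::rnorm(length(tgt_pts), sd = 0.3),
                                ncol = 3)
    tgt <- surface_cloud(tgt_pts, ref$normals %*% t(T_true$rotation))
    loss <- robust_loss(1, 2)
    res <- icp(tgt, ref, loss = loss, max_dist = 10, max_iter = 60,
               tol_mm = 1e-4, tol_deg = 1e-4)
    # freeze the final correspondence set and weights, then hand the same
    # 6-parameter problem to a general-purpose optimizer
    corr <- find_correspondences(tgt, ref, res$transform, max_dist = 10,
                                 loss = loss)
    p <- cbind(corr$px, corr$py, corr$pz)
    n <- cbind(corr$nx, corr$ny, corr$nz)
    q0 <- apply_transform(rt_inverse(res$transform), cbind(corr$qx, corr$qy, corr$qz))
    cost_icp <- sum(corr$weight * corr$residual^2)
    cost_opt <- optim_pp_cost(p, n, q0, corr$weight,
                              start = as.numeric(to_sixdof(res$transform)))
    expect_lt(cost_icp, cost_opt * 1.01 + 1e-9)
  }
})

test_that("registration symmetry: A->B composed with B->A is identity", {
  ref <- make_wavy_cloud(400, seed = 46)
  T_true <- from_sixdof(c(2, 1, -1.5, 1, -1, 0.8))
  tgt <- transform_cloud(T_true, ref)
  fwd <- icp(tgt, ref, max_dist = 15, max_iter = 50)
  bwd <- icp(ref, tgt, max_dist = 15, max_iter = 50)
  round_trip <- compose(fwd$transform, bwd$transform)
  expect_lt(unname(rt_magnitude(round_trip)["trans_mm"]), 0.02)
  expect_lt(unname(rt_magnitude(round_trip)["rot_deg"]), 0.01)
})

test_that("the default schedule is five log-spaced levels from 0.2 to 100", {
  sch <- multiscale_schedule()
  expect_equal(nrow(sch), 5L)
  expect_equal(sch$density[1], 0.2)
  expect_equal(sch$density[5], 100)
  expect_true(all(diff(sch$density) > 0))
  expect_equal(sch$voxel_mm, 10 / sqrt(sch$density))
  expect_error(multiscale_schedule(c(5, 1)), "increasing")
})

test_that("multiscale registration recovers a 5 mm / 5 deg offset", {
  ph <- small_phantom()
  cams <- small_cameras()
  ref <- render_fused(ph, rt_identity(), cams)
  T_true <- from_sixdof(c(5, -5, 3, 5, -5, 4))
  tgt <- render_fused(ph, T_true, cams)
  tgt <- estimate_normals(suppressWarnings(crop(tgt, default_roi())),
                          viewpoint = c(0, 0, 600))
  res <- multiscale_register(tgt, ref)
  err <- compose(res$transform, rt_inverse(T_true))
  # resampled surfaces (not identical point sets), so tolerance is looser
  expect_lt(unname(rt_magnitude(err)["trans_mm"]), 0.1)
  expect_lt(unname(rt_magnitude(err)["rot_deg"]), 0.1)
  expect_length(res$iterations_used, 5L)
  expect_true(all(res$correspondence_count > 100))
})
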