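#' Robust loss parameters for correspondence weighting
#'
#' Correspondence weights come from the iteratively-reweighted-least-squares
#' derivative of Barron's generalised adaptive loss, a single family that
#' interpolates quadratic (`alpha = 2`), pseudo-Huber/Charbonnier
#' (`alpha = 1`), Cauchy (`alpha = 0`) and heavier-tailed penalties. The
#' scale `c` (mm) sets the residual magnitude at which downweighting kicks
#' in; during multiscale registration it defaults to twice the voxel edge
#' of the current level (floored at 1 mm) so the weight profile stays
#' meaningful across the pyramid.
#'
#' @param alpha shape parameter (finite; 2 recovers unweighted least squares).
#' @param c scale in mm (> 0).
#' @return An object of class `robust_loss`.
#' @export
robust_loss <- function(alpha = 1, c = 1) {
  if (!is.finite(alpha)) stop("alpha must be finite")
  if (!is.numeric(c) || c <= 0) stop("scale c must be positive")
  structure(list(alpha = alpha, c = c), class = "robust_loss")
}

#' IRLS weight of Barron's generalised adaptive loss
#'
#' The weight is `(1 / r) * d rho / d r`, normalised so that `w(0) = 1`:
#' `w(r) = ((r/c)^2 / |alpha - 2| + 1)^(alpha/2 - 1)` for `alpha != 2` and
#' identically 1 in the quadratic limit `alpha = 2` (handled exactly, not
#' as a division by zero). For `alpha < 2` the weight is continuous and
#' monotone non-increasing in `|r|`, which is what makes the registration
#' robust to deforming or unmatched surface regions.
#'
#' @param residual numeric vector of signed residuals (mm).
#' @param loss a `robust_loss`.
#' @return Weights in (0, 1], same length as `residual`.
#' @export
barron_weight <- function(residual, loss = robust_loss()) {
  stopifnot(inherits(loss, "robust_loss"))
  if (loss$alpha == 2) return(rep(1, length(residual)))
  u <- (residual / loss$c)^2
  (u / abs(loss$alpha - 2) + 1)^(loss$alpha / 2 - 1)
}

#' Multiscale registration schedule
#'
#' An ordered list of pyramid levels, each a surface density (points/cm2),
#' a correspondence gating distance (mm) and an iteration cap. The default
#' is the five-step rough-to-fine schedule: densities log-spaced from 0.2
#' to 100 points/cm2, gate of 4x the level's voxel edge (coarse levels must
#' tolerate a large initial error, fine levels should reject mismatches)
#' and at most 30 iterations per level.
#'
#' @param densities strictly increasing densities in points/cm2.
#' @param max_dist correspondence gates (mm), recycled to the number of
#'   levels; default `4 * voxel edge` per level.
#' @param max_iter per-level iteration caps, recycled.
#' @return A data frame of class `multiscale_schedule` with columns
#'   `density`, `voxel_mm`, `max_dist`, `max_iter`.
#' @export
multiscale_schedule <- function(densities = default_densities(),
                                max_dist = NULL, max_iter = 30) {
  if (any(diff(densities) <= 0))
    stop("densities must be strictly increasing")
  if (any(densities <= 0)) stop("densities must be positive")
  voxel <- 10 / sqrt(densities)
  if (is.null(max_dist)) max_dist <- 4 * voxel
  out <- data.frame(density = densities, voxel_mm = voxel,
                    max_dist = rep_len(max_dist, length(densities)),
                    max_iter = rep_len(as.integer(max_iter), length(densities)))
  class(out) <- c("multiscale_schedule", "data.frame")
  out
}

#' @rdname multiscale_schedule
#' @export
default_densities <- function() {
  d <- exp(seq(log(0.2), log(100), length.out = 5))
  d[1] <- 0.2                # pin the endpoints exactly
  d[length(d)] <- 100
  d
}

#' Find point-to-plane correspondences
#'
#' For every valid target point `p` (with normal `n_p`), the nearest
#' reference point under the current transform `T` is located through a
#' KD-tree; pairs farther than `max_dist` are rejected. The search is run
#' in the reference frame (target points are moved by `T^-1`), which lets
#' the reference tree be built once and reused across iterations and
#' frames. The signed residual is `(p - T q) . n_p`.
#'
#' @param target `surface_cloud` with normals (the current frame).
#' @param reference `surface_cloud` (the baseline surface).
#' @param T current `rigid_transform` estimate (reference -> target).
#' @param max_dist gating distance in mm.
#' @param loss optional `robust_loss`; when given, weights are populated,
#'   otherwise all weights are 1.
#' @param ref_tree optional prebuilt KD-tree of `reference$points`.
#' @return A data frame with columns `p*` (target point), `n*` (target
#'   normal), `q*` (reference point mapped by `T`), `residual`, `weight`,
#'   plus the matched indices `target_idx`, `ref_idx`.
#' @export
find_correspondences <- function(target, reference, T = rt_identity(),
                                 max_dist = 10, loss = NULL,
                                 ref_tree = NULL) {
  stopifnot(inherits(target, "surface_cloud"),
            inherits(reference, "surface_cloud"))
  if (is.null(target$normals)) stop("target cloud must carry normals")
  if (n_points(target) == 0L || n_points(reference) == 0L)
    stop("cannot match empty clouds")
  keep <- which(target$valid & is.finite(target$normals[, 1]))
  if (length(keep) == 0L) stop("target has no valid points with normals")
  if (is.null(ref_tree)) ref_tree <- .kd_build(reference$points)
  cc <- corr_lean(target$points[keep, , drop = FALSE],
                  target$normals[keep, , drop = FALSE],
                  reference$points, ref_tree, T, max_dist, loss)
  corr <- data.frame(px = cc$p[, 1], py = cc$p[, 2], pz = cc$p[, 3],
                     nx = cc$n[, 1], ny = cc$n[, 2], nz = cc$n[, 3],
                     qx = cc$q[, 1], qy = cc$q[, 2], qz = cc$q[, 3],
                     residual = cc$residual, weight = cc$weight,
                     target_idx = keep[cc$hit], ref_idx = cc$ref_idx,
                     row.names = NULL)
  corr
}

# matrix-based correspondence search shared by find_correspondences and
# the icp inner loop (which cannot afford per-iteration data frames).
# The search runs in the reference frame (target moved by T^-1) so the
# reference tree is reused across iterations and frames.
corr_lean <- function(P, Nrm, ref_pts, ref_tree, T, max_dist, loss = NULL) {
  p_ref <- apply_transform(rt_inverse(T), P)   # rigid => distances preserved
  nn <- .kd_nn1(ref_tree, p_ref, max_dist)
  hit <- which(!is.na(nn$idx))
  if (length(hit) == 0L)
    stop("no correspondences within max_dist = ", max_dist, " mm")
  ri <- nn$idx[hit]
  p <- P[hit, , drop = FALSE]
  n <- Nrm[hit, , drop = FALSE]
  q_cur <- apply_transform(T, ref_pts[ri, , drop = FALSE])
  residual <- rowSums((p - q_cur) * n)
  weight <- if (is.null(loss)) rep(1, length(hit))
            else barron_weight(residual, loss)
  list(p = p, n = n, q = q_cur, residual = residual, weight = weight,
       hit = hit, ref_idx = ri)
}

# weighted point-to-plane cost for a candidate increment applied to the
# current reference positions of a fixed correspondence set
pp_cost_core <- function(p, n, q, w, increment = rt_identity()) {
  q2 <- apply_transform(increment, q)
  sum(w * rowSums((p - q2) * n)^2)
}

#' Solve one linearised point-to-plane increment
#'
#' Minimises the weighted point-to-plane cost over the 6 pose parameters
#' in its small-angle linearisation: with `a_i = [q_i x n_i; n_i]` the
#' weighted 6x6 normal equations `(A' W A) x = A' W r` are solved for
#' `x = [omega; dt]`, the increment is exponentiated to an exact rotation
#' and, if the linearisation overshoots, step-halving guarantees the
#' returned increment does not increase the weighted cost on this
#' correspondence set. At least 6 correspondences spanning at least 3
#' independent normal directions are required; a rank-deficient system
#' (e.g. all normals parallel) raises a degenerate-geometry error.
#'
#' @param corr correspondence data frame from [find_correspondences()]
#'   (`q*` columns already in the current frame).
#' @return The increment as a `rigid_transform` (to be composed on the
#'   left of the current estimate).
#' @export
solve_increment <- function(corr) {
  solve_increment_core(cbind(corr$px, corr$py, corr$pz),
                       cbind(corr$nx, corr$ny, corr$nz),
                       cbind(corr$qx, corr$qy, corr$qz),
                       corr$residual, corr$weight)
}

solve_increment_core <- function(p, n, q, r, w) {
  if (length(r) < 6L) stop("need at least 6 correspondences")
  cxn <- cbind(q[, 2] * n[, 3] - q[, 3] * n[, 2],
               q[, 3] * n[, 1] - q[, 1] * n[, 3],
               q[, 1] * n[, 2] - q[, 2] * n[, 1])
  A <- cbind(cxn, n)
  AtA <- crossprod(A, A * w)
  if (rcond(AtA) < 1e-12)
    stop("degenerate geometry: correspondences do not constrain all 6 DoF")
  x <- solve(AtA, crossprod(A, w * r))
  cost0 <- sum(w * r^2)
  step <- 1
  for (i in 1:20) {
    inc <- increment_transform(step * x)
    if (pp_cost_core(p, n, q, w, inc) <= cost0 + 1e-12 * (1 + cost0))
      return(inc)
    step <- step / 2
  }
  rt_identity()
}

# exact rotation from a rotation-vector + translation 6-vector
increment_transform <- function(x) {
  w <- x[1:3]
  th <- sqrt(sum(w^2))
  R <- if (th < 1e-14) diag(3) else rot_axis_angle(w, th * 180 / pi)
  rigid_transform(orthonormalize(R), x[4:6])
}

#' Robust weighted point-to-plane ICP
#'
#' Alternates correspondence search, Barron reweighting (IRLS: weights are
#' recomputed from the current residuals every iteration, with the scale
#' held fixed) and the linearised increment solve, starting from `init`.
#' Iteration stops when the increment falls below `tol_mm` / `tol_deg` or
#' `max_iter` is reached.
#'
#' @param target `surface_cloud` with normals.
#' @param reference `surface_cloud`.
#' @param init initial `rigid_transform` (reference -> target).
#' @param loss `robust_loss` for the weights.
#' @param max_dist correspondence gate (mm).
#' @param max_iter iteration cap.
#' @param tol_mm,tol_deg convergence thresholds on the increment.
#' @param ref_tree optional prebuilt KD-tree of the reference points.
#' @return A `registration_result`: `transform`, `final_cost` (weighted
#'   cost, mm2), `iterations_used`, `correspondence_count`, `converged`.
#' @export
icp <- function(target, reference, init = rt_identity(),
                loss = robust_loss(), max_dist = 10, max_iter = 30,
                tol_mm = 0.01, tol_deg = 0.01, ref_tree = NULL) {
  if (is.null(target$normals)) stop("target cloud must carry normals")
  if (n_points(target) == 0L || n_points(reference) == 0L)
    stop("cannot register empty clouds")
  keep <- which(target$valid & is.finite(target$normals[, 1]))
  if (length(keep) == 0L) stop("target has no valid points with normals")
  P <- target$points[keep, , drop = FALSE]
  Nrm <- target$normals[keep, , drop = FALSE]
  if (is.null(ref_tree)) ref_tree <- .kd_build(reference$points)
  T <- init
  converged <- FALSE
  iters <- 0L
  inc <- rt_identity()
  cc <- NULL
  for (i in seq_len(max_iter)) {
    iters <- i
    cc <- corr_lean(P, Nrm, reference$points, ref_tree, T, max_dist, loss)
    inc <- solve_increment_core(cc$p, cc$n, cc$q, cc$residual, cc$weight)
    T <- compose(inc, T)
    mag <- rt_magnitude(inc)
    if (mag["trans_mm"] < tol_mm && mag["rot_deg"] < tol_deg) {
      converged <- TRUE
      break
    }
  }
  # cost at the final pose: residuals of the last correspondence set moved
  # by the accepted increment, with IRLS weights recomputed at that pose
  q_fin <- apply_transform(inc, cc$q)
  r_fin <- rowSums((cc$p - q_fin) * cc$n)
  w_fin <- if (is.null(loss)) rep(1, length(r_fin))
           else barron_weight(r_fin, loss)
  structure(list(transform = T,
                 final_cost = sum(w_fin * r_fin^2),
                 iterations_used = iters,
                 correspondence_count = length(r_fin),
                 converged = converged),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  s <- to_sixdof(x$transform)
  cat("<registration_result> ",
      if (x$converged) "converged" else "NOT converged",
      " after ", paste(x$iterations_used, collapse = "/"), " iterations, ",
      paste(x$correspondence_count, collapse = "/"), " correspondences, cost ",
      format(x$final_cost, digits = 4), " mm^2\n  pose: ",
      paste(sprintf("%s=%.3f", names(s), unclass(s)), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Precompute the per-level reference pyramid
#'
#' Downsamples the reference once per schedule level and builds the KD-tree
#' for each level, so that sequential tracking does not repeat this work
#' for every frame.
#'
#' @param reference `surface_cloud`.
#' @param schedule a `multiscale_schedule`.
#' @return A list of `list(cloud, tree)` per level, class
#'   `reference_pyramid`.
#' @export
build_reference_pyramid <- function(reference,
                                    schedule = multiscale_schedule()) {
  lv <- lapply(seq_len(nrow(schedule)), function(i) {
    cl <- downsample(reference, schedule$density[i])
    list(cloud = cl, tree = .kd_build(cl$points))
  })
  structure(lv, class = "reference_pyramid", schedule = schedule)
}

#' Multiscale rough-to-fine registration
#'
#' Runs [icp()] at each level of the schedule on both clouds downsampled
#' to the level's density, chaining each level's pose as the next level's
#' initialisation. Target normals are computed once at full resolution and
#' carried through downsampling by voxel averaging (they are never
#' re-estimated on the coarse clouds, which would bias them). Unless a
#' loss is supplied, the Barron scale at each level is
#' `max(2 * voxel edge, 1 mm)` with `alpha = 1`.
#'
#' @param target `surface_cloud` with normals.
#' @param reference `surface_cloud`, or a `reference_pyramid` (in which
#'   case `schedule` is taken from the pyramid).
#' @param init initial `rigid_transform`.
#' @param schedule a `multiscale_schedule`.
#' @param loss optional fixed `robust_loss` for all levels.
#' @param alpha Barron shape used when `loss` is `NULL`.
#' @param tol_mm,tol_deg per-level convergence thresholds.
#' @return A `registration_result` whose `iterations_used`,
#'   `correspondence_count` and `final_cost` are vectors over levels
#'   (`levels` holds per-level diagnostics); `transform` is the finest
#'   level's pose.
#' @export
multiscale_register <- function(target, reference, init = rt_identity(),
                                schedule = multiscale_schedule(),
                                loss = NULL, alpha = 1,
                                tol_mm = 0.01, tol_deg = 0.01) {
  if (inherits(reference, "reference_pyramid")) {
    pyramid <- reference
    schedule <- attr(pyramid, "schedule")
  } else {
    pyramid <- build_reference_pyramid(reference, schedule)
  }
  T <- init
  diag_lv <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    tgt_i <- downsample(target, schedule$density[i])
    loss_i <- if (is.null(loss))
      robust_loss(alpha, max(2 * schedule$voxel_mm[i], 1))
    else loss
    res <- tryCatch(
      icp(tgt_i, pyramid[[i]]$cloud, init = T, loss = loss_i,
          max_dist = schedule$max_dist[i], max_iter = schedule$max_iter[i],
          tol_mm = tol_mm, tol_deg = tol_deg, ref_tree = pyramid[[i]]$tree),
      error = function(e)
        stop("multiscale level ", i, " (density ",
             signif(schedule$density[i], 3), " pts/cm2) failed: ",
             conditionMessage(e), call. = FALSE))
    T <- res$transform
    diag_lv[[i]] <- res
  }
  last <- diag_lv[[nrow(schedule)]]
  structure(list(transform = T,
                 final_cost = last$final_cost,
                 iterations_used = vapply(diag_lv, `[[`, 0L, "iterations_used"),
                 correspondence_count =
                   vapply(diag_lv, `[[`, 0L, "correspondence_count"),
                 converged = last$converged,
                 levels = diag_lv),
            class = "registration_result")
}
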