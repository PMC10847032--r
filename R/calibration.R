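#' Closed-form least-squares rigid fit (Kabsch)
#'
#' Finds the rigid transform minimising `sum ||fixed_i - T moving_i||^2`
#' over ordered correspondence pairs, via SVD of the cross-covariance with
#' the determinant correction that enforces a proper rotation (det +1).
#' Requires at least 3 non-collinear pairs.
#'
#' @param moving N x 3 matrix of points in the sensor frame (mm).
#' @param fixed N x 3 matrix of the same points surveyed in the room frame.
#' @return A `rigid_transform` mapping moving -> fixed.
#' @export
fit_rigid <- function(moving, fixed) {
  moving <- as.matrix(moving)
  fixed <- as.matrix(fixed)
  if (!all(dim(moving) == dim(fixed)) || ncol(moving) != 3L)
    stop("moving and fixed must be N x 3 matrices of equal size")
  if (nrow(moving) < 3L) stop("need at least 3 correspondence pairs")
  mu_m <- colMeans(moving)
  mu_f <- colMeans(fixed)
  M <- sweep(moving, 2, mu_m)
  Fx <- sweep(fixed, 2, mu_f)
  H <- crossprod(M, Fx)
  sv <- svd(H)
  # collinear configurations leave the rotation about the line unconstrained
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300))
    stop("degenerate fiducial configuration (collinear points)")
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  rigid_transform(orthonormalize(R), as.numeric(mu_f - R %*% mu_m))
}

#' Calibrate a sensor into the treatment-room frame
#'
#' Fits the rigid sensor-to-room map from fiducials measured by the sensor
#' against their surveyed room coordinates (correspondence by row order: a
#' calibration jig has labelled markers), then verifies that the RMS
#' residual is below `threshold`. The default threshold of 0.5 mm is half
#' the sub-millimeter tracking accuracy the system targets, so that the
#' calibration contributes at most a minor share of the error budget.
#'
#' @param measured_fiducials N x 3 matrix (sensor frame, mm) or a data
#'   frame from [read_fiducials_csv()].
#' @param room_fiducials matching N x 3 matrix (room frame, mm).
#' @param threshold verification threshold on the RMS residual (mm).
#' @return A `calibration_result` with `sensor_to_room`, `rms_residual`,
#'   `fiducial_count`, per-fiducial `residuals`, the `worst_fiducial`
#'   index and the `passed` flag.
#' @export
calibrate <- function(measured_fiducials, room_fiducials, threshold = 0.5) {
  measured_fiducials <- fiducial_matrix(measured_fiducials)
  room_fiducials <- fiducial_matrix(room_fiducials)
  T <- fit_rigid(measured_fiducials, room_fiducials)
  pred <- apply_transform(T, measured_fiducials)
  res <- sqrt(rowSums((room_fiducials - pred)^2))
  rms <- sqrt(mean(res^2))
  out <- structure(list(sensor_to_room = T, rms_residual = rms,
                        fiducial_count = nrow(measured_fiducials),
                        residuals = res, worst_fiducial = which.max(res),
                        passed = rms <= threshold),
                   class = "calibration_result")
  if (!out$passed)
    warning(sprintf(paste0("calibration verification FAILED: rms residual ",
                           "%.3f mm > %.3f mm (worst fiducial #%d, ",
                           "residual %.3f mm)"),
                    rms, threshold, out$worst_fiducial, max(res)))
  out
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> ", x$fiducial_count, " fiducials, rms ",
      sprintf("%.4f", x$rms_residual), " mm — ",
      if (x$passed) "PASSED" else
        sprintf("FAILED (worst fiducial #%d)", x$worst_fiducial),
      "\n", sep = "")
  invisible(x)
}

fiducial_matrix <- function(x) {
  if (is.data.frame(x) && all(c("x_mm", "y_mm", "z_mm") %in% names(x)))
    x <- as.matrix(x[, c("x_mm", "y_mm", "z_mm")])
  unname(as.matrix(x))
}

#' Fuse per-sensor clouds into a single room-frame cloud
#'
#' Each sensor's cloud is mapped to the room frame by its calibration and
#' the clouds are concatenated; optional voxel thinning (edge in mm)
#' removes duplicate coverage where the sensors' views overlap. The
#' conventional thinning edge is the voxel of the finest registration
#' level (1 mm at 100 points/cm2).
#'
#' @param clouds list of `surface_cloud`, one per sensor.
#' @param calibs list of `calibration_result` (or `rigid_transform`),
#'   one per cloud.
#' @param thin_voxel optional voxel edge (mm) for duplicate thinning.
#' @return The fused `surface_cloud` in room coordinates.
#' @export
fuse <- function(clouds, calibs, thin_voxel = NULL) {
  if (length(clouds) != length(calibs))
    stop("need exactly one calibration per cloud")
  mapped <- mapply(function(cl, ca) {
    T <- if (inherits(ca, "calibration_result")) ca$sensor_to_room else ca
    transform_cloud(T, cl)
  }, clouds, calibs, SIMPLIFY = FALSE)
  pts <- do.call(rbind, lapply(mapped, `[[`, "points"))
  has_n <- all(vapply(mapped, function(c) !is.null(c$normals), TRUE))
  nrm <- if (has_n) do.call(rbind, lapply(mapped, `[[`, "normals"))
  val <- do.call(c, lapply(mapped, `[[`, "valid"))
  out <- surface_cloud(pts, nrm, val)
  if (!is.null(thin_voxel)) out <- downsample_voxel(out, thin_voxel)
  out
}
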