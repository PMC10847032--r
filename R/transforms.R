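#' Rigid-body transforms and six-degree-of-freedom poses
#'
#' The room coordinate frame is right-handed with +x toward the patient's
#' left (LR axis), +y superior (SI) and +z anterior (AP); translations are
#' in mm, rotations in degrees. A `rigid_transform` maps reference-surface
#' coordinates toward the current (target) surface, so the transform
#' returned by the registration *is* the patient motion estimate.
#'
#' Euler angles follow the extrinsic x-y-z convention: rotations about the
#' fixed room axes applied in the order x, then y, then z, i.e.
#' `R = Rz(rz) %*% Ry(ry) %*% Rx(rx)`. For the small (< 5 deg) angles seen
#' in intra-fraction motion the ordering effect is second order; the
#' convention is fixed and documented rather than configurable.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (mm).
#' @return An object of class `rigid_transform` with elements `rotation`
#'   and `translation`.
#' @examples
#' T1 <- rigid_transform(rot_axis_angle(c(0, 0, 1), 30), c(1, 2, 3))
#' compose(T1, rt_inverse(T1))  # identity
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || anyNA(rotation))
    stop("rotation must be a 3x3 numeric matrix")
  if (length(translation) != 3L || anyNA(translation))
    stop("translation must be a length-3 numeric vector")
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-9 || abs(det(rotation) - 1) > 1e-9)
    stop("rotation is not orthonormal with determinant +1 (error ",
         format(err, digits = 3), ")")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
rt_identity <- function() rigid_transform()

#' @export
print.rigid_transform <- function(x, ...) {
  s <- to_sixdof(x)
  cat("<rigid_transform>  t = (",
      paste(sprintf("%.3f", x$translation), collapse = ", "), ") mm;  ",
      "euler xyz = (", paste(sprintf("%.3f", s[4:6]), collapse = ", "),
      ") deg\n", sep = "")
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `compose(A, B)` returns the map "apply `B`, then `A`". The rotation of
#' the result is re-orthonormalised by SVD projection so that long chains
#' of compositions do not drift away from the rotation group.
#'
#' @param A,B `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose <- function(A, B) {
  stopifnot(inherits(A, "rigid_transform"), inherits(B, "rigid_transform"))
  R <- A$rotation %*% B$rotation
  rigid_transform(orthonormalize(R),
                  as.numeric(A$rotation %*% B$translation) + A$translation)
}

#' @rdname compose
#' @param T a `rigid_transform`.
#' @export
rt_inverse <- function(T) {
  stopifnot(inherits(T, "rigid_transform"))
  Rt <- t(T$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% T$translation))
}

# Nearest rotation matrix in Frobenius norm (SVD projection, det +1).
orthonormalize <- function(R) {
  s <- svd(R)
  D <- diag(c(1, 1, sign(det(s$u %*% t(s$v)))))
  s$u %*% D %*% t(s$v)
}

#' Rotation matrix about an axis
#'
#' @param axis length-3 axis (need not be unit).
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @return 3x3 rotation matrix.
#' @export
rot_axis_angle <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Six-degree-of-freedom pose vector
#'
#' A named numeric vector `(tx, ty, tz, rx, ry, rz)`: translations in mm
#' along LR/SI/AP and extrinsic x-y-z Euler angles in degrees about the
#' same fixed axes.
#'
#' @param tx,ty,tz translations (mm).
#' @param rx,ry,rz rotations (deg).
#' @return A named numeric vector of class `sixdof`.
#' @export
sixdof <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0) {
  structure(c(tx = tx, ty = ty, tz = tz, rx = rx, ry = ry, rz = rz),
            class = "sixdof")
}

#' Convert between rigid transforms and six-DoF pose vectors
#'
#' `from_sixdof` builds the transform `R = Rz %*% Ry %*% Rx` with the given
#' translation; `to_sixdof` extracts the extrinsic x-y-z Euler angles.
#' Extraction fails with an explicit error at gimbal lock (|ry| = 90 deg),
#' which is far outside the clinical motion range.
#'
#' @param s a `sixdof` vector (or any named/positional numeric of length 6).
#' @param T a `rigid_transform`.
#' @return `from_sixdof`: a `rigid_transform`; `to_sixdof`: a `sixdof`.
#' @export
from_sixdof <- function(s) {
  s <- as.numeric(s)
  stopifnot(length(s) == 6L)
  R <- rot_axis_angle(c(0, 0, 1), s[6]) %*%
       rot_axis_angle(c(0, 1, 0), s[5]) %*%
       rot_axis_angle(c(1, 0, 0), s[4])
  rigid_transform(orthonormalize(R), s[1:3])
}

#' @rdname from_sixdof
#' @export
to_sixdof <- function(T) {
  stopifnot(inherits(T, "rigid_transform"))
  R <- T$rotation
  sy <- -R[3, 1]
  if (abs(sy) > 1 - 1e-9)
    stop("gimbal lock: ry is at +/-90 deg, Euler extraction is degenerate")
  ry <- asin(sy)
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  sixdof(T$translation[1], T$translation[2], T$translation[3],
         rx * 180 / pi, ry * 180 / pi, rz * 180 / pi)
}

#' Magnitude of a rigid transform
#'
#' Translation norm (mm) and geodesic rotation angle (deg); used for
#' convergence checks and error diagnostics.
#'
#' @param T a `rigid_transform`.
#' @return Named numeric `c(trans_mm =, rot_deg =)`.
#' @export
rt_magnitude <- function(T) {
  tr <- sum(diag(T$rotation))
  ang <- acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
  c(trans_mm = sqrt(sum(T$translation^2)), rot_deg = ang)
}

#' Apply a rigid transform to an N x 3 matrix of points
#'
#' @param T a `rigid_transform`.
#' @param pts N x 3 numeric matrix (mm).
#' @return N x 3 matrix of transformed points.
#' @export
apply_transform <- function(T, pts) {
  stopifnot(inherits(T, "rigid_transform"))
  pts <- as.matrix(pts)
  sweep(pts %*% t(T$rotation), 2, -T$translation)
}
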