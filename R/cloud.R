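#' Surface point clouds
#'
#' A `surface_cloud` holds N points (mm, room or sensor frame), optional
#' unit normals and a per-point validity flag. Points with an invalid flag
#' (e.g. degenerate normal neighborhoods) are kept in the container but
#' excluded from registration.
#'
#' @param points N x 3 numeric matrix (mm).
#' @param normals N x 3 matrix of unit normals, or `NULL`.
#' @param valid logical vector of length N; defaults to all `TRUE`.
#' @return An object of class `surface_cloud`.
#' @export
surface_cloud <- function(points, normals = NULL, valid = NULL) {
  points <- unname(as.matrix(points))
  if (length(points) == 0L) points <- matrix(numeric(0), 0, 3)
  if (ncol(points) != 3L) stop("points must be an N x 3 matrix")
  storage.mode(points) <- "double"
  n <- nrow(points)
  if (!is.null(normals)) {
    normals <- unname(as.matrix(normals))
    storage.mode(normals) <- "double"
    if (!all(dim(normals) == dim(points)))
      stop("normals must match points in dimension")
    len <- sqrt(rowSums(normals^2))
    bad <- is.finite(len) & abs(len - 1) > 1e-6
    if (any(bad, na.rm = TRUE))
      stop(sum(bad), " normals are not unit length")
  }
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (length(valid) != n) stop("valid must have one flag per point")
  structure(list(points = points, normals = normals, valid = as.logical(valid)),
            class = "surface_cloud")
}

#' @rdname surface_cloud
#' @param x a `surface_cloud`.
#' @export
n_points <- function(x) nrow(x$points)

#' @export
print.surface_cloud <- function(x, ...) {
  cat("<surface_cloud> ", n_points(x), " points",
      if (!is.null(x$normals)) " (+normals)" else "",
      if (any(!x$valid)) paste0(", ", sum(!x$valid), " invalid") else "",
      "\n", sep = "")
  invisible(x)
}

# subset rows of a cloud, keeping normals/valid aligned
cloud_subset <- function(cloud, i) {
  surface_cloud(cloud$points[i, , drop = FALSE],
                if (!is.null(cloud$normals)) cloud$normals[i, , drop = FALSE],
                cloud$valid[i])
}

#' Apply a rigid transform to a surface cloud
#'
#' Points are rotated then translated; normals are rotated only. Pairwise
#' distances and normal-to-surface angles are preserved exactly (up to
#' floating point).
#'
#' @param T a `rigid_transform`.
#' @param cloud a `surface_cloud`.
#' @return The transformed `surface_cloud`.
#' @export
transform_cloud <- function(T, cloud) {
  stopifnot(inherits(cloud, "surface_cloud"))
  surface_cloud(apply_transform(T, cloud$points),
                if (!is.null(cloud$normals)) cloud$normals %*% t(T$rotation),
                cloud$valid)
}

#' Oriented-box region of interest
#'
#' The ROI isolates the tracked anatomy (the face) from couch and headrest
#' points. It is an oriented box: a point is inside iff its coordinates in
#' the box frame lie within the closed interval +/- `half_extents`. Using
#' an oriented rather than axis-aligned box makes rotation propagation
#' during tracking exact.
#'
#' @param center box center, length-3 (mm).
#' @param half_extents strictly positive half-sizes, length-3 (mm).
#' @param orientation 3x3 orthonormal matrix (box axes as columns).
#' @return An object of class `region_of_interest`.
#' @export
region_of_interest <- function(center, half_extents, orientation = diag(3)) {
  center <- as.numeric(center)
  half_extents <- as.numeric(half_extents)
  stopifnot(length(center) == 3L, length(half_extents) == 3L)
  if (any(half_extents <= 0)) stop("half_extents must be strictly positive")
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-9)
    stop("orientation must be orthonormal")
  structure(list(center = center, half_extents = half_extents,
                 orientation = orientation),
            class = "region_of_interest")
}

#' @export
print.region_of_interest <- function(x, ...) {
  cat("<region_of_interest> center (",
      paste(sprintf("%.1f", x$center), collapse = ", "),
      ") mm, half-extents (",
      paste(sprintf("%.1f", x$half_extents), collapse = ", "), ") mm\n",
      sep = "")
  invisible(x)
}

#' Crop a cloud to a region of interest
#'
#' Keeps exactly the points inside the closed oriented box; normals and
#' validity flags stay aligned with their points. An empty result is legal
#' (a warning is emitted and the caller decides how to proceed).
#'
#' @param cloud a `surface_cloud`.
#' @param roi a `region_of_interest`.
#' @return The cropped `surface_cloud`.
#' @export
crop <- function(cloud, roi) {
  stopifnot(inherits(cloud, "surface_cloud"),
            inherits(roi, "region_of_interest"))
  if (n_points(cloud) == 0L) stop("cannot crop an empty cloud")
  local <- sweep(cloud$points, 2, roi$center) %*% roi$orientation
  inside <- abs(local[, 1]) <= roi$half_extents[1] &
            abs(local[, 2]) <= roi$half_extents[2] &
            abs(local[, 3]) <= roi$half_extents[3]
  if (!any(inside)) warning("ROI crop produced an empty cloud")
  cloud_subset(cloud, inside)
}

#' Voxel-grid downsampling to a target surface density
#'
#' The cloud is reduced on a cubic voxel grid with edge
#' `sqrt(1 / density)` (density in points per cm2, edge converted to mm);
#' each occupied voxel contributes one representative: the centroid of its
#' points, with the average of their normals re-normalised. The result is
#' independent of point ordering. Densities span the multiscale schedule
#' range 0.2 to 100 points/cm2.
#'
#' @param cloud a `surface_cloud`.
#' @param density target density in points per square centimeter (> 0).
#' @return The downsampled `surface_cloud`.
#' @export
downsample <- function(cloud, density) {
  stopifnot(inherits(cloud, "surface_cloud"))
  if (!is.numeric(density) || length(density) != 1L || density <= 0)
    stop("density must be a single positive number (points per cm2)")
  if (n_points(cloud) == 0L) stop("cannot downsample an empty cloud")
  voxel <- 10 / sqrt(density)  # mm
  downsample_voxel(cloud, voxel)
}

# voxel-grid reduction with explicit edge length (mm)
downsample_voxel <- function(cloud, voxel) {
  pts <- cloud$points
  ijk <- floor(sweep(pts, 2, apply(pts, 2, min)) / voxel)
  key <- ijk[, 1] + 2^20 * ijk[, 2] + 2^40 * ijk[, 3]
  grp <- match(key, key)                       # first-occurrence group id
  cnt <- as.vector(rowsum(rep(1, nrow(pts)), grp))
  cen <- rowsum(pts, grp) / cnt
  nrm <- NULL
  if (!is.null(cloud$normals)) {
    nm <- cloud$normals
    nm[!cloud$valid | !is.finite(nm[, 1]), ] <- 0
    acc <- rowsum(nm, grp)
    len <- sqrt(rowSums(acc^2))
    ok <- len > 1e-9
    acc[ok, ] <- acc[ok, ] / len[ok]
    acc[!ok, ] <- NA_real_
    nrm <- acc
    val <- ok
  } else {
    val <- rep(TRUE, nrow(cen))
  }
  surface_cloud(cen, nrm, val)
}

#' Estimate per-point normals by k-nearest-neighbor PCA
#'
#' The normal at each point is the eigenvector of the smallest eigenvalue
#' of its k-NN covariance, sign-oriented to face `viewpoint` (normally the
#' sensor position). Degenerate neighborhoods (collinear points) get an
#' invalid flag and are excluded from registration downstream. `k = 30` is
#' the conventional choice for depth-camera clouds at mm-scale spacing.
#'
#' @param cloud a `surface_cloud`.
#' @param k number of neighbors (N > k >= 3).
#' @param viewpoint length-3 position the normals should face (mm).
#' @return The cloud with `normals` and `valid` populated.
#' @export
estimate_normals <- function(cloud, k = 30, viewpoint = c(0, 0, 1000)) {
  stopifnot(inherits(cloud, "surface_cloud"))
  n <- n_points(cloud)
  if (k < 3) stop("k must be at least 3")
  if (n <= k) stop("cloud must have more than k points")
  res <- .cpp_normals(cloud$points, as.integer(k), as.numeric(viewpoint))
  surface_cloud(cloud$points, res$normals, cloud$valid & res$valid)
}
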