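#' Virtual pinhole depth camera
#'
#' Camera frame convention: x right, y down, z along the optical axis (all
#' mm); `pose` maps camera coordinates to the room frame. Pixel `(r, c)`
#' corresponds to image-plane coordinates `u = c - 1`, `v = r - 1`.
#'
#' @param fx,fy focal lengths in pixels.
#' @param cx,cy principal point in pixels.
#' @param width,height image resolution in pixels.
#' @param pose `rigid_transform` camera -> room.
#' @param near,far clip distances (mm).
#' @return An object of class `depth_camera`.
#' @export
depth_camera <- function(fx, fy, cx, cy, width, height,
                         pose = rt_identity(), near = 200, far = 1500) {
  if (width <= 0 || height <= 0) stop("resolution must be positive")
  stopifnot(inherits(pose, "rigid_transform"))
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height),
                 pose = pose, near = near, far = far),
            class = "depth_camera")
}

#' Camera pose looking at a target point
#'
#' @param eye camera position (mm, room frame).
#' @param target point the optical axis passes through (mm).
#' @param up approximate room-frame up direction used to fix the roll.
#' @return A `rigid_transform` (camera -> room).
#' @export
look_at <- function(eye, target = c(0, 0, 0), up = c(0, 0, 1)) {
  z <- target - eye
  z <- z / sqrt(sum(z^2))
  x <- c(z[2] * up[3] - z[3] * up[2],
         z[3] * up[1] - z[1] * up[3],
         z[1] * up[2] - z[2] * up[1])
  nx <- sqrt(sum(x^2))
  if (nx < 1e-9) stop("view direction is parallel to 'up'")
  x <- x / nx
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  rigid_transform(cbind(x, y, z), eye)
}

#' Default two-camera couch-mounted geometry
#'
#' Two 848 x 480 stereo-depth-style cameras (65 x 40 degree field of view)
#' flanking the head at about 450 mm range, mounted about 30 cm above the
#' torso plane on either side of the patient, both aimed at the head
#' center (the room origin). This geometry gives each camera an unobscured
#' oblique view of one side of the face, with the forehead and nose seen
#' by both.
#'
#' @param range_mm approximate camera-to-head distance.
#' @return List of two `depth_camera` objects named `left` and `right`.
#' @export
default_cameras <- function(range_mm = 450) {
  fx <- 424 / tan(65 / 2 * pi / 180)   # 65 deg horizontal FOV
  fy <- 240 / tan(40 / 2 * pi / 180)   # 40 deg vertical FOV
  s <- range_mm / 450
  mk <- function(side) {
    eye <- c(side * 310, -150, 280) * s
    depth_camera(fx = fx, fy = fy, cx = 423.5, cy = 239.5,
                 width = 848, height = 480,
                 pose = look_at(eye, c(0, 0, 0), up = c(0, 0, 1)))
  }
  list(left = mk(1), right = mk(-1))
}

#' Depth-camera noise model
#'
#' Axial Gaussian noise applied along each pixel's viewing ray with
#' standard deviation `sigma_mm * (z / ref_depth_mm)^2` (the quadratic
#' depth dependence characteristic of stereo depth sensing), followed by
#' quantisation of the z-depth and optional per-pixel dropout. The same
#' seed and scene always produce the identical frame.
#'
#' @param sigma_mm axial sigma at the reference depth (mm).
#' @param ref_depth_mm reference depth (mm).
#' @param quant_mm quantisation step of the stored depth (mm).
#' @param dropout probability that a pixel returns no depth.
#' @param seed RNG seed.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(sigma_mm = 1.0, ref_depth_mm = 450,
                        quant_mm = 0.25, dropout = 0, seed = 1) {
  if (sigma_mm < 0 || quant_mm < 0 || dropout < 0 || dropout > 1)
    stop("noise parameters must be non-negative (dropout in [0, 1])")
  structure(list(sigma_mm = sigma_mm, ref_depth_mm = ref_depth_mm,
                 quant_mm = quant_mm, dropout = dropout, seed = seed),
            class = "noise_model")
}

#' @rdname noise_model
#' @export
zero_noise <- function() noise_model(sigma_mm = 0, quant_mm = 0, dropout = 0)

#' Render a depth frame of the phantom
#'
#' Z-buffer rasterisation of the phantom mesh under the given rigid pose,
#' seen by a pinhole depth camera: per-pixel visibility honours
#' self-occlusion (the nose can hide a cheek). The noise model perturbs
#' each pixel's range along its viewing ray, then the z-depth is quantised
#' and dropout applied. Valid pixels are back-projected through the camera
#' pose into a room-frame `surface_cloud`.
#'
#' @param phantom a `head_phantom` (or any list with `vertices`/`faces`).
#' @param pose `rigid_transform` applied to the phantom (its motion).
#' @param cam a `depth_camera`.
#' @param noise a `noise_model`; `zero_noise()` for ideal rendering.
#' @param return_image also return the (noisy) z-depth matrix.
#' @return A `surface_cloud` in room coordinates; when `return_image` is
#'   `TRUE`, a list `(cloud, depth)`.
#' @export
render_depth <- function(phantom, pose = rt_identity(), cam,
                         noise = zero_noise(), return_image = FALSE) {
  stopifnot(inherits(cam, "depth_camera"), inherits(noise, "noise_model"))
  V_room <- apply_transform(pose, phantom$vertices)
  V_cam <- apply_transform(rt_inverse(cam$pose), V_room)
  depth <- .cpp_render_depth(V_cam, phantom$faces, cam$fx, cam$fy,
                             cam$cx, cam$cy, cam$width, cam$height,
                             cam$near, cam$far)
  hit <- which(is.finite(depth))
  if (length(hit) == 0L) {
    warning("phantom is entirely outside the camera frustum")
    empty <- surface_cloud(matrix(numeric(0), 0, 3))
    return(if (return_image) list(cloud = empty, depth = depth) else empty)
  }
  rc <- arrayInd(hit, dim(depth))
  u <- rc[, 2] - 1
  v <- rc[, 1] - 1
  dirs <- cbind((u - cam$cx) / cam$fx, (v - cam$cy) / cam$fy, 1)
  norm_d <- sqrt(rowSums(dirs^2))
  z <- depth[hit]
  if (noise$sigma_mm > 0 || noise$quant_mm > 0 || noise$dropout > 0) {
    z <- with_seed(noise$seed, {
      zn <- z
      if (noise$sigma_mm > 0) {
        sigma <- noise$sigma_mm * (zn / noise$ref_depth_mm)^2
        # range perturbation delta along the ray changes z by delta/|dir|
        zn <- zn + stats::rnorm(length(zn), 0, sigma) / norm_d
      }
      if (noise$quant_mm > 0) zn <- round(zn / noise$quant_mm) * noise$quant_mm
      if (noise$dropout > 0)
        zn[stats::runif(length(zn)) < noise$dropout] <- NA_real_
      zn
    })
  }
  keep <- is.finite(z) & z > 0
  pts_cam <- dirs[keep, , drop = FALSE] * z[keep]
  cloud <- surface_cloud(apply_transform(cam$pose, pts_cam))
  if (return_image) {
    img <- depth
    img[hit] <- z
    list(cloud = cloud, depth = img)
  } else cloud
}
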