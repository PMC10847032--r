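#' Parameters of the parametric head phantom
#'
#' The phantom is a superellipsoid cranium with radial facial features
#' (nose ridge, brow, chin, cheeks) added as angular Gaussian bumps, plus
#' a small seeded smooth perturbation standing in for individual surface
#' texture. Semi-axes default to adult head dimensions; feature amplitudes
#' are in mm along the local radial direction.
#'
#' @param a,b,c superellipsoid semi-axes (mm) along LR, SI, AP.
#' @param exponent superellipsoid exponent (2 = ellipsoid; larger is boxier).
#' @param nose_mm,brow_mm,chin_mm,cheek_mm feature amplitudes (mm), each in
#'   \[0, 40\].
#' @param texture_mm amplitude of the seeded smooth perturbation (mm).
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(a = 75, b = 105, c = 88, exponent = 2.5,
                           nose_mm = 25, brow_mm = 6, chin_mm = 10,
                           cheek_mm = 4, texture_mm = 1) {
  amps <- c(nose_mm, brow_mm, chin_mm, cheek_mm, texture_mm)
  if (any(amps < 0) || any(amps > 40))
    stop("feature amplitudes must lie in [0, 40] mm")
  if (any(c(a, b, c) <= 0) || exponent < 2)
    stop("semi-axes must be positive and exponent >= 2")
  structure(list(a = a, b = b, c = c, exponent = exponent,
                 nose_mm = nose_mm, brow_mm = brow_mm, chin_mm = chin_mm,
                 cheek_mm = cheek_mm, texture_mm = texture_mm),
            class = "phantom_params")
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate the head phantom mesh
#'
#' Builds a triangulated head-like surface on a latitude/longitude grid:
#' polar angle `theta` from the superior (+y) pole, azimuth `phi` measured
#' from the anterior (+z) direction, radial distance given by the
#' superellipsoid plus the feature bumps of [phantom_params()]. The mesh
#' (about 39,000 triangles) is deterministic for a given `(params, seed)`
#' and every vertex lies within a 250 mm sphere. Vertices carry anatomical
#' region labels (`nose`, `brow`, `cheek_l`, `cheek_r`, `jaw`, `larynx`,
#' `cranium`) used by the facial-deformation generator.
#'
#' @param params a `phantom_params`.
#' @param seed integer seed for the texture perturbation.
#' @param n_theta,n_phi grid resolution (rows x wrapped columns).
#' @return A list of class `head_phantom` with `vertices` (N x 3, mm),
#'   `faces` (M x 3, 1-based), `labels` (factor per vertex), `params`,
#'   `seed`.
#' @export
make_phantom <- function(params = phantom_params(), seed = 1,
                         n_theta = 101, n_phi = 196) {
  stopifnot(inherits(params, "phantom_params"))
  theta <- seq(0, pi, length.out = n_theta)
  phi <- seq(-pi, pi, length.out = n_phi + 1)[seq_len(n_phi)]
  g <- expand.grid(theta = theta, phi = phi)    # theta varies fastest
  st <- sin(g$theta)
  d <- cbind(st * sin(g$phi), cos(g$theta), st * cos(g$phi))
  m <- params$exponent
  r0 <- (abs(d[, 1] / params$a)^m + abs(d[, 2] / params$b)^m +
         abs(d[, 3] / params$c)^m)^(-1 / m)

  ang_bump <- function(th0, sth, ph0, sph) {
    dph <- (g$phi - ph0 + pi) %% (2 * pi) - pi
    exp(-0.5 * ((g$theta - th0) / sth)^2 - 0.5 * (dph / sph)^2)
  }
  bump <- params$nose_mm  * ang_bump(pi / 2 + 0.10, 0.30, 0, 0.10) +
          params$brow_mm  * ang_bump(pi / 2 - 0.35, 0.10, 0, 0.45) +
          params$chin_mm  * ang_bump(pi / 2 + 0.75, 0.15, 0, 0.25) +
          params$cheek_mm * (ang_bump(pi / 2 + 0.25, 0.25,  0.55, 0.22) +
                             ang_bump(pi / 2 + 0.25, 0.25, -0.55, 0.22))
  texture <- 0
  if (params$texture_mm > 0) {
    texture <- with_seed(seed, {
      acc <- 0
      for (j in 1:6) {
        k1 <- sample(2:6, 1); k2 <- sample(2:6, 1)
        aj <- runif(1, 0, params$texture_mm / 4)
        p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
        acc <- acc + aj * cos(k1 * g$theta + p1) * cos(k2 * g$phi + p2)
      }
      acc * sin(g$theta)  # vanish at the poles so they stay single points
    })
  }
  r <- r0 + bump + texture
  V <- d * r

  # quad grid -> triangles, wrapping in phi
  faces <- matrix(0L, 2 * (n_theta - 1) * n_phi, 3)
  k <- 1L
  idx <- function(i, j) (j - 1L) * n_theta + i
  for (j in seq_len(n_phi)) {
    jn <- if (j == n_phi) 1L else j + 1L
    i <- seq_len(n_theta - 1L)
    f1 <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, jn))
    f2 <- cbind(idx(i, j), idx(i + 1L, jn), idx(i, jn))
    faces[k:(k + 2L * (n_theta - 1L) - 1L), ] <- rbind(f1, f2)
    k <- k + 2L * (n_theta - 1L)
  }

  lab <- rep("cranium", nrow(V))
  th <- g$theta; ph <- g$phi
  cheek <- th > pi / 2 - 0.65 & th < pi / 2 + 0.45 &
           abs(ph) > 0.30 & abs(ph) < 1.1
  lab[cheek & ph > 0] <- "cheek_l"
  lab[cheek & ph < 0] <- "cheek_r"
  lab[th > pi / 2 - 0.55 & th < pi / 2 - 0.15 & abs(ph) < 0.75] <- "brow"
  lab[th > pi / 2 - 0.15 & th < pi / 2 + 0.40 & abs(ph) < 0.28] <- "nose"
  lab[th > pi / 2 + 0.45 & th < pi / 2 + 0.95 & abs(ph) < 0.45] <- "jaw"
  lab[th > pi / 2 + 0.95 & th < pi / 2 + 1.35 & abs(ph) < 0.40] <- "larynx"

  structure(list(vertices = unname(as.matrix(V)), faces = faces,
                 labels = factor(lab), params = params, seed = seed),
            class = "head_phantom")
}

#' @export
print.head_phantom <- function(x, ...) {
  cat("<head_phantom> ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " triangles, area ",
      sprintf("%.0f", phantom_area(x) / 100), " cm^2\n", sep = "")
  invisible(x)
}

#' Total mesh surface area (mm2)
#'
#' @param phantom a `head_phantom`.
#' @return Numeric scalar, mm2.
#' @export
phantom_area <- function(phantom) {
  V <- phantom$vertices
  F <- phantom$faces
  e1 <- V[F[, 2], ] - V[F[, 1], ]
  e2 <- V[F[, 3], ] - V[F[, 1], ]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Default face region of interest for the head phantom
#'
#' An axis-aligned box (at identity orientation) from the forehead to just
#' below the chin, deep enough to include the nose tip while excluding the
#' posterior half of the head (and any couch/headrest structure behind it).
#'
#' @param phantom a `head_phantom` (used only for its scale).
#' @return A `region_of_interest`.
#' @export
default_roi <- function(phantom = NULL) {
  region_of_interest(center = c(0, -15, 75), half_extents = c(75, 82, 58))
}

#' Static neck-support slab
#'
#' A simple flat structure just inferior of the chin, standing in for the
#' clinical neck support. Passed to [simulate_session()] as a static mesh
#' it stays put while the phantom moves, which is the scene feature that
#' makes adaptive region-of-interest propagation matter: a frozen ROI
#' progressively fills with static support points as the head moves away.
#'
#' The surface is contoured (a Gaussian ridge across the SI direction), as
#' clinical supports are; a flat slab would be a degenerate case for
#' point-to-plane registration, which is blind to in-plane sliding.
#'
#' @param x_half half-width (mm).
#' @param y_range inferior-superior extent (mm).
#' @param z0 base height of the support surface (mm).
#' @param ridge_mm height of the contour ridge (mm).
#' @return A mesh list (`vertices`, `faces`).
#' @export
support_mesh <- function(x_half = 80, y_range = c(-150, -40), z0 = 35,
                         ridge_mm = 30) {
  xs <- seq(-x_half, x_half, by = 8)
  ys <- seq(y_range[1], y_range[2], by = 4)
  g <- expand.grid(x = xs, y = ys)
  z <- z0 + ridge_mm * exp(-0.5 * ((g$y + 95) / 20)^2)
  nx <- length(xs)
  faces <- NULL
  for (j in seq_len(length(ys) - 1L)) {
    i <- seq_len(nx - 1L)
    a <- (j - 1L) * nx + i
    faces <- rbind(faces, cbind(a, a + 1L, a + nx),
                   cbind(a + 1L, a + nx + 1L, a + nx))
  }
  list(vertices = unname(cbind(g$x, g$y, z)), faces = faces)
}
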