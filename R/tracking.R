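#' Frame sequences
#'
#' An ordered list of surface frames (room frame, sensors already fused),
#' each a timestamp in seconds plus a `surface_cloud`. Timestamps must be
#' strictly increasing.
#'
#' @param clouds list of `surface_cloud`.
#' @param timestamps numeric vector of seconds, strictly increasing.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(clouds, timestamps) {
  if (length(clouds) != length(timestamps))
    stop("one timestamp per frame required")
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  structure(list(clouds = clouds, timestamps = as.numeric(timestamps)),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat("<frame_sequence> ", length(x$clouds), " frames",
      if (length(x$timestamps))
        sprintf(" over %.2f s", diff(range(x$timestamps))),
      "\n", sep = "")
  invisible(x)
}

#' @rdname frame_sequence
#' @param x a `frame_sequence`.
#' @export
n_frames <- function(x) length(x$clouds)

#' Propagate a region of interest by a motion estimate
#'
#' The box center is mapped by `T` and the orientation is left-multiplied
#' by `T`'s rotation; half-extents are unchanged. Applied with the current
#' total motion estimate this keeps the ROI fixed with respect to the
#' patient's head as it moves.
#'
#' @param roi a `region_of_interest`.
#' @param T a `rigid_transform`.
#' @return The shifted `region_of_interest`.
#' @export
shift_roi <- function(roi, T) {
  stopifnot(inherits(roi, "region_of_interest"),
            inherits(T, "rigid_transform"))
  region_of_interest(as.numeric(apply_transform(T, matrix(roi$center, 1))),
                     roi$half_extents,
                     orthonormalize(T$rotation %*% roi$orientation))
}

#' Tracker configuration
#'
#' Bundles the registration schedule, robust-loss shape, convergence
#' thresholds and normal-estimation settings. All values serialise to YAML
#' ([write_tracker_config()]) so a tracking run is fully reproducible from
#' config + input data.
#'
#' @param schedule a `multiscale_schedule`.
#' @param alpha Barron loss shape (scale is tied to each level's voxel).
#' @param tol_mm,tol_deg per-level ICP convergence thresholds.
#' @param normal_k neighbors for target normal estimation.
#' @param viewpoint normals are oriented to face this point (mm); by
#'   default a point above the anterior face, between the two couch
#'   cameras. Orientation only fixes the sign, which the squared
#'   point-to-plane cost does not depend on.
#' @return A list of class `tracker_config`.
#' @export
tracker_config <- function(schedule = multiscale_schedule(), alpha = 1,
                           tol_mm = 0.01, tol_deg = 0.01, normal_k = 30,
                           viewpoint = c(0, 0, 600)) {
  structure(list(schedule = schedule, alpha = alpha, tol_mm = tol_mm,
                 tol_deg = tol_deg, normal_k = normal_k,
                 viewpoint = viewpoint),
            class = "tracker_config")
}

#' @rdname tracker_config
#' @param cfg a `tracker_config`.
#' @param path YAML file path.
#' @export
write_tracker_config <- function(cfg, path) {
  yaml::write_yaml(list(
    schedule = list(density = cfg$schedule$density,
                    max_dist = cfg$schedule$max_dist,
                    max_iter = cfg$schedule$max_iter),
    alpha = cfg$alpha, tol_mm = cfg$tol_mm, tol_deg = cfg$tol_deg,
    normal_k = cfg$normal_k, viewpoint = cfg$viewpoint), path)
  invisible(path)
}

#' @rdname tracker_config
#' @export
read_tracker_config <- function(path) {
  y <- yaml::read_yaml(path)
  tracker_config(schedule = multiscale_schedule(y$schedule$density,
                                                y$schedule$max_dist,
                                                y$schedule$max_iter),
                 alpha = y$alpha, tol_mm = y$tol_mm, tol_deg = y$tol_deg,
                 normal_k = y$normal_k, viewpoint = unlist(y$viewpoint))
}

#' Sequential surface tracking with adaptive ROI and warm starts
#'
#' For each frame `k` the incoming cloud is cropped with the ROI
#' propagated from the previous motion estimate (the user-defined ROI is
#' only used as given for the first frame), target normals are estimated,
#' and the multiscale registration is warm-started from the previous
#' frame's pose (`identity` for the first frame). The ROI for frame `k+1`
#' is always derived from the initial ROI and the *current total* estimate
#' (`shift_roi(roi0, T_k)`) rather than incrementally chained, so errors
#' cannot accumulate in the box pose. A frame whose crop is empty or whose
#' registration fails is flagged (`converged = FALSE`), carries the
#' previous estimate forward and tracking continues with the last good
#' ROI.
#'
#' @param frames a `frame_sequence`.
#' @param reference `surface_cloud` baseline (frame 0 of the session, a
#'   prior session, or a planning-CT surface imported as PLY in room
#'   coordinates).
#' @param roi0 initial `region_of_interest`; must intersect frame 1.
#' @param cfg a `tracker_config`.
#' @param verbose print one line per frame.
#' @return A motion-trace data frame (columns
#'   `t_s, tx_mm, ty_mm, tz_mm, rx_deg, ry_deg, rz_deg, converged,
#'   final_cost`), with the per-frame `registration_result`s in
#'   `attr(, "diagnostics")`.
#' @export
track <- function(frames, reference, roi0, cfg = tracker_config(),
                  verbose = FALSE) {
  stopifnot(inherits(frames, "frame_sequence"),
            inherits(reference, "surface_cloud"),
            inherits(roi0, "region_of_interest"))
  pyramid <- build_reference_pyramid(reference, cfg$schedule)
  nf <- n_frames(frames)
  T_prev <- rt_identity()
  roi_prev <- roi0
  rows <- vector("list", nf)
  diagn <- vector("list", nf)
  for (k in seq_len(nf)) {
    frame <- frames$clouds[[k]]
    ok <- TRUE
    res <- NULL
    tgt <- tryCatch(suppressWarnings(crop(frame, roi_prev)),
                    error = function(e) NULL)
    if (is.null(tgt) || n_points(tgt) <= cfg$normal_k) {
      ok <- FALSE
    } else {
      tgt <- estimate_normals(tgt, k = cfg$normal_k,
                              viewpoint = cfg$viewpoint)
      res <- tryCatch(
        multiscale_register(tgt, pyramid, init = T_prev,
                            alpha = cfg$alpha,
                            tol_mm = cfg$tol_mm, tol_deg = cfg$tol_deg),
        error = function(e) NULL)
      if (is.null(res)) ok <- FALSE
    }
    if (ok) {
      T_prev <- res$transform
      roi_prev <- shift_roi(roi0, T_prev)
    }
    s <- to_sixdof(T_prev)
    rows[[k]] <- data.frame(t_s = frames$timestamps[k],
                            tx_mm = s[["tx"]], ty_mm = s[["ty"]],
                            tz_mm = s[["tz"]], rx_deg = s[["rx"]],
                            ry_deg = s[["ry"]], rz_deg = s[["rz"]],
                            converged = ok && isTRUE(res$converged),
                            final_cost = if (ok) res$final_cost else NA_real_)
    diagn[[k]] <- res
    if (verbose)
      message(sprintf("frame %d/%d: t=(%.2f, %.2f, %.2f) mm r=(%.2f, %.2f, %.2f) deg%s",
                      k, nf, s[["tx"]], s[["ty"]], s[["tz"]],
                      s[["rx"]], s[["ry"]], s[["rz"]],
                      if (!ok) "  [LOST]" else ""))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "diagnostics") <- diagn
  out
}
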