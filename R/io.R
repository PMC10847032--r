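#' Read and write surface clouds as PLY
#'
#' Supports ASCII and binary little-endian PLY with float32 vertex
#' properties `x, y, z` and optionally `nx, ny, nz` (mm units). This is the
#' interchange format for reference surfaces (including surfaces exported
#' from a planning CT in room coordinates) and for simulator output.
#'
#' @param cloud a `surface_cloud`.
#' @param path file path.
#' @param format `"binary"` (little-endian, default) or `"ascii"`.
#' @return `write_ply` returns `path` invisibly; `read_ply` returns a
#'   `surface_cloud`.
#' @export
write_ply <- function(cloud, path, format = c("binary", "ascii")) {
  stopifnot(inherits(cloud, "surface_cloud"))
  format <- match.arg(format)
  n <- n_points(cloud)
  has_n <- !is.null(cloud$normals)
  hdr <- c("ply",
           if (format == "binary") "format binary_little_endian 1.0"
           else "format ascii 1.0",
           "comment sgrtrack surface cloud (mm)",
           paste("element vertex", n),
           "property float x", "property float y", "property float z",
           if (has_n) c("property float nx", "property float ny",
                        "property float nz"),
           "end_header")
  dat <- cloud$points
  if (has_n) {
    nm <- cloud$normals
    nm[!is.finite(nm)] <- 0
    dat <- cbind(dat, nm)
  }
  if (format == "ascii") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    if (n > 0)
      writeLines(apply(format_ply_num(dat), 1, paste, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    if (n > 0)
      writeBin(as.numeric(t(dat)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

format_ply_num <- function(m) {
  matrix(formatC(m, format = "g", digits = 9), nrow(m), ncol(m))
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  raw_all <- readBin(path, "raw", file.size(path))
  pos <- grepRaw("end_header", raw_all, fixed = TRUE)
  if (length(pos) == 0L) stop("PLY header not terminated")
  nl <- grepRaw("\n", raw_all, offset = pos[1], fixed = TRUE)
  if (length(nl) == 0L) stop("PLY header not terminated")
  body_from <- nl[1] + 1L
  hdr <- strsplit(rawToChar(raw_all[seq_len(nl[1])]), "\r?\n")[[1]]
  body <- raw_all[seq.int(body_from, length.out = length(raw_all) - body_from + 1L)]
  if (hdr[1] != "ply") stop("not a PLY file: ", path)
  fmt <- grep("^format ", hdr, value = TRUE)
  binary <- grepl("binary_little_endian", fmt)
  if (!binary && !grepl("ascii", fmt))
    stop("unsupported PLY format: ", fmt)
  el <- grep("^element ", hdr, value = TRUE)
  if (length(el) != 1L || !grepl("^element vertex ", el))
    stop("only single-element vertex PLY files are supported")
  n <- as.integer(sub("^element vertex ", "", el))
  props <- sub("^property\\s+\\S+\\s+", "", grep("^property ", hdr, value = TRUE))
  ptypes <- sub("^property\\s+(\\S+).*$", "\\1", grep("^property ", hdr, value = TRUE))
  if (!all(ptypes %in% c("float", "float32")))
    stop("only float32 vertex properties are supported")
  np <- length(props)
  if (n == 0L) {
    dat <- matrix(numeric(0), 0, np)
  } else if (binary) {
    dat <- matrix(readBin(body, "numeric", n * np, size = 4L,
                          endian = "little"), n, np, byrow = TRUE)
  } else {
    dat <- matrix(scan(text = rawToChar(body), n = n * np, quiet = TRUE),
                  n, np, byrow = TRUE)
  }
  colnames(dat) <- props
  need <- c("x", "y", "z")
  if (!all(need %in% props)) stop("PLY must contain x, y, z properties")
  pts <- dat[, need, drop = FALSE]
  nrm <- NULL
  if (all(c("nx", "ny", "nz") %in% props)) {
    nrm <- dat[, c("nx", "ny", "nz"), drop = FALSE]
    len <- sqrt(rowSums(nrm^2))
    ok <- len > 1e-6
    nrm[ok, ] <- nrm[ok, ] / len[ok]   # undo float32 rounding
    nrm[!ok, ] <- NA_real_
    dimnames(nrm) <- NULL
    return(surface_cloud(unname(pts), nrm, ok))
  }
  surface_cloud(unname(pts))
}

#' Read and write 6-DoF motion traces as CSV
#'
#' The trace dialect has header
#' `t_s,tx_mm,ty_mm,tz_mm,rx_deg,ry_deg,rz_deg`, UTF-8, '.' decimal, one
#' row per frame, timestamps strictly increasing. Extra columns (e.g.
#' `converged`, `final_cost` from tracking) are preserved on write and
#' ignored by consumers that do not need them.
#'
#' @param trace a data frame in the trace dialect.
#' @param path file path.
#' @return `read_trace_csv` returns the trace data frame.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(is.data.frame(trace))
  need <- trace_cols()
  if (!all(need %in% names(trace)))
    stop("trace must contain columns ", paste(need, collapse = ", "))
  utils::write.csv(trace[, c(need, setdiff(names(trace), need))],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

trace_cols <- function() {
  c("t_s", "tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg", "rz_deg")
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  tr <- utils::read.csv(path)
  if (!all(trace_cols() %in% names(tr)))
    stop("not a motion-trace CSV: ", path)
  if (is.unsorted(tr$t_s, strictly = TRUE))
    stop("trace timestamps must be strictly increasing")
  tr
}

#' Read fiducial coordinates for calibration
#'
#' CSV dialect `label,x_mm,y_mm,z_mm`. Correspondence between the measured
#' and surveyed lists is by row order (a calibration jig has known labels).
#'
#' @param path file path.
#' @return data frame with columns `label`, `x_mm`, `y_mm`, `z_mm`.
#' @export
read_fiducials_csv <- function(path) {
  fd <- utils::read.csv(path)
  need <- c("label", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(fd)))
    stop("fiducial CSV must contain columns ", paste(need, collapse = ", "))
  fd
}

#' Store and load a sensor calibration as JSON
#'
#' The 4x4 homogeneous sensor-to-room matrix is stored row-major together
#' with the RMS fiducial residual and a timestamp.
#'
#' @param calib a `calibration_result` from [calibrate()].
#' @param path file path.
#' @return `read_calibration_json` returns a `calibration_result`.
#' @export
write_calibration_json <- function(calib, path) {
  stopifnot(inherits(calib, "calibration_result"))
  M <- rbind(cbind(calib$sensor_to_room$rotation,
                   calib$sensor_to_room$translation), c(0, 0, 0, 1))
  jsonlite::write_json(
    list(matrix_row_major = as.numeric(t(M)),
         rms_residual_mm = calib$rms_residual,
         fiducial_count = calib$fiducial_count,
         passed = calib$passed,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  M <- matrix(j$matrix_row_major, 4, 4, byrow = TRUE)
  structure(list(sensor_to_room = rigid_transform(M[1:3, 1:3], M[1:3, 4]),
                 rms_residual = j$rms_residual_mm,
                 fiducial_count = j$fiducial_count,
                 passed = isTRUE(j$passed), worst_fiducial = NA_integer_,
                 residuals = NULL),
            class = "calibration_result")
}

#' Read and write 16-bit depth images
#'
#' Depth frames are stored as 16-bit grayscale PNG at 0.1 mm per unit
#' (range 0 to 6553.5 mm; 0 marks invalid pixels) with a JSON sidecar
#' holding the camera intrinsics and pose so a frame can be re-projected
#' without the session that produced it.
#'
#' @param depth numeric matrix of z-depths (mm), `NA` for invalid pixels.
#' @param path PNG path; the sidecar is written to `paste0(path, ".json")`
#'   when `camera` is given.
#' @param camera optional `depth_camera` to store in the sidecar.
#' @return `read_depth_png` returns a list with `depth` (matrix, mm, `NA`
#'   invalid) and `camera` (or `NULL` when no sidecar is present).
#' @export
write_depth_png <- function(depth, path, camera = NULL) {
  img <- round(depth * 10)
  img[!is.finite(img)] <- 0L
  storage.mode(img) <- "integer"
  .cpp_write_png16(img, path.expand(path))
  if (!is.null(camera)) {
    jsonlite::write_json(
      list(fx = camera$fx, fy = camera$fy, cx = camera$cx, cy = camera$cy,
           width = camera$width, height = camera$height,
           near_mm = camera$near, far_mm = camera$far,
           mm_per_unit = 0.1,
           pose_row_major = as.numeric(t(rbind(cbind(camera$pose$rotation,
                                                     camera$pose$translation),
                                               c(0, 0, 0, 1))))),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_depth_png
#' @export
read_depth_png <- function(path) {
  img <- png::readPNG(path)
  depth <- img * 65535 / 10
  depth[depth == 0] <- NA_real_
  cam <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    j <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    M <- matrix(j$pose_row_major, 4, 4, byrow = TRUE)
    cam <- depth_camera(fx = j$fx, fy = j$fy, cx = j$cx, cy = j$cy,
                        width = j$width, height = j$height,
                        pose = rigid_transform(M[1:3, 1:3], M[1:3, 4]),
                        near = j$near_mm, far = j$far_mm)
  }
  list(depth = depth, camera = cam)
}
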