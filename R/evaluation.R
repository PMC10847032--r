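#' Tracking error against ground truth
#'
#' The tracking error is the difference between the motion measured by
#' the tracker and the ground-truth motion trace. The truth (normally the
#' denser signal) is linearly interpolated to the measured timestamps and
#' subtracted per axis: translation errors in mm, rotation errors as the
#' component-wise Euler-angle difference in deg (valid in the small-angle
#' regime of head motion, <= 5 deg). The geodesic rotation angle between
#' measured and true orientation is reported as a diagnostic column.
#'
#' @param measured motion-trace data frame from [track()].
#' @param truth ground-truth motion-trace data frame.
#' @return An `error_trace` data frame: `t_s`, `ex_mm`, `ey_mm`, `ez_mm`,
#'   `erx_deg`, `ery_deg`, `erz_deg`, `rot_geodesic_deg`.
#' @export
align_and_diff <- function(measured, truth) {
  stopifnot(is.data.frame(measured), is.data.frame(truth))
  lo <- max(min(measured$t_s), min(truth$t_s))
  hi <- min(max(measured$t_s), max(truth$t_s))
  if (lo > hi) stop("measured and truth traces do not overlap in time")
  keep <- measured$t_s >= lo & measured$t_s <= hi
  m <- measured[keep, , drop = FALSE]
  axes <- trace_cols()[-1]
  tr_i <- vapply(axes, function(cn)
    stats::approx(truth$t_s, truth[[cn]], xout = m$t_s, ties = "ordered")$y,
    numeric(nrow(m)))
  err <- as.matrix(m[, axes]) - tr_i
  geo <- vapply(seq_len(nrow(m)), function(i) {
    Tm <- from_sixdof(as.numeric(m[i, axes]))
    Tt <- from_sixdof(as.numeric(tr_i[i, ]))
    unname(rt_magnitude(compose(Tm, rt_inverse(Tt)))["rot_deg"])
  }, numeric(1))
  out <- data.frame(t_s = m$t_s, ex_mm = err[, 1], ey_mm = err[, 2],
                    ez_mm = err[, 3], erx_deg = err[, 4],
                    ery_deg = err[, 5], erz_deg = err[, 6],
                    rot_geodesic_deg = geo)
  class(out) <- c("error_trace", "data.frame")
  out
}

#' Per-axis error summary statistics
#'
#' For each axis: mean, sample standard deviation (n - 1), quartiles by
#' linear interpolation, whiskers at 1.5x the interquartile range clipped
#' to the data range, and the mean absolute error used by the accuracy
#' gates. Requires at least two samples (the standard deviation is
#' undefined for one).
#'
#' @param err an `error_trace` from [align_and_diff()].
#' @return A data frame, one row per axis: `axis`, `n`, `mean`, `sd`,
#'   `p25`, `p50`, `p75`, `whisker_lo`, `whisker_hi`, `mean_abs`.
#' @export
summarize_errors <- function(err) {
  axes <- c("ex_mm", "ey_mm", "ez_mm", "erx_deg", "ery_deg", "erz_deg")
  stopifnot(all(axes %in% names(err)))
  if (nrow(err) < 2L)
    stop("need at least 2 samples (sd undefined for a single sample)")
  rows <- lapply(axes, function(a) {
    x <- err[[a]]
    q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
    iqr <- q[3] - q[1]
    data.frame(axis = a, n = length(x), mean = mean(x), sd = stats::sd(x),
               p25 = q[1], p50 = q[2], p75 = q[3],
               whisker_lo = max(min(x), q[1] - 1.5 * iqr),
               whisker_hi = min(max(x), q[3] + 1.5 * iqr),
               mean_abs = mean(abs(x)))
  })
  do.call(rbind, rows)
}

#' Benchmark report over one or more tracked scenarios
#'
#' Produces the per-axis error summary for every scenario (and, when a
#' scenario has frames flagged as deformed, separately for its rigid and
#' deformation segments), together with pass/fail verdicts against the
#' configured accuracy gates (default: mean absolute error below 1 mm per
#' translation axis and 1 deg per rotation axis).
#'
#' @param scenarios named list; each element a list with `measured`,
#'   `truth` and optionally `segments` (character per measured frame,
#'   e.g. `"rigid"`/`"deformed"`).
#' @param gate_mm,gate_deg accuracy gates on the per-axis mean absolute
#'   error.
#' @param out_dir optional directory; when given, writes `report.json`,
#'   `summary.csv` and `boxplot_data.csv` (quartiles/whiskers per axis).
#' @return A data frame of class `benchmark_report`: one row per
#'   scenario/segment/axis with the summary statistics, `gate` and
#'   `passed`.
#' @export
benchmark_report <- function(scenarios, gate_mm = 1, gate_deg = 1,
                             out_dir = NULL) {
  stopifnot(is.list(scenarios), length(names(scenarios)) == length(scenarios))
  rows <- list()
  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    if (is.null(sc$measured) || is.null(sc$truth)) {
      warning("scenario '", nm, "' is missing measured or truth; skipped")
      next
    }
    err <- align_and_diff(sc$measured, sc$truth)
    segs <- if (is.null(sc$segments)) rep("all", nrow(sc$measured))
            else as.character(sc$segments)
    segs <- segs[seq_len(nrow(err))]
    for (sg in unique(segs)) {
      s <- summarize_errors(err[segs == sg, , drop = FALSE])
      s$scenario <- nm
      s$segment <- sg
      s$gate <- ifelse(grepl("_mm$", s$axis), gate_mm, gate_deg)
      s$passed <- s$mean_abs < s$gate
      rows[[length(rows) + 1L]] <- s
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("scenario", "segment", "axis", "n", "mean", "sd",
                 "p25", "p50", "p75", "whisker_lo", "whisker_hi",
                 "mean_abs", "gate", "passed")]
  rownames(out) <- NULL
  class(out) <- c("benchmark_report", "data.frame")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(out[, c("scenario", "segment", "axis",
                             "p25", "p50", "p75",
                             "whisker_lo", "whisker_hi")],
                     file.path(out_dir, "boxplot_data.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(gates = list(mm = gate_mm, deg = gate_deg),
                              all_passed = all(out$passed),
                              summary = out),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}
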