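#' Anterior-posterior acceleration trace
#'
#' The basic container of the package: a tibble with one row per sample and
#' columns `sample` (1-based index), `time` (seconds from the first sample)
#' and `accel` (anterior-posterior acceleration; the unit is recorded but
#' never interpreted). The sampling rate and sensor placement travel as
#' attributes so a trace can be piped through the detector without extra
#' bookkeeping.
#'
#' @param accel Numeric vector of AP acceleration samples (no missing values,
#'   at least 2 samples).
#' @param fs Sampling rate in samples/s (positive).
#' @param placement One of `"lower_back"`, `"heel_left"`, `"heel_right"`.
#' @param units Unit label, e.g. `"g"` or `"m/s^2"` (recorded only).
#' @return A tibble of class `"accel_trace"` with columns `sample`, `time`,
#'   `accel` and attributes `fs`, `placement`, `units`.
#' @examples
#' tr <- accel_trace(sin(2 * pi * 2 * (0:499) / 100), fs = 100)
#' trace_fs(tr)
#' @export
accel_trace <- function(accel, fs,
                        placement = c("lower_back", "heel_left", "heel_right"),
                        units = "g") {
  placement <- match.arg(placement)
  accel <- as.double(accel)
  if (length(accel) < 2) {
    abort_stage("an acceleration trace needs at least 2 samples", "stepmatch_invalid_trace")
  }
  if (anyNA(accel) || any(!is.finite(accel))) {
    abort_stage("acceleration trace contains missing or non-finite values",
                "stepmatch_invalid_trace")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort_stage("sampling rate `fs` must be a single positive number",
                "stepmatch_invalid_trace")
  }
  out <- tibble::tibble(
    sample = seq_along(accel),
    time = (seq_along(accel) - 1) / fs,
    accel = accel
  )
  attr(out, "fs") <- as.double(fs)
  attr(out, "placement") <- placement
  attr(out, "units") <- units
  class(out) <- c("accel_trace", class(out))
  out
}

#' @rdname accel_trace
#' @param x An `accel_trace` or `marker_trace`.
#' @export
trace_fs <- function(x) attr(x, "fs")

#' @rdname accel_trace
#' @export
trace_placement <- function(x) attr(x, "placement") %||% attr(x, "site")

# rebuild an accel_trace from a plain numeric vector, inheriting metadata
retrace <- function(accel, like, fs = trace_fs(like)) {
  accel_trace(accel, fs = fs, placement = attr(like, "placement"),
              units = attr(like, "units"))
}

#' Segmentation window
#'
#' A closed 1-based sample window `[start, end]` marking the manually
#' segmented part of a gait episode (from some samples before the first
#' heel strike to some samples after the last included one). Its length is
#' `end - start + 1`.
#'
#' @param start,end First and last sample index (1-based, inclusive),
#'   `1 <= start < end`.
#' @return A list of class `"seg_window"` with elements `start` and `end`.
#' @export
seg_window <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != 1 || length(end) != 1 || is.na(start) || is.na(end) ||
      start < 1 || end <= start) {
    abort_stage(sprintf("invalid segment window [%s, %s]: need 1 <= start < end",
                        start, end), "stepmatch_invalid_window")
  }
  structure(list(start = start, end = end), class = "seg_window")
}

#' @export
print.seg_window <- function(x, ...) {
  cat(sprintf("<seg_window> samples [%d, %d] (%d samples)\n",
              x$start, x$end, x$end - x$start + 1))
  invisible(x)
}

#' Extract a segment of a trace
#'
#' Returns the samples inside the window as a new trace. The window is kept
#' alongside (attribute `window`) and the `sample` column retains the
#' original raw-trace indices, so positions in the segment are always
#' recoverable in raw coordinates.
#'
#' @param trace An [accel_trace()].
#' @param window A [seg_window()] valid for the trace.
#' @return An `accel_trace` covering `window`, with attribute `window` and
#'   original `sample` indices.
#' @export
segment_trace <- function(trace, window) {
  stopifnot(inherits(trace, "accel_trace"), inherits(window, "seg_window"))
  n <- nrow(trace)
  if (window$end > n) {
    abort_stage(sprintf("segment window [%d, %d] exceeds trace length %d",
                        window$start, window$end, n), "stepmatch_invalid_window")
  }
  out <- retrace(trace$accel[window$start:window$end], trace)
  out$sample <- seq(window$start, window$end)
  out$time <- (out$sample - 1) / trace_fs(trace)
  attr(out, "window") <- window
  out
}

#' Read an acceleration trace from delimited text
#'
#' One row per sample; the acceleration column is selected by name or index.
#' The sampling rate is always supplied by the caller (never inferred from
#' the file).
#'
#' @param path Path to a delimited text file.
#' @param fs Sampling rate in samples/s.
#' @param placement Sensor placement, see [accel_trace()].
#' @param col Column holding the AP acceleration, by name or 1-based index
#'   (default 1).
#' @param delim Field delimiter (default `","`).
#' @param header Logical; does the file start with a header row? Defaults to
#'   `TRUE` when `col` is a name, `FALSE` otherwise.
#' @param invert_ap Negate the signal (for sensors mounted with opposite
#'   polarity; positive is taken as anterior).
#' @param units Unit label, recorded only.
#' @return An [accel_trace()].
#' @export
read_trace <- function(path, fs,
                       placement = c("lower_back", "heel_left", "heel_right"),
                       col = 1, delim = ",", header = is.character(col),
                       invert_ap = FALSE, units = "g") {
  placement <- match.arg(placement)
  if (!file.exists(path)) {
    abort_stage(paste0("trace file not found: ", path), "stepmatch_parse_error")
  }
  dat <- tryCatch(
    readr::read_delim(path, delim = delim, col_names = header == TRUE,
                      show_col_types = FALSE, progress = FALSE,
                      col_types = readr::cols(.default = readr::col_character())),
    error = function(e) abort_stage(paste0("unreadable trace file ", path, ": ",
                                           conditionMessage(e)),
                                    "stepmatch_parse_error")
  )
  if (nrow(dat) == 0) {
    abort_stage(paste0("trace file is empty: ", path), "stepmatch_parse_error")
  }
  if (is.character(col) && !col %in% names(dat)) {
    abort_stage(sprintf("column '%s' not found in %s (columns: %s)",
                        col, path, paste(names(dat), collapse = ", ")),
                "stepmatch_parse_error")
  }
  if (is.numeric(col) && col > ncol(dat)) {
    abort_stage(sprintf("column %d requested but %s has only %d column(s)",
                        col, path, ncol(dat)), "stepmatch_parse_error")
  }
  raw <- dat[[col]]
  vals <- suppressWarnings(as.numeric(raw))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    abort_stage(sprintf("non-numeric value '%s' at data row %d, column %s of %s",
                        raw[bad], bad, as.character(col), path),
                "stepmatch_parse_error")
  }
  if (invert_ap) vals <- -vals
  accel_trace(vals, fs = fs, placement = placement, units = units)
}

#' Write an acceleration trace to delimited text
#'
#' Inverse of [read_trace()]: one sample per row, single column `accel`,
#' numeric content preserved to full double precision.
#'
#' @param trace An [accel_trace()].
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, delim = ",") {
  stopifnot(inherits(trace, "accel_trace"))
  readr::write_delim(tibble::tibble(accel = trace$accel), path, delim = delim)
  invisible(path)
}

#' Optical marker trace
#'
#' Per-sample 3-D marker positions (mm) with a visibility mask, as produced
#' by an optoelectronic motion tracking system. Axes are labelled `ap`
#' (anterior-posterior, the walking direction), `ml` (medio-lateral) and
#' `vert` (vertical).
#'
#' @param ap,ml,vert Numeric position vectors (mm), equal length.
#' @param visible Logical vector, same length; `FALSE` where the marker was
#'   not tracked.
#' @param fs Sampling rate in samples/s.
#' @param site One of `"heel_left"`, `"heel_right"`, `"lower_back"`.
#' @param marker_id Marker label used for tie-breaking in [select_marker()].
#' @return A tibble of class `"marker_trace"` with columns `sample`, `time`,
#'   `ap`, `ml`, `vert`, `visible`.
#' @export
marker_trace <- function(ap, ml = rep(0, length(ap)), vert = rep(0, length(ap)),
                         visible = rep(TRUE, length(ap)), fs = 200,
                         site = c("heel_left", "heel_right", "lower_back"),
                         marker_id = "m1") {
  site <- match.arg(site)
  n <- length(ap)
  if (length(ml) != n || length(vert) != n || length(visible) != n) {
    abort_stage("marker position and visibility vectors must have equal length",
                "stepmatch_invalid_trace")
  }
  if (!is.numeric(fs) || fs <= 0) {
    abort_stage("marker sampling rate must be positive", "stepmatch_invalid_trace")
  }
  out <- tibble::tibble(
    sample = seq_len(n),
    time = (seq_len(n) - 1) / fs,
    ap = as.double(ap), ml = as.double(ml), vert = as.double(vert),
    visible = as.logical(visible)
  )
  attr(out, "fs") <- as.double(fs)
  attr(out, "site") <- site
  attr(out, "marker_id") <- as.character(marker_id)
  class(out) <- c("marker_trace", class(out))
  out
}

#' Read a marker trace from CSV
#'
#' Expects x/y/z position columns for one marker plus (optionally) a
#' visibility column. An empty or NaN position cell also marks the sample as
#' not visible (occluded markers are exported that way by tracking software).
#'
#' @param path CSV file path.
#' @param fs Sampling rate in samples/s.
#' @param site,marker_id See [marker_trace()].
#' @param cols Named character vector mapping `ap`, `ml`, `vert` to file
#'   column names.
#' @param visible_col Optional name of a logical/0-1 visibility column.
#' @param delim Field delimiter.
#' @return A [marker_trace()].
#' @export
read_marker_trace <- function(path, fs,
                              site = c("heel_left", "heel_right", "lower_back"),
                              marker_id = "m1",
                              cols = c(ap = "ap", ml = "ml", vert = "vert"),
                              visible_col = NULL, delim = ",") {
  site <- match.arg(site)
  if (!file.exists(path)) {
    abort_stage(paste0("marker file not found: ", path), "stepmatch_parse_error")
  }
  dat <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  for (ax in c("ap", "ml", "vert")) {
    if (!cols[[ax]] %in% names(dat)) {
      abort_stage(sprintf("marker file %s lacks column '%s' (for axis %s)",
                          path, cols[[ax]], ax), "stepmatch_parse_error")
    }
  }
  ap <- suppressWarnings(as.numeric(dat[[cols[["ap"]]]]))
  ml <- suppressWarnings(as.numeric(dat[[cols[["ml"]]]]))
  vert <- suppressWarnings(as.numeric(dat[[cols[["vert"]]]]))
  visible <- !(is.na(ap) | is.na(ml) | is.na(vert))
  if (!is.null(visible_col)) {
    visible <- visible & as.logical(dat[[visible_col]])
  }
  ap[!visible] <- 0; ml[!visible] <- 0; vert[!visible] <- 0
  marker_trace(ap, ml, vert, visible, fs = fs, site = site, marker_id = marker_id)
}

#' Resample a trace to a lower sampling rate
#'
#' Generic over [accel_trace()] and [marker_trace()]. The default mode for an
#' integer rate ratio is plain decimation (every k-th sample kept, no
#' anti-alias filter), which preserves the originally measured values; linear
#' interpolation onto the target time grid is available as an alternative and
#' is used automatically for non-integer ratios. Visibility masks are
#' resampled conservatively: a target sample is visible only if all source
#' samples it draws on are visible. Upsampling is refused unless
#' `allow_upsample = TRUE` (then linear interpolation is used).
#'
#' @param x An `accel_trace` or `marker_trace`.
#' @param target_fs Target sampling rate in samples/s.
#' @param method `"decimate"` (default) or `"linear"`.
#' @param allow_upsample Permit `target_fs > fs`.
#' @return An object of the same class at `target_fs`, duration preserved
#'   within one sample period.
#' @export
resample_to <- function(x, target_fs, method = c("decimate", "linear"),
                        allow_upsample = FALSE) {
  UseMethod("resample_to")
}

resample_plan <- function(fs, n, target_fs, method, allow_upsample) {
  if (target_fs <= 0) abort_stage("target fs must be positive", "stepmatch_resample_error")
  if (target_fs > fs && !allow_upsample) {
    abort_stage(sprintf("upsampling %g -> %g samples/s requires allow_upsample = TRUE",
                        fs, target_fs), "stepmatch_resample_error")
  }
  ratio <- fs / target_fs
  integer_ratio <- isTRUE(all.equal(ratio, round(ratio))) && ratio >= 1
  if (method == "decimate" && integer_ratio) {
    list(mode = "decimate", k = as.integer(round(ratio)),
         idx = seq(1L, n, by = as.integer(round(ratio))))
  } else {
    t_new <- seq(0, by = 1 / target_fs, length.out = max(2L, floor((n - 1) * target_fs / fs) + 1L))
    list(mode = "linear", t_new = t_new)
  }
}

#' @rdname resample_to
#' @export
resample_to.accel_trace <- function(x, target_fs, method = c("decimate", "linear"),
                                    allow_upsample = FALSE) {
  method <- match.arg(method)
  fs <- trace_fs(x)
  if (isTRUE(all.equal(fs, target_fs))) return(x)
  plan <- resample_plan(fs, nrow(x), target_fs, method, allow_upsample)
  vals <- if (plan$mode == "decimate") {
    x$accel[plan$idx]
  } else {
    stats::approx(x$time, x$accel, xout = plan$t_new, rule = 2)$y
  }
  retrace(vals, x, fs = target_fs)
}

#' @rdname resample_to
#' @export
resample_to.marker_trace <- function(x, target_fs, method = c("decimate", "linear"),
                                     allow_upsample = FALSE) {
  method <- match.arg(method)
  fs <- trace_fs(x)
  if (isTRUE(all.equal(fs, target_fs))) return(x)
  plan <- resample_plan(fs, nrow(x), target_fs, method, allow_upsample)
  if (plan$mode == "decimate") {
    k <- plan$k
    idx <- plan$idx
    # conservative visibility: all k source samples in the block must be visible
    vis <- vapply(idx, function(i) {
      all(x$visible[i:min(i + k - 1L, nrow(x))])
    }, logical(1))
    marker_trace(x$ap[idx], x$ml[idx], x$vert[idx], vis, fs = target_fs,
                 site = attr(x, "site"), marker_id = attr(x, "marker_id"))
  } else {
    t_new <- plan$t_new
    f <- function(v) stats::approx(x$time, v, xout = t_new, rule = 2)$y
    # a linearly interpolated sample is visible only if both bracketing
    # source samples are visible
    vis_num <- stats::approx(x$time, as.numeric(x$visible), xout = t_new,
                             rule = 2)$y
    marker_trace(f(x$ap), f(x$ml), f(x$vert), vis_num >= 1 - 1e-9,
                 fs = target_fs, site = attr(x, "site"),
                 marker_id = attr(x, "marker_id"))
  }
}
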