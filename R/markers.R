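#' Visibility intervals around anchor events
#'
#' For every anchor (a heel-strike event detected from heel accelerometry),
#' a window of `width` samples centred on the anchor is evaluated on the
#' marker's visibility mask. An interval is complete when the marker is
#' visible at every sample; anchors too close to the trace edge yield a
#' clipped interval that is marked incomplete.
#'
#' @param marker A [marker_trace()], already resampled to the anchors'
#'   sampling rate.
#' @param anchors An [event_series()] of anchor events.
#' @param width Interval width in samples (default 40).
#' @return A tibble with one row per anchor: `anchor` (sample index),
#'   `start`, `end` (inclusive), `clipped`, `complete`.
#' @export
visible_intervals <- function(marker, anchors, width = 40) {
  stopifnot(inherits(marker, "marker_trace"))
  n <- nrow(marker)
  half <- floor(width / 2)
  purrr::map_dfr(anchors$event, function(a) {
    start <- a - half
    end <- a + half - 1L
    clipped <- start < 1 || end > n
    s <- max(1L, start); e <- min(n, end)
    complete <- !clipped && all(marker$visible[s:e])
    tibble::tibble(anchor = a, start = s, end = e,
                   clipped = clipped, complete = complete)
  })
}

#' Select the best-visible marker of a body site
#'
#' From the candidate markers placed on the same area, the one with the
#' largest number of complete visibility intervals over the whole gait
#' episode is selected; ties are broken by the lowest `marker_id`.
#'
#' @param candidates List of [marker_trace()]s for one site.
#' @param anchors An [event_series()] of anchor events.
#' @param width Interval width in samples.
#' @return The selected `marker_trace`, with attribute `n_complete`.
#' @export
select_marker <- function(candidates, anchors, width = 40) {
  if (length(candidates) == 0) {
    abort_stage("no candidate markers for this site", "stepmatch_invalid_input")
  }
  counts <- vapply(candidates, function(m) {
    sum(visible_intervals(m, anchors, width)$complete)
  }, numeric(1))
  ids <- vapply(candidates, function(m) attr(m, "marker_id"), character(1))
  best <- order(-counts, ids)[1]
  out <- candidates[[best]]
  attr(out, "n_complete") <- counts[best]
  out
}

#' Heel strikes from optical markers
#'
#' The reference method: within each complete visibility interval, the heel
#' strike is the instant at which the anterior-posterior distance between
#' the selected heel marker and the selected lower-back marker is maximal
#' (the heel is farthest in front of the trunk exactly at touch-down).
#' Incomplete intervals yield no event and are reported as missed. Ties in
#' the argmax take the earliest sample.
#'
#' @param heel,back Selected [marker_trace()]s of one heel and the lower
#'   back, same sampling rate and length. An interval is complete only if
#'   both markers are visible throughout.
#' @param intervals Tibble from [visible_intervals()] built from that foot's
#'   anchors.
#' @param signed Use the signed difference `heel_ap - back_ap` (default);
#'   `FALSE` uses the absolute distance.
#' @return A list of class `"reference_detection"`: `events` (an
#'   [event_series()] with method `"marker_reference"`), `missed` (integer
#'   ordinal positions of missed anchors), `n_anchors`, `missed_fraction`.
#' @export
heelstrike_from_markers <- function(heel, back, intervals, signed = TRUE) {
  stopifnot(inherits(heel, "marker_trace"), inherits(back, "marker_trace"))
  if (nrow(heel) != nrow(back) ||
      !isTRUE(all.equal(trace_fs(heel), trace_fs(back)))) {
    abort_stage("heel and back marker traces must share length and sampling rate",
                "stepmatch_invalid_input")
  }
  if (!all(c("ap") %in% names(heel)) || !all(c("ap") %in% names(back))) {
    abort_stage("AP axis not identified in marker input", "stepmatch_config_error")
  }
  dist <- heel$ap - back$ap
  if (!signed) dist <- abs(dist)
  vis <- heel$visible & back$visible
  events <- integer(0)
  missed <- integer(0)
  for (k in seq_len(nrow(intervals))) {
    iv <- intervals[k, ]
    ok <- !iv$clipped && all(vis[iv$start:iv$end])
    if (!ok) {
      missed <- c(missed, k)
      next
    }
    seg <- dist[iv$start:iv$end]
    events <- c(events, iv$start + which.max(seg) - 1L)
  }
  ev <- event_series(sort(events), trace_fs(heel), method = "marker_reference")
  structure(list(events = ev, missed = missed, n_anchors = nrow(intervals),
                 missed_fraction = length(missed) / max(1L, nrow(intervals))),
            class = "reference_detection")
}

#' @export
print.reference_detection <- function(x, ...) {
  cat(sprintf("<reference_detection> %d events, %d/%d anchors missed (%.1f%%)\n",
              nrow(x$events), length(x$missed), x$n_anchors,
              100 * x$missed_fraction))
  invisible(x)
}

#' Run the full marker reference method
#'
#' Resamples all candidate markers to the anchors' sampling rate, selects
#' the best-visible marker per site, evaluates the visibility intervals
#' around both feet's anchors and estimates heel strikes as AP-distance
#' maxima. Anchors must be the combined heel-accelerometry events (the
#' `foot` column tells which heel marker each anchor is matched against).
#'
#' @param heel_left,heel_right,back Lists of candidate [marker_trace()]s
#'   per site.
#' @param anchors Combined heel [event_series()] with a `foot` column (from
#'   [detect_steps_heel()]), at the target sampling rate.
#' @param fs Target sampling rate (default 100 samples/s).
#' @param width Interval width in samples at `fs` (default 40).
#' @return A `"reference_detection"` (see [heelstrike_from_markers()]) whose
#'   `missed` positions index the combined anchor series.
#' @export
marker_reference <- function(heel_left, heel_right, back, anchors, fs = 100,
                             width = 40) {
  res <- function(m) resample_to(m, fs)
  heel_left <- lapply(heel_left, res)
  heel_right <- lapply(heel_right, res)
  back <- lapply(back, res)
  sel_back <- select_marker(back, anchors, width)
  out_events <- integer(0)
  missed <- integer(0)
  for (side in c("left", "right")) {
    cand <- if (side == "left") heel_left else heel_right
    side_rows <- which(anchors$foot == side)
    side_anchors <- event_series(anchors$event[side_rows], fs,
                                 method = "heel_accel_combined")
    sel <- select_marker(cand, side_anchors, width)
    ivs <- visible_intervals(sel, side_anchors, width)
    # completeness additionally requires the back marker
    hs <- heelstrike_from_markers(sel, sel_back, ivs)
    out_events <- c(out_events, hs$events$event)
    missed <- c(missed, side_rows[hs$missed])
  }
  ev <- event_series(sort(out_events), fs, method = "marker_reference")
  structure(list(events = ev, missed = sort(missed), n_anchors = nrow(anchors),
                 missed_fraction = length(missed) / max(1L, nrow(anchors))),
            class = "reference_detection")
}
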