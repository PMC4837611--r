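# interior local maxima; the first sample of a flat plateau counts
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# greedy admission by descending height under a minimum-distance constraint;
# ties broken by earlier index; returns admitted indices sorted ascending
greedy_select <- function(idx, height, min_dist) {
  ord <- order(-height, idx)
  kept <- integer(0)
  for (i in idx[ord]) {
    if (all(abs(kept - i) >= min_dist)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Template length of a lower-back (step-cycle) signal
#'
#' The template length TL is the step cycle expressed in samples:
#' `round(fs / dominant_frequency)`, with the dominant frequency taken from
#' the unbiased autocovariance of the segmented signal via
#' [dominant_frequency()].
#'
#' @param seg Segmented [accel_trace()] (or numeric vector with `fs` given).
#' @param config A [detector_config()].
#' @param fs Sampling rate, taken from `seg` when it is a trace.
#' @return A list of class `"template_length"`: `tl` (samples),
#'   `dominant_freq` (Hz), `placement`.
#' @export
template_length_lowback <- function(seg, config = detector_config(),
                                    fs = trace_fs(seg)) {
  x <- if (inherits(seg, "accel_trace")) seg$accel else as.double(seg)
  acov <- unbiased_autocovariance(x)
  f <- dominant_frequency(acov, fs, band = config$freq_band,
                          resolution = config$freq_resolution,
                          min_periodicity = config$min_periodicity)
  tl <- round_half_up(fs / f)
  if (length(x) < 3 * fs / f) {
    abort_stage(sprintf("episode too short: %d samples < 3 cycles of %.0f samples",
                        length(x), fs / f), "stepmatch_too_short")
  }
  if (tl < 4 || tl >= length(x) / 2) {
    abort_stage(sprintf("template length %d invalid for a %d-sample segment",
                        tl, length(x)), "stepmatch_too_short")
  }
  structure(list(tl = tl, dominant_freq = f,
                 placement = trace_placement(seg) %||% "lower_back"),
            class = "template_length")
}

#' Template length of a heel (stride-cycle) signal
#'
#' Heel accelerations are periodic in strides, so TL is read directly off the
#' autocovariance peaks rather than the dominant frequency: the
#' autocovariance is normalized by its lag-0 value, low-pass filtered
#' (zero-phase Butterworth, cutoff at twice the dominant frequency), and TL
#' is the lag distance between the first two local maxima exceeding the 0.5
#' threshold, with lag 0 counting as the first peak.
#'
#' @inheritParams template_length_lowback
#' @return A `"template_length"` list, see [template_length_lowback()].
#' @export
template_length_heel <- function(seg, config = detector_config(),
                                 fs = trace_fs(seg)) {
  x <- if (inherits(seg, "accel_trace")) seg$accel else as.double(seg)
  acov <- unbiased_autocovariance(x)
  f <- dominant_frequency(acov, fs, band = config$freq_band,
                          resolution = config$freq_resolution,
                          min_periodicity = config$min_periodicity)
  half <- acov$acov[seq_len(max(8L, floor(length(x) / 2)))]
  norm <- half / half[1]
  cutoff <- min(2 * f / (fs / 2), 0.99)
  bf <- signal::butter(config$filter_order, cutoff, type = "low")
  # the autocovariance is an even function of the lag: filter its even
  # extension (mirror on both sides) so the zero-phase filter sees no edge
  # discontinuity, then keep the non-negative lags
  L <- length(norm)
  ext <- c(rev(norm[-1]), norm, rev(norm)[-1])
  filt <- signal::filtfilt(bf, ext)[L:(2 * L - 1)]
  peaks <- local_maxima(filt)
  # lag 0 (index 1) is the first peak by convention
  peaks <- sort(unique(c(1L, peaks)))
  qualifying <- peaks[filt[peaks] > config$acov_peak_threshold]
  if (length(qualifying) < 2) {
    abort_stage(sprintf(
      "stride periodicity not found: fewer than two autocovariance peaks above %.2f",
      config$acov_peak_threshold), "stepmatch_no_periodicity")
  }
  tl <- as.integer(qualifying[2] - qualifying[1])
  if (tl < 4 || tl >= length(x) / 2) {
    abort_stage(sprintf("template length %d invalid for a %d-sample segment",
                        tl, length(x)), "stepmatch_too_short")
  }
  structure(list(tl = tl, dominant_freq = f,
                 placement = trace_placement(seg) %||% "heel_left"),
            class = "template_length")
}

#' @export
print.template_length <- function(x, ...) {
  cat(sprintf("<template_length> %d samples (dominant %.2f Hz, %s)\n",
              x$tl, x$dominant_freq, x$placement))
  invisible(x)
}

#' Find anchor peaks for template sections
#'
#' Local maxima of the signed AP segment are admitted greedily in descending
#' amplitude under a minimum pairwise distance of 40 % TL, restricted to the
#' region more than 115 % TL samples from both ends of the segment (so every
#' admitted peak has room for a full section around it). Candidates whose
#' height above the segment median falls below `peak_min_height_frac` of the
#' tallest candidate's height above the median are discarded first:
#' anchor peaks mark the impact of each gait cycle and are several times
#' taller than the maxima noise produces between cycles, and sections
#' anchored on such spurious maxima would corrupt the averaged template.
#'
#' @param seg Segmented [accel_trace()] or numeric vector.
#' @param tl A `"template_length"` or integer TL in samples.
#' @param config A [detector_config()].
#' @return Integer vector of peak positions (segment-local, 1-based),
#'   ascending; at least 2.
#' @export
find_template_peaks <- function(seg, tl, config = detector_config()) {
  x <- if (inherits(seg, "accel_trace")) seg$accel else as.double(seg)
  tl <- if (inherits(tl, "template_length")) tl$tl else as.integer(tl)
  n <- length(x)
  margin <- round_half_up(config$section_margin * tl)
  if (n <= 2 * margin + tl) {
    abort_stage(sprintf("segment of %d samples too short for margins of %d",
                        n, margin), "stepmatch_too_few_cycles")
  }
  lo <- margin + 1L
  hi <- n - margin
  cand <- local_maxima(x)
  cand <- cand[cand >= lo & cand <= hi]
  if (length(cand) > 0 && config$peak_min_height_frac > 0) {
    # height floor measured from the segment median so the admission rule is
    # invariant to constant offsets and positive rescaling of the trace
    med <- stats::median(x)
    top <- max(x[cand])
    if (top > med) {
      cand <- cand[x[cand] >= med + config$peak_min_height_frac * (top - med)]
    }
  }
  peaks <- greedy_select(cand, x[cand], tl_samples(config$peak_min_dist_frac, tl))
  if (length(peaks) < 2) {
    abort_stage(sprintf("only %d admissible anchor peak(s); need at least 2",
                        length(peaks)), "stepmatch_too_few_cycles")
  }
  peaks
}

#' Extract peak-anchored sections
#'
#' Each section starts `round(pre_fraction * TL)` samples before its anchor
#' peak (to include the slope preceding the peak) and ends TL samples after
#' it, so all sections share the length `round(pre_fraction * TL) + TL`.
#' Sections that would cross the segment boundary are dropped with a warning.
#'
#' @param seg Segmented [accel_trace()] or numeric vector.
#' @param peaks Anchor peak positions from [find_template_peaks()].
#' @param tl Template length (samples) or `"template_length"`.
#' @param pre_fraction Fraction of TL preceding the anchor (0.15 lower back,
#'   0.05 heel).
#' @return List of equal-length numeric vectors (at least 2).
#' @export
extract_sections <- function(seg, peaks, tl, pre_fraction = 0.15) {
  x <- if (inherits(seg, "accel_trace")) seg$accel else as.double(seg)
  tl <- if (inherits(tl, "template_length")) tl$tl else as.integer(tl)
  pre <- tl_samples(pre_fraction, tl)
  n <- length(x)
  sections <- list()
  for (p in peaks) {
    if (p - pre < 1 || p + tl - 1 > n) {
      rlang::warn(sprintf("section at peak %d crosses the segment boundary; dropped", p))
      next
    }
    sections[[length(sections) + 1]] <- x[(p - pre):(p + tl - 1)]
  }
  if (length(sections) < 2) {
    abort_stage("fewer than 2 sections survive; too few gait cycles",
                "stepmatch_too_few_cycles")
  }
  sections
}

#' Dynamic time warping alignment of two sequences
#'
#' Classic DTW with absolute-difference local cost, the symmetric step set
#' \{(1,0), (0,1), (1,1)\} unweighted, pinned endpoints and no window
#' constraint. Ties in the backtracking prefer the diagonal step, so equal
#' inputs align along the diagonal.
#'
#' @param a,b Non-empty numeric vectors.
#' @return List with `cost` (optimal cumulative cost) and `path` (two-column
#'   integer matrix of aligned index pairs, from `(1,1)` to
#'   `(length(a), length(b))`).
#' @export
dtw_align <- function(a, b) {
  a <- as.double(a); b <- as.double(b)
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) {
    abort_stage("DTW inputs must be non-empty", "stepmatch_invalid_input")
  }
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    ai <- a[i]
    prev <- D[i, ]
    cur <- D[i + 1, ]
    for (j in seq_len(m)) {
      cur[j + 1] <- abs(ai - b[j]) + min(prev[j], prev[j + 1], cur[j])
    }
    D[i + 1, ] <- cur
  }
  # backtrack, diagonal preferred on ties
  i <- n; j <- m
  path <- matrix(0L, n + m, 2)
  k <- 1L
  path[k, ] <- c(i, j)
  while (i > 1 || j > 1) {
    if (i > 1 && j > 1) {
      opts <- c(D[i, j], D[i, j + 1], D[i + 1, j])  # diag, up, left
      pick <- which.min(opts)
      if (pick == 1) { i <- i - 1; j <- j - 1 }
      else if (pick == 2) { i <- i - 1 }
      else { j <- j - 1 }
    } else if (i > 1) i <- i - 1 else j <- j - 1
    k <- k + 1L
    path[k, ] <- c(i, j)
  }
  list(cost = D[n + 1, m + 1], path = path[k:1, , drop = FALSE])
}

#' Average two sections along their DTW path
#'
#' The two sequences are aligned with [dtw_align()], the aligned pairs are
#' averaged along the warping path, and the averaged sequence is linearly
#' resampled back to `length(a)` so repeated pairwise averaging keeps a fixed
#' length.
#'
#' @param a,b Non-empty numeric vectors.
#' @return Numeric vector of `length(a)`.
#' @export
dtw_average_pair <- function(a, b) {
  al <- dtw_align(a, b)
  avg <- (a[al$path[, 1]] + b[al$path[, 2]]) / 2
  if (length(avg) == length(a)) return(avg)
  stats::approx(seq_along(avg), avg, xout = seq(1, length(avg),
                                                length.out = length(a)))$y
}

#' Build the template signal from sections
#'
#' Hierarchical pairwise reduction: consecutive sections are DTW-averaged
#' ([dtw_average_pair()]), halving the list each round (an odd leftover is
#' carried unchanged), until a single averaged signal remains. The result is
#' reduced to exactly TL samples, either by keeping the first TL samples
#' (`fit = "truncate"`, one full cycle starting at the sliding-window origin;
#' the default) or by linear resampling of the whole section
#' (`fit = "resample"`).
#'
#' @param sections List of equal-length numeric vectors (at least 2), from
#'   [extract_sections()].
#' @param tl Template length (samples) or `"template_length"`.
#' @param pre_fraction Fraction of TL preceding the anchor peak (recorded).
#' @param fit `"truncate"` or `"resample"`, see Details.
#' @return A list of class `"template_signal"`: `values` (length TL), `tl`,
#'   `pre_fraction`, `n_sections`.
#' @export
build_template <- function(sections, tl, pre_fraction = 0.15,
                           fit = c("truncate", "resample")) {
  fit <- match.arg(fit)
  tl <- if (inherits(tl, "template_length")) tl$tl else as.integer(tl)
  if (length(sections) < 2) {
    abort_stage("need at least 2 sections to build a template",
                "stepmatch_too_few_cycles")
  }
  lens <- lengths(sections)
  if (length(unique(lens)) != 1) {
    abort_stage("sections must all have the same length", "stepmatch_invalid_input")
  }
  n_sections <- length(sections)
  current <- sections
  while (length(current) > 1) {
    nxt <- list()
    i <- 1
    while (i + 1 <= length(current)) {
      nxt[[length(nxt) + 1]] <- dtw_average_pair(current[[i]], current[[i + 1]])
      i <- i + 2
    }
    if (i == length(current)) nxt[[length(nxt) + 1]] <- current[[i]]
    current <- nxt
  }
  avg <- current[[1]]
  values <- if (fit == "truncate") {
    if (length(avg) < tl) {
      stats::approx(seq_along(avg), avg, xout = seq(1, length(avg), length.out = tl))$y
    } else {
      avg[seq_len(tl)]
    }
  } else {
    stats::approx(seq_along(avg), avg, xout = seq(1, length(avg), length.out = tl))$y
  }
  structure(list(values = values, tl = tl, pre_fraction = pre_fraction,
                 n_sections = n_sections),
            class = "template_signal")
}

#' @export
print.template_signal <- function(x, ...) {
  cat(sprintf("<template_signal> %d samples, averaged from %d sections (pre %.0f%% TL)\n",
              x$tl, x$n_sections, 100 * x$pre_fraction))
  invisible(x)
}
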