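#' Detector configuration
#'
#' Collects every tunable constant of the template-match detector in one
#' list so that all of them can be overridden together (e.g. from a YAML/JSON
#' file via the command-line interface). Defaults are the published values of
#' the algorithm; the remaining entries are numerical choices documented in
#' the methods vignette.
#'
#' @param section_margin Fraction of the template length (TL) excluded at both
#'   ends of the segmented signal before anchor peaks are searched (default
#'   1.15, i.e. peaks are admitted only after 115 % TL samples from the start
#'   and before 115 % TL samples from the end).
#' @param peak_min_dist_frac Minimum distance between anchor peaks, as a
#'   fraction of TL (default 0.40).
#' @param peak_min_height_frac Minimum height of an anchor-peak candidate
#'   above the segment median, as a fraction of the tallest candidate's
#'   height above the median (default 0.5). True impact peaks
#'   are several times taller than mid-cycle maxima, so the floor keeps
#'   broadband-noise maxima in the gap between cycles from being adopted as
#'   section anchors (which would corrupt the averaged template); set to 0
#'   for the pure distance-constrained greedy rule.
#' @param pre_fraction_lowback,pre_fraction_heel Fraction of TL by which each
#'   section starts before its anchor peak, and by which selected coefficient
#'   peaks are shifted forward to approximate heel strikes: 0.15 for the
#'   lower-back (step) template, 0.05 for the heel (stride) template.
#' @param event_min_dist_frac Minimum distance between selected coefficient
#'   peaks, as a fraction of TL (default 0.60).
#' @param freq_band Physiologic band (Hz) searched for the dominant frequency
#'   of the autocovariance (default `c(0.3, 5)`).
#' @param freq_resolution Frequency grid (Hz) of the zero-padded FFT used for
#'   the dominant frequency (default 0.01).
#' @param min_periodicity Minimum value of the lag-normalized autocovariance
#'   (at lags beyond one shortest in-band period) required to accept the
#'   signal as periodic (default 0.3); below it a degenerate-signal error is
#'   raised (e.g. for white noise or constant input).
#' @param acov_peak_threshold Threshold on the normalized, low-pass filtered
#'   autocovariance peaks that define the heel (stride) template length
#'   (default 0.5).
#' @param filter_order Order of the zero-phase Butterworth low-pass applied to
#'   the normalized autocovariance for the heel template length (default 2).
#' @param sd_floor Epsilon floor applied to the normalized SD-difference
#'   signal before the coefficient ratio is taken (default 1e-3).
#' @param template_fit How the final averaged section (of length
#'   `round(pre_fraction * TL) + TL`) is reduced to the TL-sample template:
#'   `"truncate"` keeps the first TL samples (one full cycle starting at the
#'   sliding-window origin), `"resample"` linearly warps the whole section to
#'   TL samples.
#' @param range_ratio Form of the range-ratio factor applied to the sliding
#'   correlation: `"per_window_sym"` (default) multiplies each window's
#'   correlation by `min(rho, 1/rho)` with `rho = range(window)/range(template)`;
#'   `"per_window_raw"` uses `rho` itself; `"global"` applies a single constant
#'   ratio (a no-op after normalization).
#' @param invert_ap Logical; negate the AP signal on load for sensors mounted
#'   with opposite polarity.
#'
#' @return A named list of class `"detector_config"`.
#' @export
detector_config <- function(section_margin = 1.15,
                            peak_min_dist_frac = 0.40,
                            peak_min_height_frac = 0.5,
                            pre_fraction_lowback = 0.15,
                            pre_fraction_heel = 0.05,
                            event_min_dist_frac = 0.60,
                            freq_band = c(0.3, 5),
                            freq_resolution = 0.01,
                            min_periodicity = 0.3,
                            acov_peak_threshold = 0.5,
                            filter_order = 2,
                            sd_floor = 1e-3,
                            template_fit = c("truncate", "resample"),
                            range_ratio = c("per_window_sym", "per_window_raw", "global"),
                            invert_ap = FALSE) {
  stopifnot(length(freq_band) == 2, freq_band[1] > 0, freq_band[2] > freq_band[1])
  cfg <- list(
    section_margin = section_margin,
    peak_min_dist_frac = peak_min_dist_frac,
    peak_min_height_frac = peak_min_height_frac,
    pre_fraction_lowback = pre_fraction_lowback,
    pre_fraction_heel = pre_fraction_heel,
    event_min_dist_frac = event_min_dist_frac,
    freq_band = freq_band,
    freq_resolution = freq_resolution,
    min_periodicity = min_periodicity,
    acov_peak_threshold = acov_peak_threshold,
    filter_order = filter_order,
    sd_floor = sd_floor,
    template_fit = match.arg(template_fit),
    range_ratio = match.arg(range_ratio),
    invert_ap = invert_ap
  )
  structure(cfg, class = c("detector_config", "list"))
}
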