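#' Unbiased autocovariance over non-negative lags
#'
#' Lag-k value is `(1/(n-k)) * sum_t (x_t - xbar)(x_{t+k} - xbar)`, i.e. the
#' mean-removed cross product with the unbiased `1/(n-k)` normalization (so
#' lag 0 equals the sample variance with `1/n` normalization). Only
#' non-negative lags `0 .. n-1` are returned; the gait detector reads the
#' cycle length off the positive-lag part of this signal.
#'
#' @param x Numeric vector, at least 8 samples, not constant. An
#'   [accel_trace()] may be given; its `accel` column is used.
#' @return A tibble with columns `lag` (0-based) and `acov`.
#' @examples
#' a <- unbiased_autocovariance(sin(2 * pi * 2 * (0:999) / 100))
#' a$lag[which.max(a$acov[a$lag > 10]) + 10]
#' @export
unbiased_autocovariance <- function(x) {
  if (inherits(x, "accel_trace")) x <- x$accel
  x <- as.double(x)
  n <- length(x)
  if (n < 8) {
    abort_stage("autocovariance needs at least 8 samples", "stepmatch_degenerate_signal")
  }
  xc <- x - mean(x)
  if (all(abs(xc) < .Machine$double.eps * 100 * max(1, abs(mean(x))))) {
    abort_stage("constant signal has no autocovariance structure",
                "stepmatch_degenerate_signal")
  }
  # FFT-based linear cross products, then unbiased per-lag normalization
  m <- stats::nextn(2L * n, 2)
  f <- stats::fft(c(xc, rep(0, m - n)))
  s <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / m
  raw <- s[seq_len(n)]                # sum_t x_t x_{t+k}, k = 0..n-1
  acov <- raw / (n - 0:(n - 1))
  tibble::tibble(lag = 0:(n - 1), acov = acov)
}

#' Dominant frequency of an autocovariance signal
#'
#' The frequency of the largest magnitude-spectrum component of the
#' positive-lag autocovariance within a physiologic band (default 0.3-5 Hz),
#' on a zero-padded FFT grid. The unbiased normalization amplifies the noisy
#' long-lag tail (few products are averaged there), so only lags up to half
#' the signal length enter the spectrum. A degenerate-signal error is raised
#' when the signal carries no real periodicity: the lag-normalized
#' autocovariance must exceed `min_periodicity` somewhere beyond one shortest
#' in-band period.
#'
#' @param acov Output of [unbiased_autocovariance()] (tibble or plain vector
#'   over lags `0..n-1`).
#' @param fs Sampling rate in samples/s of the originating signal.
#' @param band Frequency band searched, Hz.
#' @param resolution Frequency grid step of the zero-padded FFT, Hz.
#' @param min_periodicity Periodicity floor, see Details.
#' @return Dominant frequency in Hz (scalar).
#' @export
dominant_frequency <- function(acov, fs, band = c(0.3, 5), resolution = 0.01,
                               min_periodicity = 0.3) {
  if (is.data.frame(acov)) acov <- acov$acov
  acov <- as.double(acov)
  n <- length(acov)
  if (n < 8 || acov[1] <= 0) {
    abort_stage("degenerate autocovariance input", "stepmatch_degenerate_signal")
  }
  half <- acov[seq_len(max(8L, floor(n / 2)))]
  # periodicity check: normalized autocovariance must rebound after the
  # shortest admissible period
  norm <- half / acov[1]
  min_lag <- max(2L, floor(fs / band[2]))
  if (min_lag < length(norm)) {
    rebound <- max(norm[(min_lag + 1):length(norm)])
    if (!is.finite(rebound) || rebound < min_periodicity) {
      abort_stage(sprintf(
        "no dominant periodicity: normalized autocovariance never exceeds %.2f beyond lag %d",
        min_periodicity, min_lag), "stepmatch_degenerate_signal")
    }
  } else {
    abort_stage("signal too short for the requested frequency band",
                "stepmatch_degenerate_signal")
  }
  nfft <- stats::nextn(max(length(half), ceiling(fs / resolution)), 2)
  spec <- Mod(stats::fft(c(half, rep(0, nfft - length(half)))))
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  in_band <- which(freqs >= band[1] & freqs <= band[2])
  if (length(in_band) == 0) {
    abort_stage("frequency band contains no FFT bins", "stepmatch_degenerate_signal")
  }
  freqs[in_band[which.max(spec[in_band])]]
}
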