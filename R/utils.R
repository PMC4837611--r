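#' Round half away from zero
#'
#' All "percent of template length" quantities in the detector are converted
#' to integer sample counts with this rule (deterministic and symmetric,
#' unlike banker's rounding), with a floor of one sample.
#'
#' @param x Numeric vector.
#' @return Integer vector, `x` rounded half away from zero.
#' @examples
#' round_half_up(c(7.5, -7.5, 57.5))
#' @export
round_half_up <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# samples for a fraction of the template length, never less than 1
tl_samples <- function(fraction, tl) {
  max(1L, round_half_up(fraction * tl))
}

abort_stage <- function(msg, class, stage = NULL, ...) {
  if (!is.null(stage)) msg <- paste0("[", stage, "] ", msg)
  rlang::abort(msg, class = c(class, "stepmatch_error"), ...)
}

`%||%` <- rlang::`%||%`
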