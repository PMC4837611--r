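Package: stepmatch
Title: Template-Matched Step Detection from Lower-Back and Heel Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects heel-strike events and step/stride durations from short
    (about 5 m) episodes of gait using anterior-posterior acceleration recorded
    at the lower back or at both heels. A per-episode template of one gait
    cycle is estimated from the unbiased autocovariance of the segmented
    signal, built by dynamic-time-warping averaging of peak-anchored sections,
    and slid along the signal; heel strikes are read off the peaks of the ratio
    between a sliding correlation signal and a sliding standard-deviation-of-
    difference signal. Includes the optoelectronic marker reference method
    (visibility-gated anterior-posterior heel-to-back distance maxima),
    between-method agreement statistics (absolute step-duration differences,
    ICC(2,1), normality-gated paired tests) with a stride fallback for missed
    reference events, and a synthetic gait generator with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
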