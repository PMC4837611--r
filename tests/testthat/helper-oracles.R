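# Independent brute-force oracles used to pin down expected values.
# These deliberately avoid the package's own computation paths.

# double-loop unbiased autocovariance
naive_acov <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  vapply(0:(n - 1), function(k) {
    s <- 0
    for (t in 1:(n - k)) s <- s + xc[t] * xc[t + k]
    s / (n - k)
  }, numeric(1))
}

# per-window loops for the sliding match signals (un-normalized forms)
naive_sd_diff <- function(x, tpl) {
  tl <- length(tpl)
  vapply(seq_len(length(x) - tl + 1), function(i) {
    d <- x[i:(i + tl - 1)] - tpl
    sqrt(mean((d - mean(d))^2))
  }, numeric(1))
}

naive_corr <- function(x, tpl) {
  tl <- length(tpl)
  vapply(seq_len(length(x) - tl + 1), function(i) {
    w <- x[i:(i + tl - 1)]
    if (stats::sd(w) == 0) return(0)
    r <- stats::cor(w, tpl)
    rho <- diff(range(w)) / diff(range(tpl))
    r * min(rho, 1 / rho)
  }, numeric(1))
}

# exhaustive DTW: enumerate every monotone path from (1,1) to (n,m) with
# steps {(1,0),(0,1),(1,1)} and return the minimum cumulative |a_i - b_j|
brute_dtw_cost <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- Inf
  recurse <- function(i, j, acc) {
    acc <- acc + abs(a[i] - b[j])
    if (acc >= best) return(invisible(NULL))  # prune: costs never decrease
    if (i == n && j == m) {
      best <<- acc
      return(invisible(NULL))
    }
    if (i < n && j < m) recurse(i + 1, j + 1, acc)
    if (i < n) recurse(i + 1, j, acc)
    if (j < m) recurse(i, j + 1, acc)
    invisible(NULL)
  }
  recurse(1, 1, 0)
  best
}

# ICC(2,1) via R's own two-way ANOVA decomposition
aov_icc21 <- function(a, b) {
  n <- length(a)
  dat <- data.frame(y = c(a, b),
                    subj = factor(rep(seq_len(n), 2)),
                    rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = dat))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

# the fixed synthetic study conditions used by the acceptance-style suites:
# 8-12 steps, step CV up to 3 %, asymmetry up to 5 %, derived from the seed
suite_params <- function(seed, snr_db = 10) {
  gait_params(n_steps = 8 + seed %% 5,
              step_cv = 0.03 * (seed %% 4) / 3,
              asymmetry = 0.05 * (seed %% 3) / 2,
              noise_sd = 0, snr_db = snr_db, seed = seed)
}

run_suite_trial <- function(seed, snr_db = 10) {
  tr <- generate_trial(suite_params(seed, snr_db))
  lb <- detect_steps_lowback(tr$lowback, tr$window)
  hh <- detect_steps_heel(tr$heel_left, tr$heel_right, tr$window)
  list(trial = tr, lb = lb, hh = hh)
}

# small cache so the heavy 200-trial suites are computed once per test run
.suite_cache <- new.env(parent = emptyenv())

suite_results <- function(seeds, snr_db) {
  key <- paste0("s", ifelse(is.null(snr_db), "clean", snr_db), "_",
                length(seeds), "_", seeds[1])
  if (!is.null(.suite_cache[[key]])) return(.suite_cache[[key]])
  out <- lapply(seeds, function(s) {
    r <- tryCatch(run_suite_trial(s, snr_db), error = function(e) e)
    if (inherits(r, "error")) return(list(seed = s, error = conditionMessage(r)))
    truth <- r$trial$truth$event
    list(seed = s, error = NULL,
         n_truth = length(truth),
         n_lb = nrow(r$lb$events), n_hh = nrow(r$hh$events),
         lb_events = r$lb$events$event, hh_events = r$hh$events$event,
         truth = truth,
         lb_durerr = if (nrow(r$lb$events) == length(truth))
           mean(abs(diff(r$lb$events$event) - diff(truth))) * 1000 / 100 else NA,
         hh_durerr = if (nrow(r$hh$events) == length(truth))
           mean(abs(diff(r$hh$events$event) - diff(truth))) * 1000 / 100 else NA)
  })
  .suite_cache[[key]] <- out
  out
}
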