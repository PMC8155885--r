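# Response-time analysis: moving-median smoothing, DRT/URT construction,
# the one-sided lower confidence bound, TRT run detection and fast/slow
# trial labels.
#
# DRT (determined response time) is the smoothed RT of the 4th question,
# the one governed by the hidden rule; URT (undetermined response time)
# is the mean of the smoothed 2nd and 3rd question RTs. A trial earns the
# TRT (Triple Response Time) mark when DRT has stayed below the lower 90%
# confidence bound of URT for three consecutive trials.

#' Centered moving median with truncated edges
#'
#' Windows shrink to the available neighbors at the series edges, and
#' missing values are ignored within each window (an all-missing window
#' yields `NA`).
#'
#' @param x numeric vector (may contain `NA`).
#' @param window odd window width >= 1 (default 5).
#' @return Numeric vector, same length as `x`.
#' @export
moving_median <- function(x, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("`window` must be odd and >= 1")
  n <- length(x)
  if (n == 0L) return(numeric(0))
  h <- window %/% 2L
  vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - h):min(n, i + h)]
    w <- w[!is.na(w)]
    if (length(w) == 0L) NA_real_ else median(w)
  }, 0)
}

#' Build a per-trial response-time table from an event table
#'
#' @param events data frame with `trial`, `question`, `rt_s` (long format,
#'   as from [read_events()] or [gen_rt()]).
#' @param rt_max response window in seconds; RTs outside `(0, rt_max]`
#'   become missing (default 3).
#' @return Data frame with one row per trial: `trial`, `rt_q1`..`rt_q4`.
#' @export
rt_trials <- function(events, rt_max = 3) {
  ev <- validate_events(events[, c("trial", "question",
                                   intersect("onset_s", names(events)), "rt_s")],
                        rt_max = rt_max)
  trials <- sort(unique(ev$trial))
  out <- data.frame(trial = trials)
  for (q in 1:4) {
    rtq <- ev$rt_s[ev$question == q][match(trials, ev$trial[ev$question == q])]
    out[[paste0("rt_q", q)]] <- rtq
  }
  out
}

#' Smooth per-question response times with a moving median
#'
#' @param trials output of [rt_trials()].
#' @param window moving-median window over trials (default 5).
#' @return `trials` with added columns `mm_q1`..`mm_q4`.
#' @export
smooth_rt <- function(trials, window = 5L) {
  for (q in 1:4)
    trials[[paste0("mm_q", q)]] <- moving_median(trials[[paste0("rt_q", q)]],
                                                 window = window)
  trials
}

#' Derive DRT and URT per trial
#'
#' DRT is the smoothed Q4 response time; URT the mean of the smoothed Q2
#' and Q3 response times. Trials missing any of the raw Q2/Q3/Q4
#' responses are labelled `excluded`.
#'
#' @param trials output of [smooth_rt()].
#' @return `trials` with added `drt`, `urt`, `label` columns.
#' @export
derive_drt_urt <- function(trials) {
  trials$drt <- trials$mm_q4
  trials$urt <- (trials$mm_q2 + trials$mm_q3) / 2
  trials$label <- ifelse(is.na(trials$rt_q2) | is.na(trials$rt_q3) |
                           is.na(trials$rt_q4), "excluded", "pending")
  trials
}

#' One-sided lower confidence bound of URT
#'
#' Three readings of "DRT drops below the 90% negative confidence
#' interval of URT" are implemented, all over a centered rolling window
#' that truncates at the series edges:
#'
#' * `"tolerance"` (default): a one-sided lower normal tolerance bound
#'   for URT *values*,
#'   `bound(t) = rolling_mean(urt) - k(n, confidence) * rolling_sd(raw)`,
#'   where the dispersion comes from the raw (unsmoothed) Q2/Q3 response
#'   times in the window and `k` is the tolerance factor covering a
#'   `confidence` fraction of values with `confidence` confidence
#'   (non-central t). A single DRT value is compared against the spread
#'   of URT values, so a value-scale bound is the operative reading: a
#'   confidence interval for the *mean* URT hugs the mean so closely
#'   that smoothed DRT noise crosses it constantly.
#' * `"normal_lower"`: the mean-scale confidence limit
#'   `rolling_mean(urt) - z(confidence) * rolling_sd(urt) / sqrt(n)`
#'   on the smoothed URT series, `z(0.90) = 1.2816`.
#' * `"fraction"`: `bound = confidence * urt`.
#'
#' Windows with fewer than 2 valid dispersion values degenerate to
#' `bound = urt` (reported via `message()`).
#'
#' @param trials output of [derive_drt_urt()].
#' @param confidence one-sided confidence level (default 0.90).
#' @param window rolling window width (default 5).
#' @param rule `"tolerance"`, `"normal_lower"` or `"fraction"`.
#' @return `trials` with added `bound` and `below` (`drt < bound`) columns.
#' @export
lower_bound <- function(trials, confidence = 0.90, window = 5L,
                        rule = c("tolerance", "normal_lower", "fraction")) {
  rule <- match.arg(rule)
  n <- nrow(trials)
  h <- as.integer(window) %/% 2L
  if (rule == "fraction") {
    trials$bound <- confidence * trials$urt
  } else {
    bound <- rep(NA_real_, n)
    degen <- 0L
    for (i in seq_len(n)) {
      lo <- max(1L, i - h)
      hi <- min(n, i + h)
      w <- trials$urt[lo:hi]
      w <- w[!is.na(w)]
      disp <- if (rule == "tolerance")
        c(trials$rt_q2[lo:hi], trials$rt_q3[lo:hi]) else w
      disp <- disp[!is.na(disp)]
      if (length(disp) < 2L || length(w) < 1L) {
        bound[i] <- trials$urt[i]
        degen <- degen + 1L
      } else if (rule == "tolerance") {
        k <- qt(confidence, df = length(disp) - 1L,
                ncp = qnorm(confidence) * sqrt(length(disp))) / sqrt(length(disp))
        bound[i] <- mean(w) - k * sd(disp)
      } else {
        bound[i] <- mean(w) - qnorm(confidence) * sd(disp) / sqrt(length(disp))
      }
    }
    if (degen > 0L) message("lower_bound: ", degen, " degenerate window(s), bound = urt")
    trials$bound <- bound
  }
  trials$below <- !is.na(trials$drt) & !is.na(trials$bound) &
    trials$drt < trials$bound
  trials
}

#' Mark TRT trials and assign fast/slow labels
#'
#' Within every maximal run of consecutive `below`-true trials of length
#' at least `run_length`, the `run_length`-th and all later trials of the
#' run receive the TRT mark (the mark is given when the three-trial
#' criterion completes). TRT trials are labelled `fast`, the rest `slow`;
#' `excluded` trials keep their label and break runs.
#'
#' @param trials output of [lower_bound()].
#' @param run_length required run of below-bound trials (default 3).
#' @return `trials` with `trt` (logical) and final `label` columns.
#' @export
mark_trt <- function(trials, run_length = 3L) {
  below <- trials$below & trials$label != "excluded"
  n <- length(below)
  trt <- rep(FALSE, n)
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (isTRUE(below[i])) run + 1L else 0L
    if (run >= run_length) trt[i] <- TRUE
  }
  trials$trt <- trt
  trials$label <- ifelse(trials$label == "excluded", "excluded",
                         ifelse(trt, "fast", "slow"))
  trials
}

#' Full response-time labelling pipeline
#'
#' [rt_trials()] -> [smooth_rt()] -> [derive_drt_urt()] ->
#' [lower_bound()] -> [mark_trt()].
#'
#' @inheritParams rt_trials
#' @inheritParams smooth_rt
#' @inheritParams lower_bound
#' @inheritParams mark_trt
#' @return Per-trial data frame with `drt`, `urt`, `bound`, `below`,
#'   `trt`, `label`.
#' @export
label_rt <- function(events, window = 5L, confidence = 0.90, run_length = 3L,
                     rule = "tolerance", rt_max = 3) {
  trials <- rt_trials(events, rt_max = rt_max)
  trials <- smooth_rt(trials, window = window)
  trials <- derive_drt_urt(trials)
  trials <- lower_bound(trials, confidence = confidence, window = window,
                        rule = rule)
  mark_trt(trials, run_length = run_length)
}

#' Balance fast/slow classes by down-sampling the majority class
#'
#' @param trials labelled trial table (needs `label` column with `fast`
#'   and `slow` entries; `excluded` rows are dropped).
#' @param seed integer seed for the uniform down-sampling draw.
#' @return Subset of `trials` with exactly equal fast and slow counts.
#' @export
balance_classes <- function(trials, seed = 1L) {
  keep <- trials[trials$label %in% c("fast", "slow"), , drop = FALSE]
  n_fast <- sum(keep$label == "fast")
  n_slow <- sum(keep$label == "slow")
  if (n_fast == 0L) stop("class 'fast' is empty; nothing to balance")
  if (n_slow == 0L) stop("class 'slow' is empty; nothing to balance")
  n_min <- min(n_fast, n_slow)
  set.seed(seed)
  idx_fast <- which(keep$label == "fast")
  idx_slow <- which(keep$label == "slow")
  if (n_fast > n_min) idx_fast <- sort(sample(idx_fast, n_min))
  if (n_slow > n_min) idx_slow <- sort(sample(idx_slow, n_min))
  message("balance_classes: ", n_min, " fast / ", n_min, " slow (from ",
          n_fast, "/", n_slow, ")")
  keep[sort(c(idx_fast, idx_slow)), , drop = FALSE]
}
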