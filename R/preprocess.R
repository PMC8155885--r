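# Filtering, frequency-band splitting and epoching.
#
# All filters are zero-phase (forward-backward) Butterworth designs from
# the `signal` package, applied with odd-reflection padding so that edge
# transients do not leak into short epochs. Inputs are assumed to be
# artifact-cleaned already: independent-component artifact removal is a
# documented pre-processing hook, deliberately outside this package.

# Zero-phase filter with odd-reflection padding (filtfilt itself does not
# pad). Pad length is capped by the signal length.
filtfilt_padded <- function(filt, x, pad = 1000L) {
  n <- length(x)
  p <- min(pad, n - 1L)
  if (p < 1L) return(signal::filtfilt(filt, x))
  xp <- c(2 * x[1L] - rev(x[2L:(p + 1L)]), x, 2 * x[n] - rev(x[(n - p):(n - 1L)]))
  y <- signal::filtfilt(filt, xp)
  y[(p + 1L):(p + n)]
}

apply_by_channel <- function(rec, f) {
  out <- rec$data
  for (ch in seq_len(nrow(out))) out[ch, ] <- f(rec$data[ch, ])
  recording(out, fs = rec$fs, channel_names = rec$channel_names)
}

#' Band-pass and power-line notch filtering
#'
#' Applies a zero-phase Butterworth band-pass (order 2 per pass, 4th-order
#' magnitude after forward-backward filtering) followed by a zero-phase
#' windowed-sinc FIR band-stop notch at the power-line frequency. A
#' narrow IIR notch rings for around a second at quality factor 30, which
#' would contaminate a large part of a 3-second epoch; the FIR band-stop
#' (+/- `notch_bw`/2 around the line frequency, Hamming window) has a
#' strictly finite transient instead. The band-pass removes the DC
#' offset along with sub-`low` drift.
#'
#' @param rec an [recording()] object.
#' @param low,high band-pass edges in Hz; defaults 0.5 and 50.
#' @param notch power-line frequency in Hz (default 60); `NULL` skips the
#'   notch (e.g. when `high` is already well below it).
#' @param order Butterworth order per pass (default 2).
#' @param notch_bw full stop-band width of the notch in Hz (default 10).
#' @return A filtered `eeg_recording` of the same dimensions.
#' @export
bandpass_notch <- function(rec, low = 0.5, high = 50, notch = 60, order = 2L,
                           notch_bw = 10) {
  ny <- rec$fs / 2
  if (!(low > 0 && low < high && high < ny))
    stop("filter edges must satisfy 0 < low < high < fs/2 (fs/2 = ", ny, " Hz)")
  bp <- signal::butter(order, c(low, high) / ny, type = "pass")
  # unpadded: reflection junctions excite the near-DC high-pass mode into
  # a slow swell, while the zero-state transient of a zero-mean input is
  # negligible here
  f <- function(x) signal::filtfilt(bp, x - mean(x))
  if (!is.null(notch)) {
    if (notch >= ny) stop("notch frequency must be below fs/2")
    n_taps <- min(400L, 2L * (ncol(rec$data) %/% 3L))  # even order
    h <- signal::fir1(n_taps, c(notch - notch_bw / 2, notch + notch_bw / 2) / ny,
                      type = "stop")
    bs <- signal::Arma(b = as.numeric(h), a = 1)
    g <- f
    f <- function(x) filtfilt_padded(bs, g(x))
  }
  apply_by_channel(rec, f)
}

#' Default EEG frequency-band edges
#'
#' Standard clinical band conventions, with gamma capped at 50 Hz by the
#' 0.5-50 Hz pre-filter: delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30,
#' gamma 30-50 Hz.
#'
#' @return Named list of `c(low, high)` pairs in Hz.
#' @export
default_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 50))
}

#' Split a filtered recording into frequency bands
#'
#' Each band is extracted with a zero-phase Butterworth filter (order 3
#' per pass). Bands whose edges coincide with the broadband pre-filter
#' range are treated as open at that edge (the lowest band becomes a
#' low-pass, the highest a high-pass): the pre-filter already enforces the
#' outer edges, and filtering them twice would double-attenuate there.
#' A band named `"broadband"` passes the input through unchanged.
#'
#' @param rec a (pre-filtered) [recording()] object.
#' @param bands named list of `c(low, high)` pairs; default [default_bands()].
#' @param range the broadband pre-filter range, used to recognize open
#'   outer edges (default `c(0.5, 50)`).
#' @param order Butterworth order per pass (default 3).
#' @return Named list of `eeg_recording`s, one per band.
#' @export
band_split <- function(rec, bands = default_bands(), range = c(0.5, 50),
                       order = 3L) {
  ny <- rec$fs / 2
  out <- vector("list", length(bands))
  names(out) <- names(bands)
  for (nm in names(bands)) {
    if (identical(nm, "broadband")) { out[[nm]] <- rec; next }
    b <- bands[[nm]]
    if (!(b[1] > 0 && b[1] < b[2] && b[2] < ny))
      stop("band '", nm, "' outside (0, fs/2): ", b[1], "-", b[2], " Hz")
    filt <- if (b[1] <= range[1]) {
      signal::butter(order, b[2] / ny, type = "low")
    } else if (b[2] >= range[2]) {
      signal::butter(order, b[1] / ny, type = "high")
    } else {
      signal::butter(order, b / ny, type = "pass")
    }
    out[[nm]] <- apply_by_channel(rec, function(x) filtfilt_padded(filt, x))
  }
  out
}

#' Read a trial/question event table
#'
#' Expected CSV columns: `trial`, `question` (1..4), `onset_s` (question
#' onset in seconds from recording start) and `rt_s` (response time in
#' seconds; empty/NA for no response).
#'
#' @param path CSV file path.
#' @param rt_max response window in seconds; RTs outside `(0, rt_max]` are
#'   flagged missing (default 3, the task's response window).
#' @return A data frame with columns `trial`, `question`, `onset_s`, `rt_s`.
#' @export
read_events <- function(path, rt_max = 3) {
  ev <- read.csv(path)
  need <- c("trial", "question", "onset_s", "rt_s")
  if (!all(need %in% names(ev)))
    stop("events file must have columns: ", paste(need, collapse = ", "))
  validate_events(ev[need], rt_max = rt_max)
}

validate_events <- function(ev, rt_max = 3) {
  ev <- ev[order(ev$trial, ev$question), , drop = FALSE]
  bad <- !is.na(ev$rt_s) & (ev$rt_s <= 0 | ev$rt_s > rt_max)
  if (any(bad)) {
    message("flagging ", sum(bad), " response time(s) outside (0, ", rt_max,
            "] s as missing")
    ev$rt_s[bad] <- NA_real_
  }
  for (tr in unique(ev$trial)) {
    on <- ev$onset_s[ev$trial == tr]
    if (any(diff(on) <= 0)) stop("onsets not strictly increasing in trial ", tr)
  }
  ev
}

#' Cut per-question epochs out of a recording
#'
#' Each epoch spans from a question's onset to the next question's onset
#' (for the 4th question, to the next trial's first onset; the last
#' trial's 4th epoch runs to the end of the recording). Sample indices are
#' 0-based and epochs are half-open `[start, end)`, so epochs tile the
#' recording between onsets exactly.
#'
#' @param rec an `eeg_recording` (typically one band of [band_split()]).
#' @param events event table as from [read_events()].
#' @param band band label attached to each epoch (default `"broadband"`).
#' @return A list of `eeg_epoch` objects: `samples`, `fs`, `trial`,
#'   `question`, `channel`, `band`, `rt_s`.
#' @export
epoch_recording <- function(rec, events, band = "broadband") {
  ev <- events[order(events$trial, events$question), , drop = FALSE]
  n <- ncol(rec$data)
  trials <- unique(ev$trial)
  epochs <- vector("list", 0L)
  for (ti in seq_along(trials)) {
    tr <- trials[ti]
    sub <- ev[ev$trial == tr, ]
    if (nrow(sub) != 4L) stop("trial ", tr, " does not have 4 questions")
    ends_s <- c(sub$onset_s[-1L],
                if (ti < length(trials)) ev$onset_s[ev$trial == trials[ti + 1L]][1L]
                else n / rec$fs)
    start_i <- floor(sub$onset_s * rec$fs)   # 0-based
    end_i <- floor(ends_s * rec$fs)
    if (any(end_i > n) || any(start_i < 0))
      stop("bounds error: trial ", tr, " events extend beyond the recording (",
           n / rec$fs, " s)")
    for (q in 1:4) {
      idx <- (start_i[q] + 1L):end_i[q]      # half-open [start, end)
      for (ch in seq_len(nrow(rec$data))) {
        epochs[[length(epochs) + 1L]] <- structure(
          list(samples = rec$data[ch, idx], fs = rec$fs, trial = tr,
               question = q, channel = rec$channel_names[ch], band = band,
               rt_s = sub$rt_s[q]),
          class = "eeg_epoch")
      }
    }
  }
  epochs
}
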