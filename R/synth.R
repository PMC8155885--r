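# Seeded synthetic fixtures: response-time series with a planted Q4
# speed-up, multichannel EEG whose signal complexity differs between
# classes in a chosen subset of (channel, band) features, and feature
# tables with a planted informative subset. Everything the pipeline
# assumes about real data is emulated here so every stage is testable
# without a recording.

#' Synthetic-data configuration
#'
#' Defaults describe the emulated study conditions: 100 trials of four
#' 3-second questions at 1000 Hz, nine frontal channels, a learning
#' onset at trial 50 after which the 4th question's response speeds up
#' by 0.5 s against 0.1 s response noise, and a complexity gap of 0.6
#' between the AR(1) coefficients of the two classes in the informative
#' features.
#'
#' @param n_trials number of trials.
#' @param channels channel labels (default [frontal_channels()]).
#' @param bands band labels; may include `"broadband"` (default the five
#'   named bands).
#' @param fs sampling rate in Hz (default 1000).
#' @param epoch_s question duration in seconds (default 3).
#' @param informative character vector of informative feature names
#'   (`"CHANNEL_band"`); default the theta and gamma bands of F3.
#' @param complexity_gap gap between class-conditional AR(1)
#'   coefficients, in `[0, 1)` (default 0.6).
#' @param ar_base baseline AR(1) coefficient (default 0.2).
#' @param learning_onset trial index L at which Q4 speeds up (default 50).
#' @param rt_base baseline response time in seconds (default 1.5).
#' @param rt_effect Q4 speed-up in seconds for trials >= L (default 0.5).
#' @param rt_noise_sd response-time noise SD in seconds (default 0.1).
#' @param seed integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_trials = 100L, channels = frontal_channels(),
                         bands = c("gamma", "beta", "alpha", "delta", "theta"),
                         fs = 1000, epoch_s = 3,
                         informative = c("F3_theta", "F3_gamma"),
                         complexity_gap = 0.6, ar_base = 0.2,
                         learning_onset = 50L, rt_base = 1.5,
                         rt_effect = 0.5, rt_noise_sd = 0.1, seed = 1L) {
  if (complexity_gap < 0 || complexity_gap >= 1)
    stop("`complexity_gap` must be in [0, 1)")
  if (rt_effect < 0) stop("`rt_effect` must be nonnegative")
  if (learning_onset >= n_trials) stop("`learning_onset` must be < n_trials")
  if (complexity_gap > 0 && length(informative) == 0L)
    stop("`informative` must be nonempty when complexity_gap > 0")
  if (ar_base + complexity_gap >= 1)
    stop("ar_base + complexity_gap must stay below 1")
  structure(list(n_trials = as.integer(n_trials), channels = channels,
                 bands = bands, fs = fs, epoch_s = epoch_s,
                 informative = informative, complexity_gap = complexity_gap,
                 ar_base = ar_base, learning_onset = as.integer(learning_onset),
                 rt_base = rt_base, rt_effect = rt_effect,
                 rt_noise_sd = rt_noise_sd, seed = as.integer(seed)),
            class = "synth_config")
}

# Unit-variance AR(1) series: x_t = a x_{t-1} + sqrt(1 - a^2) e_t.
ar1_series <- function(n, a) {
  e <- rnorm(n)
  if (a == 0) return(e)
  as.numeric(stats::filter(e * sqrt(1 - a^2), a, method = "recursive"))
}

#' Generate a synthetic response-time event table
#'
#' `RT(t, q) = rt_base + noise`; for trials at or after the learning
#' onset, Q4's RT is reduced by `rt_effect`. Onsets tile the session:
#' question q of trial t starts at `((t-1)*4 + (q-1)) * epoch_s`.
#'
#' @param cfg a [synth_config()].
#' @return Event data frame: `trial`, `question`, `onset_s`, `rt_s`.
#' @export
gen_rt <- function(cfg) {
  set.seed(cfg$seed + 1L)
  ev <- expand.grid(question = 1:4, trial = seq_len(cfg$n_trials))[, c("trial", "question")]
  ev$onset_s <- ((ev$trial - 1L) * 4L + (ev$question - 1L)) * cfg$epoch_s
  rt <- cfg$rt_base + rnorm(nrow(ev), sd = cfg$rt_noise_sd)
  speedup <- ev$question == 4L & ev$trial >= cfg$learning_onset
  rt[speedup] <- rt[speedup] - cfg$rt_effect
  ev$rt_s <- pmin(pmax(rt, 0.05), cfg$epoch_s)
  ev
}

#' Generate a synthetic EEG recording with planted complexity structure
#'
#' Each channel is a sum of unit-variance band components, one per
#' configured band. Components of informative (channel, band) features
#' use an AR(1) process whose coefficient is `ar_base` for slow-class
#' trials and `ar_base + complexity_gap` for fast-class trials (trials
#' at or after `learning_onset + 2`, where the TRT rule fires); all
#' other components use `ar_base` for both classes. Named bands are
#' filtered into their frequency range and re-normalized, so class
#' separation lives in the signal's temporal structure, not its
#' variance; a `"broadband"` band stays unfiltered.
#'
#' @param cfg a [synth_config()].
#' @return List with `recording` (an [recording()]) and `events` (from
#'   [gen_rt()]).
#' @export
gen_epochs <- function(cfg) {
  events <- gen_rt(cfg)
  set.seed(cfg$seed + 2L)
  band_edges <- default_bands()
  n_ep <- as.integer(round(cfg$fs * cfg$epoch_s))
  n_total <- n_ep * 4L * cfg$n_trials
  fast_from <- cfg$learning_onset + 2L
  data <- matrix(0, nrow = length(cfg$channels), ncol = n_total)
  filters <- lapply(cfg$bands, function(b) {
    if (identical(b, "broadband")) return(NULL)
    edges <- band_edges[[b]]
    if (is.null(edges)) stop("unknown band '", b, "'")
    ny <- cfg$fs / 2
    if (edges[1] <= 0.5) signal::butter(3L, edges[2] / ny, type = "low")
    else if (edges[2] >= 50 || edges[2] >= 0.98 * ny)
      signal::butter(3L, edges[1] / ny, type = "high")
    else signal::butter(3L, pmin(edges / ny, 0.98), type = "pass")
  })
  for (ci in seq_along(cfg$channels)) {
    ch <- cfg$channels[ci]
    sig <- numeric(n_total)
    for (bi in seq_along(cfg$bands)) {
      b <- cfg$bands[bi]
      info <- paste(ch, b, sep = "_") %in% cfg$informative
      # epoch-wise AR(1) so the coefficient can switch with the class
      comp <- numeric(n_total)
      pos <- 0L
      for (tr in seq_len(cfg$n_trials)) {
        a <- if (info && tr >= fast_from) cfg$ar_base + cfg$complexity_gap
             else cfg$ar_base
        for (q in 1:4) {
          comp[pos + seq_len(n_ep)] <- ar1_series(n_ep, a)
          pos <- pos + n_ep
        }
      }
      if (!is.null(filters[[bi]])) {
        comp <- filtfilt_padded(filters[[bi]], comp)
        s <- sd(comp)
        if (s > 0) comp <- comp / s
      }
      sig <- sig + comp
    }
    data[ci, ] <- sig
  }
  list(recording = recording(data, fs = cfg$fs, channel_names = cfg$channels),
       events = events)
}

#' Generate a feature table with a planted informative subset
#'
#' Emulates the assembled MSE feature table directly in feature space:
#' every column carries a baseline profile decreasing with scale plus
#' unit noise, and the columns of informative features are shifted down
#' by `separation` SDs for the fast class (coarse-grained regular
#' signals have lower entropy). Balanced classes by construction.
#'
#' @param space a [feature_space()].
#' @param informative indices (or names) of informative features.
#' @param n_per_class trials per class.
#' @param tau_max scales per feature.
#' @param separation class separation in within-class SD units
#'   (default 1).
#' @param seed integer seed.
#' @return A `feature_table`.
#' @export
gen_feature_table <- function(space = feature_space(),
                              informative = 1:3, n_per_class = 80L,
                              tau_max = 5L, separation = 1, seed = 1L) {
  if (is.character(informative))
    informative <- match(informative, space$features$name)
  set.seed(seed)
  nf <- nrow(space$features)
  n <- 2L * n_per_class
  label <- rep(c("fast", "slow"), each = n_per_class)
  baseline <- rep(1.5 * exp(-0.1 * seq_len(tau_max)), times = nf)
  x <- matrix(rnorm(n * nf * tau_max), nrow = n)
  x <- sweep(x, 2L, baseline, "+")
  info_cols <- which(rep(seq_len(nf), each = tau_max) %in% informative)
  x[label == "fast", info_cols] <- x[label == "fast", info_cols] - separation
  colnames(x) <- paste0(rep(space$features$name, each = tau_max),
                        "_s", rep(seq_len(tau_max), times = nf))
  # shuffle rows so folds are not degenerate by construction
  ord <- sample(n)
  tbl <- feature_table(x[ord, , drop = FALSE], label[ord], space, tau_max)
  attr(tbl, "informative") <- sort(informative)
  tbl
}
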