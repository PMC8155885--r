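# Sample entropy and multiscale entropy profiles.

#' Coarse-grain a time series
#'
#' Replaces non-overlapping blocks of `tau` consecutive samples by their
#' mean; trailing samples that do not fill a block are dropped, so the
#' output has `floor(N / tau)` points.
#'
#' @param x numeric vector.
#' @param tau scale level, integer >= 1.
#' @return Numeric vector of length `floor(length(x) / tau)`.
#' @export
coarse_grain <- function(x, tau) {
  tau <- as.integer(tau)
  n <- length(x)
  if (tau < 1L) stop("`tau` must be >= 1")
  if (tau > n) stop("`tau` (", tau, ") exceeds the series length (", n, ")")
  if (tau == 1L) return(x)
  nb <- n %/% tau
  colMeans(matrix(x[seq_len(nb * tau)], nrow = tau))
}

#' Template match counts for sample entropy
#'
#' Counts unordered template pairs within Chebyshev tolerance `r`:
#' `B` for templates of length `m`, `A` for length `m + 1`. Both template
#' sets start at the first `N - m` positions and self-matches are
#' excluded, so a constant input yields `A == B`.
#'
#' @param x numeric vector of length >= `m + 2`.
#' @param m template length (default 2).
#' @param r tolerance in amplitude units, > 0; matches use `<= r`.
#' @return List with integer-valued counts `A` and `B`.
#' @export
sampen_counts <- function(x, m = 2L, r) {
  m <- as.integer(m)
  if (m < 1L) stop("`m` must be >= 1")
  if (length(x) < m + 2L)
    stop("input too short for sample entropy: need at least m + 2 = ",
         m + 2L, " samples, got ", length(x))
  if (!is.numeric(r) || length(r) != 1L || r <= 0)
    stop("`r` must be a single positive tolerance")
  sampen_counts_cpp(as.numeric(x), m, r)
}

#' Sample entropy
#'
#' `-log(A / B)` in nats, with `A`, `B` from [sampen_counts()]. When no
#' `m + 1`-length matches exist (`A == 0`) the value is undefined and
#' `NA` is returned rather than an arbitrary cap.
#'
#' @inheritParams sampen_counts
#' @return Sample entropy in nats, exactly 0 when `A == B`, or `NA_real_`
#'   when undefined.
#' @export
sample_entropy <- function(x, m = 2L, r) {
  cnt <- sampen_counts(x, m = m, r = r)
  if (cnt$A == 0) return(NA_real_)
  if (cnt$A == cnt$B) return(0)
  -log(cnt$A / cnt$B)
}

#' Multiscale entropy profile
#'
#' Sample entropy of successively coarse-grained versions of a series,
#' scales 1..`tau_max`. The tolerance is fixed once as
#' `r_factor x SD(x)` on the scale-1 series (population SD) and reused at
#' every scale, so the profile reflects structure, not the variance
#' reduction that coarse-graining causes.
#'
#' @param x numeric vector, or an `eeg_epoch` (its samples are used).
#' @param m template length (default 2).
#' @param r_factor tolerance as a multiple of the scale-1 SD (default 0.15).
#' @param tau_max maximum scale (default 20).
#' @param r_abs absolute tolerance override; when given, `r_factor` is
#'   ignored (useful for constant inputs whose SD is 0).
#' @return An `mse_profile`: list with `values` (length `tau_max`, NA where
#'   undefined), `n_points` (`floor(N / tau)` per scale), `tau_max`, `m`,
#'   `r_abs`.
#' @export
mse_profile <- function(x, m = 2L, r_factor = 0.15, tau_max = 20L,
                        r_abs = NULL) {
  if (inherits(x, "eeg_epoch")) x <- x$samples
  n <- length(x)
  tau_max <- as.integer(tau_max)
  m <- as.integer(m)
  if (n %/% tau_max < m + 2L) {
    feasible <- n %/% (m + 2L)
    stop("epoch of ", n, " samples too short for tau_max = ", tau_max,
         "; largest feasible scale is ", feasible)
  }
  if (is.null(r_abs)) {
    sd_pop <- sqrt(mean((x - mean(x))^2))
    r_abs <- r_factor * sd_pop
  }
  if (r_abs <= 0)
    stop("tolerance is not positive (constant epoch?); supply `r_abs`")
  values <- numeric(tau_max)
  n_points <- integer(tau_max)
  for (tau in seq_len(tau_max)) {
    y <- coarse_grain(x, tau)
    n_points[tau] <- length(y)
    values[tau] <- sample_entropy(y, m = m, r = r_abs)
  }
  structure(list(values = values, n_points = n_points, tau_max = tau_max,
                 m = m, r_abs = r_abs),
            class = "mse_profile")
}

#' @export
print.mse_profile <- function(x, ...) {
  cat(sprintf("<mse_profile> m = %d, r_abs = %.4g, scales 1..%d\n",
              x$m, x$r_abs, x$tau_max))
  print(round(x$values, 4))
  invisible(x)
}

#' MSE profiles for a set of epochs, in long format
#'
#' @param epochs list of `eeg_epoch` objects (see [epoch_recording()]).
#' @inheritParams mse_profile
#' @return Long data frame: `trial`, `question`, `channel`, `band`,
#'   `scale`, `sampen`, `n_points`, `r_abs`. Undefined entries are `NA`;
#'   their count is reported via `message()`.
#' @export
mse_epochs <- function(epochs, m = 2L, r_factor = 0.15, tau_max = 20L) {
  rows <- lapply(epochs, function(ep) {
    prof <- mse_profile(ep$samples, m = m, r_factor = r_factor,
                        tau_max = tau_max)
    data.frame(trial = ep$trial, question = ep$question,
               channel = ep$channel, band = ep$band,
               scale = seq_len(tau_max), sampen = prof$values,
               n_points = prof$n_points, r_abs = prof$r_abs)
  })
  out <- do.call(rbind, rows)
  n_undef <- sum(is.na(out$sampen))
  if (n_undef > 0L)
    message("mse_epochs: ", n_undef, " undefined SampEn value(s) (A = 0)")
  out
}
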