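# Independent oracles and small shared utilities for the test suite.

# Naive exhaustive-pair sample-entropy counter: unordered template pairs
# from the first N - m starting positions, Chebyshev distance, inclusive
# tolerance. Kept independent of the package's optimized implementation.
sampen_oracle <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0L
  B <- 0L
  for (i in seq_len(nt - 1L)) {
    js <- (i + 1L):nt
    d <- abs(x[i] - x[js])
    for (k in seq_len(m - 1L)) d <- pmax(d, abs(x[i + k] - x[js + k]))
    hit <- d <= r
    B <- B + sum(hit)
    A <- A + sum(hit & abs(x[i + m] - x[js + m]) <= r)
  }
  list(A = A, B = B)
}

rms <- function(x) sqrt(mean(x^2))

jaccard_bits <- function(bits, truth_idx) {
  sel <- which(bits == 1L)
  length(intersect(sel, truth_idx)) / length(union(sel, truth_idx))
}

# small feature space used across ABC/classifier tests (d = 12)
toy_space <- function() feature_space(channels = paste0("C", 1:4),
                                      bands = c("x", "y", "z"))

# sine wave helper: `secs` seconds at `freq` Hz sampled at `fs`
sine_wave <- function(freq, fs = 1000, secs = 3) {
  t <- seq_len(fs * secs) / fs
  sin(2 * pi * freq * t)
}

quiet <- function(expr) suppressMessages(expr)

# 1/f ("pink") noise by spectral synthesis: amplitude ~ 1/sqrt(f),
# random phases, unit variance
one_over_f_noise <- function(n) {
  half <- n %/% 2
  amp <- 1 / sqrt(seq_len(half))
  phase <- runif(half, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- c(0, spec, Conj(rev(spec[seq_len(half - 1L)])))[seq_len(n)]
  x <- Re(fft(full, inverse = TRUE))
  (x - mean(x)) / sd(x)
}

# magnitude of the least-squares slope of an MSE profile over scales
profile_slope <- function(values) {
  scales <- seq_along(values)
  ok <- !is.na(values)
  abs(coef(lm(values[ok] ~ scales[ok]))[2])
}
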