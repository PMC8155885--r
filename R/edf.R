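# Minimal EDF (European Data Format) support: continuous recordings,
# 16-bit samples, identical sampling rate across signals. Covers the
# standard fixed-width ASCII header and little-endian int16 data records.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Samples are linearly quantized to 16 bits between the per-channel
#' physical minimum and maximum, so round-tripping is exact only up to
#' quantization (relative error about 3e-5 of the channel range).
#'
#' @param rec an [recording()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  nc <- nrow(rec$data); n <- ncol(rec$data)
  if (n %% rec$fs == 0) {
    spr <- as.integer(rec$fs); n_rec <- n %/% spr; rec_dur <- 1
  } else {
    spr <- n; n_rec <- 1L; rec_dur <- n / rec$fs
  }
  pmin_ <- apply(rec$data, 1L, min); pmax_ <- apply(rec$data, 1L, max)
  flat <- pmax_ - pmin_ < .Machine$double.eps
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.20", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * (1L + nc), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(format(rec_dur, digits = 7), 8), edf_pad(nc, 4))
  sig <- paste0(
    paste(vapply(rec$channel_names, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), nc), collapse = ""),
    paste(rep(edf_pad("uV", 8), nc), collapse = ""),
    paste(vapply(format(pmin_, digits = 7), edf_pad, "", width = 8), collapse = ""),
    paste(vapply(format(pmax_, digits = 7), edf_pad, "", width = 8), collapse = ""),
    paste(rep(edf_pad(dmin, 8), nc), collapse = ""),
    paste(rep(edf_pad(dmax, 8), nc), collapse = ""),
    paste(rep(edf_pad("", 80), nc), collapse = ""),
    paste(rep(edf_pad(spr, 8), nc), collapse = ""),
    paste(rep(edf_pad("", 32), nc), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(nc)) {
      dig <- round((rec$data[ch, idx] - pmin_[ch]) / gain[ch]) + dmin
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  ver <- rd(8); rd(80); rd(80); rd(8); rd(8)
  hbytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8)); nc <- as.integer(rd(4))
  if (is.na(nc) || nc < 1L || is.na(n_rec) || is.na(rec_dur))
    stop("format error: not a parseable EDF header in ", path)
  labels <- vapply(seq_len(nc), function(i) rd(16), "")
  for (i in seq_len(nc)) rd(80)                      # transducer
  for (i in seq_len(nc)) rd(8)                       # physical dimension
  pmin_ <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(nc)) rd(80)                      # prefiltering
  spr <- vapply(seq_len(nc), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(nc)) rd(32)                      # reserved
  if (length(unique(spr)) != 1L)
    stop("unsupported EDF: signals with differing sampling rates")
  seek(con, hbytes)
  out <- matrix(0, nrow = nc, ncol = n_rec * spr[1L])
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nc)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L, signed = TRUE,
                     endian = "little")
      if (length(dig) < spr[ch]) stop("format error: truncated EDF data records")
      out[ch, ((r - 1L) * spr[1L] + 1L):(r * spr[1L])] <-
        (dig - dmin[ch]) * gain[ch] + pmin_[ch]
    }
  }
  recording(out, fs = spr[1L] / rec_dur, channel_names = labels)
}
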