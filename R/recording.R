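#' EEG recording container
#'
#' A thin container for a multichannel EEG recording: a channels x samples
#' numeric matrix, a sampling rate, and ordered channel labels (10/20
#' system names such as `"FZ"`).
#'
#' @param data numeric matrix, channels x samples (amplitudes in microvolts).
#' @param fs sampling rate in Hz, a single positive number.
#' @param channel_names character vector of unique channel labels, one per
#'   row of `data`. Defaults to the matrix rownames, or `CH1..CHk`.
#' @return An object of class `eeg_recording` with elements `data`, `fs`,
#'   `channel_names`.
#' @export
recording <- function(data, fs, channel_names = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  if (is.null(channel_names)) {
    channel_names <- rownames(data)
    if (is.null(channel_names)) channel_names <- paste0("CH", seq_len(nrow(data)))
  }
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(data))
    stop("`channel_names` must have one entry per channel row")
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples / duration of a recording
#' @param rec an `eeg_recording`.
#' @return `n_samples`: integer sample count; `duration`: seconds.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_samples
#' @export
duration <- function(rec) ncol(rec$data) / rec$fs

#' Read a multichannel recording from CSV or EDF
#'
#' CSV layout: a header line of channel names followed by one row per
#' channel (samples across columns). The sampling rate is not stored in a
#' CSV, so it must be supplied. EDF files carry their own sampling rate.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"edf"`.
#' @param fs sampling rate in Hz, required for CSV input.
#' @return An [recording()] object.
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"), fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read recording: file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  rec <- if (format == "edf") read_edf(path) else {
    if (is.null(fs)) stop("`fs` must be given when reading CSV recordings")
    lines <- readLines(path)
    if (length(lines) < 2L) stop("format error: CSV needs a header plus one row per channel")
    chn <- strsplit(trimws(lines[1L]), ",")[[1L]]
    rows <- lapply(lines[-1L], function(l) as.numeric(strsplit(l, ",")[[1L]]))
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L)
      stop("format error: ragged CSV rows (sample counts ", paste(unique(lens), collapse = "/"), ")")
    if (length(rows) != length(chn))
      stop("format error: header names ", length(chn), " channels but file has ", length(rows), " rows")
    m <- do.call(rbind, rows)
    if (anyNA(m)) stop("format error: non-numeric values in CSV recording")
    recording(m, fs = fs, channel_names = chn)
  }
  message(sprintf("read_recording: %d channels, %d samples, fs = %g Hz",
                  nrow(rec$data), ncol(rec$data), rec$fs))
  rec
}

#' Write a recording as CSV (header of channel names, one row per channel)
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rec$channel_names, collapse = ","), con)
  apply(rec$data, 1L, function(row)
    writeLines(paste(format(row, digits = 10, trim = TRUE, scientific = FALSE),
                     collapse = ","), con))
  invisible(path)
}
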