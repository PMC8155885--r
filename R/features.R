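# Feature-space definition, feature-table assembly and bit masking.
#
# The classifier features are the MSE profiles of (channel, band) pairs.
# A selection bit vector over those pairs is the "food source" the ABC
# optimizer searches over: each bit gates that pair's full profile.

#' Default frontal channel set (10/20 system)
#' @return Character vector of the nine frontal channels.
#' @export
frontal_channels <- function() {
  c("AF3", "AF4", "F3", "F4", "F5", "F6", "F7", "F8", "FZ")
}

#' Define the (channel, band) feature space
#'
#' With the `"pairwise"` encoding each (channel, band) pair is one
#' selectable feature (d = 45 under the defaults), ordered channel-major.
#' The `"factored"` encoding instead uses one bit per channel plus one
#' per band (d = 14); a pair is retained when both its channel and band
#' bits are set.
#'
#' @param channels ordered channel labels (default [frontal_channels()]).
#' @param bands ordered band labels (default gamma, beta, alpha, delta,
#'   theta).
#' @param encoding `"pairwise"` or `"factored"`.
#' @return A `feature_space`: list with `channels`, `bands`, `features`
#'   (data frame of pairs), `d` (selection-vector length), `encoding`.
#' @export
feature_space <- function(channels = frontal_channels(),
                          bands = c("gamma", "beta", "alpha", "delta", "theta"),
                          encoding = c("pairwise", "factored")) {
  encoding <- match.arg(encoding)
  features <- expand.grid(band = bands, channel = channels,
                          stringsAsFactors = FALSE)[, c("channel", "band")]
  features$name <- paste(features$channel, features$band, sep = "_")
  d <- if (encoding == "pairwise") nrow(features)
       else length(channels) + length(bands)
  structure(list(channels = channels, bands = bands, features = features,
                 d = d, encoding = encoding),
            class = "feature_space")
}

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf("<feature_space> %d channels x %d bands, %s encoding, d = %d\n",
              length(x$channels), length(x$bands), x$encoding, x$d))
  invisible(x)
}

# Expand a selection bit vector to per-(channel,band)-pair indicators.
feature_bits <- function(space, bits) {
  if (length(bits) != space$d)
    stop("selection vector has length ", length(bits), ", expected d = ", space$d)
  bits <- as.integer(bits)
  if (space$encoding == "pairwise") return(bits)
  ch_bits <- bits[seq_along(space$channels)]
  bd_bits <- bits[length(space$channels) + seq_along(space$bands)]
  as.integer(ch_bits[match(space$features$channel, space$channels)] &
               bd_bits[match(space$features$band, space$bands)])
}

#' Assemble the classifier feature table
#'
#' Joins long-format MSE profiles with trial labels into one row per
#' labelled trial. By default only the 4th question's epochs feed the
#' table (the question governed by the hidden rule); passing several
#' questions concatenates their profiles. Rows containing undefined
#' SampEn values are dropped with a reported count.
#'
#' @param profiles long data frame from [mse_epochs()].
#' @param labels per-trial label table (needs `trial` and `label`,
#'   e.g. from [label_rt()] / [balance_classes()]); only fast/slow rows
#'   are used.
#' @param space a [feature_space()].
#' @param tau_max number of scales per feature (default 20).
#' @param questions which question epochs to use (default 4).
#' @return A `feature_table`: list with `x` (numeric matrix, one row per
#'   trial), `label` (factor fast/slow), `trial`, `space`, `tau_max`,
#'   `col_feature` (feature index of every column), `questions`.
#' @export
assemble_features <- function(profiles, labels, space = feature_space(),
                              tau_max = 20L, questions = 4L) {
  lab <- labels[labels$label %in% c("fast", "slow"), c("trial", "label")]
  if (nrow(lab) == 0L) stop("no fast/slow labelled trials to assemble")
  feats <- space$features
  cols <- expand.grid(scale = seq_len(tau_max), feature = seq_len(nrow(feats)),
                      question = seq_along(questions))[, c("question", "feature", "scale")]
  col_names <- paste0(feats$name[cols$feature],
                      if (length(questions) > 1L) paste0("_q", questions[cols$question]) else "",
                      "_s", cols$scale)
  # order columns feature-major within question: question, then feature, then scale
  x <- matrix(NA_real_, nrow = nrow(lab), ncol = nrow(cols),
              dimnames = list(lab$trial, col_names))
  key_p <- paste(profiles$trial, profiles$question, profiles$channel,
                 profiles$band, profiles$scale)
  for (qi in seq_along(questions)) {
    q <- questions[qi]
    sel <- cols$question == qi
    key_c <- paste(rep(lab$trial, each = sum(sel)), q,
                   feats$channel[cols$feature[sel]],
                   feats$band[cols$feature[sel]], cols$scale[sel])
    idx <- match(key_c, key_p)
    if (anyNA(idx)) {
      miss <- unique(key_c[is.na(idx)])
      stop("missing MSE profile entries for labelled trials, e.g.: ",
           paste(head(miss, 3L), collapse = "; "))
    }
    x[, sel] <- matrix(profiles$sampen[idx], nrow = nrow(lab), byrow = TRUE)
  }
  undef <- apply(x, 1L, anyNA)
  if (any(undef))
    message("assemble_features: dropping ", sum(undef),
            " trial(s) with undefined SampEn entries")
  x <- x[!undef, , drop = FALSE]
  lab <- lab[!undef, , drop = FALSE]
  structure(list(x = x, label = factor(lab$label, levels = c("fast", "slow")),
                 trial = lab$trial, space = space, tau_max = as.integer(tau_max),
                 col_feature = rep(cols$feature, 1L), questions = questions),
            class = "feature_table")
}

#' Construct a feature table directly from a matrix
#'
#' Used by the synthetic generator and tests; columns must be grouped by
#' feature with `tau_max` consecutive scale columns per feature.
#'
#' @param x numeric matrix (rows = trials, columns = features x scales).
#' @param label factor or character vector of `fast`/`slow` labels.
#' @param space a [feature_space()].
#' @param tau_max scales per feature.
#' @return A `feature_table`.
#' @export
feature_table <- function(x, label, space, tau_max) {
  tau_max <- as.integer(tau_max)
  nf <- nrow(space$features)
  if (ncol(x) != nf * tau_max)
    stop("x has ", ncol(x), " columns, expected ", nf, " x ", tau_max)
  structure(list(x = as.matrix(x),
                 label = factor(as.character(label), levels = c("fast", "slow")),
                 trial = seq_len(nrow(x)), space = space, tau_max = tau_max,
                 col_feature = rep(seq_len(nf), each = tau_max),
                 questions = 4L),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d trials x %d columns (%d features x %d scales); %s\n",
              nrow(x$x), ncol(x$x), length(unique(x$col_feature)), x$tau_max,
              paste(names(table(x$label)), table(x$label), sep = ": ",
                    collapse = ", ")))
  invisible(x)
}

#' Mask a feature table with a selection bit vector
#'
#' Retains only the columns of features whose bit is 1 (all scales of
#' each retained feature). An all-zero selection yields a table with zero
#' columns; the ABC fitness layer assigns such tables fitness 0.
#'
#' @param table a `feature_table`.
#' @param bits 0/1 vector of length `space$d`.
#' @return A `feature_table` with the retained columns, plus a `bits`
#'   element recording the selection.
#' @export
mask_features <- function(table, bits) {
  fb <- feature_bits(table$space, bits)
  keep <- fb[table$col_feature] == 1L
  out <- table
  out$x <- table$x[, keep, drop = FALSE]
  out$col_feature <- table$col_feature[keep]
  out$bits <- as.integer(bits)
  out
}

#' Write a feature table to CSV
#' @param table a `feature_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(table, path) {
  df <- data.frame(trial = table$trial, label = as.character(table$label),
                   table$x, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
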