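meta_cols <- function() c("channel", "segment", "label")

#' Extract the multiband entropy feature table of a recording
#'
#' The full feature-extraction front end: each channel is cut into
#' non-overlapping `segment_seconds` windows, each window is bandpassed
#' to the bank's global range (100-600 Hz by default), decomposed into
#' the N subbands, and each subband yields the eight-entropy vector.
#' Rows are channel-segment pairs; feature columns are subband-major
#' (`S01.APE ... S01.Ren, S02.APE, ...`), giving the `N * 8` per-row
#' vector that selection later prunes.
#'
#' Rows containing an undefined-estimator sentinel (`NA`) are dropped
#' with a warning, never imputed.
#'
#' @param rec an [ieeg_recording()].
#' @param bands an [make_filterbank()] table.
#' @param params an [entropy_params()] list.
#' @param segment_seconds segment length in seconds (default 20).
#' @param prefilter bandpass each segment to the bank's global range
#'   before subbanding (default `TRUE`).
#' @param zero_phase zero-phase filtering (default `TRUE`).
#' @param verbose print per-channel progress.
#' @return A data.frame of class `ieeg_features` with columns `channel`,
#'   `segment`, `label` and the feature columns; attributes
#'   `n_subbands`, `entropies`, `feature_cols`.
#' @export
extract_features <- function(rec, bands = make_filterbank(),
                             params = entropy_params(),
                             segment_seconds = 20, prefilter = TRUE,
                             zero_phase = TRUE, verbose = FALSE) {
  segs <- segment_recording(rec, segment_seconds)
  n_sub <- nrow(bands)
  ents <- entropy_names()
  fcols <- as.vector(t(outer(sprintf("S%02d", seq_len(n_sub)), ents,
                             paste, sep = ".")))
  glo <- min(bands$low_edge)
  ghi <- max(bands$high_edge)
  rows <- vector("list", length(segs))
  for (i in seq_along(segs)) {
    seg <- segs[[i]]
    if (verbose && seg$segment_index == 1L)
      message("channel ", seg$channel_id)
    x <- seg$x
    if (prefilter)
      x <- bandpass_filter(x, glo, ghi, rec$fs, order = bands$order[1L],
                           zero_phase = zero_phase)
    sub <- decompose(list(x = x), bands, fs = rec$fs,
                     zero_phase = zero_phase)
    v <- vapply(seq_len(n_sub),
                function(n) entropy_vector(sub, n, params),
                numeric(length(ents)))
    rows[[i]] <- c(as.vector(v))  # subband-major
  }
  feats <- do.call(rbind, rows)
  colnames(feats) <- fcols
  out <- data.frame(
    channel = vapply(segs, `[[`, "", "channel_id"),
    segment = vapply(segs, `[[`, 0L, "segment_index"),
    label = factor(vapply(segs, `[[`, "", "label"),
                   levels = c("focal", "nonfocal")),
    feats, check.names = FALSE)
  bad <- !stats::complete.cases(out)
  if (any(bad)) {
    warning(sum(bad), " channel-segment row(s) dropped: ",
            "undefined entropy estimate (see earlier warnings)")
    out <- out[!bad, , drop = FALSE]
  }
  structure(out, n_subbands = n_sub, entropies = ents,
            feature_cols = fcols,
            class = c("ieeg_features", "data.frame"))
}

#' Feature columns of one subband
#' @param ft an `ieeg_features` table.
#' @param n subband index.
#' @return Character vector of column names.
#' @export
subband_cols <- function(ft, n) {
  fcols <- attr(ft, "feature_cols")
  fcols[startsWith(fcols, sprintf("S%02d.", n))]
}

#' Numeric feature matrix of a feature table
#' @param ft an `ieeg_features` table.
#' @return Numeric matrix of the feature columns only.
#' @export
feature_matrix <- function(ft) {
  as.matrix(ft[, attr(ft, "feature_cols"), drop = FALSE])
}

#' Write / read a feature table as tidy TSV
#'
#' Long format: one row per (channel, segment, subband, entropy, value),
#' the batch-extraction interchange schema.
#'
#' @param ft an `ieeg_features` table.
#' @param path TSV path.
#' @return `path` invisibly for the writer; an `ieeg_features` table for
#'   the reader.
#' @export
write_features_tsv <- function(ft, path) {
  fcols <- attr(ft, "feature_cols")
  long <- do.call(rbind, lapply(fcols, function(cn) {
    parts <- strsplit(cn, ".", fixed = TRUE)[[1L]]
    data.frame(channel = ft$channel, segment = ft$segment,
               label = as.character(ft$label),
               subband = as.integer(sub("^S", "", parts[1L])),
               entropy = parts[2L], value = ft[[cn]])
  }))
  long <- long[order(long$channel, long$segment, long$subband), ]
  utils::write.table(long, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_features_tsv
#' @export
read_features_tsv <- function(path) {
  long <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  n_sub <- max(long$subband)
  ents <- entropy_names()
  fcols <- as.vector(t(outer(sprintf("S%02d", seq_len(n_sub)), ents,
                             paste, sep = ".")))
  key <- unique(long[, c("channel", "segment", "label")])
  key <- key[order(key$channel, key$segment), ]
  wide <- matrix(NA_real_, nrow(key), length(fcols),
                 dimnames = list(NULL, fcols))
  row_id <- match(paste(long$channel, long$segment),
                  paste(key$channel, key$segment))
  col_id <- match(sprintf("S%02d.%s", long$subband, long$entropy), fcols)
  wide[cbind(row_id, col_id)] <- long$value
  out <- data.frame(channel = key$channel, segment = key$segment,
                    label = factor(key$label,
                                   levels = c("focal", "nonfocal")),
                    wide, check.names = FALSE)
  structure(out, n_subbands = n_sub, entropies = ents,
            feature_cols = fcols,
            class = c("ieeg_features", "data.frame"))
}
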