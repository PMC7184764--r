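#' Construct a multichannel iEEG recording
#'
#' A recording bundles a channels-by-samples numeric matrix (microvolts)
#' with its sampling rate, channel labels and the epileptologist-style
#' channel annotation: a logical seizure-onset-zone (SOZ) mask marking the
#' focal channels.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz (scalar, > 0).
#' @param channel_ids character vector of channel labels; defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @param soz_mask logical vector, one entry per channel; `TRUE` marks a
#'   SOZ (focal) channel.
#' @return An object of class `ieeg_recording`: a list with elements
#'   `data`, `fs`, `channel_ids`, `soz_mask`.
#' @examples
#' rec <- ieeg_recording(matrix(rnorm(3 * 100), 3), fs = 2000,
#'                       soz_mask = c(TRUE, FALSE, FALSE))
#' rec
#' @export
ieeg_recording <- function(data, fs, channel_ids = NULL, soz_mask = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)")
  nch <- nrow(data)
  if (nch < 2L)
    stop("a recording needs at least 2 channels, got ", nch)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive scalar sampling rate in Hz")
  if (is.null(channel_ids))
    channel_ids <- paste0("ch", seq_len(nch))
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != nch)
    stop("`channel_ids` has length ", length(channel_ids),
         " but the matrix has ", nch, " channels")
  if (anyDuplicated(channel_ids))
    stop("duplicated channel id: ",
         channel_ids[duplicated(channel_ids)][1L])
  if (is.null(soz_mask))
    soz_mask <- rep(FALSE, nch)
  if (!is.logical(soz_mask) || length(soz_mask) != nch || anyNA(soz_mask))
    stop("`soz_mask` must be a complete logical vector of length ", nch)
  rownames(data) <- channel_ids
  structure(
    list(data = data, fs = fs, channel_ids = channel_ids,
         soz_mask = soz_mask),
    class = "ieeg_recording")
}

#' @export
print.ieeg_recording <- function(x, ...) {
  cat(sprintf(
    "<ieeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d SOZ\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
    sum(x$soz_mask)))
  if (any(x$soz_mask))
    cat("  SOZ channels:", paste(x$channel_ids[x$soz_mask],
                                 collapse = ", "), "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `ieeg_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

read_soz_sidecar <- function(path) {
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  ids[nzchar(ids) & !startsWith(ids, "#")]
}

#' Read a multichannel recording with SOZ labels
#'
#' Two on-disk layouts are accepted:
#' \describe{
#'   \item{EDF}{`path` ends in `.edf`; sampling rate and channel labels
#'     come from the EDF header; `labels` is a plain-text file listing the
#'     SOZ channel ids, one per line (or a character vector of ids).}
#'   \item{delimited matrix}{a tab/comma-delimited numeric matrix,
#'     channels as rows; `labels` is a JSON sidecar with keys `fs`
#'     (Hz), optional `channel_ids`, and `soz` (array of SOZ channel ids).}
#' }
#'
#' @param path path to the signal file.
#' @param labels path to the label sidecar (SOZ list for EDF, JSON for a
#'   delimited matrix), or a character vector of SOZ channel ids for EDF.
#' @return An [ieeg_recording()].
#' @export
read_recording <- function(path, labels) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    edf <- read_edf(path)
    soz_ids <- if (length(labels) == 1L && file.exists(labels))
      read_soz_sidecar(labels) else as.character(labels)
    unknown <- setdiff(soz_ids, edf$channel_ids)
    if (length(unknown))
      stop("SOZ label names unknown channel: ", unknown[1L])
    ieeg_recording(edf$data, fs = edf$fs, channel_ids = edf$channel_ids,
                   soz_mask = edf$channel_ids %in% soz_ids)
  } else {
    meta <- jsonlite::read_json(labels, simplifyVector = TRUE)
    if (is.null(meta$fs)) stop("sidecar ", labels, " lacks `fs`")
    data <- as.matrix(utils::read.table(path, header = FALSE,
                                        sep = sniff_sep(path)))
    dimnames(data) <- NULL
    channel_ids <- meta$channel_ids %||% paste0("ch", seq_len(nrow(data)))
    if (length(channel_ids) != nrow(data))
      stop("sidecar lists ", length(channel_ids), " channels but matrix has ",
           nrow(data), " rows; first sidecar channel: ", channel_ids[1L])
    soz_ids <- as.character(meta$soz %||% character())
    unknown <- setdiff(soz_ids, channel_ids)
    if (length(unknown))
      stop("SOZ label names unknown channel: ", unknown[1L])
    ieeg_recording(data, fs = meta$fs, channel_ids = channel_ids,
                   soz_mask = channel_ids %in% soz_ids)
  }
}

sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recording to disk
#'
#' Inverse of [read_recording()]. For `format = "edf"` the signal goes to
#' a 16-bit EDF file and the SOZ ids to a one-per-line text sidecar; for
#' `format = "matrix"` the signal goes to a tab-delimited matrix and the
#' metadata (fs, channel ids, SOZ list) to a JSON sidecar.
#'
#' @param rec an [ieeg_recording()].
#' @param path output signal file.
#' @param labels output sidecar path.
#' @param format `"edf"` or `"matrix"`; default guessed from `path`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, labels,
                            format = c("auto", "edf", "matrix")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "matrix"
  if (format == "edf") {
    write_edf(rec$data, rec$fs, rec$channel_ids, path)
    writeLines(rec$channel_ids[rec$soz_mask], labels)
  } else {
    utils::write.table(rec$data, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    jsonlite::write_json(
      list(fs = rec$fs, channel_ids = rec$channel_ids,
           soz = rec$channel_ids[rec$soz_mask]),
      labels, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Cut a recording into fixed-length non-overlapping segments
#'
#' Each channel is cut into consecutive windows of
#' `round(fs * segment_seconds)` samples starting at sample 1.  A trailing
#' remainder shorter than one window is dropped, so every channel yields
#' `floor(duration / segment_seconds)` segments.  Segments inherit the
#' focal/non-focal label of their channel's SOZ mask entry.
#'
#' @param rec an [ieeg_recording()].
#' @param segment_seconds window length in seconds (default 20).
#' @return A list of class `ieeg_segments`; each element is a segment:
#'   `list(x, channel_id, segment_index, label)` with `label` one of
#'   `"focal"`/`"nonfocal"`. Attributes `fs`, `n_segments` (per channel)
#'   and `segment_length` carry the layout.
#' @export
segment_recording <- function(rec, segment_seconds = 20) {
  L <- round(rec$fs * segment_seconds)
  n_samp <- ncol(rec$data)
  if (n_samp < L)
    stop("recording shorter than one segment (",
         n_samp, " < ", L, " samples)")
  s <- n_samp %/% L
  segs <- vector("list", nrow(rec$data) * s)
  idx <- 1L
  for (ch in seq_len(nrow(rec$data))) {
    lab <- if (rec$soz_mask[ch]) "focal" else "nonfocal"
    for (j in seq_len(s)) {
      segs[[idx]] <- list(
        x = rec$data[ch, ((j - 1L) * L + 1L):(j * L)],
        channel_id = rec$channel_ids[ch],
        segment_index = j,
        label = lab)
      idx <- idx + 1L
    }
  }
  structure(segs, class = "ieeg_segments", fs = rec$fs,
            n_segments = s, segment_length = L)
}

#' @export
print.ieeg_segments <- function(x, ...) {
  cat(sprintf(
    "<ieeg_segments> %d segments (%d per channel), L = %d samples @ %g Hz\n",
    length(x), attr(x, "n_segments"), attr(x, "segment_length"),
    attr(x, "fs")))
  invisible(x)
}
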