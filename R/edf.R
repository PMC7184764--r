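# Minimal EDF (European Data Format) i/o: fixed-layout ASCII header +
# little-endian 16-bit samples, one value range per signal.  Covers what
# an iEEG export needs (continuous signals, equal sampling rate); no
# EDF+ annotations.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = -width, flag = " ")
}

read_ascii <- function(con, n) {
  rawToChar(readBin(con, "raw", n))
}

#' Read an EDF file
#'
#' @param path path to an `.edf` file whose signals share one sampling
#'   rate.
#' @return list with `data` (channels x samples matrix, physical units),
#'   `fs` (Hz) and `channel_ids`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_ascii(con, 8L)                      # version
  read_ascii(con, 80L + 80L + 8L + 8L)     # patient, recording, date, time
  read_ascii(con, 8L)                      # header bytes
  read_ascii(con, 44L)                     # reserved
  n_rec <- as.integer(read_ascii(con, 8L))
  rec_dur <- as.numeric(read_ascii(con, 8L))
  ns <- as.integer(read_ascii(con, 4L))
  if (is.na(ns) || ns < 1L) stop("unsupported format: bad EDF header in ", path)
  fld <- function(w) trimws(vapply(seq_len(ns), function(i) read_ascii(con, w),
                                   ""))
  labels <- fld(16L)
  fld(80L); fld(8L)                        # transducer, physical dimension
  phys_min <- as.numeric(fld(8L))
  phys_max <- as.numeric(fld(8L))
  dig_min <- as.numeric(fld(8L))
  dig_max <- as.numeric(fld(8L))
  fld(80L)                                 # prefiltering
  spr <- as.integer(fld(8L))               # samples per record
  fld(32L)                                 # reserved
  if (length(unique(spr / rec_dur)) != 1L)
    stop("unsupported format: signals with differing sampling rates")
  fs <- spr[1L] / rec_dur
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- phys_min[s] +
        (dig - dig_min[s]) * (phys_max[s] - phys_min[s]) /
          (dig_max[s] - dig_min[s])
      data[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <- phys
    }
  }
  list(data = data, fs = fs, channel_ids = labels)
}

#' Write an EDF file
#'
#' Signals are scaled per channel to the full signed 16-bit range, so the
#' round trip through [read_edf()] is exact up to one quantization step
#' (amplitude / 32767).
#'
#' @param data channels x samples numeric matrix (physical units, uV).
#' @param fs sampling rate in Hz.
#' @param channel_ids channel labels (<= 16 characters each).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(data, fs, channel_ids, path) {
  ns <- nrow(data)
  n_samp <- ncol(data)
  # single data record holding the whole signal keeps any fs exact
  rec_dur <- n_samp / fs
  header_bytes <- 256L + 256L * ns
  pm <- apply(abs(data), 1L, max)
  pm[pm == 0] <- 1
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, w) writeBin(charToRaw(pad_field(x, w)), con)
  put("0", 8L)
  put("X X X X", 80L)
  put("Startdate X X X X", 80L)
  put("01.01.00", 8L); put("00.00.00", 8L)
  put(header_bytes, 8L)
  put("", 44L)
  put(1L, 8L)
  put(format(rec_dur, digits = 7), 8L)
  put(ns, 4L)
  for (id in channel_ids) put(id, 16L)
  for (i in seq_len(ns)) put("iEEG electrode", 80L)
  for (i in seq_len(ns)) put("uV", 8L)
  for (i in seq_len(ns)) put(format(-pm[i], digits = 7), 8L)
  for (i in seq_len(ns)) put(format(pm[i], digits = 7), 8L)
  for (i in seq_len(ns)) put(-32767L, 8L)
  for (i in seq_len(ns)) put(32767L, 8L)
  for (i in seq_len(ns)) put("", 80L)
  for (i in seq_len(ns)) put(n_samp, 8L)
  for (i in seq_len(ns)) put("", 32L)
  for (i in seq_len(ns)) {
    dig <- as.integer(round(data[i, ] / pm[i] * 32767))
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}
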