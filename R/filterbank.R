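#' Design a contiguous bandpass filter bank
#'
#' Splits `[global_low, global_high]` Hz into contiguous, non-overlapping
#' bands of equal `width`, each realized as a Butterworth bandpass of the
#' given order.  The default reproduces the high-frequency analysis bank
#' used for interictal HFO work: 100-600 Hz in ten 50 Hz subbands
#' covering the ripple (100-250 Hz) and fast-ripple (250-600 Hz) ranges.
#'
#' @param global_low,global_high overall band edges in Hz.
#' @param width subband width in Hz; must divide the overall range.
#' @param order Butterworth prototype order (default 3).
#' @return A data.frame of class `ieeg_filterbank` with columns `index`,
#'   `low_edge`, `high_edge`, `order`.
#' @examples
#' make_filterbank(100, 600, 50)   # 10 bands
#' @export
make_filterbank <- function(global_low = 100, global_high = 600,
                            width = 50, order = 3) {
  if (global_low <= 0 || global_high <= global_low)
    stop("need 0 < global_low < global_high")
  n_bands <- (global_high - global_low) / width
  if (abs(n_bands - round(n_bands)) > 1e-9)
    stop("band range ", global_low, "-", global_high,
         " Hz is not divisible by width ", width, " Hz")
  n_bands <- as.integer(round(n_bands))
  lows <- global_low + width * (seq_len(n_bands) - 1L)
  structure(
    data.frame(index = seq_len(n_bands), low_edge = lows,
               high_edge = lows + width, order = as.integer(order)),
    class = c("ieeg_filterbank", "data.frame"))
}

butter_bandpass <- function(low, high, order, fs) {
  ny <- fs / 2
  if (high >= ny)
    stop("band edge ", high, " Hz is at or above Nyquist (", ny, " Hz)")
  signal::butter(order, c(low, high) / ny, type = "pass")
}

#' Bandpass filter one signal
#'
#' @param x numeric vector.
#' @param low,high band edges in Hz.
#' @param fs sampling rate in Hz.
#' @param order Butterworth order.
#' @param zero_phase apply the filter forward and backward
#'   (`signal::filtfilt`, no phase distortion, squared magnitude
#'   response); `FALSE` gives the causal single pass.
#' @return Filtered vector, same length as `x`.
#' @export
bandpass_filter <- function(x, low, high, fs, order = 3,
                            zero_phase = TRUE) {
  flt <- butter_bandpass(low, high, order, fs)
  if (zero_phase) signal::filtfilt(flt, x) else
    as.numeric(signal::filter(flt, x))
}

#' Decompose a segment into subband signals
#'
#' Applies every band of the filter bank to the segment, yielding an
#' L-by-N matrix of narrowband signals (one column per subband).
#'
#' @param seg a segment from [segment_recording()], or a plain numeric
#'   vector.
#' @param bands an [make_filterbank()] band table.
#' @param fs sampling rate in Hz; taken from the segment set when `seg`
#'   comes from [segment_recording()] and `fs` is missing.
#' @param zero_phase see [bandpass_filter()].
#' @return A list of class `ieeg_subbands`: `signals` (L x N matrix),
#'   `bands`, `fs`, plus the parent segment's `channel_id`,
#'   `segment_index` and `label` when available.
#' @export
decompose <- function(seg, bands, fs = NULL, zero_phase = TRUE) {
  x <- if (is.list(seg)) seg$x else seg
  if (is.null(fs)) fs <- attr(seg, "fs")
  if (is.null(fs)) stop("`fs` is required when `seg` is a plain vector")
  L <- length(x)
  # filtfilt needs a few filter lengths of data to settle
  if (L < 24L * max(bands$order))
    stop("segment of ", L, " samples is too short for stable filtering")
  signals <- matrix(0, nrow = L, ncol = nrow(bands))
  for (i in seq_len(nrow(bands)))
    signals[, i] <- bandpass_filter(x, bands$low_edge[i],
                                    bands$high_edge[i], fs,
                                    order = bands$order[i],
                                    zero_phase = zero_phase)
  colnames(signals) <- sprintf("S%d", bands$index)
  structure(
    list(signals = signals, bands = bands, fs = fs,
         channel_id = if (is.list(seg)) seg$channel_id else NA_character_,
         segment_index = if (is.list(seg)) seg$segment_index else NA_integer_,
         label = if (is.list(seg)) seg$label else NA_character_),
    class = "ieeg_subbands")
}

#' Magnitude response of one filter-bank band
#'
#' @param band one-row slice of a filter bank.
#' @param freqs frequencies (Hz) at which to evaluate.
#' @param fs sampling rate in Hz.
#' @param zero_phase square the magnitude (forward-backward application).
#' @return numeric vector of linear magnitude gains at `freqs`.
#' @export
band_response <- function(band, freqs, fs, zero_phase = TRUE) {
  flt <- butter_bandpass(band$low_edge, band$high_edge, band$order, fs)
  w <- 2 * pi * freqs / fs
  z <- exp(1i * w)
  num <- outer(z, 0:(length(flt$b) - 1L), function(zz, k) zz^(-k)) %*% flt$b
  den <- outer(z, 0:(length(flt$a) - 1L), function(zz, k) zz^(-k)) %*% flt$a
  h <- abs(as.vector(num / den))
  if (zero_phase) h^2 else h
}
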