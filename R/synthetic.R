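#' Configuration of the synthetic interictal iEEG generator
#'
#' Describes a labeled multichannel recording: pink (1/f^gamma) Gaussian
#' background plus two families of Poisson-timed, Gaussian-windowed
#' sinusoidal bursts emulating high-frequency oscillations — ripples
#' (100-250 Hz) and fast ripples (250-600 Hz).  SOZ channels carry
#' `rate_ratio` times the baseline burst rate; that rate contrast is the
#' only systematic SOZ/non-SOZ difference, which is exactly what the
#' detection pipeline is supposed to pick up.
#'
#' Defaults are desk scale (12 channels, 2 SOZ, 5 min at 2 kHz) with the
#' strong-contrast regime (`rate_ratio = 8`, burst amplitude 3 background
#' SDs); baseline rates of 2 ripple and 1 fast-ripple bursts per minute
#' on non-SOZ channels sit in the range reported for interictal HFOs.
#'
#' @param n_channels,n_soz channel counts (`n_soz < n_channels`).
#' @param soz_channels SOZ channel indices; default the first `n_soz`.
#' @param fs sampling rate, Hz.
#' @param duration recording length, seconds.
#' @param bg_gamma 1/f^gamma background spectral exponent.
#' @param bg_amplitude background SD, microvolts.
#' @param ripple,fast_ripple burst-family settings: `rate` (bursts/min,
#'   baseline), `duration_ms`, `amplitude` (multiples of the background
#'   SD), `band` (Hz).
#' @param rate_ratio SOZ over non-SOZ burst-rate multiplier (>= 1).
#' @param seed integer seed; generation is bit-reproducible for a fixed
#'   seed and the global RNG state is restored.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_channels = 12L, n_soz = 2L,
                         soz_channels = NULL, fs = 2000,
                         duration = 300, bg_gamma = 1,
                         bg_amplitude = 25,
                         ripple = list(rate = 2, duration_ms = 80,
                                       amplitude = 3, band = c(100, 250)),
                         fast_ripple = list(rate = 1, duration_ms = 40,
                                            amplitude = 3,
                                            band = c(250, 600)),
                         rate_ratio = 8, seed = 1L) {
  if (is.null(soz_channels)) soz_channels <- seq_len(n_soz)
  n_soz <- length(soz_channels)
  if (n_soz >= n_channels)
    stop("need n_soz < n_channels")
  if (rate_ratio < 1) stop("rate_ratio must be >= 1")
  for (fam in list(ripple, fast_ripple))
    if (fam$band[2L] >= fs / 2)
      stop("burst band edge ", fam$band[2L],
           " Hz is at or above Nyquist (", fs / 2, " Hz)")
  structure(list(n_channels = as.integer(n_channels),
                 soz_channels = as.integer(soz_channels), fs = fs,
                 duration = duration, bg_gamma = bg_gamma,
                 bg_amplitude = bg_amplitude, ripple = ripple,
                 fast_ripple = fast_ripple, rate_ratio = rate_ratio,
                 seed = seed),
            class = "synth_config")
}

# 1/f^gamma Gaussian noise via spectral shaping, unit SD
pink_noise <- function(n, gamma) {
  w <- stats::rnorm(n)
  if (gamma == 0) return(w)
  W <- stats::fft(w)
  k <- c(1, seq_len(n - 1L))
  f <- pmin(k, n - k)  # symmetric frequency index, DC -> bin 1
  W <- W * f^(-gamma / 2)
  W[1L] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x / stats::sd(x)
}

gabor_burst <- function(fs, freq, duration_ms, amplitude, phase) {
  n <- max(round(fs * duration_ms / 1000), 8L)
  t <- (seq_len(n) - (n + 1) / 2) / fs
  sigma <- (duration_ms / 1000) / 6
  amplitude * exp(-t^2 / (2 * sigma^2)) * sin(2 * pi * freq * t + phase)
}

#' Generate a labeled synthetic interictal iEEG recording
#'
#' @param config a [synth_config()].
#' @return List of class `synth_ieeg`: `recording` (an
#'   [ieeg_recording()]) and `annotations`, a data.frame of every
#'   injected burst (`channel`, `onset_s`, `band` family, `freq_hz`,
#'   `amplitude`).
#' @export
generate_ieeg <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    n_samp <- round(config$fs * config$duration)
    data <- matrix(0, config$n_channels, n_samp)
    ann <- list()
    soz <- seq_len(config$n_channels) %in% config$soz_channels
    for (ch in seq_len(config$n_channels)) {
      x <- pink_noise(n_samp, config$bg_gamma) * config$bg_amplitude
      for (fam_name in c("ripple", "fast_ripple")) {
        fam <- config[[fam_name]]
        rate <- fam$rate * if (soz[ch]) config$rate_ratio else 1
        n_burst <- stats::rpois(1L, rate * config$duration / 60)
        if (n_burst == 0L) next
        # keep burst centers inside the family band even after the
        # Gaussian envelope widens the spectrum
        margin <- min(25, diff(fam$band) / 4)
        freqs <- stats::runif(n_burst, fam$band[1L] + margin,
                              fam$band[2L] - margin)
        onsets <- stats::runif(n_burst, 0,
                               config$duration - fam$duration_ms / 1000)
        phases <- stats::runif(n_burst, 0, 2 * pi)
        for (b in seq_len(n_burst)) {
          wav <- gabor_burst(config$fs, freqs[b], fam$duration_ms,
                             fam$amplitude * config$bg_amplitude,
                             phases[b])
          i0 <- round(onsets[b] * config$fs) + 1L
          idx <- i0:(i0 + length(wav) - 1L)
          keep <- idx <= n_samp
          x[idx[keep]] <- x[idx[keep]] + wav[keep]
        }
        ann[[length(ann) + 1L]] <- data.frame(
          channel = paste0("ch", ch), onset_s = onsets, band = fam_name,
          freq_hz = freqs, amplitude = fam$amplitude)
      }
      data[ch, ] <- x
    }
    rec <- ieeg_recording(data, fs = config$fs, soz_mask = soz)
    annotations <- if (length(ann)) do.call(rbind, ann) else
      data.frame(channel = character(), onset_s = numeric(),
                 band = character(), freq_hz = numeric(),
                 amplitude = numeric())
    structure(list(recording = rec, annotations = annotations,
                   config = config),
              class = "synth_ieeg")
  })
}

#' @export
print.synth_ieeg <- function(x, ...) {
  print(x$recording)
  cat("  ", nrow(x$annotations), "injected bursts\n")
  invisible(x)
}

#' Eight-patient electrode-montage profiles
#'
#' The electrode layouts of the clinical eight-patient reference cohort
#' (see [reference_benchmarks()]): channel count, SOZ channel indices,
#' and the per-patient sparsity preset (entropies kept per subband).
#'
#' @return A data.frame with one row per profile: `patient`,
#'   `n_electrodes`, `soz_channels` (list column of indices), `n_soz`,
#'   `G` (selection preset, `|delta1|`).
#' @export
patient_profiles <- function() {
  soz <- list(
    Pt1 = c(10, 11, 16),
    Pt2 = c(9, 10, 13, 14, 17, 18, 26, 32, 38),
    Pt3 = c(7, 8, 9, 10, 11, 17, 18),
    Pt4 = c(16, 22, 23),
    Pt5 = c(34, 40, 41),
    Pt6 = c(9, 10, 11, 12, 32, 37),
    Pt7 = c(15, 16, 29, 30, 35, 36, 42, 48),
    Pt8 = c(6, 7, 8))
  out <- data.frame(
    patient = names(soz),
    n_electrodes = c(60L, 50L, 42L, 36L, 60L, 70L, 71L, 76L),
    n_soz = lengths(soz),
    G = c(5L, 5L, 3L, 5L, 3L, 4L, 6L, 3L))
  out$soz_channels <- unname(soz)
  out
}

#' Synthetic recording shaped like one reference patient
#'
#' Generates a synthetic stand-in for one clinical montage: the profile's
#' electrode count and SOZ channel indices, 30 minutes at 2 kHz (hence 90
#' twenty-second segments per channel).  The signal content is synthetic
#' (see [synth_config()]); only the montage geometry follows the profile.
#'
#' @param patient_profile profile id, `"Pt1"` ... `"Pt8"`.
#' @param duration recording length in seconds (default the full 1800).
#' @param ... further [synth_config()] overrides (e.g. `seed`).
#' @return A `synth_ieeg` list, as from [generate_ieeg()].
#' @export
make_cohort_recording <- function(patient_profile, duration = 1800,
                                    ...) {
  prof <- patient_profiles()
  i <- match(patient_profile, prof$patient)
  if (is.na(i)) stop("unknown profile: ", patient_profile)
  cfg <- synth_config(n_channels = prof$n_electrodes[i],
                      soz_channels = prof$soz_channels[[i]],
                      fs = 2000, duration = duration, ...)
  generate_ieeg(cfg)
}
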