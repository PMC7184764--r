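#' Default parameters of the eight-entropy feature set
#'
#' Central place for the estimator settings: embedding dimension `d = 2`
#' and tolerance `r = 0.2 * SD` for approximate/sample entropy, `d = 3`,
#' `tau = 1` for permutation entropy, Rényi order `alpha = 2`, Tsallis
#' index `q = 2`, and the bispectrum estimator layout (number of epochs
#' and FFT length).  `ape_max_samples` bounds the O(L^2) approximate- and
#' sample-entropy cost on long segments by stride subsampling; set it to
#' `Inf` for the exact path.
#'
#' @param d_embed embedding dimension for approximate/sample entropy.
#' @param r_factor tolerance as a multiple of the signal SD.
#' @param pe_d,pe_tau permutation-entropy order and time lag.
#' @param alpha Rényi order (not 1).
#' @param q Tsallis entropic index (not 1).
#' @param metric template distance, `"chebyshev"` (default) or
#'   `"euclidean"`.
#' @param ape_max_samples maximum samples fed to approximate/sample
#'   entropy; longer signals are stride-subsampled.
#' @param bispec_epochs,bispec_nfft bispectrum averaging epochs and FFT
#'   length per epoch.
#' @param renyi_literal use the non-standard literal Rényi variant (see
#'   [renyi_spectral()]).
#' @return A named list of class `entropy_params`.
#' @export
entropy_params <- function(d_embed = 2L, r_factor = 0.2, pe_d = 3L,
                           pe_tau = 1L, alpha = 2, q = 2,
                           metric = c("chebyshev", "euclidean"),
                           ape_max_samples = 4000L, bispec_epochs = 31L,
                           bispec_nfft = 1024L, renyi_literal = FALSE) {
  stopifnot(d_embed >= 2L, r_factor > 0, pe_tau >= 1L, alpha != 1, q != 1)
  structure(list(d_embed = as.integer(d_embed), r_factor = r_factor,
                 pe_d = as.integer(pe_d), pe_tau = as.integer(pe_tau),
                 alpha = alpha, q = q, metric = match.arg(metric),
                 ape_max_samples = ape_max_samples,
                 bispec_epochs = as.integer(bispec_epochs),
                 bispec_nfft = as.integer(bispec_nfft),
                 renyi_literal = renyi_literal),
            class = "entropy_params")
}

#' Fixed order of the eight entropy features
#' @return Character vector of the feature names, in canonical order.
#' @export
entropy_names <- function() c("APE", "PE", "Sh", "Sp", "Ts", "S2", "S1", "Ren")

#' Approximate entropy
#'
#' Regularity statistic of Pincus: the log-likelihood that template
#' vectors of length `d` close within tolerance `r` stay close when
#' extended to length `d + 1`, self-matches included:
#' `APE = phi(d) - phi(d+1)` with
#' `phi(m) = mean_i log C_i^m(r)` and `C_i^m(r)` the fraction of
#' templates within `r` of template `i`.
#'
#' @param x numeric signal.
#' @param d embedding dimension (default 2).
#' @param r tolerance; default `0.2 * sd(x)`.
#' @param metric `"chebyshev"` (max-coordinate, the standard) or
#'   `"euclidean"` template distance.
#' @return Approximate entropy (nats).
#' @export
approximate_entropy <- function(x, d = 2L, r = 0.2 * stats::sd(x),
                                metric = c("chebyshev", "euclidean")) {
  metric <- match.arg(metric)
  L <- length(x)
  if (L <= d + 1L)
    stop("signal of length ", L, " too short for embedding dimension ", d)
  if (is.na(r) || r < 0) stop("tolerance `r` must be >= 0")
  apen_cpp(as.numeric(x), as.integer(d), r, metric == "chebyshev")
}

#' Sample entropy
#'
#' Bias-reduced variant of approximate entropy: `-log(A/B)` where `B`
#' and `A` count template pairs matching within `r` at dimensions `d`
#' and `d + 1`, self-matches excluded.  When no `d + 1` pair matches the
#' statistic is undefined; `NA` is returned with a warning (sentinel,
#' never silently imputed).
#'
#' @inheritParams approximate_entropy
#' @return Sample entropy (nats), or `NA` when undefined.
#' @export
sample_entropy <- function(x, d = 2L, r = 0.2 * stats::sd(x),
                           metric = c("chebyshev", "euclidean")) {
  metric <- match.arg(metric)
  L <- length(x)
  if (L <= d + 1L)
    stop("signal of length ", L, " too short for embedding dimension ", d)
  if (is.na(r) || r < 0) stop("tolerance `r` must be >= 0")
  ab <- sampen_counts_cpp(as.numeric(x), as.integer(d), r,
                          metric == "chebyshev")
  if (ab[2L] == 0 || ab[1L] == 0) {
    warning("undefined sample entropy: no template matches within r")
    return(NA_real_)
  }
  -log(ab[1L] / ab[2L])
}

# ordinal pattern key per embedding window: rank vector encoded base d,
# ties broken by time index (stable), vectorized over windows
ordinal_pattern_keys <- function(x, d, tau) {
  n <- length(x) - (d - 1L) * tau
  emb <- vapply(seq_len(d),
                function(k) x[(1L + (k - 1L) * tau):(n + (k - 1L) * tau)],
                numeric(n))
  if (n == 1L) emb <- matrix(emb, nrow = 1L)
  key <- integer(n)
  for (k in seq_len(d)) {
    rk <- integer(n)
    for (j in seq_len(d)) {
      if (j == k) next
      rk <- rk + (emb[, j] < emb[, k]) + (emb[, j] == emb[, k]) * (j < k)
    }
    key <- key + rk * d^(k - 1L)
  }
  key
}

#' Permutation entropy
#'
#' Shannon entropy (base 2) of the ordinal-pattern distribution of
#' length-`d`, lag-`tau` embedding windows.  Bounded by `log2(d!)`;
#' equal values inside a window are ranked by time order.
#'
#' @param x numeric signal.
#' @param d embedding order (default 3).
#' @param tau time lag (default 1).
#' @return Permutation entropy in bits, in `[0, log2(d!)]`.
#' @export
permutation_entropy <- function(x, d = 3L, tau = 1L) {
  n <- length(x) - (d - 1L) * tau
  if (n < 2L)
    stop("signal of length ", length(x),
         " too short for order ", d, ", lag ", tau)
  counts <- table(ordinal_pattern_keys(x, d, tau))
  p <- as.numeric(counts) / n
  -sum(p * log2(p))
}

#' Normalized power-spectral distribution
#'
#' One-sided periodogram of the signal (rectangular window, DC bin
#' excluded) normalized to a probability distribution over frequency
#' bins: `p_f = P_f / sum(P_f)`.
#'
#' @param x numeric signal.
#' @return Numeric probability vector over the positive-frequency bins.
#' @export
power_spectrum_probs <- function(x) {
  L <- length(x)
  if (L < 4L) stop("signal too short for a spectrum")
  Pall <- Mod(stats::fft(x))^2
  P <- Pall[2:(L %/% 2 + 1L)]
  tot <- sum(P)
  # a constant signal leaves only round-off outside the DC bin
  if (!is.finite(tot) || tot <= 0 || tot <= sum(Pall) * 1e-20)
    stop("zero spectral power")
  P / tot
}

#' Spectral Shannon entropy
#' @param p_f probability vector from [power_spectrum_probs()].
#' @return `-sum(p log p)` in nats, ignoring empty bins.
#' @export
shannon_spectral <- function(p_f) {
  p <- p_f[p_f > 0]
  -sum(p * log(p))
}

#' Spectral Rényi entropy
#'
#' Standard Rényi entropy of order `alpha`:
#' `(1 / (1 - alpha)) * log(sum(p^alpha))`, which is `<=` the Shannon
#' entropy for `alpha > 1`.  `literal = TRUE` instead evaluates the
#' variant `(1 / (1 - alpha)) * sum(log(p^2))`, which diverges whenever a
#' bin is empty; it is provided for comparison only.
#'
#' @param p_f probability vector.
#' @param alpha Rényi order, `alpha != 1` (default 2).
#' @param literal evaluate the non-standard variant form.
#' @return Rényi entropy (nats).
#' @export
renyi_spectral <- function(p_f, alpha = 2, literal = FALSE) {
  if (alpha == 1) stop("alpha = 1 is the Shannon limit; use shannon_spectral()")
  if (literal) return(sum(log(p_f^2)) / (1 - alpha))
  log(sum(p_f^alpha)) / (1 - alpha)
}

#' Spectral Tsallis entropy
#'
#' `(1 - sum(p^q)) / (q - 1)`; for `q = 2` this lies in `[0, 1 - 1/F]`
#' over `F` bins.
#'
#' @param p_f probability vector.
#' @param q entropic index, `q != 1` (default 2).
#' @return Tsallis entropy.
#' @export
tsallis_spectral <- function(p_f, q = 2) {
  if (q == 1) stop("q = 1 is the Shannon limit; use shannon_spectral()")
  (1 - sum(p_f^q)) / (q - 1)
}

.domain_cache <- new.env(parent = emptyenv())

# principal bispectral domain f1 >= f2 >= 0, f1 + f2 <= Nyquist,
# as a logical mask plus its (f1+1, f2+1) index vectors, cached per nfft
principal_domain <- function(nfft) {
  key <- as.character(nfft)
  got <- .domain_cache[[key]]
  if (!is.null(got)) return(got)
  K <- nfft %/% 2L
  idx <- 0:K
  mask <- outer(idx, idx, ">=") & (outer(idx, idx, "+") <= K)
  w <- which(mask, arr.ind = TRUE)           # rows = f1 + 1, cols = f2 + 1
  out <- list(mask = mask, i1 = w[, 1L], i2 = w[, 2L])
  .domain_cache[[key]] <- out
  out
}

#' Bispectrum estimate (direct FFT method)
#'
#' Estimates `B(f1, f2) = E[F(f1) F(f2) conj(F(f1 + f2))]` by splitting
#' the signal into `epochs` non-overlapping epochs of `nfft` samples,
#' removing each epoch's mean, and averaging the triple product of epoch
#' FFTs over the principal domain `f1 >= f2 >= 0`, `f1 + f2 <= ` Nyquist.
#'
#' @param x numeric signal of length `>= epochs * nfft`.
#' @param epochs number of averaging epochs.
#' @param nfft FFT length per epoch.
#' @return List of class `ieeg_bispectrum`: complex matrix `B`
#'   (`(nfft/2 + 1)` square, rows `f1`, cols `f2`), logical `mask` of the
#'   principal domain, `nfft`, `epochs`.
#' @export
bispectrum <- function(x, epochs = 31L, nfft = 1024L) {
  L <- length(x)
  if (L < epochs * nfft)
    stop("signal of ", L, " samples too short for ", epochs,
         " epochs of ", nfft)
  K <- nfft %/% 2L
  ep <- matrix(x[seq_len(epochs * nfft)], nfft, epochs)
  ep <- sweep(ep, 2L, colMeans(ep))
  Fm <- stats::mvfft(ep)                     # nfft x epochs
  dom <- principal_domain(nfft)
  mask <- dom$mask
  i1 <- dom$i1; i2 <- dom$i2; i12 <- i1 + i2 - 1L
  acc <- complex(length(i1))
  for (e in seq_len(epochs)) {
    Fe <- Fm[, e]
    acc <- acc + Fe[i1] * Fe[i2] * Conj(Fe[i12])
  }
  B <- matrix(0 + 0i, K + 1L, K + 1L)
  B[mask] <- acc / epochs
  structure(list(B = B, mask = mask, nfft = nfft, epochs = epochs),
            class = "ieeg_bispectrum")
}

#' Bispectral phase entropies
#'
#' Shannon entropies of the normalized bispectral magnitude over the
#' principal domain: `S1` from `p = |B| / sum|B|` and `S2` from
#' `q = |B|^2 / sum|B|^2`.  Squaring sharpens the distribution, so
#' `S2 <= S1`.
#'
#' @param B an [bispectrum()] object (or a complex matrix, in which case
#'   every entry is used).
#' @return Named numeric vector `c(S1 = , S2 = )`, in nats.
#' @export
phase_entropies <- function(B) {
  mag <- if (inherits(B, "ieeg_bispectrum")) Mod(B$B[B$mask]) else Mod(B)
  tot <- sum(mag)
  if (tot <= 0 || !is.finite(tot)) stop("zero bispectral mass")
  p <- mag / tot
  q <- mag^2 / sum(mag^2)
  c(S1 = shannon_spectral(p), S2 = shannon_spectral(q))
}

subsample_for_templates <- function(x, max_samples) {
  L <- length(x)
  if (!is.finite(max_samples) || L <= max_samples) return(x)
  x[seq(1L, L, by = ceiling(L / max_samples))]
}

#' Eight-entropy feature vector of one subband signal
#'
#' Computes, in canonical order ([entropy_names()]): approximate entropy
#' (APE), permutation entropy (PE), spectral Shannon (Sh), sample entropy
#' (Sp), spectral Tsallis (Ts), bispectral phase entropies (S2, S1) and
#' spectral Rényi (Ren).  The approximate/sample tolerance is
#' `r_factor * SD` of the (possibly subsampled) subband signal, scoped
#' per subband per segment.  Estimators that are undefined on the input
#' (no sample-entropy matches, zero spectral or bispectral power) yield
#' `NA` sentinels with a warning.
#'
#' @param sub an [decompose()] result, or a plain numeric vector.
#' @param n subband index into `sub$signals` (ignored for a vector).
#' @param params an [entropy_params()] list.
#' @return Named numeric vector of length 8.
#' @export
entropy_vector <- function(sub, n = 1L, params = entropy_params()) {
  x <- if (inherits(sub, "ieeg_subbands")) sub$signals[, n] else sub
  xt <- subsample_for_templates(x, params$ape_max_samples)
  r <- params$r_factor * stats::sd(xt)
  out <- c(APE = NA_real_, PE = NA_real_, Sh = NA_real_, Sp = NA_real_,
           Ts = NA_real_, S2 = NA_real_, S1 = NA_real_, Ren = NA_real_)
  out["APE"] <- approximate_entropy(xt, d = params$d_embed, r = r,
                                    metric = params$metric)
  out["Sp"] <- sample_entropy(xt, d = params$d_embed, r = r,
                              metric = params$metric)
  out["PE"] <- permutation_entropy(x, d = params$pe_d, tau = params$pe_tau)
  spec <- tryCatch(power_spectrum_probs(x), error = function(e) {
    warning("spectral entropies undefined: ", conditionMessage(e))
    NULL
  })
  if (!is.null(spec)) {
    out["Sh"] <- shannon_spectral(spec)
    out["Ren"] <- renyi_spectral(spec, alpha = params$alpha,
                                 literal = params$renyi_literal)
    out["Ts"] <- tsallis_spectral(spec, q = params$q)
  }
  ph <- tryCatch({
    nfft <- params$bispec_nfft
    epochs <- min(params$bispec_epochs, length(x) %/% nfft)
    if (epochs < 1L) stop("signal shorter than one bispectrum epoch")
    phase_entropies(bispectrum(x, epochs = epochs, nfft = nfft))
  }, error = function(e) {
    warning("phase entropies undefined: ", conditionMessage(e))
    NULL
  })
  if (!is.null(ph)) {
    out["S1"] <- ph[["S1"]]
    out["S2"] <- ph[["S2"]]
  }
  out
}
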