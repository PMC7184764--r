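test_that("approximate entropy matches the brute-force oracle", {
  set.seed(10)
  x <- runif(200)
  r <- 0.2 * sd(x)
  expect_equal(approximate_entropy(x, 2, r), oracle_apen(x, 2, r),
               tolerance = 1e-10)
  expect_equal(approximate_entropy(x, 2, r, metric = "euclidean"),
               oracle_apen(x, 2, r, "euclidean"), tolerance = 1e-10)
  expect_equal(approximate_entropy(x, 3, 0.5 * r),
               oracle_apen(x, 3, 0.5 * r), tolerance = 1e-10)
  expect_equal(approximate_entropy(rep(5, 50)), 0)
})

test_that("approximate entropy ranks periodic below shuffled", {
  set.seed(11)
  per <- rep(c(1, 2), 50)
  shuf <- sample(per)
  r <- 0.2 * sd(per)
  expect_lte(approximate_entropy(per, r = r),
             approximate_entropy(shuf, r = r))
})

test_that("sample entropy matches the brute-force oracle", {
  set.seed(12)
  x <- runif(200)
  r <- 0.2 * sd(x)
  expect_equal(sample_entropy(x, 2, r), oracle_sampen(x, 2, r),
               tolerance = 1e-10)
  expect_equal(sample_entropy(x, 2, r, metric = "euclidean"),
               oracle_sampen(x, 2, r, "euclidean"), tolerance = 1e-10)
  expect_equal(sample_entropy(rep(2, 50)), 0)
  # a sinusoid is more regular than its shuffle
  s <- sin(2 * pi * 5 * seq_len(400) / 400)
  set.seed(13)
  expect_lt(sample_entropy(s), sample_entropy(sample(s)))
})

test_that("sample entropy with no matches is an NA sentinel, not a crash", {
  x <- c(0, 10, -3, 25, -17, 40, -31, 57, -45, 70)  # widely spread
  expect_warning(v <- sample_entropy(x, 2, r = 0.01), "undefined")
  expect_true(is.na(v))
})

test_that("permutation entropy counts ordinal patterns exactly", {
  set.seed(14)
  x <- rnorm(500)
  expect_equal(permutation_entropy(x, 3, 1), oracle_pe(x, 3, 1))
  expect_equal(permutation_entropy(x, 4, 2), oracle_pe(x, 4, 2))
  expect_equal(permutation_entropy(seq_len(50)), 0)   # single pattern
  expect_lte(permutation_entropy(x, 3, 1), log2(factorial(3)))
  # iid noise approaches the log2(d!) ceiling
  expect_gt(permutation_entropy(rnorm(20000), 3, 1), log2(6) - 0.01)
})

test_that("permutation entropy is invariant to monotone transforms", {
  set.seed(15)
  x <- rnorm(300)
  expect_equal(permutation_entropy(exp(x)), permutation_entropy(x))
  expect_equal(permutation_entropy(2 * x + 7), permutation_entropy(x))
})

test_that("template entropies with r = 0.2 SD are scale invariant", {
  set.seed(16)
  x <- rnorm(150)
  expect_equal(approximate_entropy(3.7 * x), approximate_entropy(x),
               tolerance = 1e-12)
  expect_equal(sample_entropy(3.7 * x), sample_entropy(x),
               tolerance = 1e-12)
})

test_that("spectral probabilities normalize and localize tones", {
  L <- 1024
  t <- seq_len(L)
  x <- sin(2 * pi * 32 * t / L)          # exact FFT bin
  p <- power_spectrum_probs(x)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_gte(max(p), 0.99)
  expect_equal(which.max(p), 32L)
  two <- x + sin(2 * pi * 100 * t / L)
  p2 <- power_spectrum_probs(two)
  expect_equal(sort(p2, decreasing = TRUE)[1:2], c(0.5, 0.5),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(power_spectrum_probs(numeric(64)), "zero spectral power")
})

test_that("spectral entropy family matches closed forms and oracles", {
  F_bins <- 16
  one <- c(1, rep(0, F_bins - 1))
  unif <- rep(1 / F_bins, F_bins)
  expect_equal(shannon_spectral(one), 0)
  expect_equal(shannon_spectral(unif), log(F_bins))
  expect_equal(renyi_spectral(one), 0)
  expect_equal(renyi_spectral(unif), log(F_bins))
  expect_equal(tsallis_spectral(one), 0)
  expect_equal(tsallis_spectral(unif), 1 - 1 / F_bins)
  set.seed(17)
  p <- runif(40); p <- p / sum(p)
  expect_equal(shannon_spectral(p), oracle_shannon(p), tolerance = 1e-12)
  expect_equal(tsallis_spectral(p), 1 - sum(p^2), tolerance = 1e-12)
  expect_equal(tsallis_spectral(p, 3), oracle_tsallis(p, 3),
               tolerance = 1e-12)
  expect_lte(renyi_spectral(p), shannon_spectral(p))
  expect_error(renyi_spectral(p, alpha = 1), "alpha")
  expect_error(tsallis_spectral(p, q = 1), "q = 1")
})

test_that("bispectrum peaks at quadratically phase-coupled triples", {
  set.seed(18)
  nfft <- 256
  n <- 16 * nfft
  t <- seq_len(n)
  f1 <- 24 / nfft; f2 <- 9 / nfft
  ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
  x <- cos(2 * pi * f1 * t + ph1) + cos(2 * pi * f2 * t + ph2) +
    cos(2 * pi * (f1 + f2) * t + ph1 + ph2) + 0.1 * rnorm(n)
  bs <- bispectrum(x, epochs = 16, nfft = nfft)
  mag <- Mod(bs$B)
  peak <- which(mag == max(mag[bs$mask]), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(24 + 1, 9 + 1))  # (f1, f2) bins
})

test_that("bispectrum of white noise shrinks with more epochs", {
  set.seed(19)
  x <- rnorm(64 * 128)
  few <- max(Mod(bispectrum(x, epochs = 4, nfft = 128)$B))
  many <- max(Mod(bispectrum(x, epochs = 64, nfft = 128)$B))
  expect_lt(many, few)
  expect_error(bispectrum(rnorm(100), epochs = 4, nfft = 128),
               "too short")
})

test_that("phase entropies follow the bispectral magnitude distribution", {
  single <- matrix(0 + 0i, 4, 4); single[2, 2] <- 3 + 1i
  ph <- phase_entropies(single)
  expect_equal(unname(ph), c(0, 0))
  unif <- matrix(2 + 0i, 5, 5)
  expect_equal(unname(phase_entropies(unif)), rep(log(25), 2))
  expect_error(phase_entropies(matrix(0 + 0i, 3, 3)), "zero bispectral")
  # coupled harmonics concentrate bispectral mass relative to noise
  set.seed(20)
  nfft <- 128; n <- 16 * nfft; t <- seq_len(n)
  coup <- cos(2 * pi * 12 / nfft * t) + cos(2 * pi * 7 / nfft * t) +
    cos(2 * pi * 19 / nfft * t) + 0.05 * rnorm(n)
  s_coup <- phase_entropies(bispectrum(coup, 16, nfft))
  s_noise <- phase_entropies(bispectrum(rnorm(n), 16, nfft))
  expect_lt(s_coup[["S1"]], s_noise[["S1"]])
  # squaring sharpens: S2 <= S1 everywhere
  expect_lte(s_coup[["S2"]], s_coup[["S1"]])
  expect_lte(s_noise[["S2"]], s_noise[["S1"]])
})

test_that("the eight-entropy vector is complete, ordered, deterministic", {
  set.seed(21)
  fb <- make_filterbank(100, 600, 50)
  seg <- list(x = rnorm(4000))
  sub <- decompose(seg, fb, fs = 2000)
  prm <- entropy_params(bispec_epochs = 4, bispec_nfft = 512)
  v1 <- entropy_vector(sub, 3, prm)
  v2 <- entropy_vector(sub, 3, prm)
  expect_identical(v1, v2)
  expect_named(v1, c("APE", "PE", "Sh", "Sp", "Ts", "S2", "S1", "Ren"))
  expect_true(all(is.finite(v1)))
  expect_true(v1[["PE"]] <= log2(6) && v1[["Ts"]] < 1)
  expect_lte(v1[["Ren"]], v1[["Sh"]])
})

test_that("constant input degenerates to zero template entropies and NA
           spectral sentinels", {
  suppressWarnings(v <- entropy_vector(rep(1, 2000),
                                       params = entropy_params()))
  expect_equal(unname(v[c("APE", "Sp", "PE")]), c(0, 0, 0))
  expect_true(all(is.na(v[c("Sh", "Ren", "Ts", "S1", "S2")])))
  expect_warning(entropy_vector(rep(1, 2000), params = entropy_params()),
                 "spectral")
})
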