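---
title: "Multiband entropy features for interictal focus localization: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiband entropy features for interictal focus localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ieegfocus)
```

## The problem

In drug-resistant focal epilepsy, surgical outcome depends on correctly
delineating the seizure onset zone (SOZ) from intracranial EEG (iEEG).
Epileptologists label the SOZ by reviewing days of recordings around
habitual seizures; an automatic detector that flags likely SOZ channels
from a short *interictal* (between-seizure) excerpt would substantially
shorten that review. The physiological handle is that high-frequency
activity — ripples (~100–250 Hz) and fast ripples (~250–600 Hz) — occurs
at elevated rates on epileptogenic tissue, and that this activity changes
the complexity of the narrowband signal in ways entropy statistics can
measure.

`ieegfocus` implements a complete detector around that idea:

1. split each channel of a labeled recording into non-overlapping 20-s
   segments (a 30-min, 2 kHz recording gives 90 segments of
   L = 40,000 samples per channel);
2. bandpass each segment to 100–600 Hz and decompose it with a bank of
   ten 3rd-order Butterworth bandpass filters, each 50 Hz wide;
3. compute eight entropies per subband — approximate (APE), sample (Sp)
   and permutation (PE) entropy on the time series, Shannon (Sh),
   Rényi (Ren, order 2) and Tsallis (Ts, index 2) entropy on the
   normalized power spectrum, and two phase entropies (S1, S2) on the
   normalized bispectral magnitude — giving an 80-dimensional feature
   vector per channel-segment;
4. per subband, select the most discriminative entropies with a sparse
   LDA (elastic-net optimal scoring) and concatenate the selected
   columns;
5. balance the heavily outnumbered focal class with ADASYN inside each
   training fold;
6. classify segments as focal/non-focal with an RBF-kernel SVM under
   segment-wise 10-fold cross-validation;
7. aggregate detections into per-channel counts, threshold them into a
   ROC, and report the trapezoid-rule area (channel AUC) as the
   focus-identification score.

## Model assumptions

* **Labels propagate from channels to segments.** Every segment of a SOZ
  channel is treated as focal. This is a weak-label assumption — real
  SOZ channels are not epileptiform in every 20-s window — and it bounds
  attainable segment-level sensitivity; channel-level aggregation is
  what the detector is judged on.
* **Stationarity within a segment.** All eight estimators treat the
  40,000-sample window as one stationary stretch.
* **Equal-length segments.** Every entropy is length-dependent, so the
  segmenter drops any trailing remainder shorter than one window rather
  than emit a short segment.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `segment_seconds` | 20 s | analysis window; 90 windows per 30 min |
| band range / width | 100–600 Hz / 50 Hz | ripple + fast-ripple range, N = 10 subbands |
| filter order | 3 | Butterworth bandpass prototype |
| `zero_phase` | `TRUE` | forward–backward filtering |
| `d_embed`, `r_factor` | 2, 0.2 | APE/Sp embedding and tolerance (r = 0.2·SD) |
| `pe_d`, `pe_tau` | 3, 1 | permutation-entropy order and lag |
| `alpha`, `q` | 2, 2 | Rényi order, Tsallis index |
| `ape_max_samples` | 4000 | stride-subsampling bound for the O(L²) estimators |
| `bispec_epochs`, `bispec_nfft` | 31, 1024 | bispectrum averaging layout |
| `delta`, `G` | 3, 3 | sparse-LDA ridge weight and entropies kept per subband |
| `adasyn_beta`, `adasyn_k` | 1, 5 | full balancing, 5 nearest neighbors |
| `svm_cost`, `svm_gamma` | 1, 1/dim | RBF-SVM defaults |
| `k` | 10 | cross-validation folds |

Per-profile presets for `G` (3–6 depending on the montage) ship with
`patient_profiles()`.

## Design choices in detail

**Zero-phase filtering.** Only the filter order is fixed by the method
definition; the application direction is an implementation choice. A
causal bandpass has band-dependent group delay, which would desynchronize
subbands derived from the same window, so the bank applies each filter
forward and backward (`signal::filtfilt`). This squares the magnitude
response — attenuation doubles in dB — and is recorded in the config as
`zero_phase = TRUE`, switchable to the causal single pass.

**Tolerance scoping for APE/Sp.** The tolerance is r = 0.2·SD *of the
subband signal of the segment being measured*, not of the channel or the
broadband signal. This keeps the template statistics scale-free within
each band (they are then exactly invariant to amplitude rescaling, which
the test suite asserts), at the cost of making r a per-(segment, subband)
quantity.

**Quadratic-cost estimators on 40,000 samples.** APE and Sp are O(L²).
At the default `ape_max_samples = 4000` the segment is stride-subsampled
(every 10th sample at 2 kHz) before template matching; the exact path is
available by setting `ape_max_samples = Inf`. Subsampling a narrowband
signal at stride 10 aliases the carrier but preserves the
regularity-vs-irregularity contrast the features exploit; tests compare
estimators against brute-force oracles on short signals where the
default and exact paths coincide.

**Rényi form.** The standard Rényi entropy
(1/(1−α))·ln Σ p^α is used. A literal variant,
(1/(1−α))·Σ ln p², circulates in parts of the applied literature but
diverges whenever a spectral bin is empty; it is available behind
`renyi_literal = TRUE` for comparison and is never the default.

**Bispectrum estimator.** The bispectrum is estimated by the direct FFT
method: the segment is cut into `bispec_epochs = 31` non-overlapping
epochs of `bispec_nfft = 1024` samples, each epoch is mean-removed and
FFT'd, and the triple product F(f1)F(f2)F*(f1+f2) is averaged over
epochs on the principal domain f1 ≥ f2 ≥ 0, f1+f2 ≤ Nyquist. Epoching
and FFT length are estimator choices, not method constants; they are
exposed in `entropy_params()`.

**Sparse LDA.** The two-class optimal-scoring problem fixes the class
score vector in closed form (normalized, orthogonal to the constant
score), leaving a single penalized regression. The sparsity control is
interpreted as a *stop-at-G* rule: a negative L1 weight is not a valid
penalty, and the sparse-discriminant literature ties the parameter's
magnitude to the desired number of active variables. The implementation
traces the L1 path by coordinate descent on the ridge-augmented problem,
bisects the penalty to the point where exactly G features are active,
and reports the ridge refit on that support. The refit guarantees the
penalized loss at the solution never exceeds the loss at zero or at the
truncated full ridge solution (asserted in the tests), and at G = D the
fit is exactly the ridge closed form. Feature columns are z-scored with
training-fold statistics before fitting because the eight entropies live
on incommensurate scales; selection indices always refer to the original
columns.

**ADASYN.** Neighborhoods are Euclidean. For each minority (focal)
sample, the majority share among its K = 5 nearest neighbors in the full
training set sets its generation weight; per-seed counts are
integerized by largest remainder so the synthetic total is exact; each
synthetic point interpolates its seed toward one of the seed's K nearest
*minority* neighbors. Balancing runs strictly inside each training fold,
after feature selection — the pipeline order is extraction → selection →
balancing → SVM. Undersized minorities reduce K with a warning rather
than fail.

**Cross-validation layout.** Folds partition *segment indices* in
contiguous blocks (segments 1–9 → fold 1, and so on), and all channels
of a segment share its fold. Contiguous blocks avoid temporal leakage
between adjacent 20-s windows that random shuffling would allow. Whether
to shuffle is genuinely open; the block layout is this package's
documented choice.

**SVM defaults.** C = 1 and γ = 1/dim. The method definition leaves SVM
hyperparameters open; fixed, stated defaults make runs reproducible.
The segment decision is the SVM sign — no probability calibration.

**Channel AUC.** The detection-count threshold sweeps every integer from
zero to the fold maximum; the resulting (FPR, sensitivity) polyline is
integrated by the trapezoid rule and per-fold areas are averaged. This
is numerically identical to the Mann–Whitney rank statistic with half
credit for ties, which the tests assert against a brute-force pairwise
oracle.

**Degenerate inputs.** A constant (or otherwise spectrally empty)
subband has no defined spectral or bispectral entropies; estimators
raise a structured error which the feature extractor converts into an
`NA` sentinel, and rows carrying sentinels are dropped with a warning —
never silently imputed. Sample entropy with no template matches behaves
the same way.

## The synthetic generator

Clinical iEEG with SOZ annotations cannot be redistributed, so the
package ships a generator that emulates the *structure* of such data:
per-channel 1/f^γ Gaussian background (γ = 1, 25 µV SD) plus
Poisson-timed, Gaussian-windowed sinusoidal bursts in a ripple family
(100–250 Hz, 80 ms, baseline 2/min) and a fast-ripple family
(250–600 Hz, 40 ms, baseline 1/min), with burst amplitude 3 background
SDs. SOZ channels receive `rate_ratio` times the baseline burst rate;
that contrast is the only systematic class difference. Montage profiles
(`Pt1`–`Pt8`, 36–76 electrodes, 3–9 SOZ channels) reproduce the
geometry of the reference cohort; `make_cohort_recording()` builds a
30-min, 2 kHz recording on any of them.

What the generator does *not* emulate: spike-and-wave morphology,
non-stationary background, line noise, electrode artifacts, inter-channel
correlation, or clinically calibrated HFO rates. Passing the recovery
tests therefore shows the pipeline can detect a rate contrast expressed
through high-frequency bursts — it does not certify clinical
performance.

## Problem sizes and numerical checks

The test and acceptance runs use a desk-scale dataset — 12 channels, 2
SOZ, 5 minutes at 2 kHz (15 segments per channel, 180 channel-segment
rows) with 5 folds — chosen so a full pipeline run completes in minutes
on one core while keeping every stage nontrivially exercised (folds
containing 3 segments, 24–36 focal training rows before balancing).
Under strong contrast (`rate_ratio = 8`, amplitude 3 SD) the detector's
mean channel AUC is expected ≥ 0.9; under the null (`rate_ratio = 1`)
it should sit near 0.5. Estimator correctness is established separately:
every entropy equals an independently written brute-force oracle to
1e-10 on short signals, and channel AUC equals the rank-statistic oracle
to 1e-12.

Reference cohort arithmetic (likelihood ratios, F scores, cohort means)
is recomputed from the bundled plain-text benchmark table
(`reference_benchmarks()`); the underlying recordings are not available,
so per-patient AUCs are inputs there, not outputs.

## Known limitations

* Segment-level sensitivity is bounded by the weak-label assumption;
  expect low SEN with high SPE on realistic contrast levels.
* The sparse-LDA score-vector closed form is two-class only.
* The EDF writer targets continuous equal-rate signals (one data record;
  16-bit quantization at full scale); EDF+ annotations are not parsed.
* Subband selection is fixed by the bank definition; no data-adaptive
  band choice.
* With very small minorities (a 2-SOZ montage leaves 2 focal training
  rows per fold at desk scale) ADASYN degenerates toward seed
  duplication; warnings make this visible.
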