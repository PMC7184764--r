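#' One-call focus localization pipeline
#'
#' Runs the whole detector on a labeled recording: multiband entropy
#' feature extraction ([extract_features()]), segment-wise
#' cross-validated classification ([run_cv()]), and channel-level
#' aggregation ([detection_map()], [channel_auc()]).
#'
#' @param rec an [ieeg_recording()] with at least one SOZ and one
#'   non-SOZ channel.
#' @param bands an [make_filterbank()] table.
#' @param params an [entropy_params()] list.
#' @param segment_seconds segment length (default 20 s).
#' @param k folds (default 10).
#' @param algo pipeline variant, see [run_cv()].
#' @param G entropies kept per subband (default 3).
#' @param seed seed for ADASYN synthesis.
#' @param verbose report progress.
#' @param ... further [run_cv()] arguments.
#' @return List of class `focus_result`: `features`, `cv`, `map`,
#'   `segment_metrics` (one row), `channel_auc` (list with `per_fold`,
#'   `mean`).
#' @export
localize_focus <- function(rec, bands = make_filterbank(),
                           params = entropy_params(),
                           segment_seconds = 20, k = 10L,
                           algo = "fba-fs-ada", G = 3L, seed = NULL,
                           verbose = FALSE, ...) {
  ft <- extract_features(rec, bands, params,
                         segment_seconds = segment_seconds,
                         verbose = verbose)
  cv <- run_cv(ft, k = k, algo = algo, G = G, seed = seed, ...)
  map <- detection_map(cv)
  structure(
    list(features = ft, cv = cv, map = map,
         segment_metrics = segment_metrics(
           confusion(cv$predictions$pred, cv$predictions$label)),
         channel_auc = channel_auc(map)),
    class = "focus_result")
}

#' @export
print.focus_result <- function(x, ...) {
  cat("<focus_result>", x$cv$algo, "with", x$cv$k, "folds\n")
  cat("segment metrics:\n")
  print(round(x$segment_metrics, 2))
  cat(sprintf("channel AUC (mean over folds): %.3f\n", x$channel_auc$mean))
  invisible(x)
}

#' Reference benchmark table of the eight-patient cohort
#'
#' Published per-patient benchmark values for the interictal
#' high-frequency entropy detector on an eight-patient clinical iEEG
#' cohort, shipped as plain text with the package: segment-level
#' sensitivity/specificity/precision/fall-out (percent) and F score for
#' the full pipeline, segment-level AUC for the three ablations, and the
#' channel-level focus-identification AUC.  The raw recordings are not
#' distributable; this table is the arithmetic surface the evaluation
#' module's metric conventions are checked against.
#'
#' @return A data.frame, one row per patient `Pt1` ... `Pt8`.
#' @export
reference_benchmarks <- function() {
  utils::read.table(
    system.file("extdata", "reference_benchmarks.tsv",
                package = "ieegfocus"),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
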