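#' Segment-wise k-fold cross-validated focus detection
#'
#' Partitions the segment indices into `k` contiguous blocks (all
#' channels of a segment share its fold, avoiding temporal leakage
#' between adjacent windows).  Per fold the training pipeline is:
#' z-score the feature columns with training statistics, optionally
#' select entropies per subband with sparse LDA, optionally balance the
#' focal class with ADASYN, train an RBF-kernel SVM, and predict the
#' held-out segments.  Every segment is predicted exactly once.
#'
#' The three algorithm variants are the usual ablations: `"fba"` (filter
#' bank + entropies + SVM), `"fba-ada"` (adds ADASYN), `"fba-fs-ada"`
#' (adds sparse-LDA selection; default).
#'
#' @param ft an [extract_features()] table.
#' @param k number of folds (default 10).
#' @param algo `"fba-fs-ada"`, `"fba-ada"` or `"fba"`.
#' @param G entropies kept per subband when selecting (default 3).
#' @param delta sparse-LDA ridge penalty (default 3).
#' @param adasyn_beta,adasyn_k ADASYN balance level and neighbor count.
#' @param svm_cost SVM soft-margin cost (default 1).
#' @param svm_gamma RBF kernel width; default `1 / n_features`.
#' @param seed integer seed driving ADASYN synthesis (per fold,
#'   `seed + fold`); RNG state is restored afterwards.
#' @return An object of class `focus_cv`: `predictions` (data.frame with
#'   `channel`, `segment`, `label`, `pred`, `fold`), `solutions`
#'   (per-fold sparse-LDA fits or `NULL`), `k`, `algo`, `soz_channels`.
#' @export
run_cv <- function(ft, k = 10L, algo = c("fba-fs-ada", "fba-ada", "fba"),
                   G = 3L, delta = 3, adasyn_beta = 1, adasyn_k = 5L,
                   svm_cost = 1, svm_gamma = NULL, seed = NULL) {
  algo <- match.arg(algo)
  segs <- sort(unique(ft$segment))
  if (length(segs) < k)
    stop("cannot make ", k, " folds from ", length(segs), " segments")
  fold_of_seg <- ceiling(seq_along(segs) * k / length(segs))
  fold <- fold_of_seg[match(ft$segment, segs)]
  use_fs <- algo == "fba-fs-ada"
  use_ada <- algo != "fba"
  fcols_all <- attr(ft, "feature_cols")
  preds <- vector("list", k)
  sols <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- ft[fold != f, , drop = FALSE]
    te <- ft[fold == f, , drop = FALSE]
    attr(tr, "n_subbands") <- attr(ft, "n_subbands")
    attr(tr, "feature_cols") <- fcols_all
    if (!any(tr$label == "focal"))
      stop("training fold ", f, " has no focal rows")
    mu <- colMeans(tr[, fcols_all, drop = FALSE])
    sdv <- apply(tr[, fcols_all, drop = FALSE], 2L, stats::sd)
    sdv[sdv == 0] <- 1
    ztr <- tr
    zte <- te
    ztr[, fcols_all] <- sweep(sweep(tr[, fcols_all], 2L, mu), 2L, sdv, "/")
    zte[, fcols_all] <- sweep(sweep(te[, fcols_all], 2L, mu), 2L, sdv, "/")
    for (a in c("n_subbands", "feature_cols", "entropies")) {
      attr(ztr, a) <- attr(ft, a)
      attr(zte, a) <- attr(ft, a)
    }
    class(ztr) <- class(zte) <- class(ft)
    if (use_fs) {
      sol <- fit_slda_subbands(ztr, delta = delta, G = G)
      sols[[f]] <- sol
      ztr <- select_features(ztr, sol)
      zte <- select_features(zte, sol)
    }
    fcols <- attr(ztr, "feature_cols")
    Xtr <- as.matrix(ztr[, fcols, drop = FALSE])
    ytr <- ztr$label == "focal"
    if (use_ada) {
      bal <- adasyn_balance(Xtr, ytr, beta = adasyn_beta, K = adasyn_k,
                            seed = if (is.null(seed)) NULL else seed + f)
      Xtr <- bal$X
      ytr <- bal$focal
    }
    fit <- e1071::svm(Xtr, factor(ifelse(ytr, "focal", "nonfocal"),
                                  levels = c("focal", "nonfocal")),
                      kernel = "radial", cost = svm_cost,
                      gamma = if (is.null(svm_gamma)) 1 / ncol(Xtr)
                              else svm_gamma,
                      scale = FALSE)
    yhat <- stats::predict(fit, as.matrix(zte[, fcols, drop = FALSE]))
    preds[[f]] <- data.frame(channel = te$channel, segment = te$segment,
                             label = te$label,
                             pred = factor(as.character(yhat),
                                           levels = c("focal", "nonfocal")),
                             fold = f)
  }
  predictions <- do.call(rbind, preds)
  soz <- unique(predictions$channel[predictions$label == "focal"])
  structure(list(predictions = predictions, solutions = sols, k = k,
                 algo = algo, soz_channels = soz),
            class = "focus_cv")
}

#' @export
print.focus_cv <- function(x, ...) {
  cm <- confusion(x$predictions$pred, x$predictions$label)
  cat(sprintf("<focus_cv> %s, %d folds, %d predictions\n", x$algo, x$k,
              nrow(x$predictions)))
  print(cm)
  invisible(x)
}

#' Confusion counts of focal-segment detection
#'
#' @param pred predicted labels: factor/character with `"focal"`, or
#'   logical (`TRUE` = focal).
#' @param label true labels, same conventions.
#' @return Named integer vector of class `confusion_counts`:
#'   `TP`, `FN`, `FP`, `TN` (positive class = focal).
#' @export
confusion <- function(pred, label) {
  p <- if (is.logical(pred)) pred else as.character(pred) == "focal"
  y <- if (is.logical(label)) label else as.character(label) == "focal"
  stopifnot(length(p) == length(y))
  structure(c(TP = sum(p & y), FN = sum(!p & y),
              FP = sum(p & !y), TN = sum(!p & !y)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("  TP %d  FN %d  FP %d  TN %d\n",
              x["TP"], x["FN"], x["FP"], x["TN"]))
  invisible(x)
}

#' Segment-level detection metrics
#'
#' Sensitivity, specificity, precision (PPV) and fall-out (FPR) on the
#' 0-100 percent scale, the F score on the 0-1 scale, and the positive
#' likelihood ratio `PLR = SEN / FPR`.  A metric whose denominator is
#' zero is reported as `NA` (undefined), never silently replaced.
#'
#' @param counts a [confusion()] result (or any named vector with
#'   `TP`, `FN`, `FP`, `TN`).
#' @return A one-row data.frame: `SEN`, `SPE`, `PPV`, `FPR` (percent),
#'   `F1` (fraction), `PLR` (ratio).
#' @export
segment_metrics <- function(counts) {
  TP <- counts[["TP"]]; FN <- counts[["FN"]]
  FP <- counts[["FP"]]; TN <- counts[["TN"]]
  sen <- if (TP + FN > 0) TP / (TP + FN) * 100 else NA_real_
  spe <- if (TN + FP > 0) TN / (TN + FP) * 100 else NA_real_
  ppv <- if (TP + FP > 0) TP / (TP + FP) * 100 else NA_real_
  fpr <- if (TN + FP > 0) FP / (TN + FP) * 100 else NA_real_
  data.frame(SEN = sen, SPE = spe, PPV = ppv, FPR = fpr,
             F1 = f_score(sen, ppv),
             PLR = positive_likelihood_ratio(sen, fpr))
}

#' Positive likelihood ratio from printed rates
#'
#' `PLR = SEN / FPR`, both on the percent scale, as used to compare
#' detectors from their reported sensitivity and fall-out.
#'
#' @param sen sensitivity in percent.
#' @param fpr fall-out (false positive rate) in percent.
#' @return The ratio, `NA` if either input is `NA`, `Inf` if `fpr = 0`.
#' @export
positive_likelihood_ratio <- function(sen, fpr) {
  ifelse(is.na(sen) | is.na(fpr), NA_real_,
         ifelse(fpr == 0, Inf, sen / fpr))
}

#' F score from printed sensitivity and precision
#'
#' Harmonic mean of recall and precision given on the percent scale,
#' returned as a fraction in `[0, 1]`.
#'
#' @param sen sensitivity (recall) in percent.
#' @param ppv precision in percent.
#' @return F score in `[0, 1]`.
#' @export
f_score <- function(sen, ppv) {
  ifelse(is.na(sen) | is.na(ppv) | sen + ppv == 0, NA_real_,
         2 * sen * ppv / (sen + ppv) / 100)
}

#' Per-channel detection map of a cross-validation run
#'
#' Per-fold, per-channel counts of segments detected as focal — the
#' substrate of channel-level focus identification — plus the overall
#' channel-by-segment binary detection matrix.
#'
#' @param cv a [run_cv()] result.
#' @return An object of class `channel_detection_map`: `counts`
#'   (channels x folds matrix), `detections` (channels x segments 0/1
#'   matrix), `soz` (logical per channel), `channel_ids`.
#' @export
detection_map <- function(cv) {
  pr <- cv$predictions
  chans <- unique(pr$channel)
  folds <- sort(unique(pr$fold))
  counts <- matrix(0L, length(chans), length(folds),
                   dimnames = list(chans, paste0("fold", folds)))
  for (f in seq_along(folds)) {
    sel <- pr$fold == folds[f] & pr$pred == "focal"
    tab <- table(pr$channel[sel])
    counts[names(tab), f] <- as.integer(tab)
  }
  segs <- sort(unique(pr$segment))
  det <- matrix(0L, length(chans), length(segs),
                dimnames = list(chans, paste0("seg", segs)))
  hit <- pr$pred == "focal"
  det[cbind(match(pr$channel[hit], chans),
            match(pr$segment[hit], segs))] <- 1L
  structure(list(counts = counts, detections = det,
                 soz = chans %in% cv$soz_channels, channel_ids = chans),
            class = "channel_detection_map")
}

# ROC by thresholding detection counts at 0..max, trapezoid area
roc_auc_counts <- function(counts, soz) {
  if (!any(soz) || all(soz))
    stop("channel AUC needs both SOZ and non-SOZ channels")
  thr <- 0:(max(counts) + 1L)
  sen <- vapply(thr, function(t) mean(counts[soz] >= t), numeric(1L))
  fpr <- vapply(thr, function(t) mean(counts[!soz] >= t), numeric(1L))
  ord <- order(fpr, sen)
  fpr <- fpr[ord]; sen <- sen[ord]
  sum(diff(fpr) * (sen[-1L] + sen[-length(sen)]) / 2)
}

#' Channel-level AUC for focus identification
#'
#' Sweeps a detection-count threshold from zero to the per-fold maximum,
#' forms the (FPR, sensitivity) ROC over channels, integrates by the
#' trapezoid rule, and averages the per-fold areas.  Numerically
#' identical to the Mann-Whitney rank statistic with half credit for
#' ties.
#'
#' @param map a [detection_map()], or a numeric vector of per-channel
#'   counts (then `soz` must be given).
#' @param soz logical SOZ mask, only for the vector form.
#' @return For a map: list with `per_fold` (numeric vector) and `mean`.
#'   For a vector: the single AUC.
#' @export
channel_auc <- function(map, soz = NULL) {
  if (is.numeric(map)) {
    if (is.null(soz)) stop("`soz` mask required with a counts vector")
    return(roc_auc_counts(map, soz))
  }
  per_fold <- apply(map$counts, 2L, roc_auc_counts, soz = map$soz)
  list(per_fold = per_fold, mean = mean(per_fold))
}

#' Write the detection report tables
#'
#' Emits the three result tables of an evaluation run as TSV:
#' `segment_metrics.tsv` (overall confusion-derived metrics),
#' `channel_auc.tsv` (per-fold and mean channel AUC), and
#' `detections.tsv` (channel-by-segment 0/1 matrix with SOZ flag and
#' per-channel detection counts, heatmap-ready).
#'
#' @param cv a [run_cv()] result.
#' @param dir output directory (created if needed).
#' @return The detection map, invisibly.
#' @export
detection_report <- function(cv, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  map <- detection_map(cv)
  sm <- segment_metrics(confusion(cv$predictions$pred,
                                  cv$predictions$label))
  utils::write.table(sm, file.path(dir, "segment_metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  auc <- channel_auc(map)
  utils::write.table(
    data.frame(fold = c(names(auc$per_fold), "mean"),
               auc = c(auc$per_fold, auc$mean)),
    file.path(dir, "channel_auc.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  det <- data.frame(channel = map$channel_ids,
                    soz = as.integer(map$soz),
                    map$detections,
                    n_detected = rowSums(map$detections),
                    check.names = FALSE)
  utils::write.table(det, file.path(dir, "detections.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(map)
}
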