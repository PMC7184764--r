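test_that("segment folds partition every segment exactly once", {
  ft <- fake_feature_table(n_channels = 3, n_segments = 90, n_soz = 1)
  cv <- run_cv(ft, k = 10, algo = "fba", seed = 1)
  pr <- cv$predictions
  expect_equal(nrow(pr), 3 * 90)
  per_fold <- table(pr$fold) / 3
  expect_true(all(per_fold == 9))
  expect_equal(sort(unique(pr$segment)), 1:90)
  # each (channel, segment) predicted exactly once
  expect_equal(anyDuplicated(pr[, c("channel", "segment")]), 0)
  # all channels of a segment share its fold
  expect_true(all(tapply(pr$fold, pr$segment,
                         function(f) length(unique(f))) == 1))
})

test_that("small fold layouts and channel order invariance hold", {
  ft <- fake_feature_table(n_channels = 4, n_segments = 4, n_soz = 2)
  cv <- run_cv(ft, k = 2, algo = "fba", seed = 1)
  expect_true(all(table(cv$predictions$fold) == 8))  # 2 segs x 4 chans
  # shuffling channel order leaves segment fold assignment unchanged
  perm <- c(3, 1, 4, 2)
  ftp <- ft[order(match(ft$channel, paste0("ch", perm))), ]
  for (a in c("n_subbands", "feature_cols", "entropies"))
    attr(ftp, a) <- attr(ft, a)
  class(ftp) <- class(ft)
  cvp <- run_cv(ftp, k = 2, algo = "fba", seed = 1)
  f1 <- tapply(cv$predictions$fold, cv$predictions$segment, unique)
  f2 <- tapply(cvp$predictions$fold, cvp$predictions$segment, unique)
  expect_identical(f1, f2)
})

test_that("a training fold with no focal rows is an error", {
  ft <- fake_feature_table(n_channels = 3, n_segments = 6, n_soz = 0)
  expect_error(run_cv(ft, k = 2, algo = "fba"), "no focal")
})

test_that("ablations run from one switch with the same fold layout", {
  ft <- fake_feature_table(n_channels = 4, n_segments = 20, n_soz = 1,
                           noise_sd = 0.5)
  for (algo in c("fba", "fba-ada", "fba-fs-ada")) {
    cv <- run_cv(ft, k = 5, algo = algo, G = 2, seed = 3)
    expect_equal(nrow(cv$predictions), nrow(ft))
    expect_s3_class(cv, "focus_cv")
  }
})

test_that("confusion counts match hand tallies", {
  y <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  p <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  cm <- confusion(p, y)
  expect_equal(unclass(cm), c(TP = 2, FN = 1, FP = 2, TN = 3),
               ignore_attr = TRUE)
  all_good <- confusion(y, y)
  expect_equal(all_good[["FN"]] + all_good[["FP"]], 0)
  none <- confusion(rep(FALSE, 8), y)
  expect_equal(none[["TP"]], 0)
  expect_equal(cm[["TP"]] + cm[["FN"]], sum(y))
  expect_equal(cm[["FP"]] + cm[["TN"]], sum(!y))
})

test_that("segment metrics follow the percent/fraction conventions", {
  m <- segment_metrics(c(TP = 2, FN = 0, FP = 0, TN = 5))
  expect_equal(m$SEN, 100)
  expect_equal(m$SPE, 100)
  expect_equal(m$F1, 1)
  expect_true(is.infinite(m$PLR))
  m2 <- segment_metrics(c(TP = 0, FN = 0, FP = 1, TN = 4))
  expect_true(is.na(m2$SEN))     # undefined, not fabricated
  m3 <- segment_metrics(c(TP = 3, FN = 1, FP = 2, TN = 14))
  expect_equal(m3$SPE + m3$FPR, 100)
  expect_equal(m3$PLR, m3$SEN / m3$FPR)
  expect_equal(m3$F1, 2 * (m3$SEN * m3$PPV) / (m3$SEN + m3$PPV) / 100)
})

test_that("channel AUC equals the Mann-Whitney rank oracle", {
  expect_equal(channel_auc(c(5, 6, 0, 1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(channel_auc(rep(3, 6), c(TRUE, FALSE, TRUE, FALSE,
                                        FALSE, FALSE)), 0.5)
  set.seed(60)
  for (i in 1:20) {
    counts <- rpois(12, 3)
    soz <- rep(c(TRUE, FALSE), c(3, 9))
    expect_equal(channel_auc(counts, soz),
                 oracle_mann_whitney(counts[soz], counts[!soz]),
                 tolerance = 1e-12)
  }
  expect_error(channel_auc(c(1, 2), c(TRUE, TRUE)), "both")
})

test_that("detection maps count per-fold focal detections", {
  ft <- fake_feature_table(n_channels = 4, n_segments = 10, n_soz = 1,
                           noise_sd = 0.2)
  cv <- run_cv(ft, k = 5, algo = "fba-ada", seed = 4)
  map <- detection_map(cv)
  expect_equal(dim(map$counts), c(4, 5))
  expect_equal(sum(map$counts),
               sum(cv$predictions$pred == "focal"))
  expect_equal(rowSums(map$detections), rowSums(map$counts),
               ignore_attr = TRUE)
  expect_equal(map$soz, c(TRUE, FALSE, FALSE, FALSE))
  auc <- channel_auc(map)
  expect_length(auc$per_fold, 5)
  expect_true(all(auc$per_fold >= 0 & auc$per_fold <= 1))
  expect_equal(auc$mean, mean(auc$per_fold))
})

test_that("detection reports round-trip through TSV", {
  ft <- fake_feature_table(n_channels = 3, n_segments = 8, n_soz = 1)
  cv <- run_cv(ft, k = 4, algo = "fba", seed = 5)
  dir <- withr::local_tempdir()
  map <- detection_report(cv, dir)
  det <- read.table(file.path(dir, "detections.tsv"), header = TRUE,
                    sep = "\t", check.names = FALSE)
  expect_equal(det$channel, map$channel_ids)
  seg_cols <- grep("^seg", names(det))
  expect_equal(det$n_detected, rowSums(det[, seg_cols]))
  expect_equal(as.matrix(det[, seg_cols]), map$detections,
               ignore_attr = TRUE)
  auc_tab <- read.table(file.path(dir, "channel_auc.tsv"), header = TRUE,
                        sep = "\t")
  expect_equal(auc_tab$auc[auc_tab$fold == "mean"],
               channel_auc(map)$mean)
  expect_true(file.exists(file.path(dir, "segment_metrics.tsv")))
})
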