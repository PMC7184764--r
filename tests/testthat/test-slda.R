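test_that("zero sparsity reproduces the ridge closed form", {
  set.seed(30)
  cls <- rep(c(TRUE, FALSE), c(8, 12))
  M <- matrix(rnorm(20 * 8), 20)
  fit <- fit_slda(M, cls, delta = 3, delta1 = 0)
  H1 <- 8; H2 <- 12
  theta <- c(H2, -H1) / sqrt(H1 * H2)
  y <- ifelse(cls, theta[1], theta[2])
  expect_equal(fit$beta, as.numeric(ridge_oracle(M, y, 3)),
               tolerance = 1e-10)
  expect_equal(fit$index_set, 1:8)
  # score normalization and orthogonality to the constant score
  expect_equal(sum(ifelse(cls, theta[1], theta[2])), 0)
  expect_equal((H1 * theta[1]^2 + H2 * theta[2]^2) / 20, 1)
})

test_that("selection finds the informative feature", {
  set.seed(31)
  cls <- rep(c(TRUE, FALSE), c(10, 30))
  M <- cbind(ifelse(cls, 1, 0) + rnorm(40, sd = 0.1),
             matrix(rnorm(40 * 7), 40))
  fit <- fit_slda(scale(M), cls, G = 1)
  expect_equal(fit$index_set, 1L)
  expect_equal(sum(fit$beta != 0), 1L)
})

test_that("the requested number of features is active, and the penalized
           objective improves on zero and on the truncated ridge", {
  set.seed(32)
  cls <- rep(c(TRUE, FALSE), c(15, 25))
  M <- scale(matrix(rnorm(40 * 8), 40) +
               outer(as.numeric(cls), c(1, .8, .5, 0, 0, 0, 0, 0)))
  for (G in c(1, 2, 3, 5, 8)) {
    fit <- fit_slda(M, cls, delta = 3, G = G)
    expect_equal(length(fit$index_set), G)
    y <- ifelse(cls, fit$theta[1], fit$theta[2])
    Mc <- scale(M, scale = FALSE)
    loss <- function(b) sum((y - Mc %*% b)^2) + 3 * sum(b^2)
    expect_lte(loss(fit$beta), loss(numeric(8)))
    ridge_full <- as.numeric(ridge_oracle(M, y, 3))
    trunc <- numeric(8); trunc[fit$index_set] <- ridge_full[fit$index_set]
    expect_lte(loss(fit$beta), loss(trunc) + 1e-10)
  }
})

test_that("the support path agrees with an independent elastic-net solver", {
  skip_if_not_installed("glmnet")
  set.seed(33)
  cls <- rep(c(TRUE, FALSE), c(12, 28))
  M <- scale(matrix(rnorm(40 * 8), 40) +
               outer(as.numeric(cls), c(2, 1.2, .7, .4, 0, 0, 0, 0)))
  theta <- c(28, -12) / sqrt(12 * 28)
  y <- ifelse(cls, theta[1], theta[2])
  # ridge-augmented lasso = elastic net with our fixed delta
  delta <- 3
  Xa <- rbind(scale(M, scale = FALSE), sqrt(delta) * diag(8))
  ya <- c(y - mean(y), rep(0, 8))
  gfit <- glmnet::glmnet(Xa, ya, alpha = 1, intercept = FALSE,
                         standardize = FALSE, nlambda = 300,
                         lambda.min.ratio = 1e-4)
  for (G in c(1, 2, 3)) {
    df <- colSums(as.matrix(gfit$beta) != 0)
    lam_idx <- which(df >= G)[1]
    g_support <- unname(sort(which(as.matrix(gfit$beta)[, lam_idx] != 0)))
    mine <- fit_slda(M, cls, delta = delta, G = G)
    expect_true(all(mine$index_set %in% g_support) ||
                  length(g_support) > G)
    if (length(g_support) == G)
      expect_equal(mine$index_set, g_support)
  }
})

test_that("selected tables concatenate to N*G columns, invariant to row
           order", {
  ft <- fake_feature_table(n_channels = 6, n_segments = 8, n_soz = 2,
                           n_subbands = 2)
  sols <- fit_slda_subbands(ft, G = 3)
  sel <- select_features(ft, sols)
  expect_length(attr(sel, "feature_cols"), 2 * 3)
  # no-sparsity identity: G = D keeps all 8 entropies per subband
  sols_all <- fit_slda_subbands(ft, G = 8)
  sel_all <- select_features(ft, sols_all)
  expect_length(attr(sel_all, "feature_cols"), 2 * 8)
  # permuting rows permutes rows only, never the chosen columns
  perm <- sample(nrow(ft))
  ftp <- ft[perm, , drop = FALSE]
  for (a in c("n_subbands", "feature_cols", "entropies"))
    attr(ftp, a) <- attr(ft, a)
  class(ftp) <- class(ft)
  selp <- select_features(ftp, sols)
  expect_identical(attr(selp, "feature_cols"), attr(sel, "feature_cols"))
  expect_equal(selp[[4]], sel[[4]][perm])
})

test_that("train-fitted selection applies to held-out rows by plain
           column subsetting", {
  ft <- fake_feature_table(n_channels = 5, n_segments = 12)
  train <- ft[ft$segment <= 8, ]
  test <- ft[ft$segment > 8, ]
  for (part in list(train, test)) NULL
  for (a in c("n_subbands", "feature_cols", "entropies")) {
    attr(train, a) <- attr(ft, a); attr(test, a) <- attr(ft, a)
  }
  class(train) <- class(test) <- class(ft)
  sols <- fit_slda_subbands(train, G = 2)
  sel_te <- select_features(test, sols)
  manual_cols <- unlist(lapply(1:2, function(n)
    subband_cols(ft, n)[sols[[n]]$index_set]))
  expect_identical(attr(sel_te, "feature_cols"), manual_cols)
  expect_equal(as.matrix(sel_te[, manual_cols]),
               as.matrix(test[, manual_cols]), ignore_attr = TRUE)
})

test_that("weight maps expose the selection structure", {
  ft <- fake_feature_table(n_channels = 6, n_segments = 10, n_soz = 2,
                           n_subbands = 2, noise_sd = 0.1)
  sols_all <- fit_slda_subbands(ft, G = 8)
  W <- weight_map(sols_all)
  expect_equal(dim(W), c(2, 8))
  expect_true(all(W > 0))
  sols1 <- fit_slda_subbands(ft, G = 1)
  W1 <- weight_map(sols1)
  expect_equal(sum(W1 != 0), 2)  # one per subband
  # the informative entropy (column 1 = APE of the fake table) dominates
  sols3 <- fit_slda_subbands(ft, G = 3)
  W3 <- weight_map(sols3)
  expect_equal(which.max(colMeans(W3)), 1L, ignore_attr = TRUE)
})

test_that("degenerate inputs are rejected", {
  M <- matrix(rnorm(40), 10)
  expect_error(fit_slda(M, rep(TRUE, 10), G = 2), "class")
  expect_error(fit_slda(M, rep(c(TRUE, FALSE), 5), G = 5),
               "cannot select")
})
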