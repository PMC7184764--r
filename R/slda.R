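#' Sparse linear discriminant fit for one subband's entropy features
#'
#' Two-class sparse LDA in the optimal-scoring form: with class-indicator
#' matrix `C` (rows = channel-segment pairs, columns = focal/nonfocal)
#' and class-score vector `theta`, minimize
#' `||C theta - M beta||^2 + delta ||beta||^2 + delta1 ||beta||_1`
#' subject to `(1/H) theta' C'C theta = 1`.  For two classes there is a
#' single discriminative direction, and the score vector is fixed in
#' closed form by the normalization plus orthogonality to the trivial
#' constant score: `theta = (H2, -H1) / sqrt(H1 H2)` (the fixed point the
#' `(1, 1)'` initialization reaches after one orthogonalization and
#' normalization step).
#'
#' `|delta1|` is interpreted as the desired number `G` of selected
#' features (a stopping rule on the elastic-net path, not a literal
#' negative penalty): the L1 path is traced by coordinate descent with a
#' decreasing penalty until `G` features are active, and the reported
#' coefficients are the ridge (`delta`) refit on that support, so exactly
#' `G` entries of `beta` are non-zero.  With `delta1 = 0` (or `G` equal
#' to the number of columns) the fit is the ridge closed form
#' `(M'M + delta I)^{-1} M' C theta` with no selection.
#'
#' @param M numeric matrix, rows = training channel-segment pairs,
#'   columns = the D entropy features of one subband (standardize the
#'   columns with training statistics before calling).
#' @param classes logical or two-level factor of row labels; `TRUE` (or
#'   level `"focal"`) marks the focal class.
#' @param delta ridge penalty weight (default 3).
#' @param delta1 sparsity control; `G = round(|delta1|)` features are
#'   selected. `0` disables selection.
#' @param G number of features to select, overriding `delta1`.
#' @return An object of class `slda_solution`: `beta` (length D, exactly
#'   `G` non-zeros), `index_set` (selected column indices, `I_n`),
#'   `theta`, `delta`, `delta1`, `G`, and `entry_order` (order in which
#'   features activated along the path).
#' @examples
#' set.seed(1)
#' cls <- rep(c(TRUE, FALSE), c(10, 30))
#' M <- cbind(ifelse(cls, 1, 0) + rnorm(40, sd = 0.1),
#'            matrix(rnorm(40 * 3), 40))
#' fit_slda(scale(M), cls, G = 1)$index_set   # picks column 1
#' @export
fit_slda <- function(M, classes, delta = 3, delta1 = -3, G = NULL) {
  M <- as.matrix(M)
  H <- nrow(M)
  D <- ncol(M)
  focal <- slda_focal_mask(classes)
  if (length(focal) != H)
    stop("class labels length ", length(focal), " != ", H, " rows")
  H1 <- sum(focal)
  H2 <- H - H1
  if (H1 < 2L || H2 < 2L)
    stop("need at least 2 rows per class, got ", H1, " focal / ",
         H2, " nonfocal")
  if (is.null(G)) G <- as.integer(round(abs(delta1)))
  if (G == 0L) G <- D  # delta1 = 0: plain ridge, keep everything
  if (G > D) stop("cannot select G = ", G, " of D = ", D, " features")

  # class scores: orthogonal to the constant score, (1/H) theta'C'C theta = 1
  theta <- c(H2, -H1) / sqrt(H1 * H2)
  y <- ifelse(focal, theta[1L], theta[2L])
  y <- y - mean(y)  # zero already by construction; guards rounding
  Mc <- sweep(M, 2L, colMeans(M))

  if (G == D) {
    beta <- ridge_refit(Mc, y, seq_len(D), delta, D)
    entry <- seq_len(D)
  } else {
    path <- enet_support_path(Mc, y, delta, G)
    entry <- path$entry_order
    beta <- ridge_refit(Mc, y, path$support, delta, D)
  }
  structure(list(beta = beta, index_set = sort(which(beta != 0)),
                 theta = theta, delta = delta,
                 delta1 = if (is.null(delta1)) -G else delta1, G = G,
                 entry_order = entry,
                 feature_names = colnames(M) %||% paste0("f", seq_len(D))),
            class = "slda_solution")
}

slda_focal_mask <- function(classes) {
  if (is.logical(classes)) return(classes)
  cl <- as.character(classes)
  lv <- unique(cl)
  if (length(lv) > 2L) stop("sparse LDA here is two-class only")
  if ("focal" %in% lv) cl == "focal" else cl == lv[1L]
}

ridge_refit <- function(Mc, y, support, delta, D) {
  Ms <- Mc[, support, drop = FALSE]
  b <- solve(crossprod(Ms) + delta * diag(length(support)),
             crossprod(Ms, y))
  beta <- numeric(D)
  beta[support] <- b
  beta
}

# Elastic-net coordinate descent at one L1 penalty; objective
# ||y - M b||^2 + delta ||b||^2 + lam1 ||b||_1
enet_cd <- function(Mc, y, delta, lam1, beta, col_ss, max_iter = 500L,
                    tol = 1e-10) {
  r <- y - Mc %*% beta
  for (it in seq_len(max_iter)) {
    delta_max <- 0
    for (k in seq_along(beta)) {
      bk <- beta[k]
      ck <- sum(Mc[, k] * r) + col_ss[k] * bk
      bnew <- sign(ck) * max(abs(ck) - lam1 / 2, 0) / (col_ss[k] + delta)
      if (bnew != bk) {
        r <- r - Mc[, k] * (bnew - bk)
        delta_max <- max(delta_max, abs(bnew - bk))
        beta[k] <- bnew
      }
    }
    if (delta_max < tol) break
  }
  beta
}

# trace the decreasing-L1 path until G features are active; returns the
# support and the order in which features entered
enet_support_path <- function(Mc, y, delta, G) {
  D <- ncol(Mc)
  col_ss <- colSums(Mc^2)
  lam_max <- 2 * max(abs(crossprod(Mc, y)))
  if (lam_max == 0) stop("degenerate fit: features carry no class signal")
  lams <- lam_max * 0.97^(0:600)
  beta <- numeric(D)
  entry_order <- integer(0)
  prev_active <- integer(0)
  lo_lam <- lam_max
  for (lam in lams) {
    beta <- enet_cd(Mc, y, delta, lam, beta, col_ss)
    active <- which(beta != 0)
    entry_order <- c(entry_order, setdiff(active, entry_order))
    if (length(active) == G)
      return(list(support = active, entry_order = entry_order))
    if (length(active) > G) {
      # several features entered at once: bisect between the last
      # penalty with < G actives and this one
      hi <- lo_lam; lo <- lam
      for (i in 1:60) {
        mid <- (hi + lo) / 2
        bm <- enet_cd(Mc, y, delta, mid, numeric(D), col_ss)
        am <- which(bm != 0)
        if (length(am) == G)
          return(list(support = am,
                      entry_order = c(entry_order[entry_order %in% am],
                                      setdiff(am, entry_order))))
        if (length(am) > G) hi <- mid else lo <- mid
      }
      # discrete jump past G: keep the first G path entrants
      return(list(support = sort(entry_order[seq_len(G)]),
                  entry_order = entry_order))
    }
    prev_active <- active
    lo_lam <- lam
  }
  stop("L1 path exhausted before reaching ", G, " active features")
}

#' @export
print.slda_solution <- function(x, ...) {
  cat(sprintf("<slda_solution> G = %d of %d features: %s\n", x$G,
              length(x$beta),
              paste(x$feature_names[x$index_set], collapse = ", ")))
  invisible(x)
}

#' Fit sparse LDA per subband on a feature table
#'
#' Z-scores each subband's columns with the statistics of the supplied
#' (training) rows, then runs [fit_slda()] subband by subband.
#'
#' @param ft an [extract_features()] table (training rows only).
#' @param delta ridge penalty (default 3).
#' @param G number of entropies to keep per subband (default 3).
#' @return List of `slda_solution`, one per subband.
#' @export
fit_slda_subbands <- function(ft, delta = 3, G = 3L) {
  n_sub <- attr(ft, "n_subbands")
  lapply(seq_len(n_sub), function(n) {
    cols <- subband_cols(ft, n)
    M <- scale(as.matrix(ft[, cols, drop = FALSE]))
    M[is.nan(M)] <- 0  # zero-variance column
    fit_slda(M, ft$label, delta = delta, G = G)
  })
}

#' Apply per-subband feature selection
#'
#' Subsets each subband's columns to the fitted index set `I_n` and
#' concatenates across subbands, producing the selected feature table
#' (per channel-segment vector of length `sum(G_n)`).  Fit the solutions
#' on training rows only; the same column subsetting then applies to any
#' rows.
#'
#' @param ft an [extract_features()] table.
#' @param solutions list of per-subband [fit_slda()] solutions.
#' @return The feature table restricted to the selected columns
#'   (metadata columns kept).
#' @export
select_features <- function(ft, solutions) {
  n_sub <- attr(ft, "n_subbands")
  if (length(solutions) != n_sub)
    stop("need one solution per subband (", n_sub, ")")
  keep <- unlist(lapply(seq_len(n_sub), function(n) {
    idx <- solutions[[n]]$index_set
    if (length(idx) == 0L)
      stop("empty selection in subband ", n)
    subband_cols(ft, n)[idx]
  }))
  out <- ft[, c(meta_cols(), keep), drop = FALSE]
  attr(out, "n_subbands") <- n_sub
  attr(out, "entropies") <- attr(ft, "entropies")
  attr(out, "feature_cols") <- keep
  class(out) <- class(ft)
  out
}

#' Subband-by-entropy weight map
#'
#' Absolute sparse-LDA weights arranged as a subbands-by-entropies
#' matrix (zero where a feature was not selected), the substrate of the
#' usual selection heat map.
#'
#' @param solutions list of per-subband [fit_slda()] solutions.
#' @return Numeric `N x D` matrix, rows `S1..SN`, columns the entropy
#'   names.
#' @export
weight_map <- function(solutions) {
  W <- t(vapply(solutions, function(s) abs(s$beta),
                numeric(length(solutions[[1L]]$beta))))
  rownames(W) <- sprintf("S%d", seq_along(solutions))
  colnames(W) <- sub("^S\\d+\\.", "", solutions[[1L]]$feature_names)
  W
}
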