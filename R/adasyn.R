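# run code with a temporary, restorable RNG state when a seed is given
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Adaptive synthetic oversampling (ADASYN) of the focal class
#'
#' Balances an imbalanced training set by synthesizing minority (focal)
#' feature vectors, more densely where minority samples are surrounded by
#' the majority class:
#' \enumerate{
#'   \item the synthetic budget is `I_tilde = (J - I) * beta` for `I`
#'     minority and `J` majority samples (`beta = 1` balances fully, so
#'     `I + I_tilde = J`);
#'   \item each minority sample `i` gets weight
#'     `Gamma_i = (Theta_i / K) / Z`, where `Theta_i` counts majority
#'     samples among its `K` Euclidean nearest neighbors in the whole
#'     training set and `Z` normalizes `sum(Gamma) = 1`;
#'   \item per-seed counts `g_i = Gamma_i * I_tilde` are integerized by
#'     largest remainder so `sum(g) = I_tilde` exactly;
#'   \item each synthetic point interpolates its seed toward a randomly
#'     chosen one of the seed's `K` nearest minority neighbors:
#'     `v = a + (b - a) * u`, `u ~ U[0, 1]`.
#' }
#'
#' @param X numeric matrix of training feature vectors (rows = samples).
#' @param focal logical vector (or factor with level `"focal"`) marking
#'   the minority class rows.
#' @param beta desired balance level in `[0, 1]` (default 1).
#' @param K number of nearest neighbors (default 5); reduced with a
#'   warning when the minority class is smaller than `K + 1`.
#' @param seed optional integer for reproducible synthesis; the global
#'   RNG state is restored afterwards.
#' @return An object of class `adasyn_balanced`: `X` and `focal`
#'   (original rows first, then synthetics), `n_synthetic`, and the
#'   per-seed diagnostics `Theta`, `Gamma`, `g`, plus `K` actually used.
#' @export
adasyn_balance <- function(X, focal, beta = 1, K = 5L, seed = NULL) {
  X <- as.matrix(X)
  focal <- slda_focal_mask(focal)
  if (!is.numeric(beta) || beta < 0 || beta > 1)
    stop("`beta` must lie in [0, 1]")
  I_min <- sum(focal)
  J_maj <- sum(!focal)
  if (I_min == 0L) stop("no minority (focal) samples to oversample")
  n_syn <- as.integer(round((J_maj - I_min) * beta))
  empty <- structure(
    list(X = X, focal = focal, n_synthetic = 0L,
         Theta = integer(I_min), Gamma = rep(1 / I_min, I_min),
         g = integer(I_min), K = K),
    class = "adasyn_balanced")
  if (n_syn <= 0L) return(empty)
  if (I_min <= K) {
    K_min <- max(I_min - 1L, 1L)
    warning("minority class has ", I_min, " samples <= K = ", K,
            "; using K = ", K_min, " for minority neighbors")
  } else K_min <- K
  K_all <- min(K, nrow(X) - 1L)

  min_idx <- which(focal)
  d2 <- as.matrix(stats::dist(X))^2
  # Theta_i: majority members among the K nearest neighbors (full set)
  Theta <- vapply(min_idx, function(i) {
    ord <- order(d2[i, -i], seq_len(nrow(X) - 1L))[seq_len(K_all)]
    nb <- seq_len(nrow(X))[-i][ord]
    sum(!focal[nb])
  }, integer(1L))
  Z <- sum(Theta / K_all)
  if (Z == 0) {
    warning("no majority samples in any minority neighborhood; ",
            "spreading synthesis uniformly")
    Gamma <- rep(1 / I_min, I_min)
  } else Gamma <- (Theta / K_all) / Z

  # largest-remainder integerization: sum(g) = n_syn exactly
  raw <- Gamma * n_syn
  g <- floor(raw)
  left <- n_syn - sum(g)
  if (left > 0L) {
    top <- order(raw - g, decreasing = TRUE)[seq_len(left)]
    g[top] <- g[top] + 1L
  }

  syn <- with_seed(seed, {
    out <- vector("list", I_min)
    for (ii in seq_len(I_min)) {
      if (g[ii] == 0L) next
      a <- X[min_idx[ii], ]
      others <- setdiff(min_idx, min_idx[ii])
      if (length(others) == 0L) {
        out[[ii]] <- matrix(rep(a, g[ii]), nrow = g[ii], byrow = TRUE)
        next
      }
      ord <- order(d2[min_idx[ii], others], seq_along(others))
      nb_pool <- others[ord[seq_len(min(K_min, length(others)))]]
      pick <- nb_pool[sample.int(length(nb_pool), g[ii], replace = TRUE)]
      u <- stats::runif(g[ii])
      out[[ii]] <- X[pick, , drop = FALSE] * u +
        matrix(rep(a, g[ii]), nrow = g[ii], byrow = TRUE) * (1 - u)
    }
    do.call(rbind, out)
  })
  structure(
    list(X = rbind(X, syn),
         focal = c(focal, rep(TRUE, nrow(syn))),
         n_synthetic = nrow(syn), Theta = Theta, Gamma = Gamma, g = g,
         K = K_all),
    class = "adasyn_balanced")
}

#' @export
print.adasyn_balanced <- function(x, ...) {
  cat(sprintf(
    "<adasyn_balanced> %d rows (%d synthetic), %d focal / %d nonfocal\n",
    nrow(x$X), x$n_synthetic, sum(x$focal), sum(!x$focal)))
  invisible(x)
}
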