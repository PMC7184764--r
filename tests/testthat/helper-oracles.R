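# Independent brute-force oracles, written from the defining formulas
# only -- deliberately naive double loops, no code shared with the
# package implementations.

oracle_dist <- function(a, b, metric) {
  if (metric == "chebyshev") max(abs(a - b)) else sqrt(sum((a - b)^2))
}

# approximate entropy: phi(m) with self-matches, templates 1..L-m+1
oracle_apen <- function(x, d, r, metric = "chebyshev") {
  L <- length(x)
  phi <- function(m) {
    n <- L - m + 1
    lc <- numeric(n)
    for (i in 1:n) {
      cnt <- 0
      for (j in 1:n) {
        if (oracle_dist(x[i:(i + m - 1)], x[j:(j + m - 1)], metric) <= r)
          cnt <- cnt + 1
      }
      lc[i] <- log(cnt / n)
    }
    mean(lc)
  }
  phi(d) - phi(d + 1)
}

# sample entropy: pair counts over the first L-d templates, no self-match
oracle_sampen <- function(x, d, r, metric = "chebyshev") {
  L <- length(x)
  n <- L - d
  A <- 0; B <- 0
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    if (oracle_dist(x[i:(i + d - 1)], x[j:(j + d - 1)], metric) <= r)
      B <- B + 1
    if (oracle_dist(x[i:(i + d)], x[j:(j + d)], metric) <= r)
      A <- A + 1
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# permutation entropy by explicit stable-order pattern strings
oracle_pe <- function(x, d, tau) {
  n <- length(x) - (d - 1) * tau
  pats <- character(n)
  for (i in 1:n) {
    w <- x[i + (0:(d - 1)) * tau]
    pats[i] <- paste(order(w), collapse = "-")  # order() is stable
  }
  p <- as.numeric(table(pats)) / n
  -sum(p * log2(p))
}

oracle_shannon <- function(p) {
  s <- 0
  for (pi in p) if (pi > 0) s <- s - pi * log(pi)
  s
}

oracle_tsallis <- function(p, q) {
  s <- 0
  for (pi in p) s <- s + pi^q
  (1 - s) / (q - 1)
}

# probability of ranking a random positive above a random negative,
# half credit for ties
oracle_mann_whitney <- function(pos, neg) {
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

ridge_oracle <- function(M, y, delta) {
  Mc <- scale(M, scale = FALSE)
  solve(crossprod(Mc) + delta * diag(ncol(Mc)), crossprod(Mc, y - mean(y)))
}
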