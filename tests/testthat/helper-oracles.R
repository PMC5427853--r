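# Independent brute-force RLQ: explicit loops over the weighted
# cross-covariance, then a dense SVD.
bruteRLQ <- function(R, L, Q) {
  N <- sum(L)
  Pm <- L / N
  r <- rowSums(Pm); cc <- colSums(Pm)
  std <- function(X, w) {
    for (j in seq_len(ncol(X))) {
      m <- sum(w * X[, j])
      v <- sum(w * (X[, j] - m)^2)
      X[, j] <- if (v < 1e-12) 0 else (X[, j] - m) / sqrt(v)
    }
    X
  }
  Rs <- std(as.matrix(R), r); Qs <- std(as.matrix(Q), cc)
  Cross <- matrix(0, ncol(Rs), ncol(Qs))
  for (a in seq_len(ncol(Rs))) for (b in seq_len(ncol(Qs)))
    for (i in seq_len(nrow(L))) for (j in seq_len(ncol(L)))
      Cross[a, b] <- Cross[a, b] +
        r[i] * cc[j] * (Pm[i, j] / (r[i] * cc[j]) - 1) * Rs[i, a] * Qs[j, b]
  svd(Cross)
}

smallInstance <- function(seed) {
  set.seed(seed)
  L <- matrix(rpois(30, 3) + 1, 6, 5,
              dimnames = list(paste0("q", 1:6), paste0("s", 1:5)))
  R <- matrix(rnorm(18), 6, 3, dimnames = list(rownames(L), paste0("e", 1:3)))
  Q <- matrix(rnorm(10), 5, 2, dimnames = list(colnames(L), paste0("t", 1:2)))
  list(L = L, R = R, Q = Q)
}


# Oracle: Pearson correlation on the individual-inflated table (one row
# per stem, carrying its site's and its species' value).
inflatedPearson <- function(rVar, qVar, L) {
  xs <- ys <- numeric(0)
  for (i in seq_len(nrow(L))) for (j in seq_len(ncol(L))) {
    n <- L[i, j]
    if (n > 0) {
      xs <- c(xs, rep(rVar[i], n))
      ys <- c(ys, rep(qVar[j], n))
    }
  }
  cor(xs, ys)
}

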