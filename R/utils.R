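# Internal helpers shared across modules.

# Run expr with a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Weighted mean/variance with weights summing to 1 (population form).
wMean <- function(x, w) sum(w * x)
wVar <- function(x, w) {
  m <- sum(w * x)
  sum(w * (x - m)^2)
}

# Standardize columns of X to weighted mean 0, weighted variance 1.
# Zero-variance columns raise an error naming the column.
wStandardize <- function(X, w, tol = 1e-12) {
  X <- as.matrix(X)
  w <- w / sum(w)
  for (j in seq_len(ncol(X))) {
    v <- wVar(X[, j], w)
    if (v < tol)
      stop("zero-variance variable after weighting: ",
           colnames(X)[j] %||% j)
    X[, j] <- (X[, j] - wMean(X[, j], w)) / sqrt(v)
  }
  X
}

# Weighted Pearson correlation (population form, weights sum to 1).
wCor <- function(x, y, w) {
  w <- w / sum(w)
  vx <- wVar(x, w); vy <- wVar(y, w)
  if (vx <= 0 || vy <= 0) return(NA_real_)
  sum(w * (x - wMean(x, w)) * (y - wMean(y, w))) / sqrt(vx * vy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic eigenvector sign: largest-|entry| coordinate made positive.
fixSigns <- function(V) {
  for (j in seq_len(ncol(V))) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  V
}

# Natural-log transform rule for strictly positive tables; columns with
# zero or negative values get a log1p shift instead, reported via attribute.
logTransform <- function(X) {
  X <- as.matrix(X)
  shifted <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    if (all(X[, j] > 0)) X[, j] <- log(X[, j])
    else {
      X[, j] <- log1p(X[, j] - min(0, min(X[, j])))
      shifted[j] <- TRUE
    }
  }
  if (any(shifted))
    message("log1p shift applied to non-positive variables: ",
            paste(colnames(X)[shifted], collapse = ", "))
  attr(X, "log1pShifted") <- shifted
  X
}

checkDistanceMatrix <- function(D, what = "distance matrix") {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop(what, " must be square")
  if (max(abs(D - t(D))) > 1e-12 * max(1, max(abs(D))))
    stop(what, " is not symmetric")
  if (any(diag(D) != 0)) stop(what, " must have a zero diagonal")
  if (any(D < 0)) stop(what, " must be non-negative")
  D
}
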