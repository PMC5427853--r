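## Abundance-weighted mean pairwise distance, tip-shuffle null models and
## the sign-flipped standardized effect sizes NRI / S.E.S. PW.

#' Abundance-weighted mean pairwise distance within one sample
#'
#' \deqn{MPD = \sum_{i \ne j} f_i f_j D_{ij} / \sum_{i \ne j} f_i f_j}
#' with \eqn{f} the relative abundances; conspecific (i = j) pairs are
#' excluded.  Undefined (NA) when fewer than two species are present.
#'
#' @param abundances per-species counts (named or in the order of D).
#' @param D species x species distance matrix.
#' @return the mean pairwise distance, or NA when undefined.
#' @export
mpd <- function(abundances, D) {
  D <- checkDistanceMatrix(as.matrix(D))
  if (!is.null(names(abundances)))
    abundances <- abundances[rownames(D)]
  if (sum(abundances > 0) < 2) return(NA_real_)
  f <- abundances / sum(abundances)
  num <- as.numeric(t(f) %*% D %*% f)   # diagonal is zero: i != j only
  den <- 1 - sum(f^2)
  num / den
}

#' Abundance-weighted MPD for every quadrat of an abundance matrix
#'
#' Vectorized form of \code{\link{mpd}} over the rows of L.
#'
#' @param L quadrats x species abundance matrix (columns match D labels).
#' @param D species x species distance matrix.
#' @return numeric vector (NA for quadrats with < 2 species).
#' @export
mpdQuadrats <- function(L, D) {
  L <- as.matrix(L)
  D <- as.matrix(D)
  if (!is.null(colnames(L)) && !is.null(rownames(D)))
    D <- D[colnames(L), colnames(L), drop = FALSE]
  tot <- rowSums(L)
  Fm <- L / ifelse(tot > 0, tot, 1)
  num <- rowSums((Fm %*% D) * Fm)
  den <- 1 - rowSums(Fm^2)
  out <- ifelse(rowSums(L > 0) >= 2, num / den, NA_real_)
  names(out) <- rownames(L)
  out
}

#' Tip-shuffle null moments of a quadrat-level metric
#'
#' Per iteration, one pool-wide permutation of the species labels is
#' applied to the tips of the tree / dendrogram (equivalently to the rows
#' and columns of its distance matrix) and the metric is recomputed for
#' every quadrat.  Species abundance, frequency and occurrence in L are
#' untouched; only relatedness is randomized.
#'
#' @param L quadrats x species abundance matrix.
#' @param D species distance matrix (patristic or cophenetic).
#' @param nIter number of shuffles (>= 99).
#' @param seed integer seed.
#' @param metricFn function(L, D) returning a per-quadrat vector; default
#'   \code{\link{mpdQuadrats}}.
#' @return list with per-quadrat \code{mean} and \code{sd} of the null
#'   metric and \code{nIter}.
#' @export
tipShuffleNull <- function(L, D, nIter = 999, seed = NULL,
                           metricFn = mpdQuadrats) {
  if (nIter < 99) stop("nIter must be >= 99")
  D <- as.matrix(D)
  s <- ncol(D)
  # permutations act on the sorted label set, so the null is invariant to
  # the storage order of species columns under a given seed
  ord <- if (!is.null(rownames(D))) order(rownames(D)) else seq_len(s)
  withSeed(seed, {
    acc <- matrix(NA_real_, nIter, nrow(as.matrix(L)))
    for (it in seq_len(nIter)) {
      p <- ord[sample.int(s)]
      Dp <- D[p, p, drop = FALSE]
      dimnames(Dp) <- list(rownames(D)[ord], rownames(D)[ord])
      acc[it, ] <- metricFn(L, Dp)
    }
    list(mean = colMeans(acc), sd = apply(acc, 2, sd), nIter = nIter)
  })
}

#' Sign-flipped standardized effect size (NRI / S.E.S. PW)
#'
#' \deqn{-1 \times (obs - mean_{null}) / sd_{null}}
#' Positive values indicate clustering (observed distances smaller than
#' the null), negative values overdispersion.  A zero null standard
#' deviation yields index 0 with a degeneracy flag (attribute
#' \code{degenerate}).
#'
#' @param obs observed metric (vectorized).
#' @param meanNull,sdNull null moments.
#' @return numeric vector with logical attribute \code{degenerate}.
#' @export
nri <- function(obs, meanNull, sdNull) {
  if (any(sdNull < 0, na.rm = TRUE)) stop("sdNull must be >= 0")
  degen <- !is.na(sdNull) & sdNull == 0
  idx <- -1 * (obs - meanNull) / ifelse(degen, 1, sdNull)
  idx[degen] <- 0
  attr(idx, "degenerate") <- degen
  idx
}

#' @rdname nri
#' @export
sesPW <- nri

#' Per-quadrat dispersion indices against the tip-shuffle null
#'
#' Computes the observed abundance-weighted MPD, the tip-shuffle null
#' moments and the sign-flipped standardized effect size for every
#' quadrat.  With a patristic distance matrix this is the net relatedness
#' index (NRI); with cophenetic distances from the trait dendrogram it is
#' S.E.S. PW.
#'
#' @param L quadrats x species abundance matrix.
#' @param D species distance matrix.
#' @param nIter null iterations.
#' @param seed integer seed.
#' @return data.frame: quadrat, nSpecies, obs, meanNull, sdNull, index,
#'   degenerate, defined.
#' @export
dispersionIndices <- function(L, D, nIter = 999, seed = NULL) {
  L <- as.matrix(L)
  obs <- mpdQuadrats(L, D)
  nullm <- tipShuffleNull(L, D, nIter = nIter, seed = seed)
  idx <- nri(obs, nullm$mean, nullm$sd)
  data.frame(quadrat = rownames(L) %||% as.character(seq_len(nrow(L))),
             nSpecies = rowSums(L > 0),
             obs = unname(obs), meanNull = nullm$mean, sdNull = nullm$sd,
             index = as.numeric(idx),
             degenerate = attr(idx, "degenerate"),
             defined = !is.na(obs),
             row.names = NULL)
}

#' Axis-side aggregation of dispersion indices
#'
#' Splits quadrats by the sign of their first-axis RLQ site score and
#' summarizes the index on each side: mean, one-sample two-sided Student
#' t-test of mean = 0, and (optionally) a spatially corrected p-value
#' from the intercept-only SAR error model.
#'
#' @param indices data.frame from \code{\link{dispersionIndices}} (or any
#'   frame with columns quadrat, index, defined).
#' @param scores named per-quadrat axis-1 site scores (names match
#'   quadrat ids).
#' @param scale quadrat side recorded in the output.
#' @param W optional full-grid row-standardized weight matrix (with
#'   dimnames) for the SAR-corrected test.
#' @return data.frame: scale, side, n, meanIndex, t, p, rhoSAR, pSAR.
#' @export
axisSideSummary <- function(indices, scores, scale = NA, W = NULL) {
  stopifnot(!is.null(names(scores)))
  keep <- indices$defined & !is.na(indices$index) &
    indices$quadrat %in% names(scores)
  d <- indices[keep, , drop = FALSE]
  sgn <- ifelse(scores[d$quadrat] >= 0, "positive", "negative")
  oneSide <- function(side) {
    v <- d$index[sgn == side]
    q <- d$quadrat[sgn == side]
    n <- length(v)
    if (n < 3)
      return(data.frame(scale = scale, side = side, n = n,
                        meanIndex = if (n) mean(v) else NA_real_,
                        t = NA_real_, p = NA_real_,
                        rhoSAR = NA_real_, pSAR = NA_real_))
    tt <- if (sd(v) > 0) t.test(v, mu = 0) else NULL
    rho <- pSAR <- NA_real_
    if (!is.null(W) && n >= 10) {
      Ws <- W[q, q, drop = FALSE]
      rs <- rowSums(Ws)
      connected <- rs > 0
      if (sum(connected) >= 10) {
        Ws <- Ws[connected, connected, drop = FALSE]
        Ws <- Ws / rowSums(Ws)
        fit <- try(fitSarError(v[connected], Ws), silent = TRUE)
        if (!inherits(fit, "try-error")) {
          rho <- fit$rho; pSAR <- fit$interceptP
        }
      }
    }
    data.frame(scale = scale, side = side, n = n, meanIndex = mean(v),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p = if (is.null(tt)) NA_real_ else tt$p.value,
               rhoSAR = rho, pSAR = pSAR)
  }
  out <- rbind(oneSide("positive"), oneSide("negative"))
  rownames(out) <- NULL
  out
}
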