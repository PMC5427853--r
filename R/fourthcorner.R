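## Fourth-corner statistics: per-pair weighted correlations through L and
## permutation tests under null models 2 (sites) and 4 (species).

# Weighted standardization of a single variable; returns NULL on zero
# variance so callers can choose the error path.
fcStd <- function(x, w) {
  w <- w / sum(w)
  m <- sum(w * x)
  v <- sum(w * (x - m)^2)
  if (v < 1e-12) return(NULL)
  (x - m) / sqrt(v)
}

#' Fourth-corner statistic for a quantitative site and species variable
#'
#' Pearson correlation between a per-site variable and a per-species
#' variable on the individual-inflated table (every stem contributes the
#' value of its site and of its species), computed as the abundance-
#' weighted cross product \eqn{\sum_{ij} p_{ij} \tilde{x}_i \tilde{y}_j}
#' of the variables standardized under the marginal weights of L.
#'
#' @param rVar per-site numeric vector (length nrow(L)).
#' @param qVar per-species numeric vector (length ncol(L)).
#' @param L sites x species non-negative abundance matrix.
#' @return the statistic (a correlation in [-1, 1]).
#' @export
fourthCornerStat <- function(rVar, qVar, L) {
  L <- as.matrix(L)
  if (length(rVar) != nrow(L) || length(qVar) != ncol(L))
    stop("dimension mismatch between variables and L")
  if (any(L < 0)) stop("L must be non-negative")
  Pm <- L / sum(L)
  r <- rowSums(Pm); cc <- colSums(Pm)
  xs <- fcStd(rVar, r)
  ys <- fcStd(qVar, cc)
  if (is.null(xs)) stop("degenerate input: site variable has zero variance ",
                        "under the abundance weights")
  if (is.null(ys)) stop("degenerate input: species variable has zero ",
                        "variance under the abundance weights")
  as.numeric(crossprod(xs, Pm %*% ys))
}

#' Permutation test of a fourth-corner statistic
#'
#' Null model 2 permutes the rows of L (sites: breaks the environment to
#' species link while keeping the trait to species link); null model 4
#' permutes the columns of L (species: breaks the trait link).  Two-sided
#' p-values use the plus-one rule; the combined p-value is the maximum of
#' the two, significant only when both links hold.
#'
#' @param rVar,qVar,L as in \code{\link{fourthCornerStat}}.
#' @param nPerm number of permutations (>= 99).
#' @param seed integer seed.
#' @param returnNull also return the two null distributions.
#' @return data.frame with \code{stat}, \code{p2}, \code{p4},
#'   \code{pCombined} (and attribute \code{null} when requested).
#' @export
fourthCornerTest <- function(rVar, qVar, L, nPerm = 999, seed = NULL,
                             returnNull = FALSE) {
  if (nPerm < 99) stop("nPerm must be >= 99")
  L <- as.matrix(L)
  Pm <- L / sum(L)
  r <- rowSums(Pm); cc <- colSums(Pm)
  xs <- fcStd(rVar, r); ys <- fcStd(qVar, cc)
  if (is.null(xs) || is.null(ys))
    stop("degenerate input: zero weighted variance")
  obs <- as.numeric(crossprod(xs, Pm %*% ys))
  # permuting rows (cols) of L is equivalent to permuting the pairing of
  # rVar (qVar) with the margins; the projections below are fixed.
  w2 <- as.numeric(Pm %*% ys)        # site-side projection, model 2
  u4 <- as.numeric(crossprod(Pm, xs))  # species-side projection, model 4
  withSeed(seed, {
    null2 <- vapply(seq_len(nPerm), function(i) {
      xp <- fcStd(rVar[sample.int(length(rVar))], r)
      if (is.null(xp)) 0 else sum(w2 * xp)
    }, 0)
    null4 <- vapply(seq_len(nPerm), function(i) {
      yp <- fcStd(qVar[sample.int(length(qVar))], cc)
      if (is.null(yp)) 0 else sum(u4 * yp)
    }, 0)
    p2 <- (sum(abs(null2) >= abs(obs)) + 1) / (nPerm + 1)
    p4 <- (sum(abs(null4) >= abs(obs)) + 1) / (nPerm + 1)
    out <- data.frame(stat = obs, p2 = p2, p4 = p4,
                      pCombined = max(p2, p4))
    if (returnNull) attr(out, "null") <- list(model2 = null2, model4 = null4)
    out
  })
}

#' Fourth-corner tests over a grid of variable pairs
#'
#' Runs \code{\link{fourthCornerTest}} for every column pair of a
#' site-side table R and species-side table Q, reporting raw and
#' Holm-adjusted combined p-values.
#'
#' @param R sites x variables matrix.
#' @param Q species x variables matrix.
#' @param L abundance matrix.
#' @param nPerm permutations per pair.
#' @param seed integer seed.
#' @return data.frame: rVar, qVar, stat, p2, p4, pCombined, pHolm.
#' @export
fourthCornerGrid <- function(R, Q, L, nPerm = 999, seed = NULL) {
  R <- as.matrix(R); Q <- as.matrix(Q)
  combos <- expand.grid(rVar = seq_len(ncol(R)), qVar = seq_len(ncol(Q)))
  seeds <- if (is.null(seed)) rep(list(NULL), nrow(combos))
           else as.list(seed + seq_len(nrow(combos)))
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    res <- fourthCornerTest(R[, combos$rVar[k]], Q[, combos$qVar[k]], L,
                            nPerm = nPerm, seed = seeds[[k]])
    cbind(data.frame(rVar = colnames(R)[combos$rVar[k]],
                     qVar = colnames(Q)[combos$qVar[k]]), res)
  })
  out <- do.call(rbind, rows)
  out$pHolm <- p.adjust(out$pCombined, method = "holm")
  rownames(out) <- NULL
  out
}

# Total co-inertia (Frobenius norm squared of the weighted cross table)
# between prepared site-side and species-side blocks through L.
coInertiaObs <- function(X, Q, L0, r, cc) {
  Cross <- crossprod(X * r, L0 %*% (Q * cc))
  sum(Cross^2)
}

#' Global matrix-pair association test
#'
#' Tests the overall association between a site-side block and a
#' species-side block through L: the observed value is the total
#' co-inertia (the sum of squared fourth-corner statistics over all
#' variable pairs), the null distribution comes from permuting rows of L
#' (model 2) and columns of L (model 4).  The standardized effect size
#' uses the pooled null draws of both models and
#' \code{P = max(p2, p4)}.
#'
#' @param bundle an aligned \linkS4class{FiveMatrixBundle}.
#' @param pair which blocks to test: "ET", "EP", "ST", "SP" or "RQ"
#'   (site-side E and S jointly versus species-side T and P jointly).
#' @param nPerm permutations per null model.
#' @param seed integer seed.
#' @param pcoaTarget PCoA-axis retention for the T and P blocks.
#' @return one-row data.frame: pair, Obs, SES, P, p2, p4.
#' @export
globalAssociation <- function(bundle, pair = c("RQ", "ET", "EP", "ST", "SP"),
                              nPerm = 999, seed = NULL, pcoaTarget = 0.95) {
  pair <- match.arg(pair)
  L <- abundanceMatrix(bundle)
  ca <- correspondenceAnalysis(L)
  r <- ca@rowWeights; cc <- ca@colWeights
  L0 <- ca@details$L0
  Taxes <- retainPcoaAxes(pcoaOrdination(traitDist(bundle)), pcoaTarget)
  Paxes <- retainPcoaAxes(pcoaOrdination(phyloDist(bundle)), pcoaTarget)
  E <- envMatrix(bundle); S <- spatialMatrix(bundle)
  prepR <- switch(substr(pair, 1, 1),
                  R = function(M) cbind(
                        blockScale(M[, seq_len(ncol(E)), drop = FALSE], r, TRUE),
                        blockScale(M[, ncol(E) + seq_len(ncol(S)),
                                     drop = FALSE], r)),
                  E = function(M) blockScale(M, r, TRUE),
                  S = function(M) blockScale(M, r))
  rawR <- switch(substr(pair, 1, 1), R = cbind(E, S), E = E, S = S)
  prepQ <- switch(substr(pair, 2, 2),
                  Q = function(M) cbind(
                        blockScale(M[, seq_len(ncol(Taxes)), drop = FALSE], cc),
                        blockScale(M[, ncol(Taxes) + seq_len(ncol(Paxes)),
                                     drop = FALSE], cc)),
                  T = function(M) blockScale(M, cc),
                  P = function(M) blockScale(M, cc))
  rawQ <- switch(substr(pair, 2, 2), Q = cbind(Taxes, Paxes),
                 T = Taxes, P = Paxes)
  sideR <- prepR(rawR)
  sideQ <- prepQ(rawQ)
  obs <- coInertiaObs(sideR, sideQ, L0, r, cc)
  n <- nrow(L); s <- ncol(L)
  # fixed projections: permuting L's rows == permuting sideR's rows, etc.
  B <- L0 %*% (sideQ * cc)      # sites x q
  A <- crossprod(sideR * r, L0)   # p x species
  withSeed(seed, {
    null2 <- vapply(seq_len(nPerm), function(i) {
      Xp <- prepR(rawR[sample.int(n), , drop = FALSE])
      sum(crossprod(Xp * r, B)^2)
    }, 0)
    null4 <- vapply(seq_len(nPerm), function(i) {
      Qp <- prepQ(rawQ[sample.int(s), , drop = FALSE])
      sum((A %*% (Qp * cc))^2)
    }, 0)
    p2 <- (sum(null2 >= obs) + 1) / (nPerm + 1)
    p4 <- (sum(null4 >= obs) + 1) / (nPerm + 1)
    pooled <- c(null2, null4)
    data.frame(pair = pair, Obs = obs,
               SES = (obs - mean(pooled)) / sd(pooled),
               P = max(p2, p4), p2 = p2, p4 = p4)
  })
}

#' Table of global association tests for all matrix pairs
#'
#' Runs \code{\link{globalAssociation}} for the joint pair R-Q and the
#' four elementary pairs E-T, E-P, S-T, S-P, producing the standard
#' scale-by-pair Obs / SES / P summary.
#'
#' @inheritParams globalAssociation
#' @param scale optional quadrat side recorded in the output.
#' @return data.frame with one row per pair.
#' @export
globalAssociationTable <- function(bundle, nPerm = 999, seed = NULL,
                                   scale = NA, pcoaTarget = 0.95) {
  pairs <- c("RQ", "ET", "EP", "ST", "SP")
  seeds <- if (is.null(seed)) rep(list(NULL), length(pairs))
           else as.list(seed + seq_along(pairs))
  rows <- lapply(seq_along(pairs), function(k)
    globalAssociation(bundle, pairs[k], nPerm = nPerm, seed = seeds[[k]],
                      pcoaTarget = pcoaTarget))
  out <- do.call(rbind, rows)
  out <- cbind(scale = scale, out)
  rownames(out) <- NULL
  out
}
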