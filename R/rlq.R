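## RLQ co-inertia: classic three-table core and the five-matrix extension.

# Center (and optionally scale) columns under weights w; zero-variance
# columns become all-zero rather than erroring: a centred constant carries
# no inertia and must vanish from the co-inertia.
rlqPrep <- function(X, w, scale = TRUE, tol = 1e-12) {
  X <- as.matrix(X)
  w <- w / sum(w)
  m <- colSums(X * w)
  Xc <- X - matrix(m, nrow(X), ncol(X), byrow = TRUE)
  v <- colSums(Xc * Xc * w)
  zero <- v < tol
  if (scale) {
    f <- ifelse(zero, 0, 1 / sqrt(pmax(v, tol)))
    Xc <- Xc * matrix(f, nrow(X), ncol(X), byrow = TRUE)
  } else if (any(zero)) {
    Xc[, zero] <- 0
  }
  Xc
}

newRLQ <- function(d, u, v, Rs, Qs, r, c, extras = list()) {
  keep <- d^2 > 1e-12 * max(d^2, 1e-300)
  if (!any(keep)) keep <- seq_len(min(1, length(d)))
  d <- d[keep]
  u <- u[, keep, drop = FALSE]
  v <- v[, keep, drop = FALSE]
  siteSc <- Rs %*% u
  # deterministic sign: largest |site score| positive per axis
  for (j in seq_len(ncol(siteSc))) {
    k <- which.max(abs(siteSc[, j]))
    if (siteSc[k, j] < 0) {
      u[, j] <- -u[, j]; v[, j] <- -v[, j]; siteSc[, j] <- -siteSc[, j]
    }
  }
  spSc <- Qs %*% v
  ax <- paste0("Axis", seq_along(d))
  dimnames(siteSc) <- list(rownames(Rs), ax)
  dimnames(spSc) <- list(rownames(Qs), ax)
  lam <- d^2
  pct <- if (sum(lam) > 0) lam / sum(lam) else rep(0, length(lam))
  new("RLQResult",
      eigenvalues = lam, pctVariance = pct,
      siteScores = siteSc, speciesScores = spSc,
      envCor = matrix(0, 0, 0), spatialCor = matrix(0, 0, 0),
      traitCor = matrix(0, 0, 0), phyloCor = matrix(0, 0, 0),
      details = c(list(u = u, v = v, R = Rs, Q = Qs,
                       siteWeights = r, speciesWeights = c,
                       totalCoinertia = sum(lam)), extras))
}

#' Classic RLQ co-inertia analysis
#'
#' Singular value decomposition of the weighted cross-covariance
#' \eqn{R^T D_r \tilde{L} D_c Q}, where \eqn{\tilde{L}} is the
#' correspondence-analysis-standardized abundance table
#' (\eqn{p_{ij}/(r_i c_j) - 1}) and \eqn{D_r, D_c} its marginal weights.
#' Site scores are projections of the site-side table R, species scores
#' projections of the species-side table Q; eigenvalues (squared singular
#' values) sum to the total co-inertia.
#'
#' @param R sites x variables table (rows match rows of L).
#' @param L sites x species non-negative abundance matrix.
#' @param Q species x variables table (rows match columns of L).
#' @param scaleTables center and scale R and Q columns under the CA
#'   weights; set FALSE when the tables are pre-standardized block-wise
#'   (as in \code{\link{extendedRLQ}}), in which case columns are centred
#'   only.
#' @return an \linkS4class{RLQResult}.
#' @export
rlqCore <- function(R, L, Q, scaleTables = TRUE) {
  R <- as.matrix(R); L <- as.matrix(L); Q <- as.matrix(Q)
  if (nrow(R) != nrow(L))
    stop("dimension mismatch: R has ", nrow(R), " rows but L has ", nrow(L))
  if (nrow(Q) != ncol(L))
    stop("dimension mismatch: Q has ", nrow(Q), " rows but L has ",
         ncol(L), " columns")
  ca <- correspondenceAnalysis(L)
  r <- ca@rowWeights; cc <- ca@colWeights
  L0 <- ca@details$L0
  Rs <- rlqPrep(R, r, scale = scaleTables)
  Qs <- rlqPrep(Q, cc, scale = scaleTables)
  Cross <- crossprod(Rs * r, L0 %*% (Qs * cc))
  sv <- svd(Cross)
  newRLQ(sv$d, sv$u, sv$v, Rs, Qs, r, cc)
}

# Retain the smallest number of leading PCoA axes reaching `target` of the
# total (corrected) positive inertia.
retainPcoaAxes <- function(ord, target = 0.95, nMax = Inf) {
  lam <- eigenvalues(ord)
  if (sum(lam) <= 0)
    return(ord@rowScores[, 1, drop = FALSE])
  k <- which(cumsum(lam) / sum(lam) >= target)[1]
  k <- min(k, ncol(ord@rowScores), nMax)
  ord@rowScores[, seq_len(k), drop = FALSE]
}

# Center a block under weights and rescale it to unit total inertia
# (sum of weighted column variances = 1); near-zero blocks stay zero.
blockScale <- function(X, w, standardizeCols = FALSE, tol = 1e-12) {
  X <- rlqPrep(X, w, scale = standardizeCols)
  wn <- w / sum(w)
  inertia <- sum(colSums(X * X * wn))   # columns are already centred
  if (inertia > tol) X <- X / sqrt(inertia)
  X
}

#' Extended five-matrix RLQ analysis
#'
#' Combines environment and space on the site side and traits and
#' phylogeny on the species side of an RLQ co-inertia.  The site-side
#' table is \code{[standardized E | MEM basis]}, the species-side table
#' \code{[PCoA axes of T | PCoA axes of P]}; each of the four blocks is
#' rescaled to unit total inertia (equal a-priori influence) before the
#' core decomposition.  Axis scores thus decompose into an environmental
#' and a spatial combination on the site side (returned in
#' \code{details}), and weighted Pearson correlations of every original
#' variable with every axis are returned per block.
#'
#' @param bundle an aligned \linkS4class{FiveMatrixBundle}.
#' @param nAxes number of axes to report (default \code{min(4, rank)}).
#' @param pcoaTarget fraction of positive inertia the retained PCoA axes
#'   of T and P must reach (default 0.95).
#' @return an \linkS4class{RLQResult} with correlation tables filled.
#' @export
extendedRLQ <- function(bundle, nAxes = 4, pcoaTarget = 0.95) {
  stopifnot(is(bundle, "FiveMatrixBundle"))
  L <- abundanceMatrix(bundle)
  ca <- correspondenceAnalysis(L)
  r <- ca@rowWeights; cc <- ca@colWeights
  L0 <- ca@details$L0

  E <- envMatrix(bundle); S <- spatialMatrix(bundle)
  Taxes <- retainPcoaAxes(pcoaOrdination(traitDist(bundle)), pcoaTarget)
  Paxes <- retainPcoaAxes(pcoaOrdination(phyloDist(bundle)), pcoaTarget)

  Eb <- blockScale(E, r, standardizeCols = TRUE)
  Sb <- blockScale(S, r)
  Tb <- blockScale(Taxes, cc)
  Pb <- blockScale(Paxes, cc)

  Rtab <- cbind(Eb, Sb)
  Qtab <- cbind(Tb, Pb)
  Cross <- crossprod(Rtab * r, L0 %*% (Qtab * cc))
  sv <- svd(Cross)
  res <- newRLQ(sv$d, sv$u, sv$v, Rtab, Qtab, r, cc,
                extras = list(blocks = list(nE = ncol(E), nS = ncol(S),
                                            nT = ncol(Taxes),
                                            nP = ncol(Paxes)),
                              Taxes = Taxes, Paxes = Paxes))
  # eigenvalues and pctVariance stay defined over ALL axes (so axis-k
  # percentages are fractions of the total co-inertia); only the reported
  # scores are truncated to nAxes.
  k <- min(nAxes, ncol(res@siteScores))
  res@siteScores <- res@siteScores[, seq_len(k), drop = FALSE]
  res@speciesScores <- res@speciesScores[, seq_len(k), drop = FALSE]
  u <- res@details$u[, seq_len(k), drop = FALSE]
  v <- res@details$v[, seq_len(k), drop = FALSE]
  res@details$u <- u; res@details$v <- v

  iE <- seq_len(ncol(E)); iS <- ncol(E) + seq_len(ncol(S))
  iT <- seq_len(ncol(Taxes)); iP <- ncol(Taxes) + seq_len(ncol(Paxes))
  res@details$siteScoresEnv <-
    Rtab[, iE, drop = FALSE] %*% u[iE, , drop = FALSE]
  res@details$siteScoresSpace <-
    Rtab[, iS, drop = FALSE] %*% u[iS, , drop = FALSE]

  corBlock <- function(X, scores, w) {
    out <- matrix(NA_real_, ncol(X), ncol(scores),
                  dimnames = list(colnames(X), colnames(scores)))
    for (j in seq_len(ncol(X)))
      for (a in seq_len(ncol(scores)))
        out[j, a] <- wCor(X[, j], scores[, a], w)
    out
  }
  res@envCor <- corBlock(E, res@siteScores, r)
  res@spatialCor <- corBlock(S, res@siteScores, r)
  res@traitCor <- corBlock(Taxes, res@speciesScores, cc)
  res@phyloCor <- corBlock(Paxes, res@speciesScores, cc)
  validObject(res)
  res
}

#' Per-axis interpretation table of an RLQ result
#'
#' Weighted Pearson correlations of every site-side and species-side
#' variable with one axis, plus signed site scores for map rendering
#' (positive versus negative coordinate, size proportional to |score|).
#' Raw trait or environment tables can be supplied to correlate original
#' variables rather than ordination axes.
#'
#' @param result an \linkS4class{RLQResult} from \code{\link{extendedRLQ}}.
#' @param axis axis index (default 1; the axis analysed throughout).
#' @param traits optional species x trait matrix for trait correlations.
#' @param env optional sites x variable matrix for env correlations.
#' @return list with \code{correlations} (data.frame: variable, block, r)
#'   and \code{sites} (data.frame: site, score, sign).
#' @export
axisSummary <- function(result, axis = 1, traits = NULL, env = NULL) {
  if (axis > length(result@eigenvalues))
    stop("axis ", axis, " exceeds the ", length(result@eigenvalues),
         " available axes")
  sc <- result@siteScores[, axis]
  sp <- result@speciesScores[, axis]
  r <- result@details$siteWeights
  cc <- result@details$speciesWeights
  rows <- list()
  addBlock <- function(M, block) {
    if (!length(M)) return(NULL)
    data.frame(variable = rownames(M), block = block,
               r = M[, axis], row.names = NULL)
  }
  if (!is.null(env)) {
    env <- as.matrix(env)[names(sc), , drop = FALSE]
    rows$env <- data.frame(variable = colnames(env), block = "env",
                           r = apply(env, 2, wCor, y = sc, w = r),
                           row.names = NULL)
  } else rows$env <- addBlock(result@envCor, "env")
  rows$spatial <- addBlock(result@spatialCor, "spatial")
  if (!is.null(traits)) {
    traits <- as.matrix(traits)[names(sp), , drop = FALSE]
    rows$trait <- data.frame(variable = colnames(traits), block = "trait",
                             r = apply(traits, 2, wCor, y = sp, w = cc),
                             row.names = NULL)
  } else rows$trait <- addBlock(result@traitCor, "trait")
  rows$phylo <- addBlock(result@phyloCor, "phylo")
  correlations <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(correlations) <- NULL
  sites <- data.frame(site = names(sc), score = unname(sc),
                      sign = ifelse(sc >= 0, "positive", "negative"),
                      row.names = NULL)
  list(correlations = correlations, sites = sites)
}
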