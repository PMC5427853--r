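#' Partition a stem map into a quadrat abundance matrix
#'
#' Divides the plot into square quadrats of the given side and tabulates
#' stems by quadrat and species.  Quadrat intervals are half-open
#' \eqn{[x, x + s)} so every stem falls in exactly one quadrat;
#' \code{sum(L)} always equals the stem count.
#'
#' @param stemMap a \linkS4class{StemMap}.
#' @param scale quadrat side in metres; must divide both plot dimensions.
#' @return list with the \code{grid} (a \linkS4class{QuadratGrid}) and the
#'   quadrats x species abundance matrix \code{L}.
#' @examples
#' cfg <- simConfig(plotWidth = 100, plotHeight = 50, nSpecies = 10,
#'                  nIndividuals = 200, nEnvVars = 2, nTraits = 2, seed = 3)
#' ds <- simulateDataset(cfg)
#' p <- partition(ds@stemMap, 10)
#' dim(p$L)
#' @export
partition <- function(stemMap, scale) {
  stopifnot(is(stemMap, "StemMap"))
  pd <- plotDim(stemMap)
  grid <- quadratGrid(pd["width"], pd["height"], scale)
  s <- stems(stemMap)
  ix <- floor(s$x / scale)
  iy <- floor(s$y / scale)
  qid <- iy * grid@nX + ix + 1L
  ids <- quadratIds(grid)
  spp <- sort(unique(s$species))
  L <- table(factor(qid, levels = seq_len(nQuadrats(grid))),
             factor(s$species, levels = spp))
  L <- matrix(as.integer(L), nrow = nQuadrats(grid),
              dimnames = list(ids, spp))
  list(grid = grid, L = L)
}

#' Aggregate fine-scale quadrat values to a coarser grid
#'
#' Coarser-scale environment is the mean of the constituent fine-scale
#' quadrats; abundance-like tables can be summed instead.
#'
#' @param values quadrat x variable matrix on \code{fineGrid}.
#' @param fineGrid,coarseGrid nested \linkS4class{QuadratGrid}s over the
#'   same plot (the coarse side must be a multiple of the fine side).
#' @param fun "mean" (environment) or "sum" (abundance).
#' @return matrix on the coarse grid.
#' @export
aggregateToGrid <- function(values, fineGrid, coarseGrid,
                            fun = c("mean", "sum")) {
  fun <- match.arg(fun)
  stopifnot(fineGrid@plotWidth == coarseGrid@plotWidth,
            fineGrid@plotHeight == coarseGrid@plotHeight)
  ratio <- coarseGrid@scale / fineGrid@scale
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("coarse scale must be a multiple of the fine scale")
  values <- as.matrix(values)
  xy <- centroids(fineGrid)
  ix <- floor(xy[, "x"] / coarseGrid@scale)
  iy <- floor(xy[, "y"] / coarseGrid@scale)
  parent <- factor(iy * coarseGrid@nX + ix + 1L,
                   levels = seq_len(nQuadrats(coarseGrid)))
  out <- apply(values, 2, function(v) {
    s <- tapply(v, parent, sum)
    if (fun == "mean") s / tabulate(parent, nbins = nlevels(parent)) else s
  })
  out <- matrix(out, nrow = nQuadrats(coarseGrid),
                dimnames = list(quadratIds(coarseGrid), colnames(values)))
  out
}

#' Queen-contiguity neighbour matrix of a quadrat grid
#'
#' Binary adjacency between quadrats sharing an edge or a corner; zero
#' diagonal, symmetric.
#'
#' @param grid a \linkS4class{QuadratGrid}.
#' @param rowStandardize divide each row by its sum (the W matrix used by
#'   Moran's I and the SAR model).
#' @return a square matrix over quadrats.
#' @export
queenNeighbors <- function(grid, rowStandardize = FALSE) {
  nx <- grid@nX; ny <- grid@nY
  n <- nx * ny
  ix <- rep(seq_len(nx) - 1L, times = ny)
  iy <- rep(seq_len(ny) - 1L, each = nx)
  A <- matrix(0, n, n, dimnames = list(quadratIds(grid), quadratIds(grid)))
  shifts <- expand.grid(dx = -1:1, dy = -1:1)
  shifts <- shifts[!(shifts$dx == 0 & shifts$dy == 0), ]
  for (k in seq_len(nrow(shifts))) {
    jx <- ix + shifts$dx[k]; jy <- iy + shifts$dy[k]
    ok <- jx >= 0 & jx < nx & jy >= 0 & jy < ny
    from <- which(ok)
    to <- jy[ok] * nx + jx[ok] + 1L
    A[cbind(from, to)] <- 1
  }
  if (rowStandardize) A <- A / rowSums(A)
  A
}

#' Moran's I with a permutation test
#'
#' \eqn{I = (n / \sum W) \, z^T W z / z^T z} for centred values \eqn{z}.
#' The p-value is two-sided around the null expectation \eqn{-1/(n-1)},
#' computed from random relabelings with the plus-one rule.
#'
#' @param values per-quadrat numeric vector.
#' @param W neighbour weight matrix (binary or row-standardized).
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @return list with \code{I}, \code{expected} and \code{p}.
#' @export
moransI <- function(values, W, nPerm = 999, seed = NULL) {
  n <- length(values)
  if (n < 3) stop("need at least 3 quadrats")
  if (sd(values) == 0) stop("degenerate input: values are constant")
  stopifnot(nrow(W) == n, ncol(W) == n)
  sw <- sum(W)
  iStat <- function(v) {
    z <- v - mean(v)
    (n / sw) * sum(z * (W %*% z)) / sum(z * z)
  }
  obs <- iStat(values)
  e0 <- -1 / (n - 1)
  perm <- withSeed(seed,
    vapply(seq_len(nPerm), function(i) iStat(sample(values)), 0))
  p <- (sum(abs(perm - e0) >= abs(obs - e0)) + 1) / (nPerm + 1)
  list(I = obs, expected = e0, p = p)
}

#' Moran's eigenvector maps of a quadrat grid
#'
#' Eigenvectors of the doubly-centred queen adjacency matrix.  Vectors with
#' positive eigenvalues (positive spatial autocorrelation) are retained and
#' returned orthonormal; they are orthogonal to the constant vector by
#' construction.  When no eigenvalue is positive (possible only on
#' degenerate 2-quadrat grids), all non-null eigenvectors are returned with
#' a warning so a spatial basis always exists.
#'
#' @param grid a \linkS4class{QuadratGrid}.
#' @param tol relative eigenvalue tolerance.
#' @return quadrats x eigenvectors matrix, columns \code{MEM1..}, with the
#'   eigenvalues in \code{attr(, "values")}.
#' @export
memBasis <- function(grid, tol = 1e-8) {
  A <- queenNeighbors(grid)
  n <- nrow(A)
  if (n < 2) stop("need at least 2 quadrats")
  # connectivity check (queen lattice is connected, but guard the contract)
  reach <- logical(n); reach[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nb <- which(rowSums(A[, frontier, drop = FALSE]) > 0 & !reach)
    reach[nb] <- TRUE
    frontier <- nb
  }
  if (!all(reach))
    stop("neighbour graph is disconnected; components of sizes ",
         paste(table(reach), collapse = ", "))
  ones <- rep(1, n)
  M <- A - outer(ones, colMeans(A)) - outer(rowMeans(A), ones) + mean(A)
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  thr <- tol * max(abs(eig$values))
  keep <- eig$values > thr
  if (!any(keep)) {
    warning("no positive MEM eigenvalues; returning all non-null vectors")
    keep <- abs(eig$values) > thr
  }
  V <- fixSigns(eig$vectors[, keep, drop = FALSE])
  dimnames(V) <- list(quadratIds(grid), paste0("MEM", seq_len(sum(keep))))
  attr(V, "values") <- eig$values[keep]
  V
}

#' Intercept-only simultaneous autoregressive (SAR) error model
#'
#' Fits \eqn{y = \mu + u}, \eqn{u = \rho W u + \epsilon} by maximum
#' likelihood, using the eigenvalues of W for the log-determinant
#' \eqn{\log|I - \rho W| = \sum_i \log(1 - \rho \lambda_i)}.  Gives a
#' spatially corrected test of mean = 0 for autocorrelated per-quadrat
#' indices.
#'
#' @param values per-quadrat numeric vector (n >= 10).
#' @param W row-standardized neighbour weight matrix.
#' @return list with \code{rho}, \code{intercept}, \code{interceptSE},
#'   \code{interceptP} (two-sided t, n - 2 df), \code{sigma2} and
#'   \code{logLik}.
#' @export
fitSarError <- function(values, W) {
  n <- length(values)
  if (n < 10) stop("need at least 10 quadrats for the SAR fit")
  stopifnot(nrow(W) == n, ncol(W) == n)
  ev <- eigen(W, only.values = TRUE)$values
  if (max(abs(Im(ev))) > 1e-8)
    stop("SAR fit needs a weight matrix with real eigenvalues ",
         "(use a row-standardized symmetric adjacency)")
  ev <- Re(ev)
  lo <- if (min(ev) < 0) 1 / min(ev) + 1e-6 else -0.999
  hi <- 1 / max(ev) - 1e-6
  ones <- rep(1, n)
  profile <- function(rho) {
    A <- diag(n) - rho * W
    a1 <- A %*% ones
    ay <- A %*% values
    mu <- sum(a1 * ay) / sum(a1 * a1)
    r <- ay - mu * a1
    s2 <- sum(r * r) / n
    ll <- sum(log(pmax(1 - rho * ev, 1e-12))) - n / 2 * log(s2)
    list(ll = ll, mu = mu, s2 = s2)
  }
  opt <- optimize(function(r) profile(r)$ll, c(lo, hi), maximum = TRUE,
                  tol = 1e-8)
  rho <- opt$maximum
  fit <- profile(rho)
  if (!is.finite(opt$objective))
    stop("SAR fit failed to converge: non-finite likelihood at rho = ", rho)
  A <- diag(n) - rho * W
  a1 <- A %*% ones
  se <- sqrt(fit$s2 / sum(a1 * a1))
  tval <- fit$mu / se
  list(rho = rho, intercept = fit$mu, interceptSE = se,
       interceptP = 2 * pt(-abs(tval), df = n - 2),
       sigma2 = fit$s2,
       logLik = opt$objective - n / 2 * (log(2 * pi) + 1))
}
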