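## Single-table ordinations and distance constructions feeding the RLQ.

newOrdination <- function(eigenvalues, rowScores, colScores, rowWeights,
                          colWeights, totalInertia, method, details = list()) {
  new("OrdinationResult", eigenvalues = eigenvalues,
      rowScores = rowScores, colScores = colScores,
      rowWeights = rowWeights, colWeights = colWeights,
      totalInertia = totalInertia, method = method, details = details)
}

#' Correspondence analysis of a site-by-species table
#'
#' Eigen-decomposition of the chi-square-standardized table
#' \eqn{(p_{ij} - r_i c_j) / \sqrt{r_i c_j}}; row and column weights are the
#' marginal relative frequencies and the total inertia equals Pearson's
#' chi-square divided by the grand total.  Row/column scores are principal
#' coordinates with a deterministic sign convention.
#'
#' @param L non-negative matrix with no zero rows or columns.
#' @param tol relative eigenvalue tolerance.
#' @return an \linkS4class{OrdinationResult} (method "CA"); the
#'   CA-standardized table \eqn{p_{ij}/(r_i c_j) - 1} needed by RLQ sits in
#'   \code{details$L0}.
#' @export
correspondenceAnalysis <- function(L, tol = 1e-8) {
  L <- as.matrix(L)
  if (any(L < 0)) stop("L must be non-negative")
  rs <- rowSums(L); cs <- colSums(L)
  if (any(rs == 0))
    stop("zero row margin at: ",
         paste(head(rownames(L)[rs == 0] %||% which(rs == 0), 5), collapse = ", "))
  if (any(cs == 0))
    stop("zero column margin at: ",
         paste(head(colnames(L)[cs == 0] %||% which(cs == 0), 5), collapse = ", "))
  N <- sum(L)
  Pm <- L / N
  r <- rowSums(Pm); cc <- colSums(Pm)
  Z <- (Pm - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(Z)
  lam <- sv$d^2
  keep <- lam > tol * max(lam, 1e-300)
  lam <- lam[keep]
  if (!length(lam)) {            # independence table: zero inertia
    U <- matrix(0, nrow(L), 0); V <- matrix(0, ncol(L), 0)
  } else {
    U <- sv$u[, keep, drop = FALSE]
    V <- sv$v[, keep, drop = FALSE]
  }
  # deterministic sign via the row standard coordinates
  for (j in seq_along(lam)) {
    k <- which.max(abs(U[, j]))
    if (U[k, j] < 0) { U[, j] <- -U[, j]; V[, j] <- -V[, j] }
  }
  rowSc <- (U / sqrt(r)) * rep(sv$d[keep], each = nrow(U))
  colSc <- (V / sqrt(cc)) * rep(sv$d[keep], each = nrow(V))
  axn <- if (length(lam)) paste0("CA", seq_along(lam)) else character(0)
  dimnames(rowSc) <- list(rownames(L), axn)
  dimnames(colSc) <- list(colnames(L), axn)
  newOrdination(lam, rowSc, colSc,
                rowWeights = setNames(r, rownames(L)),
                colWeights = setNames(cc, colnames(L)),
                totalInertia = sum(sv$d^2), method = "CA",
                details = list(L0 = Pm / outer(r, cc) - 1))
}

#' Weighted principal component analysis
#'
#' PCA of variables standardized to weighted mean 0 / variance 1 under the
#' given row weights; with uniform weights this is the classic PCA of the
#' correlation matrix and the eigenvalues sum to the number of variables.
#'
#' @param X sites x variables matrix.
#' @param rowWeights non-negative site weights (normalized internally;
#'   default uniform).
#' @param tol relative eigenvalue tolerance.
#' @return an \linkS4class{OrdinationResult} (method "PCA"); row scores are
#'   principal coordinates, column scores the variable loadings scaled by
#'   the axis standard deviation (variable-axis correlations).
#' @export
weightedPCA <- function(X, rowWeights = NULL, tol = 1e-8) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 variables")
  n <- nrow(X)
  w <- if (is.null(rowWeights)) rep(1 / n, n) else rowWeights / sum(rowWeights)
  Xs <- wStandardize(X, w)
  C <- crossprod(Xs * sqrt(w))          # weighted correlation matrix
  eig <- eigen((C + t(C)) / 2, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  keep <- lam > tol * max(lam)
  lam <- lam[keep]
  V <- fixSigns(eig$vectors[, keep, drop = FALSE])
  rowSc <- Xs %*% V
  colSc <- sweep(V, 2, sqrt(lam), `*`)
  dimnames(rowSc) <- list(rownames(X), paste0("PC", seq_along(lam)))
  dimnames(colSc) <- list(colnames(X), paste0("PC", seq_along(lam)))
  newOrdination(lam, rowSc, colSc,
                rowWeights = setNames(w, rownames(X)),
                colWeights = setNames(rep(1, ncol(X)), colnames(X)),
                totalInertia = sum(eig$values), method = "PCA",
                details = list(standardized = Xs))
}

#' Gower distance between species from quantitative traits
#'
#' Mean over traits of \eqn{|x_i - x_j| / \mathrm{range}}, skipping trait
#' pairs where either value is missing; values lie in [0, 1].
#'
#' @param traits species x trait numeric matrix (NAs allowed).
#' @return labelled symmetric distance matrix.
#' @export
gowerDistance <- function(traits) {
  X <- as.matrix(traits)
  if (ncol(X) < 1) stop("need at least one trait column")
  n <- nrow(X)
  num <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    ok <- !is.na(v)
    rg <- diff(range(v[ok]))
    if (!is.finite(rg) || rg <= 0)
      stop("trait has zero range among non-missing values: ",
           colnames(X)[j] %||% j)
    d <- abs(outer(v, v, `-`)) / rg
    share <- outer(ok, ok, `&`)
    d[!share] <- 0
    num <- num + d
    cnt <- cnt + share
  }
  if (any(cnt == 0 & upper.tri(cnt))) {
    bad <- which(cnt == 0 & upper.tri(cnt), arr.ind = TRUE)[1, ]
    stop("species pair with no shared non-missing trait: ",
         rownames(X)[bad[1]], " / ", rownames(X)[bad[2]])
  }
  D <- num / cnt
  diag(D) <- 0
  dimnames(D) <- list(rownames(X), rownames(X))
  (D + t(D)) / 2
}

#' Patristic (tip-to-tip) distances of a phylogeny
#'
#' Sum of branch lengths along the path between every pair of tips.
#'
#' @param tree an \code{ape::phylo} with branch lengths.
#' @return labelled symmetric distance matrix in tip-label order.
#' @export
patristicDistance <- function(tree) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) {
    bad <- which(is.na(tree$edge.length))[1]
    stop("missing branch length on edge ", tree$edge[bad, 1], "->",
         tree$edge[bad, 2])
  }
  D <- ape::cophenetic.phylo(tree)
  checkDistanceMatrix(D, "patristic distance")
}

# Smallest constant c such that D + c (off-diagonal) embeds in Euclidean
# space: the largest real eigenvalue of the standard 2n x 2n companion
# problem built from the double-centred D and D^2 matrices.
cailliezConstant <- function(D) {
  n <- nrow(D)
  H <- diag(n) - matrix(1 / n, n, n)
  d1 <- -0.5 * H %*% (D * D) %*% H
  d2 <- -0.5 * H %*% D %*% H
  M <- rbind(cbind(matrix(0, n, n), 2 * d1),
             cbind(-diag(n), -4 * d2))
  ev <- eigen(M, only.values = TRUE)$values
  max(Re(ev[abs(Im(ev)) < 1e-8]))
}

#' Principal coordinate analysis with Cailliez correction
#'
#' Gower double-centering and eigendecomposition of a distance matrix.  If
#' negative eigenvalues beyond tolerance appear (non-Euclidean input, as
#' Gower distances can be), the Cailliez constant is added to all
#' off-diagonal distances and the decomposition redone; the correction is
#' flagged in \code{details}.  The returned coordinates reproduce the
#' (corrected) distances.
#'
#' @param D labelled symmetric distance matrix.
#' @param tol relative tolerance for calling an eigenvalue negative.
#' @return an \linkS4class{OrdinationResult} (method "PCoA") with row
#'   scores only; \code{details$corrected} and \code{details$cailliez}
#'   record the correction.
#' @export
pcoaOrdination <- function(D, tol = 1e-8) {
  D <- checkDistanceMatrix(as.matrix(D))
  n <- nrow(D)
  if (all(D == 0)) {             # degenerate: all points coincide
    V <- matrix(0, n, 1, dimnames = list(rownames(D), "PCo1"))
    return(newOrdination(0, V, matrix(0, 0, 0),
                         rowWeights = setNames(rep(1 / n, n), rownames(D)),
                         colWeights = numeric(0), totalInertia = 0,
                         method = "PCoA",
                         details = list(corrected = FALSE, cailliez = 0)))
  }
  res <- ape::pcoa(D)
  ev <- res$values$Eigenvalues
  corrected <- FALSE
  cailliez <- 0
  if (min(ev) < -tol * max(abs(ev))) {
    res <- ape::pcoa(D, correction = "cailliez")
    corrected <- TRUE
    cailliez <- cailliezConstant(D)
    ev <- if (!is.null(res$values$Corr_eig)) res$values$Corr_eig
          else res$values$Eigenvalues
    V <- res$vectors.cor
  } else V <- res$vectors
  ev <- sort(ev, decreasing = TRUE)
  posEv <- ev[ev > tol * max(abs(ev))]
  V <- as.matrix(V)
  k <- min(length(posEv), ncol(V))
  V <- fixSigns(V[, seq_len(k), drop = FALSE])
  lam <- posEv[seq_len(k)]
  dimnames(V) <- list(rownames(D), paste0("PCo", seq_len(k)))
  n <- nrow(D)
  newOrdination(lam, V,
                matrix(0, 0, 0),
                rowWeights = setNames(rep(1 / n, n), rownames(D)),
                colWeights = numeric(0),
                totalInertia = sum(ev[ev > 0]), method = "PCoA",
                details = list(corrected = corrected, cailliez = cailliez))
}

#' UPGMA dendrogram of a distance matrix
#'
#' Average-linkage hierarchical clustering returned as an ultrametric
#' \code{ape::phylo}; the cophenetic distance between two tips equals the
#' height at which their clusters merge.
#'
#' @param D labelled symmetric distance matrix over >= 2 species.
#' @return an ultrametric \code{ape::phylo}.
#' @export
upgmaDendrogram <- function(D) {
  D <- checkDistanceMatrix(as.matrix(D))
  if (nrow(D) < 2) stop("need at least 2 species")
  hc <- hclust(as.dist(D), method = "average")
  ape::as.phylo(hc)
}
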