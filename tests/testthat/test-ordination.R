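test_that("correspondence analysis matches chi-square and transition formulas", {
  # block-diagonal 2x2: perfect association, single unit eigenvalue
  ca <- correspondenceAnalysis(matrix(c(10, 0, 0, 10), 2, 2))
  expect_equal(eigenvalues(ca), 1)

  # independence (outer product of margins): zero inertia
  L0 <- outer(c(2, 3, 5), c(1, 4, 2))
  expect_equal(correspondenceAnalysis(L0)@totalInertia, 0, tolerance = 1e-12)

  # total inertia equals Pearson chi-square / N on a toy table
  L <- matrix(c(8, 2, 1, 3, 9, 2, 1, 2, 7), 3, 3)
  ca3 <- correspondenceAnalysis(L)
  expect_equal(ca3@totalInertia,
               unname(suppressWarnings(chisq.test(L)$statistic)) / sum(L),
               tolerance = 1e-12)

  # transition formula on random tables: column principal scores are the
  # weighted averages of row scores rescaled by 1/sqrt(eigenvalue)
  for (s in 1:5) {
    set.seed(s)
    Lr <- matrix(rpois(30, 4) + 1, 6, 5)
    ca <- correspondenceAnalysis(Lr)
    Pm <- Lr / sum(Lr)
    cc <- colSums(Pm)
    for (k in seq_len(2)) {
      b <- as.numeric(crossprod(Pm, ca@rowScores[, k]) / cc) /
        sqrt(eigenvalues(ca)[k])
      expect_lt(max(abs(b - ca@colScores[, k])), 1e-9)
    }
    # independent oracle: vegan's CA eigenvalues
    ev <- vegan::cca(Lr)$CA$eig
    expect_equal(unname(eigenvalues(ca)),
                 unname(ev[seq_along(eigenvalues(ca))]), tolerance = 1e-9)
  }

  Lz <- matrix(c(1, 0, 2, 0), 2, 2,
               dimnames = list(c("q1", "q2"), c("a", "b")))
  expect_error(correspondenceAnalysis(Lz), "zero row margin")
})

test_that("weighted PCA reduces to correlation-matrix PCA and sums to p", {
  set.seed(2)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("v", 1:3)))
  ord <- weightedPCA(X)
  expect_equal(ord@totalInertia, 3, tolerance = 1e-9)
  # uniform weights: same eigenvalues as eigen(cor(X)) up to the
  # population/sample variance factor, which cancels in correlations
  evOracle <- eigen(cor(X), only.values = TRUE)$values
  expect_equal(unname(eigenvalues(ord)), evOracle, tolerance = 1e-9)

  # two perfectly correlated variables: inertia (2, 0)
  Y <- cbind(a = 1:10, b = 2 * (1:10) + 3)
  ord2 <- weightedPCA(Y)
  expect_equal(unname(eigenvalues(ord2)[1]), 2, tolerance = 1e-9)
  expect_equal(ord2@totalInertia, 2, tolerance = 1e-9)

  # many uncorrelated standardized variables: eigenvalues near 1
  set.seed(3)
  Z <- matrix(rnorm(4e4), 1e4, 4)
  expect_lt(max(abs(eigenvalues(weightedPCA(Z)) - 1)), 0.1)

  expect_error(weightedPCA(cbind(a = rep(1, 5), b = 1:5)), "zero-variance")
})

test_that("Gower distances match hand computation and cluster::daisy", {
  X <- rbind(s1 = c(0, 10), s2 = c(5, 30), s3 = c(10, 20))
  colnames(X) <- c("t1", "t2")
  D <- gowerDistance(X)
  # hand: d(s1,s2) = (5/10 + 20/20)/2 = 0.75; d(s1,s3) = (1 + 0.5)/2 = 0.75
  expect_equal(unname(D["s1", "s2"]), 0.75)
  expect_equal(unname(D["s1", "s3"]), 0.75)
  expect_equal(unname(D["s2", "s3"]), (0.5 + 0.5) / 2)
  # identical rows at distance zero; min/max pair at 1 for a single trait
  Did <- gowerDistance(rbind(a = c(1, 2), b = c(1, 2), c = c(3, 4)))
  expect_equal(unname(Did["a", "b"]), 0)
  expect_equal(unname(gowerDistance(rbind(a = 0, b = 10))["a", "b"]), 1)
  # zero-range trait columns are rejected by contract
  expect_error(gowerDistance(rbind(a = c(1, 2), b = c(1, 2))), "zero range")

  set.seed(4)
  Xr <- matrix(rnorm(24), 8, 3,
               dimnames = list(paste0("s", 1:8), paste0("t", 1:3)))
  expect_lt(max(abs(gowerDistance(Xr) -
                    as.matrix(cluster::daisy(as.data.frame(Xr),
                                             metric = "gower")))), 1e-12)

  # missing values: pairs skip the missing trait
  Xm <- rbind(a = c(0, NA), b = c(5, 2), c = c(10, 4))
  Dm <- gowerDistance(Xm)
  expect_equal(unname(Dm["a", "b"]), 0.5)   # only t1 shared
  expect_error(gowerDistance(rbind(a = c(1, NA), b = c(NA, 1),
                                   c = c(2, 3))),
               "no shared")
})

test_that("patristic distances equal graph shortest paths on the tree", {
  tre <- ape::read.tree(text = "((a:0.3,b:0.3):0.7,c:1);")
  D <- patristicDistance(tre)
  expect_equal(unname(D["a", "b"]), 0.6)    # sisters at depth d: 2d
  expect_equal(unname(D["a", "c"]), 2.0)

  # brute-force oracle: Floyd-Warshall over the tree's edge graph
  set.seed(6)
  tr <- simulatePhylogeny(5, seed = 6)
  nv <- 5 + tr$Nnode
  G <- matrix(Inf, nv, nv); diag(G) <- 0
  for (e in seq_len(nrow(tr$edge))) {
    i <- tr$edge[e, 1]; j <- tr$edge[e, 2]
    G[i, j] <- G[j, i] <- tr$edge.length[e]
  }
  for (k in seq_len(nv)) for (i in seq_len(nv)) for (j in seq_len(nv))
    if (G[i, k] + G[k, j] < G[i, j]) G[i, j] <- G[i, k] + G[k, j]
  expect_equal(unname(patristicDistance(tr)),
               unname(G[1:5, 1:5]), tolerance = 1e-12)

  trNoBl <- tre; trNoBl$edge.length <- NULL
  expect_error(patristicDistance(trNoBl), "branch length")
})

test_that("PCoA embeds distances and applies the Cailliez correction", {
  # collinear points: exact recovery of pairwise distances
  D <- as.matrix(dist(c(0, 1, 3)))
  dimnames(D) <- list(letters[1:3], letters[1:3])
  p <- pcoaOrdination(D)
  expect_false(p@details$corrected)
  expect_lt(max(abs(as.matrix(dist(p@rowScores)) - D)), 1e-9)

  # equilateral triangle: two equal positive eigenvalues
  De <- matrix(1, 3, 3) - diag(3)
  dimnames(De) <- dimnames(D)
  pe <- pcoaOrdination(De)
  expect_equal(eigenvalues(pe)[1], eigenvalues(pe)[2], tolerance = 1e-9)

  # classic non-Euclidean quadruple: correction flagged, corrected
  # distances reproduced within 1e-6
  Dq <- matrix(c(0, 2, 1, 1, 2, 0, 1, 1, 1, 1, 0, 2, 1, 1, 2, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  pq <- pcoaOrdination(Dq)
  expect_true(pq@details$corrected)
  expect_equal(pq@details$cailliez, sqrt(2), tolerance = 1e-6)
  Dcor <- Dq + pq@details$cailliez
  diag(Dcor) <- 0
  expect_lt(max(abs(as.matrix(dist(pq@rowScores)) - Dcor)), 1e-6)

  # ultrametric cophenetic distances are Euclidean: no correction
  tr <- simulatePhylogeny(15, seed = 9)
  pu <- pcoaOrdination(patristicDistance(tr))
  expect_false(pu@details$corrected)
})

test_that("UPGMA dendrograms are ultrametric with merge-height cophenetics", {
  D2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- upgmaDendrogram(D2)
  expect_equal(unname(ape::cophenetic.phylo(t2)["a", "b"]), 3)
  expect_equal(max(ape::node.depth.edgelength(t2)), 1.5)  # merge at d/2

  D3 <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- upgmaDendrogram(D3)
  cd <- ape::cophenetic.phylo(t3)
  expect_equal(unname(cd["a", "b"]), 1)    # first merge at height 0.5
  expect_equal(unname(cd["a", "c"]), 4)

  set.seed(10)
  X <- matrix(rnorm(40), 10, 4, dimnames = list(paste0("s", 1:10), NULL))
  tu <- upgmaDendrogram(as.matrix(dist(X)))
  expect_true(ape::is.ultrametric(tu, tol = 1e-8))
})
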