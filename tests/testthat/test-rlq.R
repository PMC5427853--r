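test_that("rlqCore matches the dense brute-force oracle on small instances", {
  for (s in 1:5) {
    inst <- smallInstance(s)
    res <- rlqCore(inst$R, inst$L, inst$Q)
    sv <- bruteRLQ(inst$R, inst$L, inst$Q)
    k <- length(eigenvalues(res))
    expect_lt(max(abs(eigenvalues(res) - sv$d[seq_len(k)]^2)), 1e-9)
    expect_equal(res@details$totalCoinertia, sum(sv$d^2), tolerance = 1e-9)
  }
})

test_that("total co-inertia equals the sum of squared fourth-corner statistics", {
  for (s in 1:4) {
    inst <- smallInstance(s + 10)
    res <- rlqCore(inst$R, inst$L, inst$Q)
    stats <- outer(seq_len(ncol(inst$R)), seq_len(ncol(inst$Q)),
                   Vectorize(function(a, b)
                     fourthCornerStat(inst$R[, a], inst$Q[, b], inst$L)))
    expect_equal(res@details$totalCoinertia, sum(stats^2), tolerance = 1e-9)
  }
})

test_that("rlqCore is invariant to orthogonal rotation and degenerate columns", {
  inst <- smallInstance(21)
  res <- rlqCore(inst$R, inst$L, inst$Q)
  set.seed(1)
  O <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  resRot <- rlqCore(inst$R %*% O, inst$L, inst$Q, scaleTables = FALSE)
  resRaw <- rlqCore(inst$R, inst$L, inst$Q, scaleTables = FALSE)
  expect_equal(resRot@details$totalCoinertia, resRaw@details$totalCoinertia,
               tolerance = 1e-9)

  # constant columns vanish after centring: all-constant sides give zero
  Rconst <- matrix(5, 6, 2, dimnames = list(rownames(inst$L), c("c1", "c2")))
  res0 <- rlqCore(Rconst, inst$L, inst$Q)
  expect_lt(max(eigenvalues(res0)), 1e-12)

  expect_error(rlqCore(inst$R[1:3, ], inst$L, inst$Q), "dimension mismatch")
})

test_that("the first axis maximizes co-inertia over random probes", {
  inst <- smallInstance(31)
  res <- rlqCore(inst$R, inst$L, inst$Q)
  ca <- correspondenceAnalysis(inst$L)
  Pm <- inst$L / sum(inst$L)
  r <- ca@rowWeights; cc <- ca@colWeights
  Cross <- crossprod(res@details$R * r,
                     ca@details$L0 %*% (res@details$Q * cc))
  d1sq <- eigenvalues(res)[1]
  set.seed(2)
  for (k in 1:199) {
    a <- rnorm(ncol(Cross) * 0 + nrow(Cross)); a <- a / sqrt(sum(a^2))
    b <- rnorm(ncol(Cross)); b <- b / sqrt(sum(b^2))
    expect_lte(as.numeric(t(a) %*% Cross %*% b)^2, d1sq + 1e-12)
  }
})

test_that("RLQ on CA scores reproduces the CA eigenvalue scaling relations", {
  inst <- smallInstance(41)
  ca <- correspondenceAnalysis(inst$L)
  # standardized scores: RLQ eigenvalues equal CA eigenvalues
  res <- rlqCore(ca@rowScores, inst$L, ca@colScores, scaleTables = TRUE)
  k <- length(eigenvalues(res))
  expect_equal(unname(eigenvalues(res)), unname(eigenvalues(ca)[seq_len(k)]),
               tolerance = 1e-9)
  # principal (unscaled) scores: RLQ eigenvalues equal CA eigenvalues cubed
  resP <- rlqCore(ca@rowScores, inst$L, ca@colScores, scaleTables = FALSE)
  kp <- length(eigenvalues(resP))
  expect_equal(unname(eigenvalues(resP)),
               unname(eigenvalues(ca)[seq_len(kp)]^3), tolerance = 1e-9)
})

test_that("zeroed S and P blocks collapse the extended RLQ to classic RLQ", {
  ds <- makeDataset(seed = 7, filtering = 5, nSpecies = 20,
                    nIndividuals = 600)
  mb <- makeBundle(ds, 10)
  b <- mb$bundle
  nSp <- length(speciesIds(b))
  Szero <- matrix(0, length(siteIds(b)), 2,
                  dimnames = list(siteIds(b), c("z1", "z2")))
  Pzero <- matrix(0, nSp, nSp,
                  dimnames = list(speciesIds(b), speciesIds(b)))
  bz <- new("FiveMatrixBundle", L = abundanceMatrix(b),
            E = envMatrix(b), S = Szero, T = traitDist(b), P = Pzero)
  ext <- extendedRLQ(bz)
  Taxes <- RLQspace:::retainPcoaAxes(pcoaOrdination(traitDist(b)), 0.95)
  # replicate the extended preparation: env columns standardized under the
  # CA row weights, PCoA axes centred only (the block rescaling is a
  # uniform scalar per side and cancels in ratios and correlations)
  ca <- correspondenceAnalysis(abundanceMatrix(b))
  Es <- RLQspace:::wStandardize(envMatrix(b), ca@rowWeights)
  ref <- rlqCore(Es, abundanceMatrix(b), Taxes, scaleTables = FALSE)
  # block rescaling multiplies eigenvalues by a constant; the spectra and
  # axis-1 site scores must agree up to that scale
  evE <- eigenvalues(ext); evR <- eigenvalues(ref)
  k <- min(length(evE), length(evR))
  expect_equal(evE[1:k] / evE[1], evR[1:k] / evR[1], tolerance = 1e-6)
  corr <- cor(siteScores(ext)[, 1],
              ref@siteScores[, 1])
  expect_gt(abs(corr), 1 - 1e-6)
})

test_that("extended RLQ recovers a planted trait-environment filter", {
  hits <- 0
  for (s in 1:5) {
    ds <- makeDataset(seed = s, filtering = 10, nSpecies = 300,
                      nIndividuals = 10000, plotWidth = 200,
                      plotHeight = 100, lambda = 1, nTraits = 4)
    mb <- makeBundle(ds, 10)
    res <- extendedRLQ(mb$bundle)
    a1 <- axisSummary(res, 1, traits = ds@traits[speciesIds(mb$bundle), ],
                      env = envMatrix(mb$bundle))
    ct <- a1$correlations
    rTrait <- ct$r[ct$block == "trait" & ct$variable == "trait01"]
    rEnv <- ct$r[ct$block == "env" & ct$variable == "env01"]
    if (abs(rTrait) > 0.7 && abs(rEnv) > 0.7 && rTrait * rEnv > 0)
      hits <- hits + 1
    # the niche pair tops its block's |r| table
    topTrait <- ct$variable[ct$block == "trait"][
      which.max(abs(ct$r[ct$block == "trait"]))]
    expect_identical(topTrait, "trait01")
  }
  expect_gte(hits, 4)
})

test_that("axis summaries are bounded and sign-symmetric", {
  ds <- makeDataset(seed = 9, filtering = 5, nSpecies = 20,
                    nIndividuals = 600)
  mb <- makeBundle(ds, 10)
  res <- extendedRLQ(mb$bundle)
  a1 <- axisSummary(res, 1)
  expect_true(all(abs(a1$correlations$r) <= 1 + 1e-9))
  expect_true(all(a1$sites$sign %in% c("positive", "negative")))

  # flipping the axis flips all correlations and site-score signs
  flipped <- res
  flipped@siteScores[, 1] <- -flipped@siteScores[, 1]
  flipped@speciesScores[, 1] <- -flipped@speciesScores[, 1]
  flipped@envCor[, 1] <- -flipped@envCor[, 1]
  flipped@spatialCor[, 1] <- -flipped@spatialCor[, 1]
  flipped@traitCor[, 1] <- -flipped@traitCor[, 1]
  flipped@phyloCor[, 1] <- -flipped@phyloCor[, 1]
  a2 <- axisSummary(flipped, 1)
  expect_equal(a2$correlations$r, -a1$correlations$r, tolerance = 1e-12)
  expect_equal(a2$sites$score, -a1$sites$score, tolerance = 1e-12)

  expect_error(axisSummary(res, 99), "exceeds")
})

test_that("neutral data put axis-1 variance inside its permutation envelope", {
  ds <- makeDataset(seed = 13, filtering = 0, nSpecies = 25,
                    nIndividuals = 800)
  mb <- makeBundle(ds, 10)
  b <- mb$bundle
  obs <- pctVariance(extendedRLQ(b))[1]
  set.seed(99)
  nullPct <- vapply(1:99, function(i) {
    L <- abundanceMatrix(b)
    perm <- sample.int(nrow(L))
    Lp <- L[perm, ]
    rownames(Lp) <- rownames(L)
    bp <- new("FiveMatrixBundle", L = Lp, E = envMatrix(b),
              S = spatialMatrix(b), T = traitDist(b), P = phyloDist(b))
    pctVariance(extendedRLQ(bp))[1]
  }, 0)
  expect_lte(obs, max(nullPct))
  expect_gte(obs, min(nullPct))
})
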