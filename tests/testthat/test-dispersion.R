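test_that("abundance-weighted MPD matches the hand double-sum", {
  D2 <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(mpd(c(a = 1, b = 1), D2), 4)
  # only interspecific pairs exist, so weights cancel
  expect_equal(mpd(c(a = 3, b = 1), D2), 4)

  D3 <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  ab <- c(a = 2, b = 1, c = 1)
  f <- ab / sum(ab)
  hand <- sum(outer(f, f) * D3) / (1 - sum(f^2))   # diagonal terms are zero
  expect_equal(mpd(ab, D3), hand)
  expect_equal(mpd(ab, D3), 1.8)

  expect_true(is.na(mpd(c(a = 5, b = 0, c = 0), D3)))

  # the convention excludes conspecific pairs; picante's abundance
  # weighting includes them, so the two agree only at equal frequencies
  samp <- matrix(ab, 1, dimnames = list("q", names(ab)))
  expect_gt(mpd(ab, D3), picante::mpd(samp, D3, abundance.weighted = TRUE))
})

test_that("mpdQuadrats vectorizes mpd over the rows of L", {
  ds <- makeDataset(seed = 2, filtering = 4, nSpecies = 15,
                    nIndividuals = 400)
  p <- partition(ds@stemMap, 10)
  D <- patristicDistance(ds@tree)[colnames(p$L), colnames(p$L)]
  vec <- mpdQuadrats(p$L, D)
  for (i in c(1, 5, 17, 33)) {
    expect_equal(unname(vec[i]), mpd(p$L[i, ], D))
  }
})

test_that("the tip-shuffle null preserves L and degenerates on star trees", {
  ds <- makeDataset(seed = 8, filtering = 0, nSpecies = 12,
                    nIndividuals = 300)
  p <- partition(ds@stemMap, 10)
  keep <- rowSums(p$L) > 0
  L <- p$L[keep, colSums(p$L) > 0]
  D <- patristicDistance(ds@tree)[colnames(L), colnames(L)]

  before <- serialize(L, NULL)
  n1 <- tipShuffleNull(L, D, nIter = 99, seed = 4)
  expect_identical(serialize(L, NULL), before)
  n2 <- tipShuffleNull(L, D, nIter = 99, seed = 4)
  expect_identical(n1, n2)
  expect_error(tipShuffleNull(L, D, nIter = 9), "nIter")

  # star phylogeny: all interspecific distances equal, the shuffle changes
  # nothing, sd_null is 0 and the index is flagged to 0
  Dstar <- matrix(2, ncol(L), ncol(L)) - diag(2, ncol(L))
  dimnames(Dstar) <- dimnames(D)
  tab <- dispersionIndices(L, Dstar, nIter = 99, seed = 5)
  defined <- tab[tab$defined, ]
  expect_true(all(defined$sdNull < 1e-12))
  expect_true(all(defined$index == 0))
  expect_true(all(defined$degenerate))
})

test_that("the index applies the sign-flipped standardization exactly", {
  expect_equal(as.numeric(nri(2, 3, 0.5)), 2)
  expect_equal(as.numeric(nri(3, 3, 0.5)), 0)
  expect_equal(as.numeric(nri(3.5, 3, 0.25)), -2)
  z <- nri(c(1, 2), c(1, 2), c(0, 1))
  expect_identical(attr(z, "degenerate"), c(TRUE, FALSE))
  expect_error(nri(1, 1, -1), "sdNull")
  expect_identical(sesPW, nri)
})

test_that("NRI is invariant under consistent species relabeling and P-as-T", {
  ds <- makeDataset(seed = 12, filtering = 5, nSpecies = 15,
                    nIndividuals = 500, lambda = 1)
  p <- partition(ds@stemMap, 10)
  keep <- rowSums(p$L) > 0
  L <- p$L[keep, colSums(p$L) > 0]
  D <- patristicDistance(ds@tree)[colnames(L), colnames(L)]

  t1 <- dispersionIndices(L, D, nIter = 99, seed = 3)
  set.seed(4)
  perm <- sample(colnames(L))
  t2 <- dispersionIndices(L[, perm], D[perm, perm], nIter = 99, seed = 3)
  expect_equal(t1$obs, t2$obs, tolerance = 1e-12)
  # the label-canonical tip shuffle makes even the Monte Carlo null
  # independent of species storage order
  expect_equal(t1$index, t2$index, tolerance = 1e-10)

  # functional indices computed from the same distances are identical
  expect_identical(dispersionIndices(L, D, nIter = 99, seed = 6),
                   dispersionIndices(L, D, nIter = 99, seed = 6))
})

test_that("axis-side summaries aggregate, test and flag degenerate sides", {
  idx <- data.frame(quadrat = paste0("q", 1:8),
                    index = c(0.5, 0.7, 0.2, 0.9, -0.1, -0.4, -0.6, -0.2),
                    defined = TRUE)
  sc <- setNames(c(1, 2, 1, 3, -1, -2, -1, -3), paste0("q", 1:8))
  s <- axisSideSummary(idx, sc, scale = 20)
  expect_identical(s$side, c("positive", "negative"))
  expect_equal(s$n, c(4, 4))
  expect_equal(s$meanIndex, c(mean(c(0.5, 0.7, 0.2, 0.9)),
                              mean(c(-0.1, -0.4, -0.6, -0.2))))
  tt <- t.test(c(0.5, 0.7, 0.2, 0.9), mu = 0)
  expect_equal(s$p[1], tt$p.value)

  # all-zero indices: mean 0, zero-variance t flagged as NA
  idx0 <- data.frame(quadrat = paste0("q", 1:6), index = 0, defined = TRUE)
  sc0 <- setNames(rep(c(1, -1), each = 3), paste0("q", 1:6))
  s0 <- axisSideSummary(idx0, sc0)
  expect_equal(s0$meanIndex, c(0, 0))
  expect_true(all(is.na(s0$t)))

  # a side with fewer than 3 defined quadrats is reported undefined
  scSkew <- setNames(c(rep(1, 7), -1), paste0("q", 1:8))
  sSkew <- axisSideSummary(idx, scSkew)
  expect_true(is.na(sSkew$p[sSkew$side == "negative"]))
})

test_that("neutral data give unbiased dispersion indices across seeds", {
  # Within one dataset the quadrat indices share the species pool, the
  # tree and the null draws, so the per-dataset t-test is not calibrated
  # against dataset resampling; the unbiasedness that IS guaranteed is
  # that dataset-mean indices centre on zero over independent worlds.
  m <- vapply(1:100, function(sd) {
    ds <- makeDataset(seed = sd + 900, filtering = 0, nSpecies = 15,
                      nIndividuals = 400)
    p <- partition(ds@stemMap, 10)
    keep <- rowSums(p$L) > 0
    L <- p$L[keep, colSums(p$L) > 0]
    D <- patristicDistance(ds@tree)[colnames(L), colnames(L)]
    tab <- dispersionIndices(L, D, nIter = 99, seed = sd)
    mean(tab$index[tab$defined])
  }, 0)
  expect_lt(abs(mean(m)), 3 * sd(m) / sqrt(length(m)) + 0.05)
})
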