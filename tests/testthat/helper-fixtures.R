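# Shared fixture builders; everything is generated in code at test time.

# Small coupled dataset with configurable filtering.
makeDataset <- function(seed = 1, filtering = 0, nSpecies = 30,
                        nIndividuals = 800, plotWidth = 100,
                        plotHeight = 50, lambda = 0.5, nEnvVars = 2,
                        nTraits = 3) {
  simulateDataset(simConfig(plotWidth = plotWidth, plotHeight = plotHeight,
                            nSpecies = nSpecies,
                            nIndividuals = nIndividuals,
                            nEnvVars = nEnvVars, nTraits = nTraits,
                            signalLambda = lambda,
                            filteringStrength = filtering, seed = seed))
}

# Aligned bundle (plus the pieces) at a given scale.
makeBundle <- function(ds, scale = 10) {
  p <- partition(ds@stemMap, scale)
  E <- if (ds@envGrid@scale == scale) ds@envFields
       else aggregateToGrid(ds@envFields, ds@envGrid, p$grid, "mean")
  S <- suppressWarnings(memBasis(p$grid))
  bundle <- alignBundle(p$L, E, S, gowerDistance(ds@traits),
                        patristicDistance(ds@tree))
  list(bundle = bundle, grid = p$grid, L = p$L, E = E, S = S)
}

# Rook (edge-sharing only) adjacency built independently of the package.
rookAdjacency <- function(nx, ny) {
  n <- nx * ny
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ix <- (i - 1) %% nx; iy <- (i - 1) %/% nx
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      jx <- ix + d[1]; jy <- iy + d[2]
      if (jx >= 0 && jx < nx && jy >= 0 && jy < ny)
        A[i, jy * nx + jx + 1] <- 1
    }
  }
  A
}

# Plain (unweighted) Moran's I computed from scratch for oracle use.
moranOracle <- function(v, W) {
  n <- length(v); z <- v - mean(v)
  (n / sum(W)) * sum(z * (W %*% z)) / sum(z * z)
}
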