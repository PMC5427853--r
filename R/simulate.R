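setOldClass("phylo")

#' Synthetic forest-plot dataset with known assembly rules
#'
#' @slot stemMap a \linkS4class{StemMap}.
#' @slot tree ultrametric phylogeny (\code{ape::phylo}) over the species pool.
#' @slot traits species x trait matrix (standardized columns).
#' @slot envGrid the 10-m \linkS4class{QuadratGrid} the environment lives on.
#' @slot envFields quadrat x variable matrix of standardized environmental
#'   fields.
#' @slot truth list recording the generating rules: the niche trait/env pair,
#'   filtering strength, signal lambda and regional abundance probabilities.
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
  representation(stemMap = "StemMap", tree = "phylo", traits = "matrix",
                 envGrid = "QuadratGrid", envFields = "matrix",
                 truth = "list"))

setValidity("SyntheticDataset", function(object) {
  sp <- unique(stems(object@stemMap)$species)
  if (!all(sp %in% object@tree$tip.label))
    return("stem species missing from phylogeny tips")
  if (!all(sp %in% rownames(object@traits)))
    return("stem species missing from trait table")
  TRUE
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset\n")
  show(object@stemMap)
  cat("  tree:", length(object@tree$tip.label), "tips; traits:",
      ncol(object@traits), "; env:", ncol(object@envFields),
      "fields on", nQuadrats(object@envGrid), "quadrats\n")
  cat("  truth: filtering =", object@truth$filteringStrength,
      ", lambda =", object@truth$signalLambda, "\n")
})

#' Simulate a pure-birth ultrametric phylogeny
#'
#' Yule tree with unit speciation rate, rescaled so every root-to-tip path
#' has length 1.  Tips are labelled \code{sp0001..spN}.
#'
#' @param nSpecies number of tips (>= 2).
#' @param seed integer seed (NULL uses the current RNG state).
#' @return an ultrametric \code{ape::phylo} of depth 1.
#' @examples
#' tr <- simulatePhylogeny(20, seed = 1)
#' @export
simulatePhylogeny <- function(nSpecies, seed = NULL) {
  nSpecies <- as.integer(nSpecies)
  if (is.na(nSpecies) || nSpecies < 2L)
    stop("nSpecies must be an integer >= 2")
  tree <- withSeed(seed, ape::rphylo(nSpecies, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  # relabel in the simulator's tip order for stable species ids
  tree$tip.label <- sprintf("sp%04d", seq_len(nSpecies))
  tree
}

#' Simulate traits under Brownian motion with tunable phylogenetic signal
#'
#' Trait values are multivariate normal with covariance given by the shared
#' branch lengths of a Pagel-lambda-transformed tree: off-diagonal elements
#' of the Brownian covariance are multiplied by \code{signalLambda}
#' (lambda = 1 is pure Brownian motion, lambda = 0 gives independent draws).
#' Every trait column is standardized to mean 0, sd 1 across species.
#'
#' @param tree ultrametric phylogeny.
#' @param nTraits number of independent traits.
#' @param signalLambda Pagel's lambda in [0, 1].
#' @param seed integer seed.
#' @return species x trait matrix with rownames = tip labels, columns
#'   \code{trait01..}.
#' @export
simulateTraits <- function(tree, nTraits, signalLambda = 1, seed = NULL) {
  if (signalLambda < 0 || signalLambda > 1)
    stop("signalLambda must lie in [0, 1]")
  if (!ape::is.ultrametric(tree, tol = 1e-6))
    stop("tree must be ultrametric")
  n <- length(tree$tip.label)
  C <- ape::vcv(tree)
  Cl <- signalLambda * C
  diag(Cl) <- diag(C)
  U <- chol(Cl + diag(1e-10, n))
  Z <- withSeed(seed, matrix(rnorm(n * nTraits), n, nTraits))
  X <- crossprod(U, Z)
  X <- apply(X, 2, function(v) (v - mean(v)) / sd(v))
  rownames(X) <- rownames(C)
  colnames(X) <- sprintf("trait%02d", seq_len(nTraits))
  # restore the tree's tip order
  X[tree$tip.label, , drop = FALSE]
}

#' Simulate spatially autocorrelated environmental fields
#'
#' Each field is a Gaussian random field on the 10-m quadrat grid with
#' exponential covariance \eqn{\exp(-d / range)}, standardized to mean 0,
#' sd 1 across quadrats.
#'
#' @param config a \linkS4class{SimConfig}; \code{envRange} is the
#'   autocorrelation range in metres and must be > 0.
#' @param baseScale resolution of the generated grid in metres (default 10;
#'   must divide both plot dimensions).
#' @param seed integer seed (defaults to \code{config@seed}).
#' @return list with the \code{grid} (a \linkS4class{QuadratGrid}) and the
#'   quadrat x variable matrix \code{fields}.
#' @export
simulateEnvironment <- function(config, baseScale = 10, seed = config@seed) {
  stopifnot(is(config, "SimConfig"))
  grid <- quadratGrid(config@plotWidth, config@plotHeight, baseScale)
  xy <- centroids(grid)
  n <- nrow(xy)
  d <- as.matrix(stats::dist(xy))
  Sigma <- exp(-d / config@envRange)
  U <- chol(Sigma + diag(1e-8, n))
  Z <- withSeed(seed,
                matrix(rnorm(n * config@nEnvVars), n, config@nEnvVars))
  Fm <- crossprod(U, Z)
  Fm <- apply(Fm, 2, function(v) (v - mean(v)) / sd(v))
  rownames(Fm) <- rownames(xy)
  colnames(Fm) <- sprintf("env%02d", seq_len(config@nEnvVars))
  list(grid = grid, fields = Fm)
}

# Regional relative abundances from a Fisher log-series: P(k) ~ x^k / k,
# truncated at kMax; heavy dominance typical of tropical plots.
logSeriesAbundances <- function(nSpecies, x = 0.999, kMax = 100000L) {
  k <- seq_len(kMax)
  p <- x^k / k
  counts <- sample(k, nSpecies, replace = TRUE, prob = p)
  counts / sum(counts)
}

#' Assemble a stem map under trait-environment filtering
#'
#' Species identities are drawn from a log-series regional abundance
#' distribution; each stem of species \eqn{s} is placed in quadrat \eqn{q}
#' with probability proportional to
#' \eqn{\exp(-c \, (t_s - e_q)^2)} where \eqn{t} is the first trait,
#' \eqn{e} the first environmental field and \eqn{c} the filtering
#' strength.  \code{filteringStrength = 0} gives uniform random placement.
#'
#' @param traits species x trait matrix (first column is the niche trait).
#' @param env list from \code{\link{simulateEnvironment}}.
#' @param config a \linkS4class{SimConfig}.
#' @param seed integer seed (defaults to \code{config@seed + 1}).
#' @return a \linkS4class{StemMap} with exactly
#'   \code{config@nIndividuals} stems.
#' @export
assembleCommunity <- function(traits, env, config,
                              seed = config@seed + 1L) {
  if (is.null(dim(traits)) || nrow(traits) == 0L)
    stop("empty trait table")
  stopifnot(is(config, "SimConfig"))
  grid <- env$grid
  e1 <- env$fields[, 1]
  t1 <- traits[, 1]
  nSp <- nrow(traits)
  nQ <- nQuadrats(grid)
  withSeed(seed, {
    regional <- logSeriesAbundances(nSp)
    spIdx <- sample.int(nSp, config@nIndividuals, replace = TRUE,
                        prob = regional)
    quad <- integer(config@nIndividuals)
    cs <- config@filteringStrength
    for (s in unique(spIdx)) {
      idx <- which(spIdx == s)
      w <- if (cs == 0) rep(1, nQ) else exp(-cs * (t1[s] - e1)^2)
      quad[idx] <- sample.int(nQ, length(idx), replace = TRUE, prob = w)
    }
    ix <- (quad - 1L) %% grid@nX
    iy <- (quad - 1L) %/% grid@nX
    x <- (ix + runif(length(quad))) * grid@scale
    y <- (iy + runif(length(quad))) * grid@scale
    x <- pmin(x, config@plotWidth - 1e-9)
    y <- pmin(y, config@plotHeight - 1e-9)
    sm <- data.frame(tag = sprintf("stem%06d", seq_along(quad)),
                     species = rownames(traits)[spIdx],
                     x = x, y = y, stringsAsFactors = FALSE)
    attr(sm, "regional") <- regional
    StemMap(sm, config@plotWidth, config@plotHeight)
  })
}

#' Generate a full coupled synthetic dataset
#'
#' Runs phylogeny, trait, environment and community generation with seeds
#' derived from \code{config@seed}, so a config determines the dataset
#' bit-for-bit.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{SyntheticDataset}.
#' @examples
#' ds <- simulateDataset(simConfig(plotWidth = 100, plotHeight = 100,
#'   nSpecies = 20, nIndividuals = 400, nEnvVars = 3, nTraits = 3, seed = 2))
#' @export
simulateDataset <- function(config) {
  stopifnot(is(config, "SimConfig"))
  tree <- simulatePhylogeny(config@nSpecies, seed = config@seed)
  traits <- simulateTraits(tree, config@nTraits, config@signalLambda,
                           seed = config@seed + 1000L)
  env <- simulateEnvironment(config, seed = config@seed + 3000L)
  sm <- assembleCommunity(traits, env, config, seed = config@seed + 2000L)
  truth <- list(nicheTrait = colnames(traits)[1],
                nicheEnv = colnames(env$fields)[1],
                filteringStrength = config@filteringStrength,
                signalLambda = config@signalLambda,
                regionalAbundance = attr(stems(sm), "regional"),
                seed = config@seed)
  new("SyntheticDataset", stemMap = sm, tree = tree, traits = traits,
      envGrid = env$grid, envFields = env$fields, truth = truth)
}
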