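#' @import methods
#' @importFrom stats cor sd var rnorm runif rbinom quantile pt optimize
#'   setNames complete.cases hclust as.dist cophenetic t.test p.adjust
#'   weighted.mean
#' @importFrom utils head read.csv write.csv read.delim write.table
NULL

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Simulation configuration for the synthetic forest-plot generator
#'
#' Holds every tunable of the coupled plot / trait / phylogeny / environment
#' generator.  Distances are metres; \code{signalLambda} is Pagel's lambda in
#' [0, 1]; \code{filteringStrength} is the niche-selectivity coefficient of
#' the Gaussian trait-environment matching kernel (0 = neutral placement).
#'
#' @slot plotWidth,plotHeight plot dimensions in metres.
#' @slot nSpecies number of species in the regional pool.
#' @slot nIndividuals number of stems to place.
#' @slot envRange autocorrelation range (metres) of the exponential-covariance
#'   Gaussian random fields used for the environment.
#' @slot nEnvVars number of environmental variables.
#' @slot nTraits number of quantitative traits.
#' @slot signalLambda phylogenetic signal of traits (Pagel's lambda).
#' @slot filteringStrength niche selectivity (>= 0).
#' @slot seed integer RNG seed.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    plotWidth = "numeric", plotHeight = "numeric",
    nSpecies = "integer", nIndividuals = "integer",
    envRange = "numeric", nEnvVars = "integer", nTraits = "integer",
    signalLambda = "numeric", filteringStrength = "numeric",
    seed = "integer"
  ),
  prototype(
    plotWidth = 500, plotHeight = 400,
    nSpecies = 300L, nIndividuals = 10000L,
    envRange = 50, nEnvVars = 10L, nTraits = 11L,
    signalLambda = 0.5, filteringStrength = 5,
    seed = 1L
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@plotWidth <= 0 || object@plotHeight <= 0)
    msg <- c(msg, "plot dimensions must be positive")
  if (object@nSpecies < 2L) msg <- c(msg, "nSpecies must be >= 2")
  if (object@nIndividuals < 1L) msg <- c(msg, "nIndividuals must be >= 1")
  if (object@envRange <= 0) msg <- c(msg, "envRange must be > 0")
  if (object@signalLambda < 0 || object@signalLambda > 1)
    msg <- c(msg, "signalLambda must lie in [0, 1]")
  if (object@filteringStrength < 0)
    msg <- c(msg, "filteringStrength must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' @param plotWidth,plotHeight plot dimensions in metres (defaults emulate a
#'   rectangular 20-ha plot, 500 x 400 m).
#' @param nSpecies regional species-pool size.
#' @param nIndividuals number of stems.
#' @param envRange environmental autocorrelation range in metres.
#' @param nEnvVars number of environmental fields.
#' @param nTraits number of traits.
#' @param signalLambda Pagel's lambda in [0, 1].
#' @param filteringStrength niche selectivity (>= 0; 0 is neutral).
#' @param seed integer seed.
#' @return a validated \code{SimConfig}.
#' @examples
#' cfg <- simConfig(nSpecies = 50, nIndividuals = 1000, seed = 7)
#' @export
simConfig <- function(plotWidth = 500, plotHeight = 400,
                      nSpecies = 300, nIndividuals = 10000,
                      envRange = 50, nEnvVars = 10, nTraits = 11,
                      signalLambda = 0.5, filteringStrength = 5,
                      seed = 1) {
  new("SimConfig",
    plotWidth = as.numeric(plotWidth), plotHeight = as.numeric(plotHeight),
    nSpecies = as.integer(nSpecies), nIndividuals = as.integer(nIndividuals),
    envRange = as.numeric(envRange), nEnvVars = as.integer(nEnvVars),
    nTraits = as.integer(nTraits),
    signalLambda = as.numeric(signalLambda),
    filteringStrength = as.numeric(filteringStrength),
    seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## StemMap
## ---------------------------------------------------------------------------

#' Stem map: tagged, mapped individuals of a plot census
#'
#' @slot stems data.frame with columns tag, species, x, y.
#' @slot plotWidth,plotHeight plot dimensions in metres.  Coordinates obey the
#'   half-open convention 0 <= x < plotWidth, 0 <= y < plotHeight so that
#'   every stem belongs to exactly one quadrat at every scale.
#' @exportClass StemMap
setClass("StemMap",
  representation(stems = "data.frame",
                 plotWidth = "numeric", plotHeight = "numeric"))

setValidity("StemMap", function(object) {
  s <- object@stems
  msg <- character()
  need <- c("tag", "species", "x", "y")
  if (!all(need %in% names(s)))
    return(paste("stems must have columns", paste(need, collapse = ", ")))
  if (object@plotWidth <= 0 || object@plotHeight <= 0)
    msg <- c(msg, "plot dimensions must be positive")
  if (nrow(s)) {
    if (any(!nzchar(as.character(s$species))))
      msg <- c(msg, "species labels must be non-empty")
    bad <- which(s$x < 0 | s$x >= object@plotWidth |
                 s$y < 0 | s$y >= object@plotHeight)
    if (length(bad))
      msg <- c(msg, paste0("stems outside the half-open plot bounds at rows: ",
                           paste(head(bad, 10), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a StemMap
#'
#' @param stems data.frame with columns tag, species, x, y.
#' @param plotWidth,plotHeight plot dimensions (metres).
#' @return a validated \code{StemMap}.
#' @export
StemMap <- function(stems, plotWidth, plotHeight) {
  stems$species <- as.character(stems$species)
  stems$tag <- as.character(stems$tag)
  if (anyDuplicated(stems$tag))
    warning("duplicated stem tags present; all records kept")
  new("StemMap", stems = stems,
      plotWidth = as.numeric(plotWidth), plotHeight = as.numeric(plotHeight))
}

## ---------------------------------------------------------------------------
## QuadratGrid
## ---------------------------------------------------------------------------

#' Regular quadrat partition of a rectangular plot
#'
#' Quadrat ids are row-major from the plot origin: id = iy * nX + ix + 1
#' with ix = floor(x / scale), iy = floor(y / scale).
#'
#' @slot scale quadrat side in metres.
#' @slot nX,nY number of quadrats along x and y.
#' @slot plotWidth,plotHeight plot dimensions.
#' @exportClass QuadratGrid
setClass("QuadratGrid",
  representation(scale = "numeric", nX = "integer", nY = "integer",
                 plotWidth = "numeric", plotHeight = "numeric"))

setValidity("QuadratGrid", function(object) {
  if (object@nX * object@scale != object@plotWidth)
    return("scale does not divide plotWidth")
  if (object@nY * object@scale != object@plotHeight)
    return("scale does not divide plotHeight")
  TRUE
})

#' Construct a QuadratGrid
#'
#' @param plotWidth,plotHeight plot dimensions (metres).
#' @param scale quadrat side (metres); must divide both dimensions.
#' @return a \code{QuadratGrid}.
#' @examples
#' quadratGrid(500, 400, 20)   # the 500-quadrat partition of a 20-ha plot
#' @export
quadratGrid <- function(plotWidth, plotHeight, scale) {
  nx <- plotWidth / scale
  ny <- plotHeight / scale
  if (abs(nx - round(nx)) > 1e-9)
    stop("scale ", scale, " does not divide plot width ", plotWidth)
  if (abs(ny - round(ny)) > 1e-9)
    stop("scale ", scale, " does not divide plot height ", plotHeight)
  new("QuadratGrid", scale = as.numeric(scale),
      nX = as.integer(round(nx)), nY = as.integer(round(ny)),
      plotWidth = as.numeric(plotWidth), plotHeight = as.numeric(plotHeight))
}

## ---------------------------------------------------------------------------
## FiveMatrixBundle
## ---------------------------------------------------------------------------

#' The aligned five-matrix bundle E, S, T, P linked by L
#'
#' Container for the five tables of the extended RLQ construction: a
#' sites-by-species abundance matrix L, a sites-by-variables environmental
#' matrix E, a sites-by-eigenvector spatial matrix S (Moran eigenvector
#' maps), and species-by-species trait (T) and phylogenetic (P) distance
#' matrices.  Row labels of L, E and S agree; column labels of L agree with
#' the labels of T and P.  L has no all-zero rows or columns.
#'
#' @slot L sites x species non-negative abundance matrix.
#' @slot E sites x env-variables matrix.
#' @slot S sites x spatial-basis matrix.
#' @slot T,P species x species symmetric non-negative distance matrices with
#'   zero diagonal.
#' @exportClass FiveMatrixBundle
setClass("FiveMatrixBundle",
  representation(L = "matrix", E = "matrix", S = "matrix",
                 T = "matrix", P = "matrix"))

setValidity("FiveMatrixBundle", function(object) {
  msg <- character()
  L <- object@L
  if (is.null(rownames(L)) || is.null(colnames(L)))
    return("L must carry row (site) and column (species) labels")
  if (any(L < 0)) msg <- c(msg, "L must be non-negative")
  if (any(rowSums(L) == 0)) msg <- c(msg, "L has all-zero rows")
  if (any(colSums(L) == 0)) msg <- c(msg, "L has all-zero columns")
  for (nm in c("E", "S")) {
    M <- slot(object, nm)
    if (nrow(M) && !identical(rownames(M), rownames(L)))
      msg <- c(msg, paste("row labels of", nm, "differ from L"))
  }
  for (nm in c("T", "P")) {
    D <- slot(object, nm)
    if (!identical(rownames(D), colnames(L)) ||
        !identical(colnames(D), colnames(L)))
      msg <- c(msg, paste("labels of", nm, "differ from species of L"))
    else {
      if (max(abs(D - t(D))) > 1e-8)
        msg <- c(msg, paste(nm, "is not symmetric"))
      if (any(diag(D) != 0)) msg <- c(msg, paste(nm, "has non-zero diagonal"))
      if (any(D < 0)) msg <- c(msg, paste(nm, "has negative entries"))
    }
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## OrdinationResult
## ---------------------------------------------------------------------------

#' Result of a single-table ordination (CA, weighted PCA, PCoA)
#'
#' @slot eigenvalues non-increasing eigenvalues.
#' @slot rowScores,colScores row (site) and column (variable / species)
#'   scores; PCoA carries row scores only.
#' @slot rowWeights,colWeights the weight metrics of the decomposition.
#' @slot totalInertia sum of the eigenvalues (chi-square / grand total for
#'   CA; number of variables for standardized PCA).
#' @slot method one of "CA", "PCA", "PCoA".
#' @slot details method-specific extras (e.g. the Cailliez correction flag
#'   and constant for PCoA, the CA-standardized table for RLQ).
#' @exportClass OrdinationResult
setClass("OrdinationResult",
  representation(eigenvalues = "numeric",
                 rowScores = "matrix", colScores = "matrix",
                 rowWeights = "numeric", colWeights = "numeric",
                 totalInertia = "numeric", method = "character",
                 details = "list"))

## ---------------------------------------------------------------------------
## RLQResult
## ---------------------------------------------------------------------------

#' Result of an RLQ / extended RLQ co-inertia analysis
#'
#' @slot eigenvalues squared singular values of the weighted cross-covariance
#'   (co-inertia per axis), non-increasing.
#' @slot pctVariance eigenvalue_k / sum(eigenvalues).
#' @slot siteScores,speciesScores per-quadrat and per-species axis
#'   coordinates.
#' @slot envCor,spatialCor,traitCor,phyloCor weighted Pearson correlations of
#'   every original variable of each block with each RLQ axis (the axis
#'   interpretation surface); empty matrices when a block was absent.
#' @slot details weights, block composition, singular vectors.
#' @exportClass RLQResult
setClass("RLQResult",
  representation(eigenvalues = "numeric", pctVariance = "numeric",
                 siteScores = "matrix", speciesScores = "matrix",
                 envCor = "matrix", spatialCor = "matrix",
                 traitCor = "matrix", phyloCor = "matrix",
                 details = "list"))

setValidity("RLQResult", function(object) {
  ev <- object@eigenvalues
  if (length(ev) && any(diff(ev) > 1e-8)) return("eigenvalues must be non-increasing")
  if (length(ev) && any(ev < -1e-8)) return("eigenvalues must be >= 0")
  if (length(object@pctVariance) && sum(object@eigenvalues) > 1e-12 &&
      abs(sum(object@pctVariance) - 1) > 1e-6)
    return("pctVariance must sum to 1")
  TRUE
})
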