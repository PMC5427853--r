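#' Accessors for the package's S4 containers
#'
#' Slot access goes through these accessors everywhere; the slots themselves
#' are an implementation detail.
#'
#' @return the requested component: matrices for the bundle accessors, a
#'   data.frame of stems, numeric vectors for ids/weights/eigenvalues.
#' @name accessors
NULL

#' @rdname accessors
setMethod("abundanceMatrix", "FiveMatrixBundle", function(x) x@L)
#' @rdname accessors
setMethod("envMatrix", "FiveMatrixBundle", function(x) x@E)
#' @rdname accessors
setMethod("spatialMatrix", "FiveMatrixBundle", function(x) x@S)
#' @rdname accessors
setMethod("traitDist", "FiveMatrixBundle", function(x) x@T)
#' @rdname accessors
setMethod("phyloDist", "FiveMatrixBundle", function(x) x@P)
#' @rdname accessors
setMethod("siteIds", "FiveMatrixBundle", function(x) rownames(x@L))
#' @rdname accessors
setMethod("speciesIds", "FiveMatrixBundle", function(x) colnames(x@L))

#' @rdname accessors
setMethod("stems", "StemMap", function(x) x@stems)
#' @rdname accessors
setMethod("plotDim", "StemMap",
          function(x) c(width = x@plotWidth, height = x@plotHeight))

#' @rdname accessors
setMethod("nQuadrats", "QuadratGrid", function(x) x@nX * x@nY)
#' @rdname accessors
setMethod("quadratIds", "QuadratGrid", function(x) {
  sprintf("q%05d", seq_len(x@nX * x@nY))
})
#' @rdname accessors
setMethod("centroids", "QuadratGrid", function(x) {
  ix <- rep(seq_len(x@nX) - 1L, times = x@nY)
  iy <- rep(seq_len(x@nY) - 1L, each = x@nX)
  m <- cbind(x = (ix + 0.5) * x@scale, y = (iy + 0.5) * x@scale)
  rownames(m) <- quadratIds(x)
  m
})

#' @rdname accessors
setMethod("eigenvalues", "OrdinationResult", function(x) x@eigenvalues)
#' @rdname accessors
setMethod("eigenvalues", "RLQResult", function(x) x@eigenvalues)
#' @rdname accessors
setMethod("siteScores", "RLQResult", function(x) x@siteScores)
#' @rdname accessors
setMethod("speciesScores", "RLQResult", function(x) x@speciesScores)
#' @rdname accessors
setMethod("pctVariance", "RLQResult", function(x) x@pctVariance)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@plotWidth, "x", object@plotHeight, "m plot;",
      object@nSpecies, "species,", object@nIndividuals, "stems\n")
  cat("  env: ", object@nEnvVars, " fields, range ", object@envRange,
      " m; traits: ", object@nTraits, " (lambda = ", object@signalLambda,
      "); filtering = ", object@filteringStrength,
      "; seed = ", object@seed, "\n", sep = "")
})

setMethod("show", "StemMap", function(object) {
  cat("StemMap:", nrow(object@stems), "stems of",
      length(unique(object@stems$species)), "species on a",
      object@plotWidth, "x", object@plotHeight, "m plot\n")
})

setMethod("show", "QuadratGrid", function(object) {
  cat("QuadratGrid: ", object@nX, " x ", object@nY, " quadrats of ",
      object@scale, " m (n = ", object@nX * object@nY, ")\n", sep = "")
})

setMethod("show", "FiveMatrixBundle", function(object) {
  cat("FiveMatrixBundle:", nrow(object@L), "sites x", ncol(object@L),
      "species (", sum(object@L), "individuals )\n")
  cat("  E:", ncol(object@E), "env variables; S:", ncol(object@S),
      "spatial eigenvectors; T, P:", ncol(object@T), "x", ncol(object@T),
      "distances\n")
})

setMethod("show", "OrdinationResult", function(object) {
  ev <- object@eigenvalues
  cat(object@method, "ordination:", length(ev), "axes, total inertia",
      signif(object@totalInertia, 5), "\n")
  cat("  leading eigenvalues:",
      paste(signif(head(ev, 4), 4), collapse = ", "), "\n")
})

setMethod("show", "RLQResult", function(object) {
  cat("RLQ co-inertia:", length(object@eigenvalues), "axes\n")
  cat("  eigenvalues:",
      paste(signif(head(object@eigenvalues, 4), 4), collapse = ", "), "\n")
  cat("  % variance: ",
      paste(sprintf("%.2f", 100 * head(object@pctVariance, 4)),
            collapse = ", "), "\n", sep = "")
})
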