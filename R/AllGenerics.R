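#' @rdname accessors
#' @param x an object of one of the package's classes.
#' @export
setGeneric("abundanceMatrix", function(x) standardGeneric("abundanceMatrix"))

#' @rdname accessors
#' @export
setGeneric("envMatrix", function(x) standardGeneric("envMatrix"))

#' @rdname accessors
#' @export
setGeneric("spatialMatrix", function(x) standardGeneric("spatialMatrix"))

#' @rdname accessors
#' @export
setGeneric("traitDist", function(x) standardGeneric("traitDist"))

#' @rdname accessors
#' @export
setGeneric("phyloDist", function(x) standardGeneric("phyloDist"))

#' @rdname accessors
#' @export
setGeneric("siteIds", function(x) standardGeneric("siteIds"))

#' @rdname accessors
#' @export
setGeneric("speciesIds", function(x) standardGeneric("speciesIds"))

#' @rdname accessors
#' @export
setGeneric("stems", function(x) standardGeneric("stems"))

#' @rdname accessors
#' @export
setGeneric("plotDim", function(x) standardGeneric("plotDim"))

#' @rdname accessors
#' @export
setGeneric("nQuadrats", function(x) standardGeneric("nQuadrats"))

#' @rdname accessors
#' @export
setGeneric("quadratIds", function(x) standardGeneric("quadratIds"))

#' @rdname accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname accessors
#' @export
setGeneric("siteScores", function(x) standardGeneric("siteScores"))

#' @rdname accessors
#' @export
setGeneric("speciesScores", function(x) standardGeneric("speciesScores"))

#' @rdname accessors
#' @export
setGeneric("pctVariance", function(x) standardGeneric("pctVariance"))
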