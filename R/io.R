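#' Read a stem map from a tab-separated file
#'
#' Expects a header line and columns \code{tag}, \code{species}, \code{x},
#' \code{y}.  Coordinates follow the half-open convention: a stem with
#' \code{x == plotWidth} (or \code{y == plotHeight}) is out of bounds.
#' Malformed and out-of-bounds rows are reported with their line numbers.
#'
#' @param path file path.
#' @param plotWidth,plotHeight plot dimensions in metres.
#' @return a validated \linkS4class{StemMap}.
#' @seealso \code{\link{writeStemMap}}
#' @export
readStemMap <- function(path, plotWidth, plotHeight) {
  if (!file.exists(path)) stop("stem-map file not found: ", path)
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("tag", "species", "x", "y")
  if (!all(need %in% names(d)))
    stop("stem-map header must contain: ", paste(need, collapse = ", "))
  x <- suppressWarnings(as.numeric(d$x))
  y <- suppressWarnings(as.numeric(d$y))
  bad <- which(is.na(x) | is.na(y))
  if (length(bad))
    stop("unparseable coordinates at line(s): ",
         paste(bad + 1L, collapse = ", "))   # +1 for the header
  oob <- which(x < 0 | x >= plotWidth | y < 0 | y >= plotHeight)
  if (length(oob))
    stop("stems outside the half-open plot bounds at line(s): ",
         paste(oob + 1L, collapse = ", "))
  d$x <- x; d$y <- y
  StemMap(d[need], plotWidth, plotHeight)
}

#' Write a stem map as tab-separated text
#'
#' @param stemMap a \linkS4class{StemMap}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeStemMap <- function(stemMap, path) {
  write.table(stems(stemMap)[c("tag", "species", "x", "y")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a labelled numeric matrix as CSV
#'
#' First column holds row labels; remaining columns are numeric.  Values
#' round-trip at full double precision.
#'
#' @param x numeric matrix with dimnames.
#' @param path file path.
#' @return \code{readMatrixCSV}: the matrix; \code{writeMatrixCSV}: the
#'   path, invisibly.
#' @export
writeMatrixCSV <- function(x, path) {
  d <- data.frame(id = rownames(x),
                  format(as.data.frame(x), digits = 17, trim = TRUE,
                         scientific = FALSE),
                  check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeMatrixCSV
#' @export
readMatrixCSV <- function(path) {
  d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- d[[1]]
  m
}

#' Write a JSON run-metadata sidecar
#'
#' Records the configuration, seed and package version next to a result
#' table, so every output is traceable to its inputs.
#'
#' @param path sidecar path (conventionally \code{<table>.meta.json}).
#' @param config named list of configuration values.
#' @param seed integer seed.
#' @param extra optional named list appended verbatim.
#' @return the path, invisibly.
#' @export
writeRunMetadata <- function(path, config = list(), seed = NA, extra = list()) {
  meta <- c(list(
    package = "RLQspace",
    version = as.character(utils::packageVersion("RLQspace")),
    rversion = as.character(getRversion()),
    seed = seed, config = config), extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Align the five matrices of the extended RLQ construction
#'
#' Restricts every table to the intersection of site and species labels,
#' orders all of them consistently with L, drops species absent from every
#' site (and then sites left empty), and returns a validated
#' \linkS4class{FiveMatrixBundle}.  Alignment is idempotent.
#'
#' @param L sites x species abundance matrix (labelled).
#' @param E sites x env-variables matrix.
#' @param S sites x spatial-basis matrix.
#' @param T,P species x species distance matrices (symmetric, zero
#'   diagonal).
#' @return a \linkS4class{FiveMatrixBundle}.
#' @export
alignBundle <- function(L, E, S, T, P) {
  L <- as.matrix(L); E <- as.matrix(E); S <- as.matrix(S)
  T <- checkDistanceMatrix(as.matrix(T), "T")
  P <- checkDistanceMatrix(as.matrix(P), "P")
  sites <- Reduce(intersect, list(rownames(L), rownames(E), rownames(S)))
  sp <- Reduce(intersect, list(colnames(L), rownames(T), rownames(P)))
  if (!length(sites)) stop("no common site labels between L, E and S")
  if (!length(sp)) stop("no common species labels between L, T and P")
  L <- L[sites, sp, drop = FALSE]
  # drop empty species, then empty sites, then re-check species
  repeat {
    keepSp <- colSums(L) > 0
    keepSite <- rowSums(L) > 0
    if (all(keepSp) && all(keepSite)) break
    L <- L[keepSite, keepSp, drop = FALSE]
  }
  if (!nrow(L) || !ncol(L)) stop("alignment left an empty L matrix")
  sites <- rownames(L); sp <- colnames(L)
  new("FiveMatrixBundle",
      L = L,
      E = E[sites, , drop = FALSE],
      S = S[sites, , drop = FALSE],
      T = T[sp, sp, drop = FALSE],
      P = P[sp, sp, drop = FALSE])
}
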