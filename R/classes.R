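## Central S4 containers. Grids are stored as plain numeric matrices with
## row 1 at the top of the raster (file order); coordinates are 1-based
## (row, col) pairs throughout.

#' ResistanceSurface: a cost-of-movement raster
#'
#' A rectangular grid of strictly positive, finite resistance values
#' (dimensionless cost per unit distance). Row 1 is the top of the
#' raster; coordinates are 1-based \code{(row, col)}.
#'
#' @slot values numeric matrix of resistances.
#' @seealso [resistanceSurface()], [generateSurfaceSuite()]
#' @export
setClass("ResistanceSurface", representation(values = "matrix"))

setValidity("ResistanceSurface", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (nrow(v) < 1L || ncol(v) < 1L) return("empty grid")
  if (any(!is.finite(v))) return("all resistances must be finite")
  if (any(v <= 0)) return("all resistances must be strictly positive")
  TRUE
})

#' DensitySurface: aggregated per-pixel visitation counts
#'
#' The "true" connectivity surface: the number of times each pixel was
#' visited across a collection of simulated movement paths (repeated
#' visits by one path count multiply).
#'
#' @slot counts numeric matrix of non-negative visit counts.
#' @slot nPaths number of paths aggregated.
#' @seealso [simulateDensity()]
#' @export
setClass("DensitySurface", representation(counts = "matrix", nPaths = "integer"))

setValidity("DensitySurface", function(object) {
  v <- object@counts
  if (any(!is.finite(v)) || any(v < 0)) return("counts must be finite and non-negative")
  if (any(v != round(v))) return("counts must be integral")
  TRUE
})

#' ConnPrediction: a connectivity model's output surface
#'
#' Per-pixel prediction of one connectivity model: least-cost-path
#' counts (\code{"flcp"}), summed kernel values (\code{"kernels"}) or
#' current density (\code{"circuit"}).
#'
#' @slot values numeric matrix, non-negative and finite.
#' @slot modelTag one of \code{"flcp"}, \code{"kernels"}, \code{"circuit"}.
#' @seealso [factorialLCP()], [resistantKernels()], [circuitCurrent()]
#' @export
setClass("ConnPrediction", representation(values = "matrix", modelTag = "character"))

setValidity("ConnPrediction", function(object) {
  v <- object@values
  if (any(!is.finite(v)) || any(v < 0)) return("prediction values must be finite and non-negative")
  if (!(object@modelTag %in% c("flcp", "kernels", "circuit")))
    return("modelTag must be one of 'flcp', 'kernels', 'circuit'")
  TRUE
})

#' Construct a ResistanceSurface
#'
#' @param values numeric matrix of strictly positive, finite resistances.
#' @return a [ResistanceSurface-class] object.
#' @examples
#' resistanceSurface(matrix(1, 8, 8))
#' @export
resistanceSurface <- function(values) {
  new("ResistanceSurface", values = as.matrix(values))
}

#' Construct a DensitySurface
#'
#' @param counts numeric matrix of non-negative integer visit counts.
#' @param nPaths number of paths aggregated into the counts.
#' @return a [DensitySurface-class] object.
#' @export
densitySurface <- function(counts, nPaths = NA_integer_) {
  new("DensitySurface", counts = as.matrix(counts), nPaths = as.integer(nPaths))
}

#' Extract the value grid of a surface object
#'
#' Returns the underlying numeric matrix of a [ResistanceSurface-class],
#' [DensitySurface-class] or [ConnPrediction-class] (row 1 = top of
#' raster). Plain matrices pass through unchanged.
#'
#' @param x a surface object or matrix.
#' @return numeric matrix.
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname gridValues
#' @export
setMethod("gridValues", "ResistanceSurface", function(x) x@values)
#' @rdname gridValues
#' @export
setMethod("gridValues", "DensitySurface", function(x) x@counts)
#' @rdname gridValues
#' @export
setMethod("gridValues", "ConnPrediction", function(x) x@values)
#' @rdname gridValues
#' @export
setMethod("gridValues", "matrix", function(x) x)

#' @describeIn gridValues model tag of a prediction.
#' @export
setGeneric("modelTag", function(x) standardGeneric("modelTag"))
#' @rdname gridValues
#' @export
setMethod("modelTag", "ConnPrediction", function(x) x@modelTag)

#' @export
setMethod("dim", "ResistanceSurface", function(x) dim(x@values))
#' @export
setMethod("dim", "DensitySurface", function(x) dim(x@counts))
#' @export
setMethod("dim", "ConnPrediction", function(x) dim(x@values))

.showGrid <- function(what, v, extra = "") {
  cat(sprintf("%s: %d x %d pixels%s\n", what, nrow(v), ncol(v), extra))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n", min(v), max(v), mean(v)))
}

setMethod("show", "ResistanceSurface", function(object) {
  .showGrid("ResistanceSurface", object@values)
})
setMethod("show", "DensitySurface", function(object) {
  np <- if (is.na(object@nPaths)) "" else sprintf(" (%d paths)", object@nPaths)
  .showGrid("DensitySurface", object@counts, np)
})
setMethod("show", "ConnPrediction", function(object) {
  .showGrid(sprintf("ConnPrediction [%s]", object@modelTag), object@values)
})

#' Display a surface object as an image
#'
#' @param x a surface object.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @export
setMethod("image", "ResistanceSurface", function(x, main = "resistance", ...) {
  .imageGrid(x@values, main = main, ...)
})
#' @rdname image-ResistanceSurface-method
#' @export
setMethod("image", "DensitySurface", function(x, main = "movement density", ...) {
  .imageGrid(x@counts, main = main, ...)
})
#' @rdname image-ResistanceSurface-method
#' @export
setMethod("image", "ConnPrediction", function(x, main = x@modelTag, ...) {
  .imageGrid(x@values, main = main, ...)
})

## matrices are stored row 1 = top; image() draws x along rows, so
## transpose and flip to render in map orientation
.imageGrid <- function(m, main, col = hcl.colors(64, "viridis"), ...) {
  image(t(m[nrow(m):1, , drop = FALSE]), main = main, col = col,
        axes = FALSE, asp = nrow(m) / ncol(m), ...)
  invisible(NULL)
}

## internal coercion helper: accept objects or bare matrices
.asGrid <- function(x) {
  if (is.matrix(x)) x else gridValues(x)
}

## validate a (row, col) source matrix against grid dims
.checkSources <- function(sources, nr, nc) {
  sources <- as.matrix(sources)
  if (length(sources) == 0L || nrow(sources) < 1L)
    stop("at least one source point is required")
  if (ncol(sources) != 2L)
    stop("sources must be a two-column (row, col) matrix")
  if (any(sources < 1L) || any(sources[, 1L] > nr) || any(sources[, 2L] > nc))
    stop("source coordinates out of grid bounds")
  storage.mode(sources) <- "integer"
  sources
}
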