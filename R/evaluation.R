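## Scoring one model prediction against one simulated density surface.

#' Min-max rescale a grid to [0, 1]
#'
#' Both surfaces are rescaled this way before comparison, making the
#' accuracy statistics invariant to each model's arbitrary output scale
#' (visit counts, kernel sums, current). A constant grid maps to all
#' zeros.
#'
#' @param x a surface object or numeric matrix.
#' @return numeric matrix with values in \code{[0, 1]}.
#' @examples
#' normalize01(matrix(c(0, 5, 10, 10), 2))
#' @export
normalize01 <- function(x) {
  m <- .asGrid(x)
  if (any(!is.finite(m))) stop("surface must be finite")
  rng <- range(m)
  if (rng[1L] == rng[2L]) return(matrix(0, nrow(m), ncol(m)))
  (m - rng[1L]) / (rng[2L] - rng[1L])
}

#' Accuracy statistics between a true and a predicted surface
#'
#' Both surfaces are min-max normalised, then three statistics are
#' computed: the per-pixel root-mean-squared error (bounded in
#' \code{[0, 1]}), the Pearson linear correlation over all pixels, and
#' the spatial overlap of the top-q fraction of highest-valued pixels
#' (\code{|topK(truth) intersect topK(pred)| / K} with
#' \code{K = floor(q N)}; ties broken deterministically by pixel
#' index).
#'
#' @param truth a [DensitySurface-class], matrix, or other surface.
#' @param pred a [ConnPrediction-class], matrix, or other surface of
#'   the same dimensions.
#' @param q top fraction for the overlap statistic (default 0.1, the
#'   areas of 10 percent highest connectivity).
#' @return named numeric vector \code{c(rmse, pearson, overlap)}.
#' @examples
#' compareSurfaces(matrix(c(1, 0, 0, 0), 2), matrix(c(0, 1, 0, 0), 2), q = 0.25)
#' @export
compareSurfaces <- function(truth, pred, q = 0.1) {
  a <- .asGrid(truth); b <- .asGrid(pred)
  if (!identical(dim(a), dim(b)))
    stop("truth and prediction dimensions differ")
  if (q <= 0 || q >= 1) stop("q must lie strictly between 0 and 1")
  an <- as.vector(normalize01(a))
  bn <- as.vector(normalize01(b))
  rmse <- sqrt(mean((an - bn)^2))
  pearson <- if (sd(an) == 0 || sd(bn) == 0) NA_real_ else cor(an, bn)
  K <- max(1L, floor(q * length(an)))
  topA <- order(-an, seq_along(an))[seq_len(K)]
  topB <- order(-bn, seq_along(bn))[seq_len(K)]
  overlap <- length(intersect(topA, topB)) / K
  c(rmse = rmse, pearson = pearson, overlap = overlap)
}
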