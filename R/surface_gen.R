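## Synthetic resistance surfaces of graded spatial complexity, and
## uniform random source points.

#' Generate a suite of resistance surfaces of increasing complexity
#'
#' Builds \code{nSurfaces} resistance landscapes on a common grid,
#' forming a complexity ladder. The first surface is a uniform
#' background (resistance 1) crossed by three straight high-resistance
#' barriers (resistance 100), each pierced by a 3-pixel traversable gap,
#' so any two background pixels remain connected by a finite-cost path.
#' Subsequent surfaces are spatially autocorrelated Gaussian random
#' fields synthesised spectrally with a power-law spectrum whose
#' exponent decreases along the suite (progressively more
#' high-frequency detail, i.e. shorter correlation range), rank-mapped
#' to \code{[1, 100]} and quantised to a number of resistance levels
#' that doubles at each step. Both the histogram entropy and the mean
#' absolute neighbour difference of the surfaces are therefore
#' non-decreasing along the suite, for any seed.
#'
#' @param nrows,ncols grid dimensions (at least 8).
#' @param nSurfaces number of surfaces (>= 1); the default experiment
#'   uses 7.
#' @param seed integer seed; the suite is bit-reproducible for fixed
#'   arguments.
#' @return a list of [ResistanceSurface-class] objects, ordered from
#'   simplest to most complex.
#' @examples
#' suite <- generateSurfaceSuite(64, 64, 7, seed = 42)
#' range(gridValues(suite[[3]]))
#' @export
generateSurfaceSuite <- function(nrows, ncols, nSurfaces = 7L, seed = 1L) {
  if (!is.numeric(nrows) || !is.numeric(ncols) || nrows < 8 || ncols < 8)
    stop("nrows and ncols must be at least 8")
  if (nSurfaces < 1) stop("nSurfaces must be >= 1")
  nrows <- as.integer(nrows); ncols <- as.integer(ncols)
  out <- vector("list", nSurfaces)
  out[[1L]] <- .barrierSurface(nrows, ncols)
  if (nSurfaces > 1L) {
    k <- nSurfaces - 1L
    ## spectral exponents: steep (smooth) -> shallow (rough). One white
    ## noise realisation is shared by the whole suite so that roughness
    ## increases deterministically along the ladder.
    beta <- if (k == 1L) 1.6 else seq(2.2, 1.0, length.out = k)
    levels <- pmin(6L * 2L^(seq_len(k) - 1L), nrows * ncols)
    levels[k] <- nrows * ncols  # last surface: continuous rank spread
    set.seed(seed %% 2147483629)
    noiseFT <- fft(matrix(rnorm(nrows * ncols), nrows, ncols))
    for (i in seq_len(k)) {
      field <- .spectralField(noiseFT, beta[i])
      out[[i + 1L]] <- resistanceSurface(.rankRescale(field, levels[i]))
    }
  }
  out
}

## Uniform background with three straight vertical barriers, each with a
## 3-pixel gap at a different height. Exactly two distinct values.
.barrierSurface <- function(nrows, ncols, lo = 1, hi = 100) {
  m <- matrix(lo, nrows, ncols)
  cols <- round(ncols * c(0.25, 0.5, 0.75))
  gaps <- round(nrows * c(0.7, 0.3, 0.55))
  for (b in seq_along(cols)) {
    m[, cols[b]] <- hi
    gap <- max(1L, gaps[b] - 1L):min(nrows, gaps[b] + 1L)
    m[gap, cols[b]] <- lo
  }
  resistanceSurface(m)
}

## Gaussian random field by spectral synthesis: the Fourier transform of
## a white noise field, filtered so the power spectrum falls off as
## f^-beta, then transformed back.
.spectralField <- function(noiseFT, beta) {
  nr <- nrow(noiseFT); nc <- ncol(noiseFT)
  fr <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fc <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  f <- sqrt(outer(fr^2, fc^2, `+`))
  amp <- f^(-beta / 2)
  amp[1L, 1L] <- 0  # drop the mean component
  Re(fft(noiseFT * amp, inverse = TRUE)) / (nr * nc)
}

## Map values to [1, 100] through their ranks, quantised to `levels`
## equally spaced resistance values with (near-)equal pixel counts per
## level. With levels = N this is a continuous rank spread.
.rankRescale <- function(x, levels, lo = 1, hi = 100) {
  n <- length(x)
  r <- rank(x, ties.method = "first")
  if (levels >= n) {
    v <- lo + (hi - lo) * (r - 0.5) / n
  } else {
    lev <- ceiling(r * levels / n)
    v <- lo + (hi - lo) * (lev - 0.5) / levels
  }
  matrix(v, nrow(x), ncol(x))
}

#' Sample uniform random source points on a grid
#'
#' Draws \code{n} unique pixel coordinates uniformly (without
#' replacement) over the full grid.
#'
#' @param n number of points; must not exceed \code{nrows * ncols}.
#' @param nrows,ncols grid dimensions.
#' @param seed integer seed.
#' @return an integer matrix with columns \code{row}, \code{col}
#'   (1-based, row 1 = top of raster).
#' @examples
#' sampleSources(100, 256, 256, seed = 1)[1:3, ]
#' @export
sampleSources <- function(n, nrows, ncols, seed = 1L) {
  if (n < 1 || n > nrows * ncols)
    stop("n must be between 1 and nrows * ncols")
  set.seed(seed %% 2147483629)
  idx <- sample.int(nrows * ncols, n)
  cbind(row = as.integer((idx - 1L) %% nrows + 1L),
        col = as.integer((idx - 1L) %/% nrows + 1L))
}

#' Complexity summaries of a resistance surface
#'
#' Histogram Shannon entropy (over \code{bins} equal-width bins spanning
#' \code{[1, 100]}) and mean absolute difference between horizontally and
#' vertically adjacent pixels. Used to verify the complexity ladder of
#' [generateSurfaceSuite()].
#'
#' @param surface a [ResistanceSurface-class] or matrix.
#' @param bins number of histogram bins.
#' @return named numeric vector with elements \code{entropy} and
#'   \code{neighbourDiff}.
#' @export
surfaceComplexity <- function(surface, bins = 32L) {
  v <- .asGrid(surface)
  breaks <- seq(min(1, min(v)), max(100, max(v)), length.out = bins + 1L)
  p <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = bins)
  p <- p / sum(p)
  p <- p[p > 0]
  dh <- abs(v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])
  dv <- abs(v[, -1, drop = FALSE] - v[, -ncol(v), drop = FALSE])
  c(entropy = -sum(p * log(p)),
    neighbourDiff = (sum(dh) + sum(dv)) / (length(dh) + length(dv)))
}
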