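#' Multi-scale perception: focal-window rescaling of a surface
#'
#' Replaces each pixel by the mean, maximum or minimum of the n-by-n
#' window centred on it, truncating the window at the grid edges. This
#' models an organism responding to the landscape at a spatial scale
#' coarser than single pixels. \code{n = 1} returns the input
#' unchanged.
#'
#' @param surface a [ResistanceSurface-class] or numeric matrix.
#' @param n odd positive window edge length (pixels).
#' @param fn one of \code{"mean"}, \code{"max"}, \code{"min"}.
#' @return an object of the same kind as the input.
#' @examples
#' m <- matrix(1, 3, 3); m[2, 2] <- 10
#' gridValues(focalScale(resistanceSurface(m), 3, "max"))
#' @export
focalScale <- function(surface, n = 1L, fn = c("mean", "max", "min")) {
  fn <- match.arg(fn)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n %% 2 != 1)
    stop("focal window size n must be a positive odd integer")
  n <- as.integer(n)
  m <- .asGrid(surface)
  if (n == 1L) return(surface)
  res <- .focalApply(m, n, fn)
  if (is(surface, "ResistanceSurface")) resistanceSurface(res) else res
}

## Accumulate shifted copies of the matrix over all window offsets;
## truncation at the edges falls out of the index clipping.
.focalApply <- function(m, n, fn) {
  nr <- nrow(m); nc <- ncol(m)
  h <- (n - 1L) %/% 2L
  acc <- NULL
  cnt <- if (fn == "mean") matrix(0, nr, nc) else NULL
  ## offsets: value at (r, c) aggregates m[r + dr, c + dc] for in-bounds shifts
  for (dr in -h:h) {
    srcR <- seq_len(nr) + dr
    okR <- srcR >= 1L & srcR <= nr
    for (dc in -h:h) {
      srcC <- seq_len(nc) + dc
      okC <- srcC >= 1L & srcC <= nc
      sub <- m[srcR[okR], srcC[okC], drop = FALSE]
      if (fn == "mean") {
        if (is.null(acc)) acc <- matrix(0, nr, nc)
        acc[okR, okC] <- acc[okR, okC] + sub
        cnt[okR, okC] <- cnt[okR, okC] + 1
      } else {
        if (is.null(acc)) {
          acc <- matrix(if (fn == "max") -Inf else Inf, nr, nc)
        }
        acc[okR, okC] <- if (fn == "max") pmax(acc[okR, okC], sub)
                         else pmin(acc[okR, okC], sub)
      }
    }
  }
  if (fn == "mean") acc / cnt else acc
}
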