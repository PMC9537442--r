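## Resistance-based connectivity predictors. All three share the
## walker's discretisation: 8-connected pixel graph with edge weight
## len(i, j) * (r_i + r_j) / 2, len = sqrt(2) on diagonals, so that
## energy budgets, dispersal thresholds and cost distances are
## commensurable across the truth and the predictions.

## node index convention for the compiled Dijkstra: 0-based row-major,
## idx = (row - 1) * ncol + (col - 1)
.nodeIndex <- function(sources, nc) {
  (sources[, 1L] - 1L) * nc + (sources[, 2L] - 1L)
}

#' Accumulated cost distance from a source set
#'
#' Minimum accumulated movement cost from the nearest source to every
#' pixel (multi-source shortest path on the 8-connected cost graph);
#' zero at every source.
#'
#' @param surface a [ResistanceSurface-class] or matrix.
#' @param sources integer matrix of \code{(row, col)} source pixels.
#' @return numeric matrix of accumulated costs.
#' @examples
#' costDistance(matrix(1, 5, 5), cbind(1, 1))[1, 4]  # 3 cardinal steps
#' @export
costDistance <- function(surface, sources) {
  m <- .asGrid(surface)
  sources <- .checkSources(sources, nrow(m), ncol(m))
  .cpp_grid_dijkstra(m, .nodeIndex(sources, ncol(m)))$dist
}

#' Factorial least-cost paths
#'
#' Extracts one minimum-cost path for every unordered pair of sources
#' (predecessor tie-breaking is deterministic, following the fixed
#' neighbour order) and counts, for each pixel, how many of those
#' pairwise paths pass through it.
#'
#' @inheritParams costDistance
#' @return a [ConnPrediction-class] with tag \code{"flcp"}.
#' @export
factorialLCP <- function(surface, sources) {
  m <- .asGrid(surface)
  nr <- nrow(m); nc <- ncol(m)
  sources <- .checkSources(sources, nr, nc)
  k <- nrow(sources)
  if (k < 2L) stop("factorial least-cost paths require at least 2 sources")
  ## sort the source list so the output is invariant to input order
  ord <- order(sources[, 1L], sources[, 2L])
  sources <- sources[ord, , drop = FALSE]
  idx <- .nodeIndex(sources, nc)
  counts <- matrix(0, nr, nc)
  for (a in seq_len(k - 1L)) {
    dij <- .cpp_grid_dijkstra(m, idx[a])
    pred <- t(dij$pred)  # row-major lookup by node index
    for (b in (a + 1L):k) {
      node <- idx[b]
      repeat {
        r <- node %/% nc + 1L; c <- node %% nc + 1L
        counts[r, c] <- counts[r, c] + 1
        node <- pred[node + 1L]
        if (node < 0L) break
      }
    }
  }
  new("ConnPrediction", values = counts, modelTag = "flcp")
}

#' Resistant kernels
#'
#' For each source s, the kernel \code{K_s(p) = max(0, 1 -
#' cd_s(p) / T)} decays linearly with the cost distance \code{cd_s}
#' from that source alone, truncating at the dispersal threshold
#' \code{T}; the prediction is the sum of kernels over sources.
#'
#' @inheritParams costDistance
#' @param threshold dispersal cost threshold T (> 0). The default
#'   (\code{NULL}) uses the coverage rule of [kernelThreshold()]: the
#'   cost distance within which the kernels jointly reach 30 percent of
#'   the landscape.
#' @param decay \code{"linear"} (default) or \code{"gaussian"}
#'   (\code{exp(-(cd/T)^2 * log(2) * 4)} truncated at T -- half-weight
#'   at T/2).
#' @param cdStack optional precomputed list of per-source cost-distance
#'   matrices (as produced by repeated [costDistance()] calls), used by
#'   the experiment driver to avoid recomputation.
#' @return a [ConnPrediction-class] with tag \code{"kernels"}.
#' @export
resistantKernels <- function(surface, sources, threshold = NULL,
                             decay = c("linear", "gaussian"),
                             cdStack = NULL) {
  decay <- match.arg(decay)
  m <- .asGrid(surface)
  sources <- .checkSources(sources, nrow(m), ncol(m))
  if (is.null(cdStack))
    cdStack <- lapply(seq_len(nrow(sources)), function(s)
      costDistance(m, sources[s, , drop = FALSE]))
  if (is.null(threshold)) threshold <- kernelThreshold(cdStack)
  if (!is.numeric(threshold) || threshold <= 0)
    stop("kernel threshold must be positive")
  acc <- matrix(0, nrow(m), ncol(m))
  for (cd in cdStack) {
    k <- if (decay == "linear") pmax(0, 1 - cd / threshold)
         else ifelse(cd < threshold, exp(-4 * log(2) * (cd / threshold)^2), 0)
    acc <- acc + k
  }
  new("ConnPrediction", values = acc, modelTag = "kernels")
}

#' Coverage-based dispersal threshold for resistant kernels
#'
#' The kernel threshold T is the cost-distance radius of the modelled
#' dispersal ability. When it is unknown, this rule sets T to the
#' \code{coverage} quantile of the minimum cost-distance surface (cost
#' distance to the nearest source), so the kernel ensemble reaches the
#' nearest \code{coverage} fraction of the landscape. Optionally T is
#' capped at the cost radius equivalent to a random walk of
#' \code{steps} moves: the walk's RMS net displacement is about
#' \code{sqrt(1.5 steps)} pixels (mean squared move length 1.5 on the
#' Moore grid), which costs about \code{sqrt(1.5 steps) * median
#' resistance} along a typical straight route. A walk's accumulated
#' cost grows linearly in steps, but its displacement -- the quantity a
#' dispersal threshold describes -- only as the square root, which is
#' why T is tied to displacement rather than to the raw energy budget.
#'
#' @param cdStack list of per-source cost-distance matrices.
#' @param coverage fraction of the landscape the kernels should reach
#'   (default 0.3).
#' @param steps optional expected number of walk steps (see
#'   [expectedPathSteps()]) used for the displacement cap.
#' @param medianResistance median of the (scaled) resistance surface,
#'   required with \code{steps}.
#' @return scalar threshold T.
#' @export
kernelThreshold <- function(cdStack, coverage = 0.3, steps = NULL,
                            medianResistance = NULL) {
  minCd <- Reduce(pmin, cdStack)
  Tcov <- as.numeric(quantile(minCd[minCd > 0], coverage))
  if (!is.null(steps) && is.finite(steps)) {
    if (is.null(medianResistance))
      stop("medianResistance required for the displacement cap")
    Tcov <- min(Tcov, sqrt(1.5 * steps) * medianResistance)
  }
  Tcov
}

## Undirected edge list of the 8-connected cost graph, plus an incidence
## matrix for accumulating per-pixel currents. Built once per surface.
.costEdges <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  node <- function(r, c) (r - 1L) * nc + c  # 1-based row-major
  ei <- integer(0); ej <- integer(0); w <- numeric(0)
  ## four forward directions cover every undirected Moore edge once
  dirs <- list(c(0L, 1L, 1), c(1L, 0L, 1), c(1L, 1L, sqrt(2)), c(1L, -1L, sqrt(2)))
  for (d in dirs) {
    dr <- d[1L]; dc <- d[2L]; len <- d[3L]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0L) seq_len(nc - dc) else seq.int(1L - dc, nc)
    grid <- expand.grid(r = r1, c = c1)
    i <- node(grid$r, grid$c)
    j <- node(grid$r + dr, grid$c + dc)
    w <- c(w, len * (m[cbind(grid$r, grid$c)] + m[cbind(grid$r + dr, grid$c + dc)]) / 2)
    ei <- c(ei, i); ej <- c(ej, j)
  }
  g <- 1 / w
  nE <- length(w)
  inc <- Matrix::sparseMatrix(i = c(ei, ej), j = rep(seq_len(nE), 2L),
                              x = 1, dims = c(nr * nc, nE))
  list(i = ei, j = ej, weight = w, conductance = g, incidence = inc,
       n = nr * nc)
}

## weighted graph Laplacian from an edge list
.laplacian <- function(edges) {
  A <- Matrix::sparseMatrix(i = c(edges$i, edges$j), j = c(edges$j, edges$i),
                            x = c(edges$conductance, edges$conductance),
                            dims = c(edges$n, edges$n))
  Matrix::Diagonal(x = Matrix::rowSums(A)) - A
}

#' Circuit-theory current density
#'
#' Treats the cost graph as a resistor network (edge conductance =
#' 1 / edge weight). In the default pairwise mode, for every unordered
#' source pair a unit current is injected at one terminal and withdrawn
#' at the other; node potentials solve the graph-Laplacian system and
#' each pixel's current is half the sum of absolute currents on its
#' incident edges (the full injected current at the two terminals).
#' The prediction sums these per-pixel currents over all pairs. The
#' \code{"all-to-one"} mode instead injects at every source against a
#' common ground (the last source).
#'
#' @inheritParams costDistance
#' @param tol maximum admissible relative residual of the linear solve.
#' @param mode \code{"pairwise"} (default) or \code{"all-to-one"}.
#' @return a [ConnPrediction-class] with tag \code{"circuit"}.
#' @examples
#' p <- circuitCurrent(matrix(1, 1, 3), rbind(c(1, 1), c(1, 3)))
#' gridValues(p)[1, 2]  # series circuit: middle pixel carries 1
#' @export
circuitCurrent <- function(surface, sources, tol = 1e-8,
                           mode = c("pairwise", "all-to-one")) {
  mode <- match.arg(mode)
  m <- .asGrid(surface)
  nr <- nrow(m); nc <- ncol(m)
  sources <- .checkSources(sources, nr, nc)
  k <- nrow(sources)
  if (k < 2L) stop("circuit current requires at least 2 sources")
  ord <- order(sources[, 1L], sources[, 2L])
  sources <- sources[ord, , drop = FALSE]
  sIdx <- (sources[, 1L] - 1L) * nc + sources[, 2L]  # 1-based row-major
  edges <- .costEdges(m)
  L <- .laplacian(edges)
  N <- edges$n
  ## reference node: first pixel that is not a source
  ref <- setdiff(seq_len(N), sIdx)[1L]
  keep <- setdiff(seq_len(N), ref)
  Lr <- L[keep, keep]
  ch <- Matrix::Cholesky(Lr, LDL = FALSE)
  rhs <- Matrix::sparseMatrix(i = match(sIdx, keep), j = seq_len(k), x = 1,
                              dims = c(N - 1L, k))
  X <- as.matrix(Matrix::solve(ch, rhs))
  resid <- max(abs(Lr %*% X - rhs)) / 1
  if (resid > tol)
    warning(sprintf("linear solve residual %.3g exceeds tol %.3g", resid, tol))
  V <- matrix(0, N, k)
  V[keep, ] <- X
  cur <- numeric(N)
  if (mode == "pairwise") {
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        v <- V[, a] - V[, b]
        eI <- abs(edges$conductance * (v[edges$i] - v[edges$j]))
        pc <- 0.5 * as.numeric(edges$incidence %*% eI)
        pc[sIdx[c(a, b)]] <- 1
        cur <- cur + pc
      }
    }
  } else {
    gnd <- k
    for (a in seq_len(k - 1L)) {
      v <- V[, a] - V[, gnd]
      eI <- abs(edges$conductance * (v[edges$i] - v[edges$j]))
      pc <- 0.5 * as.numeric(edges$incidence %*% eI)
      pc[sIdx[c(a, gnd)]] <- 1
      cur <- cur + pc
    }
  }
  vals <- matrix(cur, nr, nc, byrow = TRUE)
  new("ConnPrediction", values = vals, modelTag = "circuit")
}

#' Effective resistance between two pixels
#'
#' Two-point effective resistance of the cost-graph resistor network;
#' mainly a diagnostic for validating the circuit solver against
#' analytic networks.
#'
#' @inheritParams costDistance
#' @param a,b integer \code{(row, col)} terminal pixels.
#' @return scalar effective resistance.
#' @export
effectiveResistance <- function(surface, a, b) {
  m <- .asGrid(surface)
  nc <- ncol(m)
  edges <- .costEdges(m)
  L <- .laplacian(edges)
  ia <- (a[1L] - 1L) * nc + a[2L]
  ib <- (b[1L] - 1L) * nc + b[2L]
  keep <- setdiff(seq_len(edges$n), ib)  # ground b
  e <- numeric(edges$n - 1L)
  e[match(ia, keep)] <- 1
  v <- Matrix::solve(L[keep, keep], e)
  as.numeric(v[match(ia, keep)])
}
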