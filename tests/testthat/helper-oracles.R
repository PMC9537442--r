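# Independent brute-force oracles used across the suite. These stay
# deliberately naive (exhaustive relaxation, dense linear algebra) and
# share nothing with the package implementation paths they check.

# Moore-neighbourhood offsets with step lengths
mooreOffsets <- function() {
  off <- expand.grid(dr = -1:1, dc = -1:1)
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  off$len <- ifelse(off$dr != 0 & off$dc != 0, sqrt(2), 1)
  off
}

# Bellman-Ford style exhaustive relaxation for multi-source cost
# distance on the pixel cost graph.
bellmanFordCost <- function(m, sources) {
  nr <- nrow(m); nc <- ncol(m)
  d <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(sources))) d[sources[i, 1], sources[i, 2]] <- 0
  off <- mooreOffsets()
  repeat {
    changed <- FALSE
    for (r in 1:nr) for (c in 1:nc) for (k in seq_len(nrow(off))) {
      rr <- r + off$dr[k]; cc <- c + off$dc[k]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      w <- off$len[k] * (m[r, c] + m[rr, cc]) / 2
      if (d[r, c] + w < d[rr, cc]) { d[rr, cc] <- d[r, c] + w; changed <- TRUE }
    }
    if (!changed) break
  }
  d
}

# Dense conductance matrix of the pixel cost graph.
denseConductance <- function(m) {
  nr <- nrow(m); nc <- ncol(m); N <- nr * nc
  idx <- function(r, c) (r - 1) * nc + c
  G <- matrix(0, N, N)
  off <- mooreOffsets()
  for (r in 1:nr) for (c in 1:nc) for (k in seq_len(nrow(off))) {
    rr <- r + off$dr[k]; cc <- c + off$dc[k]
    if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
    G[idx(r, c), idx(rr, cc)] <- 1 / (off$len[k] * (m[r, c] + m[rr, cc]) / 2)
  }
  G
}

# Dense direct solve for pairwise current density (sum over all source
# pairs), mirroring the published per-pixel current convention.
denseCircuitOracle <- function(m, sources) {
  nr <- nrow(m); nc <- ncol(m); N <- nr * nc
  idx <- function(r, c) (r - 1) * nc + c
  G <- denseConductance(m)
  L <- diag(rowSums(G)) - G
  si <- apply(sources, 1, function(s) idx(s[1], s[2]))
  cur <- numeric(N)
  prs <- utils::combn(length(si), 2)
  for (p in seq_len(ncol(prs))) {
    a <- si[prs[1, p]]; b <- si[prs[2, p]]
    keep <- setdiff(seq_len(N), b)
    e <- numeric(N); e[a] <- 1
    v <- numeric(N); v[keep] <- solve(L[keep, keep], e[keep])
    pc <- sapply(seq_len(N), function(u) 0.5 * sum(abs(G[u, ] * (v[u] - v))))
    pc[c(a, b)] <- 1
    cur <- cur + pc
  }
  matrix(cur, nr, nc, byrow = TRUE)
}

# Classical one-way ANOVA R^2 via group means (for checking constrained
# ordination against the textbook quantity).
onewayR2 <- function(y, g) {
  g <- factor(g)
  gm <- tapply(y, g, mean)
  ssb <- sum(tabulate(g) * (gm - mean(y))^2)
  sst <- sum((y - mean(y))^2)
  ssb / sst
}

# Textbook one-way F statistic.
onewayF <- function(y, g) {
  g <- factor(g)
  k <- nlevels(g); n <- length(y)
  gm <- tapply(y, g, mean)
  ssb <- sum(tabulate(g) * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Dense generalised-eigenproblem oracle for CCA eigenvalues: weighted
# projection of the chi-square standardised matrix, then eigen of the
# cross-product.
ccaEigenOracle <- function(Y, X) {
  tot <- sum(Y)
  P <- Y / tot
  r <- rowSums(P); cm <- colSums(P)
  Q <- (P - r %o% cm) / sqrt(r %o% cm)
  mm <- stats::model.matrix(~., as.data.frame(X))[, -1, drop = FALSE]
  Z <- cbind(1, mm) * sqrt(r)
  H <- Z %*% solve(crossprod(Z)) %*% t(Z)
  Qf <- H %*% Q
  ev <- eigen(crossprod(Qf), symmetric = TRUE)$values
  ev[ev > max(ev) * 1e-10]
}

# Shannon entropy of a 32-bin histogram over [1, 100].
binEntropy <- function(v, bins = 32) {
  breaks <- seq(1, 100, length.out = bins + 1)
  p <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = bins)
  p <- p[p > 0] / sum(p)
  -sum(p * log(p))
}
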