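# The three predictors against analytic cases and brute-force oracles.

test_that("cost distance matches analytic chains and the relaxation oracle", {
  uni <- matrix(1, 5, 5)
  cd <- costDistance(uni, cbind(1, 1))
  expect_equal(cd[1, 4], 3)           # three cardinal steps at cost 1
  expect_equal(cd[1, 1], 0)
  expect_equal(cd[2, 2], sqrt(2))
  # multi-source: zero at every source
  srcs <- rbind(c(1, 1), c(5, 3))
  cd2 <- costDistance(uni, srcs)
  expect_equal(cd2[cbind(srcs[, 1], srcs[, 2])], c(0, 0))
  # 4x4 random surfaces vs exhaustive Bellman-Ford relaxation
  set.seed(13)
  for (rep in 1:4) {
    m <- matrix(runif(16, 1, 20), 4, 4)
    s <- rbind(c(sample(4, 1), sample(4, 1)))
    expect_equal(costDistance(m, s), bellmanFordCost(m, s), tolerance = 1e-12)
  }
  expect_error(costDistance(uni, matrix(0, 0, 2)), "at least one source")
})

test_that("cost distance agrees with an independent graph library", {
  set.seed(29)
  nr <- 7; nc <- 6
  m <- matrix(runif(nr * nc, 1, 30), nr, nc)
  srcs <- rbind(c(2, 2), c(6, 5))
  # build the same cost graph in igraph and take multi-source distances
  idx <- function(r, c) (r - 1) * nc + c
  edges <- NULL; weights <- NULL
  for (r in 1:nr) for (c in 1:nc) for (dr in 0:1) for (dc in -1:1) {
    if (dr == 0 && dc != 1) next
    rr <- r + dr; cc <- c + dc
    if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
    len <- if (dr != 0 && dc != 0) sqrt(2) else 1
    edges <- c(edges, idx(r, c), idx(rr, cc))
    weights <- c(weights, len * (m[r, c] + m[rr, cc]) / 2)
  }
  g <- igraph::make_graph(edges, n = nr * nc, directed = FALSE)
  dm <- igraph::distances(g, v = c(idx(2, 2), idx(6, 5)), weights = weights)
  want <- matrix(pmin(dm[1, ], dm[2, ]), nr, nc, byrow = TRUE)
  expect_equal(costDistance(m, srcs), want, tolerance = 1e-10)
})

test_that("cost distance is monotone in resistance", {
  set.seed(21)
  m <- matrix(runif(36, 1, 10), 6, 6)
  s <- cbind(1, 1)
  base <- costDistance(m, s)
  for (rep in 1:5) {
    m2 <- m
    px <- c(sample(6, 1), sample(6, 1))
    m2[px[1], px[2]] <- m2[px[1], px[2]] + 50
    expect_true(all(costDistance(m2, s) >= base - 1e-12))
  }
})

test_that("factorial LCP rasterises the unique geodesics", {
  uni <- matrix(1, 5, 9)
  p <- factorialLCP(uni, rbind(c(3, 2), c(3, 7)))
  v <- gridValues(p)
  # straight row segment has value 1, everything else 0
  expect_equal(v[3, 2:7], rep(1, 6))
  expect_equal(sum(v), 6)
  # k sources: pair count and total path-pixel identity
  set.seed(31)
  m <- matrix(runif(81, 1, 10), 9, 9)
  srcs <- sampleSources(5, 9, 9, seed = 3)
  pk <- factorialLCP(m, srcs)
  expect_s4_class(pk, "ConnPrediction")
  expect_identical(modelTag(pk), "flcp")
  # each of the 10 pairs contributes path length >= 2 pixels
  expect_gte(sum(gridValues(pk)), 2 * choose(5, 2))
  # source-order invariance
  pk2 <- factorialLCP(m, srcs[sample(5), ])
  expect_equal(gridValues(pk), gridValues(pk2))
  # path cost symmetry: cd(a -> b) == cd(b -> a)
  for (i in 1:4) {
    a <- srcs[i, , drop = FALSE]; b <- srcs[i + 1, , drop = FALSE]
    expect_equal(costDistance(m, a)[b], costDistance(m, b)[a],
                 tolerance = 1e-12)
  }
  expect_error(factorialLCP(uni, cbind(1, 1)), "at least 2")
})

test_that("resistant kernels decay linearly to the threshold", {
  uni <- matrix(1, 7, 7)
  rk <- resistantKernels(uni, cbind(1, 1), threshold = 5)
  v <- gridValues(rk)
  expect_equal(v[1, 1], 1)             # kernel value 1 at its own source
  expect_equal(v[1, 4], 1 - 3 / 5)     # 0.4 three cardinal steps out
  expect_equal(v[1, 7], 0)             # beyond the threshold
  # truncation: all pixels with cd >= T are zero
  cd <- costDistance(uni, cbind(1, 1))
  expect_true(all(v[cd >= 5] == 0))
  # summation over sources and order invariance
  srcs <- rbind(c(1, 1), c(7, 7), c(4, 2))
  rk2 <- resistantKernels(uni, srcs, threshold = 4)
  expect_gte(max(gridValues(rk2)), 1)
  rk3 <- resistantKernels(uni, srcs[c(2, 3, 1), ], threshold = 4)
  expect_equal(gridValues(rk2), gridValues(rk3))
  expect_error(resistantKernels(uni, cbind(1, 1), threshold = -2), "positive")
})

test_that("circuit current matches analytic series and parallel networks", {
  # 1x3 series strip: middle pixel carries the full unit current
  strip <- matrix(1, 1, 3)
  pr <- circuitCurrent(strip, rbind(c(1, 1), c(1, 3)))
  expect_equal(gridValues(pr)[1, 2], 1, tolerance = 1e-10)
  expect_equal(gridValues(pr)[1, 1], 1)
  # effective resistance of the strip = series sum of the two edges
  expect_equal(effectiveResistance(strip, c(1, 1), c(1, 3)), 2,
               tolerance = 1e-10)
  # two disjoint parallel corridors: each carries half the current.
  # build 3x5 with an impassably-high middle row
  m <- matrix(1, 3, 5); m[2, 2:4] <- 1e9
  pr2 <- gridValues(circuitCurrent(m, rbind(c(2, 1), c(2, 5))))
  expect_equal(pr2[1, 3], 0.5, tolerance = 1e-6)
  expect_equal(pr2[3, 3], 0.5, tolerance = 1e-6)
})

test_that("circuit current agrees with the dense direct-solve oracle", {
  set.seed(17)
  for (dims in list(c(4, 5), c(8, 8))) {
    m <- matrix(runif(prod(dims), 1, 10), dims[1], dims[2])
    srcs <- sampleSources(3, dims[1], dims[2], seed = 6)
    got <- gridValues(circuitCurrent(m, srcs))
    want <- denseCircuitOracle(m, srcs)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("Kirchhoff conservation holds at non-terminal nodes", {
  set.seed(19)
  m <- matrix(runif(48, 1, 10), 6, 8)
  srcs <- rbind(c(1, 1), c(6, 8))
  G <- denseConductance(m)
  L <- diag(rowSums(G)) - G
  N <- 48
  a <- 1; b <- (6 - 1) * 8 + 8
  keep <- setdiff(1:N, b)
  e <- numeric(N); e[a] <- 1
  v <- numeric(N); v[keep] <- solve(L[keep, keep], e[keep])
  net <- L %*% v
  nonterm <- setdiff(1:N, c(a, b))
  expect_lt(max(abs(net[nonterm])), 1e-7)
})

test_that("circuit prediction is source-order invariant", {
  set.seed(23)
  m <- matrix(runif(64, 1, 10), 8, 8)
  srcs <- sampleSources(4, 8, 8, seed = 2)
  p1 <- gridValues(circuitCurrent(m, srcs))
  p2 <- gridValues(circuitCurrent(m, srcs[c(3, 1, 4, 2), ]))
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("coverage-based kernel threshold reaches the requested fraction", {
  suite <- generateSurfaceSuite(32, 32, 3, seed = 4)
  m <- gridValues(suite[[3]])
  srcs <- sampleSources(6, 32, 32, seed = 5)
  cds <- lapply(1:6, function(s) costDistance(m, srcs[s, , drop = FALSE]))
  Tthr <- kernelThreshold(cds, coverage = 0.3)
  rk <- resistantKernels(m, srcs, threshold = Tthr, cdStack = cds)
  support <- mean(gridValues(rk) > 0)
  expect_gt(support, 0.25)
  expect_lt(support, 0.40)
  # displacement cap binds for very short walks
  Tcap <- kernelThreshold(cds, steps = 4, medianResistance = median(m))
  expect_lte(Tcap, sqrt(6) * median(m))
})
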