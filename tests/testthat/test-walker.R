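# The stochastic walker: step distribution, single paths, density
# aggregation.

test_that("step distribution follows the mixture rule", {
  uni <- matrix(1, 9, 9)
  # symmetric interior pixel, attraction on, C = D = 0: uniform 1/8
  d <- stepDistribution(c(5, 5), NULL, movementConfig("attraction"), uni)
  expect_equal(d$prob, rep(1 / 8, 8))
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  # two admissible neighbours with r = 1 and r = 3: probabilities 3:1
  strip <- matrix(c(1, 5, 3), 1, 3)  # neighbours of (1,2) are (1,1)=1,(1,3)=3
  d2 <- stepDistribution(c(1, 2), NULL, movementConfig("attraction"), strip)
  expect_equal(sort(d2$prob, decreasing = TRUE), c(0.75, 0.25))
  expect_equal(d2$prob[d2$col == 1], 0.75)  # lower resistance preferred
  # C = 1, D = 0, admissible continuation: point mass on it
  cfg <- movementConfig(autocorrC = 1)
  d3 <- stepDistribution(c(5, 5), 5L, cfg, uni)  # dir 5 = (0, +1)
  expect_equal(d3$prob[d3$dir == 5], 1)
  expect_equal(sum(d3$prob), 1)
  # destination point mass: D = 1 puts all mass on the closest neighbour
  cfg4 <- movementConfig(destBiasD = 1, destination = c(5, 9))
  d4 <- stepDistribution(c(5, 5), NULL, cfg4, uni)
  expect_equal(d4$prob[d4$row == 5 & d4$col == 6], 1)
  # persistence folds into the mechanism term at a wall
  cfg5 <- movementConfig(autocorrC = 0.5)
  d5 <- stepDistribution(c(1, 5), 2L, cfg5, uni)  # continuation (0,-1) row 0: out
  expect_equal(sum(d5$prob), 1, tolerance = 1e-12)
  expect_equal(d5$prob, rep(1 / 5, 5))  # fold: uniform over the 5 admissible
  expect_error(stepDistribution(c(1, 1), NULL, movementConfig(), matrix(1, 1, 1)),
               "degenerate")
})

test_that("step distribution normalises over random configurations", {
  set.seed(11)
  m <- matrix(runif(64, 1, 100), 8, 8)
  for (i in 1:50) {
    cur <- c(sample(8, 1), sample(8, 1))
    C <- runif(1); D <- runif(1)
    cfg <- movementConfig(sample(c("energy", "attraction", "risk"),
                                 sample(0:3, 1)),
                          autocorrC = C, destBiasD = D,
                          destination = c(sample(8, 1), sample(8, 1)))
    pd <- sample(c(NA, 1:8), 1)
    d <- stepDistribution(cur, if (is.na(pd)) NULL else pd, cfg, m)
    expect_equal(sum(d$prob), 1, tolerance = 1e-12)
    expect_true(all(d$prob >= 0))
    expect_true(all(d$row >= 1 & d$row <= 8 & d$col >= 1 & d$col <= 8))
  }
})

test_that("paths respect the step cap, adjacency and grid bounds", {
  s <- resistanceSurface(matrix(1, 32, 32))
  p <- simulatePath(s, c(16, 16), movementConfig(), seed = 4)
  expect_identical(nrow(p$coords), 501L)  # cap + start
  expect_identical(p$termination_reason, "step_cap")
  dd <- abs(diff(p$coords))
  expect_true(all(dd <= 1) && all(rowSums(dd) >= 1))  # Moore-adjacent moves
  expect_true(all(p$coords >= 1 & p$coords <= 32))
  # walks hugging the border stay inside
  p2 <- simulatePath(s, c(1, 1), movementConfig(autocorrC = 0.9), seed = 7)
  expect_true(all(p2$coords >= 1 & p2$coords <= 32))
  # determinism
  p3 <- simulatePath(s, c(16, 16), movementConfig(), seed = 4)
  expect_identical(p$coords, p3$coords)
})

test_that("energy exhaustion terminates the walk before the budget is crossed", {
  s <- resistanceSurface(matrix(2, 16, 16))
  # cheapest incident step costs 2; budget below that: no move at all
  cfg <- movementConfig("energy", energyThreshold = 1.5)
  p <- simulatePath(s, c(8, 8), cfg, seed = 1)
  expect_identical(nrow(p$coords), 1L)
  expect_identical(p$termination_reason, "energy_exhausted")
  # accumulated cost of the realised path stays below E
  cfg2 <- movementConfig("energy", energyThreshold = 40)
  p2 <- simulatePath(s, c(8, 8), cfg2, seed = 2)
  expect_identical(p2$termination_reason, "energy_exhausted")
  steps <- diff(p2$coords)
  lens <- ifelse(rowSums(abs(steps)) == 2, sqrt(2), 1)
  expect_lt(sum(lens * 2), 40)   # each move costs len * (2+2)/2 = 2 len
  expect_gt(nrow(p2$coords), 10) # but the walk did use most of the budget
})

test_that("full destination bias reaches the target in Chebyshev-distance steps", {
  s <- resistanceSurface(matrix(1, 24, 24))
  src <- c(4, 3); dst <- c(17, 20)
  k <- max(abs(src - dst))
  cfg <- movementConfig(destBiasD = 1, destination = dst)
  p <- simulatePath(s, src, cfg, seed = 3)
  expect_identical(p$termination_reason, "destination_reached")
  expect_identical(nrow(p$coords), as.integer(k) + 1L)
  cheb <- pmax(abs(p$coords[, 1] - dst[1]), abs(p$coords[, 2] - dst[2]))
  expect_true(all(diff(cheb) == -1))
})

test_that("risk shortens walks monotonically in beta", {
  s <- resistanceSurface(matrix(10, 32, 32))
  meanLen <- vapply(c(0.02, 0.1, 0.5), function(b) {
    cfg <- movementConfig("risk", riskBeta = b)
    mean(vapply(1:60, function(i)
      nrow(simulatePath(s, c(16, 16), cfg, seed = 100 + i)$coords), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanLen) < 0))
})

test_that("attraction concentrates occupancy on low-resistance terrain", {
  # two-valued strip: left half r = 1, right half r = 10
  m <- cbind(matrix(1, 20, 10), matrix(10, 20, 10))
  cfg <- movementConfig("attraction")
  d <- simulateDensity(m, cbind(10, 10), cfg, pathsPerSource = 30, seed = 5)
  counts <- gridValues(d)
  # exclude the start column shared by both halves
  expect_gt(sum(counts[, 1:9]), 2 * sum(counts[, 12:20]))
})

test_that("density aggregation conserves counts and is reproducible", {
  suite <- generateSurfaceSuite(24, 24, 3, seed = 2)
  srcs <- sampleSources(5, 24, 24, seed = 8)
  cfg <- movementConfig(c("energy", "risk"), autocorrC = 0.35)
  d <- simulateDensity(suite[[2]], srcs, cfg, pathsPerSource = 4, seed = 9)
  expect_identical(d@nPaths, 20L)
  # conservation: total counts equal total path coordinates
  total <- 0L
  for (s in 1:5) for (rep in 1:4) {
    idx <- (s - 1L) * 4L + rep
    set.seed(connscape:::.subSeed(9, idx))
    p <- connscape:::.walkOne(connscape:::.resolveConfig(suite[[2]], cfg),
                              cfg, srcs[s, ], integer())
    total <- total + nrow(p$coords)
  }
  expect_identical(sum(gridValues(d)), as.numeric(total))
  d2 <- simulateDensity(suite[[2]], srcs, cfg, pathsPerSource = 4, seed = 9)
  expect_identical(gridValues(d), gridValues(d2))
  expect_error(simulateDensity(suite[[2]], matrix(0, 0, 2), cfg, 2, 1),
               "at least one source")
})
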