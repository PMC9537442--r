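# Constrained ordination, variance partitioning and factorial ANOVA
# against closed-form oracles and the reference implementation in vegan.

test_that("RDA: perfect fit, null simulation, one-way oracle", {
  # noise-free linear function of the dummies: everything constrained
  X <- data.frame(g = factor(rep(c("a", "b", "c"), each = 4)))
  Y <- cbind(y1 = rep(c(0, 1, 3), each = 4), y2 = rep(c(2, 0, 1), each = 4))
  fit <- rdaConstrained(Y, X)
  expect_equal(fit@propConstrained, 1, tolerance = 1e-10)
  expect_equal(sum(fit@eigConstrained) + sum(fit@eigUnconstrained),
               fit@totalInertia, tolerance = 1e-8)
  # independent X: adjusted R2 near zero (n = 2000)
  set.seed(53)
  Xn <- data.frame(g = factor(sample(letters[1:4], 2000, TRUE)))
  Yn <- matrix(rnorm(2000 * 3), 2000, 3)
  expect_lt(abs(rdaConstrained(Yn, Xn)@adjR2), 0.02)
  # univariate, single two-level factor: classical one-way R2
  set.seed(59)
  g <- rep(c("u", "v"), each = 10)
  y <- rnorm(20) + (g == "v")
  fit2 <- rdaConstrained(cbind(y), data.frame(g = factor(g)),
                         standardize = FALSE)
  expect_equal(fit2@propConstrained, onewayR2(y, g), tolerance = 1e-10)
})

test_that("RDA matches vegan eigenvalues and adjusted R2", {
  set.seed(61)
  X <- data.frame(f = factor(rep(letters[1:3], 10)),
                  g = factor(rep(c("u", "v"), 15)))
  Y <- matrix(rnorm(90), 30, 3)
  mine <- rdaConstrained(Y, X)
  ref <- vegan::rda(Y ~ f + g, data = X, scale = TRUE)
  expect_equal(mine@eigConstrained,
               unname(vegan::eigenvals(ref, model = "constrained")),
               tolerance = 1e-8)
  expect_equal(mine@adjR2, vegan::RsquareAdj(ref)$adj.r.squared,
               tolerance = 1e-8)
})

test_that("CCA: degenerate cases, dense oracle, vegan cross-check", {
  # identical rows: no chi-square inertia at all
  Yc <- matrix(rep(c(1, 2, 3), each = 5), 5, 3)
  X <- data.frame(g = factor(c("a", "a", "b", "b", "b")))
  fit <- ccaConstrained(Yc, X)
  expect_equal(fit@totalInertia, 0, tolerance = 1e-12)
  expect_length(fit@eigConstrained, 0)
  # perfectly discriminating binary predictor on a 2-pattern table
  Y2 <- rbind(c(10, 0), c(10, 0), c(0, 10), c(0, 10))
  X2 <- data.frame(g = factor(c("a", "a", "b", "b")))
  expect_equal(ccaConstrained(Y2, X2)@propConstrained, 1, tolerance = 1e-10)
  # small 6x3 table: eigenvalues match the dense projection oracle
  set.seed(67)
  Y3 <- matrix(rexp(18), 6, 3)
  X3 <- data.frame(f = factor(c("a", "a", "b", "b", "c", "c")))
  mine <- ccaConstrained(Y3, X3)
  expect_equal(mine@eigConstrained, ccaEigenOracle(Y3, X3), tolerance = 1e-8)
  ref <- vegan::cca(Y3 ~ f, data = X3)
  expect_equal(mine@eigConstrained,
               unname(vegan::eigenvals(ref, model = "constrained")),
               tolerance = 1e-8)
  expect_equal(mine@totalInertia, ref$tot.chi, tolerance = 1e-8)
  expect_error(ccaConstrained(-Y3, X3), "non-negative")
})

test_that("variance partitioning decomposes correctly", {
  # single pair of orthogonal balanced factors, additive noise-free Y:
  # on the unadjusted scale the shared component is exactly zero and
  # the uniques equal the marginal R2 (the Ezekiel adjustment is
  # nonlinear, so the adjusted partition shares need not vanish)
  X <- expand.grid(a = factor(c("l", "h")), b = factor(c("u", "v", "w")))
  X <- X[rep(1:6, 4), ]
  Y <- cbind(y = 2 * (X$a == "h") + c(0, 1, 3)[as.integer(X$b)])
  vp <- variancePartition(Y, X, list(A = "a", B = "b"), adjust = FALSE)
  expect_equal(sum(vp@components) + vp@residual, 1, tolerance = 1e-10)
  expect_equal(unname(vp@components["shared:A:B"]), 0, tolerance = 1e-8)
  expect_equal(unname(vp@components["unique:A"]),
               unname(vp@adjR2["A"]), tolerance = 1e-8)
  # permutation invariance of group order
  vp2 <- variancePartition(Y, X, list(B = "b", A = "a"), adjust = FALSE)
  expect_equal(sort(vp2@components), sort(vp@components), tolerance = 1e-10)
  # three groups on random data still sum to one
  set.seed(71)
  X3 <- data.frame(a = factor(sample(2, 40, TRUE)),
                   b = factor(sample(3, 40, TRUE)),
                   c = factor(sample(2, 40, TRUE)))
  Y3 <- matrix(rnorm(80), 40, 2)
  vp3 <- variancePartition(Y3, X3, list(A = "a", B = "b", C = "c"))
  expect_equal(sum(vp3@components) + vp3@residual, 1, tolerance = 1e-8)
  expect_error(variancePartition(Y3, X3, list(A = "a", B = "a")), "overlap")
})

test_that("variance partitioning agrees with vegan::varpart", {
  set.seed(73)
  X <- data.frame(f = factor(sample(letters[1:3], 50, TRUE)),
                  g = factor(sample(c("u", "v"), 50, TRUE)))
  Y <- matrix(rnorm(150), 50, 3)
  vp <- variancePartition(Y, X, list(F = "f", G = "g"))
  ref <- vegan::varpart(scale(Y), ~f, ~g, data = X)
  frac <- ref$part$indfract$Adj.R.squared
  expect_equal(unname(vp@components["unique:F"]), frac[1], tolerance = 1e-8)
  expect_equal(unname(vp@components["unique:G"]), frac[2], tolerance = 1e-8)
  expect_equal(unname(vp@components["shared:F:G"]), frac[3], tolerance = 1e-8)
  expect_equal(vp@residual, frac[4], tolerance = 1e-8)
})

test_that("factorial ANOVA matches the textbook one-way F and additive designs", {
  # constant response: zero sums of squares for every effect
  X <- expand.grid(a = factor(1:3), b = factor(1:2))
  sm <- anovaFactorial(rep(5, 6), X)
  expect_true(all(sm$sumsq[sm$term != "Residuals"] < 1e-20))
  # one-way F equals the closed-form oracle
  set.seed(79)
  g <- factor(rep(letters[1:3], each = 7))
  y <- rnorm(21) + as.integer(g) / 2
  sm2 <- anovaFactorial(y, data.frame(g = g))
  expect_equal(sm2$F[sm2$term == "g"], onewayF(y, g), tolerance = 1e-10)
  # balanced additive two-factor design without noise: no interaction SS
  X3 <- expand.grid(a = factor(1:3), b = factor(1:4))
  X3 <- X3[rep(seq_len(12), 2), ]
  y3 <- 2 * as.integer(X3$a) - 3 * as.integer(X3$b)
  sm3 <- anovaFactorial(y3, X3)
  expect_lt(sm3$sumsq[sm3$term == "a:b"], 1e-10)
  # unbalanced design warns
  expect_warning(anovaFactorial(y3[-1], X3[-1, ]), "unbalanced")
})
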