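## Constrained ordination and variance partitioning for the synthesis
## of factorial scenario tables. The linear algebra is implemented
## directly (QR projection + SVD); vegan is used only as an independent
## cross-check in the test suite.

#' OrdinationResult: a constrained ordination fit
#'
#' @slot eigConstrained,eigUnconstrained non-negative eigenvalues in
#'   decreasing order; together they sum to the total inertia.
#' @slot totalInertia total variance (RDA) or chi-square inertia (CCA).
#' @slot propConstrained fraction of inertia explained by the
#'   constraints (= R squared).
#' @slot adjR2 Ezekiel-adjusted R squared.
#' @slot siteScores rows-by-axes scores of the observations on the
#'   constrained axes.
#' @slot responseScores responses-by-axes loadings.
#' @slot centroids list (one element per factor) of factor-level
#'   centroid positions in the constrained space.
#' @slot rank number of independent constraint columns used.
#' @export
setClass("OrdinationResult",
  representation(eigConstrained = "numeric", eigUnconstrained = "numeric",
                 totalInertia = "numeric", propConstrained = "numeric",
                 adjR2 = "numeric", siteScores = "matrix",
                 responseScores = "matrix", centroids = "list",
                 rank = "integer", method = "character"))

setValidity("OrdinationResult", function(object) {
  ec <- object@eigConstrained; eu <- object@eigUnconstrained
  if (any(ec < -1e-10) || any(eu < -1e-10)) return("negative eigenvalues")
  if (is.unsorted(rev(ec), strictly = FALSE) && length(ec) > 1)
    return("constrained eigenvalues not sorted decreasing")
  tot <- sum(ec) + sum(eu)
  if (object@totalInertia > 1e-12 &&
      abs(tot - object@totalInertia) > 1e-6 * max(1, object@totalInertia))
    return("eigenvalue totals do not match total inertia")
  TRUE
})

setMethod("show", "OrdinationResult", function(object) {
  cat(sprintf("OrdinationResult (%s): total inertia %.4g\n",
              object@method, object@totalInertia))
  cat(sprintf("  constrained %.4g (%.1f%%), adj. R2 %.4g, rank %d\n",
              sum(object@eigConstrained), 100 * object@propConstrained,
              object@adjR2, object@rank))
})

## Build a full-rank dummy design (treatment contrasts) from a factor
## data frame, dropping collinear columns with a warning.
.designMatrix <- function(X) {
  X <- as.data.frame(X)
  X[] <- lapply(X, function(col) if (is.character(col)) factor(col) else col)
  mm <- model.matrix(~., X)[, -1L, drop = FALSE]
  qrm <- qr(scale(mm, center = TRUE, scale = FALSE))
  if (qrm$rank < ncol(mm)) {
    drop <- qrm$pivot[(qrm$rank + 1L):ncol(mm)]
    warning(sprintf("dropping %d collinear design column(s): %s",
                    length(drop), paste(colnames(mm)[drop], collapse = ", ")))
    mm <- mm[, -drop, drop = FALSE]
  }
  mm
}

.ezekiel <- function(R2, n, p) {
  if (n - p - 1L <= 0L) return(NA_real_)
  1 - (1 - R2) * (n - 1) / (n - p - 1)
}

#' Redundancy analysis (RDA)
#'
#' Constrained linear ordination: the response matrix is column-centred
#' (and standardised to unit variance by default, since accuracy
#' statistics have unlike scales), regressed on the dummy-coded
#' factors, and the constrained axes are the principal axes of the
#' fitted values. Inertia is variance (divisor n - 1).
#'
#' @param Y numeric response matrix (rows = observations).
#' @param X data frame of explanatory factors (and/or numeric
#'   covariates); dummy-coded with treatment contrasts.
#' @param standardize scale responses to unit variance (default TRUE).
#' @return an [OrdinationResult-class].
#' @examples
#' X <- data.frame(g = rep(c("a", "b"), each = 5))
#' Y <- cbind(y = rep(c(0, 1), each = 5))
#' rdaConstrained(Y, X)@propConstrained  # 1: Y is exactly a function of g
#' @export
rdaConstrained <- function(Y, X, standardize = TRUE) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (nrow(as.data.frame(X)) != n) stop("Y and X row counts differ")
  sds <- apply(Y, 2L, sd)
  Yc <- scale(Y, center = TRUE, scale = if (standardize) ifelse(sds > 0, sds, 1) else FALSE)
  mm <- .designMatrix(X)
  p <- ncol(mm)
  qrX <- qr(cbind(1, mm))
  Yfit <- qr.fitted(qrX, Yc)
  Yres <- Yc - Yfit
  svF <- svd(Yfit)
  svR <- svd(Yres)
  eigC <- svF$d^2 / (n - 1)
  eigU <- svR$d^2 / (n - 1)
  eigC <- eigC[eigC > max(eigC[1], 0) * 1e-12]
  eigU <- eigU[eigU > max(eigU[1], 0) * 1e-12]
  tot <- sum(Yc^2) / (n - 1)
  R2 <- if (tot > 0) sum(eigC) / tot else 0
  nAx <- length(eigC)
  siteScores <- (svF$u[, seq_len(nAx), drop = FALSE] %*%
                 diag(svF$d[seq_len(nAx)], nAx)) / sqrt(n - 1)
  responseScores <- svF$v[, seq_len(nAx), drop = FALSE]
  rownames(responseScores) <- colnames(Y)
  new("OrdinationResult", eigConstrained = eigC, eigUnconstrained = eigU,
      totalInertia = tot, propConstrained = R2,
      adjR2 = .ezekiel(R2, n, p), siteScores = siteScores,
      responseScores = responseScores,
      centroids = .factorCentroids(X, siteScores), rank = as.integer(p),
      method = "rda")
}

#' Canonical correspondence analysis (CCA)
#'
#' Constrained ordination under the chi-square metric: the response
#' matrix (non-negative; accuracy columns should be min-shifted to 0
#' beforehand, see [minShift()]) is converted to the standardised
#' contribution matrix Q, regressed on the factors under row-mass
#' weights, and the constrained axes are the weighted principal axes of
#' the fitted values. Inertia is the total chi-square statistic divided
#' by the grand total.
#'
#' @param Y non-negative numeric response matrix with positive row
#'   sums.
#' @param X data frame of explanatory factors.
#' @return an [OrdinationResult-class].
#' @export
ccaConstrained <- function(Y, X) {
  Y <- as.matrix(Y)
  if (any(Y < 0)) stop("CCA requires non-negative responses; see minShift()")
  n <- nrow(Y)
  if (nrow(as.data.frame(X)) != n) stop("Y and X row counts differ")
  tot <- sum(Y)
  if (tot <= 0) stop("Y has no mass")
  P <- Y / tot
  r <- rowSums(P)
  if (any(r <= 0)) stop("rows with zero mass are not allowed")
  cm <- colSums(P)
  keepC <- cm > 0
  Q <- (P[, keepC, drop = FALSE] - r %o% cm[keepC]) /
    sqrt(r %o% cm[keepC])
  mm <- .designMatrix(X)
  p <- ncol(mm)
  ## weighted projection: centre X by row masses, scale rows by sqrt(r)
  Xw <- sweep(mm, 2L, colSums(r * mm))
  Z <- cbind(sqrt(r), sqrt(r) * Xw)
  qrZ <- qr(Z)
  Qfit <- qr.fitted(qrZ, Q)
  Qres <- Q - Qfit
  svF <- svd(Qfit)
  svR <- svd(Qres)
  eigC <- svF$d^2
  eigU <- svR$d^2
  eigC <- eigC[eigC > max(eigC[1], 0) * 1e-12]
  eigU <- eigU[eigU > max(eigU[1], 0) * 1e-12]
  totI <- sum(Q^2)
  R2 <- if (totI > 0) sum(eigC) / totI else 0
  nAx <- length(eigC)
  siteScores <- sweep(svF$u[, seq_len(nAx), drop = FALSE] %*%
                        diag(svF$d[seq_len(nAx)], nAx), 1L, sqrt(r), `/`)
  responseScores <- svF$v[, seq_len(nAx), drop = FALSE]
  rownames(responseScores) <- colnames(Y)[keepC]
  new("OrdinationResult", eigConstrained = eigC, eigUnconstrained = eigU,
      totalInertia = totI, propConstrained = R2,
      adjR2 = .ezekiel(R2, n, p), siteScores = siteScores,
      responseScores = responseScores,
      centroids = .factorCentroids(X, siteScores), rank = as.integer(p),
      method = "cca")
}

.factorCentroids <- function(X, siteScores) {
  X <- as.data.frame(X)
  isFac <- vapply(X, function(col) is.factor(col) || is.character(col), logical(1))
  out <- lapply(X[isFac], function(f) {
    f <- as.factor(f)
    t(vapply(levels(f), function(lv)
      colMeans(siteScores[f == lv, , drop = FALSE]),
      numeric(ncol(siteScores))))
  })
  out
}

#' Shift each column of a matrix to a zero minimum
#'
#' Prepares signed accuracy statistics (the Pearson correlation can be
#' negative) for [ccaConstrained()], preserving within-column ordering.
#'
#' @param Y numeric matrix.
#' @return matrix with columnwise minima at 0.
#' @export
minShift <- function(Y) {
  Y <- as.matrix(Y)
  sweep(Y, 2L, apply(Y, 2L, min))
}

#' PartitionResult: variance partitioning components
#'
#' @slot components named numeric vector of exclusive components: the
#'   unique adjusted R squared of each predictor group and every shared
#'   (intersection) component, by inclusion-exclusion.
#' @slot residual unexplained fraction (1 - adjusted R squared of the
#'   full model).
#' @slot adjR2 named adjusted R squared of every subset of groups
#'   fitted.
#' @export
setClass("PartitionResult",
  representation(components = "numeric", residual = "numeric",
                 adjR2 = "numeric"))

setValidity("PartitionResult", function(object) {
  s <- sum(object@components) + object@residual
  if (abs(s - 1) > 1e-6) return("components plus residual must sum to 1")
  TRUE
})

setMethod("show", "PartitionResult", function(object) {
  cat("Variance partitioning (adjusted R2 components):\n")
  comp <- sort(object@components, decreasing = TRUE)
  for (nm in names(comp)) cat(sprintf("  %-24s %8.4f\n", nm, comp[nm]))
  cat(sprintf("  %-24s %8.4f\n", "residual", object@residual))
})

#' Variance partitioning across predictor groups
#'
#' Decomposes the explained (Ezekiel-adjusted) variance of a
#' multivariate response into the unique and shared contributions of 2
#' to 4 groups of predictors, fitting an RDA for every subset of groups
#' and applying inclusion-exclusion. Components plus the residual sum
#' to 1 by construction (shared components can be negative, as is usual
#' for adjusted partitions).
#'
#' @param Y numeric response matrix.
#' @param X data frame holding all predictor columns.
#' @param groups named list mapping group labels to column names of
#'   \code{X}; groups must not overlap.
#' @param standardize passed to [rdaConstrained()].
#' @param adjust use Ezekiel-adjusted R squared (default). With
#'   \code{adjust = FALSE} the raw R squared is partitioned; only then
#'   do orthogonal balanced designs give exactly zero shared
#'   components, since the adjustment is nonlinear in R squared.
#' @return a [PartitionResult-class].
#' @examples
#' X <- expand.grid(a = c("l", "h"), b = c("u", "v"))
#' Y <- cbind(y = c(0, 1, 0, 1) + c(0, 0, 2, 2))
#' variancePartition(Y, X, list(A = "a", B = "b"))
#' @export
variancePartition <- function(Y, X, groups, standardize = TRUE,
                              adjust = TRUE) {
  X <- as.data.frame(X)
  k <- length(groups)
  if (k < 2L || k > 4L) stop("between 2 and 4 predictor groups required")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("X", seq_len(k))
  cols <- unlist(groups)
  if (anyDuplicated(cols)) stop("predictor groups must not overlap")
  if (!all(cols %in% names(X))) stop("group columns missing from X")
  ## adjusted R2 of every non-empty subset of groups
  subsets <- lapply(seq_len(2^k - 1L), function(s) which(bitwAnd(s, 2^(seq_len(k) - 1L)) > 0))
  subsetKey <- vapply(subsets, function(s) paste(names(groups)[s], collapse = "+"), "")
  f <- vapply(subsets, function(s) {
    fit <- rdaConstrained(Y, X[, unlist(groups[s]), drop = FALSE],
                          standardize = standardize)
    if (adjust) fit@adjR2 else fit@propConstrained
  }, numeric(1))
  names(f) <- subsetKey
  fOf <- function(s) {                 # s = integer vector of group ids
    if (length(s) == 0L) return(0)
    f[[paste(names(groups)[sort(s)], collapse = "+")]]
  }
  full <- seq_len(k)
  ## exclusive component of every non-empty group set T, via Moebius
  ## inversion of h(W) = f(all) - f(all minus W)
  h <- function(W) fOf(full) - fOf(setdiff(full, W))
  comps <- vapply(subsets, function(Tset) {
    total <- 0
    for (s in 0:(2^length(Tset) - 1L)) {
      W <- Tset[which(bitwAnd(s, 2^(seq_along(Tset) - 1L)) > 0)]
      total <- total + (-1)^(length(Tset) - length(W)) * h(W)
    }
    total
  }, numeric(1))
  ## canonical (sorted) labels so results are invariant to group order
  names(comps) <- vapply(subsets, function(s) {
    if (length(s) == 1L) paste0("unique:", names(groups)[s])
    else paste0("shared:", paste(sort(names(groups)[s]), collapse = ":"))
  }, "")
  new("PartitionResult", components = comps, residual = 1 - fOf(full),
      adjR2 = f)
}

#' Factorial analysis of variance of one accuracy statistic
#'
#' Fits main effects and all two-way interactions of the given factors
#' (higher-order terms are not estimable at the replication level of
#' the scenario grids). For balanced designs the sum-of-squares
#' decomposition is unique; unbalanced input falls back to sequential
#' sums of squares with a warning.
#'
#' @param y numeric response vector.
#' @param X data frame of factors.
#' @param interactions highest interaction order (1 or 2, default 2).
#' @return data frame with columns \code{term}, \code{df},
#'   \code{sumsq}, \code{meansq}, \code{F}, \code{p}.
#' @export
anovaFactorial <- function(y, X, interactions = 2L) {
  X <- as.data.frame(X)
  X[] <- lapply(X, function(col) if (is.numeric(col) && length(unique(col)) <= 8)
    factor(col) else if (is.character(col)) factor(col) else col)
  keep <- vapply(X, function(col) length(unique(col)) > 1L, logical(1))
  X <- X[, keep, drop = FALSE]
  cells <- table(X)
  if (length(unique(as.vector(cells))) > 1L)
    warning("unbalanced design: sequential (type I) sums of squares")
  rhs <- if (interactions >= 2L && ncol(X) > 1L)
    sprintf("(%s)^2", paste(names(X), collapse = " + "))
  else paste(names(X), collapse = " + ")
  dat <- cbind(X, .y = y)
  fit <- aov(as.formula(paste(".y ~", rhs)), data = dat)
  sm <- summary(fit)[[1L]]
  k <- nrow(sm)
  col <- function(nm) if (is.null(sm[[nm]])) rep(NA_real_, k) else sm[[nm]]
  data.frame(term = trimws(rownames(sm)), df = col("Df"),
             sumsq = col("Sum Sq"), meansq = col("Mean Sq"),
             F = col("F value"), p = col("Pr(>F)"),
             row.names = NULL)
}
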