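## Individual-based stochastic movement on a resistance surface.
##
## At each step the walker draws one of its admissible Moore neighbours
## from the mixture
##   P = (1 - C' - D) P_mech + C' P_persist + D P_dest,   C' = C (1 - D),
## where P_mech is proportional to 1/resistance when the attraction
## mechanism is active (uniform otherwise), P_persist is a point mass on
## the neighbour continuing the previous direction (folded into P_mech
## when there is no admissible continuation) and P_dest is a point mass
## on the admissible neighbour closest (Euclidean) to the destination.

## fixed Moore neighbour order: all tie-breaking uses this order
.MOORE <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
.STEPLEN <- ifelse(.MOORE[, 1L] != 0L & .MOORE[, 2L] != 0L, sqrt(2), 1)

#' MovementConfig: behavioural parameterisation of one movement scenario
#'
#' @slot mechanisms character subset of \code{c("energy", "attraction",
#'   "risk")} (possibly empty: a pure random walk).
#' @slot scaleN odd focal window edge (1 = pixel-scale perception).
#' @slot scaleFn focal statistic: \code{"mean"}, \code{"max"} or
#'   \code{"min"}.
#' @slot autocorrC directional autocorrelation C in \code{[0, 1]}.
#' @slot destBiasD destination bias D in \code{[0, 1]}; requires a
#'   destination when positive.
#' @slot destination integer \code{(row, col)} target, or length-0 when
#'   unused (the experiment driver then assigns one per path).
#' @slot energyThreshold accumulated-cost budget E; \code{NA} = choose
#'   250 times the median scaled resistance (roughly half the step cap
#'   on typical terrain).
#' @slot riskBeta per-step hazard scaling; \code{NA} = choose so a
#'   250-step walk on median-risk terrain survives with probability 1/2.
#' @slot maxSteps hard cap on the number of steps (default 500).
#' @slot riskSurface optional matrix/[ResistanceSurface-class] used as
#'   the mortality-risk layer; default is the resistance surface itself.
#' @seealso [movementConfig()], [simulatePath()]
#' @export
setClass("MovementConfig",
  representation(mechanisms = "character", scaleN = "integer",
                 scaleFn = "character", autocorrC = "numeric",
                 destBiasD = "numeric", destination = "integer",
                 energyThreshold = "numeric", riskBeta = "numeric",
                 maxSteps = "integer", riskSurface = "ANY"))

setValidity("MovementConfig", function(object) {
  if (!all(object@mechanisms %in% c("energy", "attraction", "risk")))
    return("mechanisms must be a subset of energy/attraction/risk")
  if (anyDuplicated(object@mechanisms)) return("duplicated mechanisms")
  if (object@scaleN < 1L || object@scaleN %% 2L != 1L)
    return("scaleN must be a positive odd integer")
  if (!(object@scaleFn %in% c("mean", "max", "min")))
    return("scaleFn must be mean, max or min")
  if (object@autocorrC < 0 || object@autocorrC > 1) return("autocorrC must be in [0, 1]")
  if (object@destBiasD < 0 || object@destBiasD > 1) return("destBiasD must be in [0, 1]")
  if (length(object@destination) %in% c(0L, 2L) == FALSE)
    return("destination must be a (row, col) pair or empty")
  if (object@maxSteps < 1L) return("maxSteps must be >= 1")
  if (!is.na(object@energyThreshold) && object@energyThreshold <= 0)
    return("energyThreshold must be positive")
  if (!is.na(object@riskBeta) && object@riskBeta < 0)
    return("riskBeta must be non-negative")
  TRUE
})

#' Construct a MovementConfig
#'
#' @param mechanisms character subset of \code{c("energy", "attraction",
#'   "risk")}.
#' @param scaleN odd focal window size (1, 3, 5 or 7 in the standard
#'   experiment).
#' @param scaleFn focal statistic (\code{"mean"}, \code{"max"},
#'   \code{"min"}).
#' @param autocorrC autocorrelation parameter C in \code{[0, 1]}.
#' @param destBiasD destination bias parameter D in \code{[0, 1]}.
#' @param destination optional \code{(row, col)} destination; required
#'   when \code{destBiasD > 0} unless the caller (e.g.
#'   [simulateDensity()]) supplies per-path destinations.
#' @param energyThreshold,riskBeta,maxSteps,riskSurface see
#'   [MovementConfig-class].
#' @return a validated [MovementConfig-class].
#' @examples
#' movementConfig(c("energy", "attraction"), scaleN = 3, autocorrC = 0.35)
#' @export
movementConfig <- function(mechanisms = character(), scaleN = 1L,
                           scaleFn = "mean", autocorrC = 0,
                           destBiasD = 0, destination = NULL,
                           energyThreshold = NA_real_, riskBeta = NA_real_,
                           maxSteps = 500L, riskSurface = NULL) {
  new("MovementConfig", mechanisms = as.character(mechanisms),
      scaleN = as.integer(scaleN), scaleFn = scaleFn,
      autocorrC = as.numeric(autocorrC), destBiasD = as.numeric(destBiasD),
      destination = as.integer(destination %||% integer()),
      energyThreshold = as.numeric(energyThreshold),
      riskBeta = as.numeric(riskBeta), maxSteps = as.integer(maxSteps),
      riskSurface = riskSurface)
}

setMethod("show", "MovementConfig", function(object) {
  mech <- if (length(object@mechanisms)) paste(object@mechanisms, collapse = "+") else "none"
  cat(sprintf("MovementConfig: mechanisms=%s scale=%dx%d(%s) C=%.2g D=%.2g maxSteps=%d\n",
              mech, object@scaleN, object@scaleN, object@scaleFn,
              object@autocorrC, object@destBiasD, object@maxSteps))
})

## Resolve a config against a concrete surface: apply the focal scaling
## once, fix the risk layer and fill in automatic E and beta. The walk
## itself only ever sees the scaled surfaces.
.resolveConfig <- function(surface, config) {
  res <- .asGrid(focalScale(surface, config@scaleN, config@scaleFn))
  riskIn <- config@riskSurface %||% res
  risk <- .asGrid(if (identical(riskIn, res)) res
                  else focalScale(riskIn, config@scaleN, config@scaleFn))
  riskMax <- max(risk)
  E <- config@energyThreshold
  if (is.na(E)) E <- 250 * median(res)
  beta <- config@riskBeta
  if (is.na(beta)) beta <- log(2) / (250 * median(risk) / riskMax)
  list(res = res, risk = risk, riskMax = riskMax, E = E, beta = beta,
       energy = "energy" %in% config@mechanisms,
       attraction = "attraction" %in% config@mechanisms,
       riskOn = "risk" %in% config@mechanisms)
}

#' Single-step transition distribution of the walker
#'
#' Reference implementation of the neighbour-choice rule (the compiled
#' walker uses the identical rule). Returns the probability of moving
#' to each admissible Moore neighbour of \code{current}.
#'
#' @param current integer \code{(row, col)} position.
#' @param prevDir previous direction as an index 1..8 into the fixed
#'   neighbour order (row-major over offsets
#'   \code{(-1,-1) ... (1,1)}), or \code{NULL} on the first step.
#' @param config a [MovementConfig-class]; its \code{destination} must
#'   be set when \code{destBiasD > 0}.
#' @param scaledSurface the focal-scaled resistance grid the walker
#'   perceives (matrix or [ResistanceSurface-class]).
#' @return data frame with columns \code{row}, \code{col}, \code{dir}
#'   (neighbour order index) and \code{prob}; probabilities sum to 1.
#' @examples
#' cfg <- movementConfig("attraction")
#' stepDistribution(c(5, 5), NULL, cfg, matrix(1, 9, 9))
#' @export
stepDistribution <- function(current, prevDir, config, scaledSurface) {
  m <- .asGrid(scaledSurface)
  nr <- nrow(m); nc <- ncol(m)
  if (nr * nc < 2L) stop("degenerate grid: no admissible neighbours")
  r <- current[1L]; c <- current[2L]
  nbr <- cbind(row = r + .MOORE[, 1L], col = c + .MOORE[, 2L], dir = 1:8)
  ok <- nbr[, 1L] >= 1L & nbr[, 1L] <= nr & nbr[, 2L] >= 1L & nbr[, 2L] <= nc
  nbr <- nbr[ok, , drop = FALSE]
  if (nrow(nbr) == 0L) stop("degenerate state: no admissible neighbours")
  D <- config@destBiasD
  Cp <- config@autocorrC * (1 - D)
  w <- if ("attraction" %in% config@mechanisms)
    1 / m[cbind(nbr[, 1L], nbr[, 2L])] else rep(1, nrow(nbr))
  pMech <- w / sum(w)
  contAt <- if (!is.null(prevDir)) match(prevDir, nbr[, "dir"]) else NA_integer_
  mechMass <- 1 - D - if (!is.na(contAt)) Cp else 0  # fold C' when no continuation
  p <- mechMass * pMech
  if (!is.na(contAt)) p[contAt] <- p[contAt] + Cp
  if (D > 0) {
    if (length(config@destination) != 2L)
      stop("destBiasD > 0 requires a destination")
    d2 <- (nbr[, 1L] - config@destination[1L])^2 +
          (nbr[, 2L] - config@destination[2L])^2
    p[which.min(d2)] <- p[which.min(d2)] + D
  }
  data.frame(row = nbr[, 1L], col = nbr[, 2L], dir = nbr[, 3L], prob = p)
}

#' Simulate one stochastic movement path
#'
#' Runs the biased random walk from \code{source} until the energy
#' budget is exhausted, a per-step mortality event occurs, the
#' destination is reached, or the step cap fires -- whichever happens
#' first. Energy accounting uses the shared cost convention
#' \code{len * (r_i + r_j) / 2} per move (len = sqrt(2) on diagonals);
#' a move whose cost would reach the budget terminates the walk without
#' being taken. Mortality on arrival at pixel j occurs with probability
#' \code{1 - exp(-beta * risk_j / max(risk))}.
#'
#' @param surface a [ResistanceSurface-class] or matrix.
#' @param source integer \code{(row, col)} start pixel.
#' @param config a [MovementConfig-class].
#' @param seed integer seed; paths are reproducible in isolation.
#' @return a list with \code{coords} (matrix of 1-based \code{(row,
#'   col)}, first row = source), \code{termination_reason} (one of
#'   \code{"step_cap"}, \code{"energy_exhausted"}, \code{"mortality"},
#'   \code{"destination_reached"}).
#' @examples
#' s <- resistanceSurface(matrix(1, 32, 32))
#' p <- simulatePath(s, c(16, 16), movementConfig(), seed = 1)
#' nrow(p$coords)  # step cap + 1
#' @export
simulatePath <- function(surface, source, config, seed = 1L) {
  ctx <- .resolveConfig(surface, config)
  source <- .checkSources(matrix(source, 1L), nrow(ctx$res), ncol(ctx$res))
  set.seed(seed %% 2147483629)
  .walkOne(ctx, config, source[1L, ], config@destination)
}

.walkOne <- function(ctx, config, source, destination) {
  dest <- if (length(destination) == 2L) destination else c(-1L, -1L)
  if (config@destBiasD > 0 && dest[1L] < 0L)
    stop("destBiasD > 0 requires a destination")
  out <- .cpp_walk_path(ctx$res, ctx$risk,
                        source[1L] - 1L, source[2L] - 1L,
                        dest[1L] - 1L, dest[2L] - 1L,
                        ctx$energy, ctx$attraction, ctx$riskOn,
                        config@autocorrC, config@destBiasD,
                        ctx$E, ctx$beta, ctx$riskMax, config@maxSteps)
  list(coords = out$coords + 1L, termination_reason = out$reason)
}

#' Aggregate many simulated paths into a density-of-movement surface
#'
#' Runs \code{pathsPerSource} paths from every source and counts pixel
#' visits (repeated visits count multiply). This is the "true"
#' connectivity surface against which model predictions are scored.
#' Seeding is hierarchical: each (source, replicate) pair gets its own
#' sub-seed derived from \code{seed}, so any individual path can be
#' reproduced in isolation.
#'
#' When \code{destBiasD > 0} and the config carries no fixed
#' destination, each path is assigned a destination drawn uniformly
#' from the other source points (under the same per-path sub-seed).
#'
#' @param surface a [ResistanceSurface-class] or matrix.
#' @param sources integer matrix of \code{(row, col)} source pixels.
#' @param config a [MovementConfig-class].
#' @param pathsPerSource replicate paths per source (>= 1).
#' @param seed integer master seed for this scenario.
#' @return a [DensitySurface-class]; the sum of its counts equals the
#'   total number of path coordinates aggregated.
#' @export
simulateDensity <- function(surface, sources, config, pathsPerSource = 100L,
                            seed = 1L) {
  if (pathsPerSource < 1) stop("pathsPerSource must be >= 1")
  ctx <- .resolveConfig(surface, config)
  nr <- nrow(ctx$res); nc <- ncol(ctx$res)
  sources <- .checkSources(sources, nr, nc)
  nS <- nrow(sources)
  counts <- matrix(0, nr, nc)
  pickDest <- config@destBiasD > 0 && length(config@destination) != 2L
  if (pickDest && nS < 2L)
    stop("per-path destinations require at least two sources")
  total <- 0L
  for (s in seq_len(nS)) {
    for (rep in seq_len(pathsPerSource)) {
      idx <- (s - 1L) * pathsPerSource + rep
      set.seed(.subSeed(seed, idx))
      dest <- config@destination
      if (pickDest) {
        others <- setdiff(seq_len(nS), s)
        dest <- sources[others[sample.int(length(others), 1L)], ]
      }
      p <- .walkOne(ctx, config, sources[s, ], dest)
      .cpp_accumulate_path(p$coords - 1L, counts)
      total <- total + 1L
    }
  }
  densitySurface(counts, nPaths = total)
}

#' Expected number of steps of a walk before termination
#'
#' First-order estimate of how many moves a walker makes under a
#' configuration, on typical (median) terrain: the step cap, shortened
#' by the energy budget (mean move cost is about 1.207 times the local
#' resistance: the average of cardinal and diagonal move lengths) and
#' by the expected lifetime under the per-step mortality hazard at
#' median risk. Used to tie the resistant-kernel dispersal threshold to
#' the scenario's dispersal ability (see [kernelThreshold()]).
#'
#' @param surface a [ResistanceSurface-class] or matrix (unscaled; the
#'   config's focal scaling is applied internally).
#' @param config a [MovementConfig-class].
#' @return expected step count (capped at \code{maxSteps}).
#' @export
expectedPathSteps <- function(surface, config) {
  ctx <- .resolveConfig(surface, config)
  med <- median(ctx$res)
  sEnergy <- if (ctx$energy) ctx$E / (1.207 * med) else Inf
  sRisk <- if (ctx$riskOn) {
    h <- 1 - exp(-ctx$beta * median(ctx$risk) / ctx$riskMax)
    if (h > 0) 1 / h else Inf
  } else Inf
  min(config@maxSteps, sEnergy, sRisk)
}

## deterministic sub-seed derivation, kept within 32-bit integer range
.subSeed <- function(seed, i) {
  as.integer((as.numeric(seed %% 2147483629) + 48271 * as.numeric(i)) %% 2147483629)
}
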