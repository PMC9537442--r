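## Orchestration of the factorial simulation experiment: scenario grid
## construction, simulation, prediction, scoring and table assembly,
## with hierarchical reproducible seeding and optional on-disk
## resumability.

.MECHANISMS <- list("energy", "attraction", "risk",
                    c("energy", "attraction"), c("energy", "risk"),
                    c("attraction", "risk"),
                    c("energy", "attraction", "risk"))

.mechLabel <- function(m) paste(substr(m, 1L, 1L), collapse = "")

#' ExperimentConfig: the full specification of one factorial experiment
#'
#' The first analysis crosses all 7 resistance surfaces with the 7
#' movement-mechanism combinations, 4 spatial scales, 3 scaling
#' functions and 3 autocorrelation levels (1764 scenarios, no
#' destination bias). The second analysis fixes scale (1), scaling
#' function (mean) and autocorrelation (0.2) and crosses surfaces and
#' mechanisms with 3 destination-bias levels (147 scenarios).
#'
#' @slot analysis \code{"first"} or \code{"second"}.
#' @slot nrows,ncols grid dimensions.
#' @slot nSurfaces number of resistance surfaces.
#' @slot nSources number of source points.
#' @slot pathsPerSource replicate paths per source.
#' @slot surfaceSeed seed for [generateSurfaceSuite()].
#' @slot masterSeed seed from which source sampling and every scenario
#'   sub-seed are derived.
#' @slot mechanisms list of mechanism combinations.
#' @slot scaleN,scaleFn,Cvals,Dvals factor levels.
#' @slot models character subset of \code{c("flcp", "kernels",
#'   "circuit")}.
#' @slot outputDir optional directory for persisted rasters and the
#'   (resumable) scenario CSV; \code{NA} keeps everything in memory.
#' @seealso [experimentConfig()], [runExperiment()]
#' @export
setClass("ExperimentConfig",
  representation(analysis = "character", nrows = "integer", ncols = "integer",
                 nSurfaces = "integer", nSources = "integer",
                 pathsPerSource = "integer", surfaceSeed = "integer",
                 masterSeed = "integer", mechanisms = "list",
                 scaleN = "integer", scaleFn = "character",
                 Cvals = "numeric", Dvals = "numeric",
                 models = "character", outputDir = "character"))

setValidity("ExperimentConfig", function(object) {
  if (!(object@analysis %in% c("first", "second")))
    return("analysis must be 'first' or 'second'")
  if (object@nrows < 8L || object@ncols < 8L) return("grid must be at least 8x8")
  if (!all(object@models %in% c("flcp", "kernels", "circuit")))
    return("unknown model tag")
  if (object@analysis == "first" && any(object@Dvals != 0))
    return("the first analysis has no destination bias")
  if (object@analysis == "second" && any(object@Dvals <= 0))
    return("the second analysis requires positive destination bias levels")
  TRUE
})

#' Construct an ExperimentConfig
#'
#' Defaults reproduce the standard factorial design at full scale
#' (256x256 grids, 100 sources, 100 paths per source: 10,000 paths per
#' scenario). See [deskProfile()] for a reduced profile.
#'
#' @param analysis \code{"first"} (vary mechanism, scale, scaling
#'   function, autocorrelation; 1764 scenarios) or \code{"second"}
#'   (vary mechanism and destination bias; 147 scenarios).
#' @param nrows,ncols,nSurfaces,nSources,pathsPerSource experiment
#'   sizes; defaults are the full-scale design.
#' @param surfaceSeed,masterSeed integer seeds.
#' @param models which predictors to score.
#' @param outputDir optional output directory (enables resumability).
#' @param scaleN,scaleFn,Cvals,Dvals,mechanisms factor levels;
#'   defaults follow the analysis chosen.
#' @return an [ExperimentConfig-class].
#' @examples
#' experimentConfig("first")           # 1764-scenario design
#' experimentConfig("second")          # 147-scenario design
#' @export
experimentConfig <- function(analysis = c("first", "second"),
                             nrows = 256L, ncols = 256L, nSurfaces = 7L,
                             nSources = 100L, pathsPerSource = 100L,
                             surfaceSeed = 1L, masterSeed = 1L,
                             models = c("flcp", "kernels", "circuit"),
                             outputDir = NA_character_,
                             scaleN = NULL, scaleFn = NULL,
                             Cvals = NULL, Dvals = NULL,
                             mechanisms = .MECHANISMS) {
  analysis <- match.arg(analysis)
  if (analysis == "first") {
    scaleN <- scaleN %||% c(1L, 3L, 5L, 7L)
    scaleFn <- scaleFn %||% c("mean", "max", "min")
    Cvals <- Cvals %||% c(0, 0.35, 0.75)
    Dvals <- Dvals %||% 0
  } else {
    scaleN <- scaleN %||% 1L
    scaleFn <- scaleFn %||% "mean"
    Cvals <- Cvals %||% 0.2
    Dvals <- Dvals %||% c(0.1, 0.3, 0.6)
  }
  new("ExperimentConfig", analysis = analysis,
      nrows = as.integer(nrows), ncols = as.integer(ncols),
      nSurfaces = as.integer(nSurfaces), nSources = as.integer(nSources),
      pathsPerSource = as.integer(pathsPerSource),
      surfaceSeed = as.integer(surfaceSeed),
      masterSeed = as.integer(masterSeed), mechanisms = mechanisms,
      scaleN = as.integer(scaleN), scaleFn = scaleFn,
      Cvals = Cvals, Dvals = Dvals, models = models,
      outputDir = outputDir)
}

#' Reduced desk profile of the standard experiment
#'
#' Same factor structure as [experimentConfig()] but on 64x64 grids
#' with 25 sources and 10 paths per source, sized so a full analysis
#' slice runs on a single CPU in minutes.
#'
#' @inheritParams experimentConfig
#' @param ... passed through to [experimentConfig()].
#' @return an [ExperimentConfig-class].
#' @export
deskProfile <- function(analysis = c("first", "second"), ...) {
  experimentConfig(analysis = match.arg(analysis), nrows = 64L, ncols = 64L,
                   nSources = 25L, pathsPerSource = 10L, ...)
}

setMethod("show", "ExperimentConfig", function(object) {
  sc <- nrow(enumerateScenarios(object))
  cat(sprintf("ExperimentConfig (%s analysis): %d scenarios\n",
              object@analysis, sc))
  cat(sprintf("  %dx%d grid, %d surfaces, %d sources x %d paths, models: %s\n",
              object@nrows, object@ncols, object@nSurfaces, object@nSources,
              object@pathsPerSource, paste(object@models, collapse = ", ")))
})

#' Enumerate the scenario grid of an experiment
#'
#' Expands the full Cartesian grid of factor levels in a deterministic
#' order with stable scenario identifiers.
#'
#' @param config an [ExperimentConfig-class].
#' @return data frame with columns \code{scenario_id},
#'   \code{surface_id} (1-based), \code{mechanism} (label such as
#'   \code{"ear"}), \code{scale_n}, \code{scale_fn}, \code{C},
#'   \code{D}.
#' @examples
#' nrow(enumerateScenarios(experimentConfig("first")))   # 1764
#' nrow(enumerateScenarios(experimentConfig("second")))  # 147
#' @export
enumerateScenarios <- function(config) {
  mechLabels <- vapply(config@mechanisms, .mechLabel, "")
  g <- expand.grid(D = config@Dvals, C = config@Cvals,
                   scale_fn = config@scaleFn, scale_n = config@scaleN,
                   mechanism = mechLabels,
                   surface_id = seq_len(config@nSurfaces),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("surface_id", "mechanism", "scale_n", "scale_fn", "C", "D")]
  g$scenario_id <- sprintf("surf%d_%s_n%d_%s_C%g_D%g", g$surface_id,
                           g$mechanism, g$scale_n, g$scale_fn, g$C, g$D)
  g[, c("scenario_id", "surface_id", "mechanism", "scale_n", "scale_fn",
        "C", "D")]
}

.mechFromLabel <- function(lab) {
  map <- c(e = "energy", a = "attraction", r = "risk")
  unname(map[strsplit(lab, "")[[1L]]])
}

#' Run a factorial connectivity evaluation experiment
#'
#' For every scenario: simulate the density-of-movement surface
#' (\code{pathsPerSource} paths from each source), score the requested
#' connectivity model predictions against it, and append one row per
#' model to the scenario table. Predictions that depend only on the
#' surface (least-cost paths, circuit) are computed once per surface
#' and reused; the resistant-kernel threshold is tied to the scenario's
#' energy budget and recomputed from cached per-source cost distances.
#' Deterministic given the config's seeds. With an \code{outputDir}
#' the scenario CSV is written incrementally and completed scenarios
#' are skipped on re-run.
#'
#' @param config an [ExperimentConfig-class].
#' @param verbose print per-scenario progress.
#' @return the scenario table: one row per scenario x model with the
#'   factor levels, \code{model}, \code{rmse}, \code{pearson},
#'   \code{overlap} and the scenario seed.
#' @export
runExperiment <- function(config, verbose = FALSE) {
  scen <- enumerateScenarios(config)
  surfaces <- generateSurfaceSuite(config@nrows, config@ncols,
                                   config@nSurfaces, config@surfaceSeed)
  sources <- sampleSources(config@nSources, config@nrows, config@ncols,
                           seed = config@masterSeed)
  csvPath <- NA_character_
  done <- character()
  if (!is.na(config@outputDir)) {
    dir.create(config@outputDir, showWarnings = FALSE, recursive = TRUE)
    csvPath <- file.path(config@outputDir, "scenario_table.csv")
    if (file.exists(csvPath)) done <- unique(read.csv(csvPath)$scenario_id)
  }
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(scen))
  for (i in seq_len(nrow(scen))) {
    sc <- scen[i, ]
    if (sc$scenario_id %in% done) next
    sid <- sc$surface_id
    key <- paste0("s", sid)
    if (is.null(cache[[key]])) {
      surf <- gridValues(surfaces[[sid]])
      pred <- list()
      if ("flcp" %in% config@models) pred$flcp <- factorialLCP(surf, sources)
      if ("circuit" %in% config@models) pred$circuit <- circuitCurrent(surf, sources)
      cdStack <- if ("kernels" %in% config@models)
        lapply(seq_len(nrow(sources)), function(s)
          costDistance(surf, sources[s, , drop = FALSE]))
      cache[[key]] <- list(surf = surf, pred = pred, cdStack = cdStack)
    }
    ce <- cache[[key]]
    cfg <- movementConfig(.mechFromLabel(sc$mechanism), scaleN = sc$scale_n,
                          scaleFn = sc$scale_fn, autocorrC = sc$C,
                          destBiasD = sc$D)
    ## content-addressed scenario seed: stable under re-ordering,
    ## resumption and factor-subset runs
    scenSeed <- .subSeed(config@masterSeed, .stringHash(sc$scenario_id))
    truth <- simulateDensity(ce$surf, sources, cfg,
                             pathsPerSource = config@pathsPerSource,
                             seed = scenSeed)
    preds <- ce$pred
    if ("kernels" %in% config@models) {
      scaled <- .asGrid(focalScale(ce$surf, sc$scale_n, sc$scale_fn))
      Tthr <- kernelThreshold(ce$cdStack,
                              steps = expectedPathSteps(ce$surf, cfg),
                              medianResistance = median(scaled))
      preds$kernels <- resistantKernels(ce$surf, sources, threshold = Tthr,
                                        cdStack = ce$cdStack)
    }
    out <- lapply(config@models, function(modelName) {
      st <- compareSurfaces(truth, preds[[modelName]])
      data.frame(sc, model = modelName, rmse = st[["rmse"]],
                 pearson = st[["pearson"]], overlap = st[["overlap"]],
                 seed = scenSeed, row.names = NULL)
    })
    res <- do.call(rbind, out)
    rows[[i]] <- res
    if (!is.na(csvPath))
      write.table(res, csvPath, sep = ",", append = file.exists(csvPath),
                  col.names = !file.exists(csvPath), row.names = FALSE)
    if (verbose)
      message(sprintf("[%d/%d] %s", i, nrow(scen), sc$scenario_id))
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (!is.na(csvPath)) tab <- read.csv(csvPath)
  ## stable ordering for determinism across resumed runs
  tab <- tab[order(match(tab$scenario_id, scen$scenario_id),
                   match(tab$model, config@models)), ]
  rownames(tab) <- NULL
  tab
}

## small deterministic polynomial string hash, exact in double
## arithmetic and kept inside 2^31
.stringHash <- function(s) {
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483629
  as.integer(h)
}

#' Pooled accuracy means per model
#'
#' Convenience summary of a scenario table: the mean of each accuracy
#' statistic by model, as reported in comparative evaluations.
#'
#' @param table a scenario table from [runExperiment()].
#' @return data frame with one row per model.
#' @export
summarizeByModel <- function(table) {
  agg <- aggregate(table[, c("rmse", "pearson", "overlap")],
                   by = list(model = table$model), FUN = mean)
  agg[order(match(agg$model, c("flcp", "kernels", "circuit"))), ]
}
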