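## Lightweight base-graphics summaries of experiment output.

#' Grouped boxplots of an accuracy statistic
#'
#' @param table scenario table from [runExperiment()].
#' @param statistic one of \code{"rmse"}, \code{"pearson"},
#'   \code{"overlap"}.
#' @param by grouping column (default \code{"model"}).
#' @param ... passed to [graphics::boxplot()].
#' @return invisibly, the boxplot statistics.
#' @export
scenarioBoxplots <- function(table, statistic = c("rmse", "pearson", "overlap"),
                             by = "model", ...) {
  statistic <- match.arg(statistic)
  invisible(boxplot(table[[statistic]] ~ table[[by]],
                    xlab = by, ylab = statistic, ...))
}

#' Ordination triplot
#'
#' Plots response loadings (arrows) and factor-level centroids of a
#' constrained ordination on its first two axes.
#'
#' @param x an [OrdinationResult-class].
#' @param y unused.
#' @param ... passed to [graphics::plot()].
#' @export
setMethod("plot", signature(x = "OrdinationResult", y = "missing"),
  function(x, y, ...) {
    sc <- x@siteScores
    if (ncol(sc) < 2L) sc <- cbind(sc, 0)
    plot(sc[, 1L], sc[, 2L], pch = ".", col = "grey60",
         xlab = sprintf("axis 1 (%.1f%%)",
                        100 * x@eigConstrained[1L] / x@totalInertia),
         ylab = if (length(x@eigConstrained) > 1L)
           sprintf("axis 2 (%.1f%%)",
                   100 * x@eigConstrained[2L] / x@totalInertia) else "axis 2",
         ...)
    abline(h = 0, v = 0, lty = 3, col = "grey80")
    rs <- x@responseScores
    if (ncol(rs) < 2L) rs <- cbind(rs, 0)
    mult <- 0.8 * max(abs(sc)) / max(abs(rs))
    arrows(0, 0, rs[, 1L] * mult, rs[, 2L] * mult, length = 0.08, col = "red3")
    text(rs[, 1L] * mult * 1.08, rs[, 2L] * mult * 1.08, rownames(rs),
         col = "red3", cex = 0.8)
    for (f in names(x@centroids)) {
      ctr <- x@centroids[[f]]
      if (ncol(ctr) < 2L) ctr <- cbind(ctr, 0)
      points(ctr[, 1L], ctr[, 2L], pch = 3, col = "blue3")
      text(ctr[, 1L], ctr[, 2L], paste(f, rownames(ctr), sep = ":"),
           pos = 3, cex = 0.7, col = "blue3")
    }
    invisible(NULL)
  })
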