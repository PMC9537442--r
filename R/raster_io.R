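## ESRI ASCII grid and CSV interchange. The ASCII grid format stores the
## raster top row first, which matches the in-memory convention here.

#' Write a grid to an ESRI ASCII raster file
#'
#' @param x a surface object or numeric matrix (row 1 = top of raster).
#' @param file output path (conventionally \code{.asc}).
#' @param xllcorner,yllcorner,cellsize georeferencing of the lower-left
#'   corner; defaults describe a unit-cell grid at the origin.
#' @param nodata value written for \code{NA} cells.
#' @return invisibly, the file path.
#' @export
writeAsciiGrid <- function(x, file, xllcorner = 0, yllcorner = 0,
                           cellsize = 1, nodata = -9999) {
  m <- .asGrid(x)
  hdr <- sprintf(
    "ncols %d\nnrows %d\nxllcorner %.10g\nyllcorner %.10g\ncellsize %.10g\nNODATA_value %.10g",
    ncol(m), nrow(m), xllcorner, yllcorner, cellsize, nodata)
  m[is.na(m)] <- nodata
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(format(m, trim = TRUE, digits = 15, scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read an ESRI ASCII raster file
#'
#' @param file path to a \code{.asc} file.
#' @return a numeric matrix (row 1 = top of raster) with attributes
#'   \code{xllcorner}, \code{yllcorner}, \code{cellsize}; nodata cells
#'   become \code{NA}.
#' @export
readAsciiGrid <- function(file) {
  lines <- readLines(file)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  attr(m, "xllcorner") <- hdr$xllcorner %||% 0
  attr(m, "yllcorner") <- hdr$yllcorner %||% 0
  attr(m, "cellsize") <- hdr$cellsize %||% 1
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write/read source points as CSV
#'
#' Two-column CSV with header \code{row,col}, 1-based coordinates.
#'
#' @param sources integer matrix with columns \code{row}, \code{col}.
#' @param file path.
#' @return \code{writeSources}: invisibly the path; \code{readSources}:
#'   an integer matrix with columns \code{row}, \code{col}.
#' @export
writeSources <- function(sources, file) {
  write.csv(as.data.frame(sources), file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeSources
#' @export
readSources <- function(file) {
  df <- read.csv(file)
  cbind(row = as.integer(df$row), col = as.integer(df$col))
}

#' Flatten simulated paths to a long-format data frame
#'
#' @param paths a list of paths as returned by [simulatePath()].
#' @return data frame with columns \code{path_id}, \code{step},
#'   \code{row}, \code{col}, \code{termination_reason}, suitable for
#'   \code{write.csv}.
#' @export
pathsToDataFrame <- function(paths) {
  if (!is.null(paths$coords)) paths <- list(paths)
  do.call(rbind, lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    data.frame(path_id = i, step = seq_len(nrow(p$coords)) - 1L,
               row = p$coords[, 1L], col = p$coords[, 2L],
               termination_reason = p$termination_reason)
  }))
}
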