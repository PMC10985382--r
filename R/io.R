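#' Read a suitability raster from a text grid
#'
#' Two plain-text dialects are supported: an ESRI ASCII grid (six-line header
#' `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` followed by the
#' rows, top row first) and a headerless whitespace-delimited grid with a
#' declared nodata sentinel. Values are validated to \[0, 1\] after masking
#' nodata; out-of-range values raise an error naming the offending range.
#'
#' @param path path to the text grid.
#' @param nodata nodata sentinel for the headerless dialect (default -9999);
#'   ignored when the file carries an ESRI header.
#' @return a [suitability_grid()]; ESRI headers populate the `extent`
#'   attribute, headerless grids are index-addressed only.
#' @export
read_raster <- function(path, nodata = -9999) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (grepl("^\\s*ncols", first, ignore.case = TRUE)) {
    hdr <- readLines(path, n = 6L)
    kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
    keys <- tolower(kv[, 1]); vals <- as.numeric(kv[, 2])
    names(vals) <- keys
    m <- as.matrix(utils::read.table(path, skip = 6L))
    dimnames(m) <- NULL
    if (nrow(m) != vals["nrows"] || ncol(m) != vals["ncols"])
      stop("grid body does not match header dimensions", call. = FALSE)
    m[m == vals["nodata_value"]] <- NA_real_
    extent <- list(xll = unname(vals["xllcorner"]),
                   yll = unname(vals["yllcorner"]),
                   cellsize = unname(vals["cellsize"]))
  } else {
    m <- as.matrix(utils::read.table(path))
    dimnames(m) <- NULL
    m[m == nodata] <- NA_real_
    extent <- NULL
  }
  suitability_grid(m, extent = extent)
}

#' Write a grid as an ESRI ASCII text raster
#'
#' Works for both continuous suitability grids and 0/1 binary maps produced
#' by [apply_threshold()]; nodata cells are written as the sentinel. Grids
#' without an extent get a unit-cell extent anchored at the origin.
#'
#' @param grid a [suitability_grid()] or a (possibly binary) matrix.
#' @param path output path.
#' @param nodata nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, nodata = -9999) {
  m <- unclass(grid)
  attr(m, "n_valid") <- NULL
  extent <- attr(grid, "extent")
  attr(m, "extent") <- NULL
  if (is.null(extent)) extent <- list(xll = 0, yll = 0, cellsize = 1)
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", extent$xll),
    sprintf("yllcorner %.10g", extent$yll),
    sprintf("cellsize %.10g", extent$cellsize),
    sprintf("NODATA_value %.10g", nodata)), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read presence points from CSV
#'
#' In `"index"` mode the file needs columns `row`, `col` (grid indices;
#' `index_base = 0` means row 0 is the raster's top line, the convention of
#' the command-line interface; `index_base = 1` matches R matrices). In
#' `"coordinate"` mode it needs `x`, `y`, which are mapped to cells through
#' the grid's extent with cell-center registration (a coordinate anywhere in
#' a cell, including its center, maps to that cell).
#'
#' @param path CSV path with a header line.
#' @param grid the [suitability_grid()] the points refer to.
#' @param mode `"index"` or `"coordinate"`.
#' @param index_base 0 or 1; origin of the row/col indices in the file.
#' @param ... passed to [extract_suitability()] (e.g. `on_nodata`).
#' @return a `presence_points` object (see [extract_suitability()]).
#' @export
read_points <- function(path, grid, mode = c("index", "coordinate"),
                        index_base = 0, ...) {
  mode <- match.arg(mode)
  grid <- as_suitability_grid(grid)
  d <- utils::read.csv(path)
  if (mode == "index") {
    if (!all(c("row", "col") %in% names(d)))
      stop("index mode expects CSV columns `row`, `col`; found: ",
           paste(names(d), collapse = ", "), call. = FALSE)
    if (!index_base %in% c(0, 1))
      stop("`index_base` must be 0 or 1", call. = FALSE)
    pts <- data.frame(row = d$row + (1 - index_base),
                      col = d$col + (1 - index_base))
  } else {
    if (!all(c("x", "y") %in% names(d)))
      stop("coordinate mode expects CSV columns `x`, `y`; found: ",
           paste(names(d), collapse = ", "), call. = FALSE)
    e <- attr(grid, "extent")
    if (is.null(e))
      stop("grid has no extent; coordinate mode unavailable", call. = FALSE)
    col <- floor((d$x - e$xll) / e$cellsize) + 1
    row <- nrow(grid) - floor((d$y - e$yll) / e$cellsize)
    out <- which(col < 1 | col > ncol(grid) | row < 1 | row > nrow(grid))
    if (length(out))
      stop(sprintf("point %d at (x=%g, y=%g) is outside the grid extent",
                   out[1], d$x[out[1]], d$y[out[1]]), call. = FALSE)
    pts <- data.frame(row = row, col = col)
  }
  extract_suitability(grid, pts, ...)
}
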