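#' Suitability grid
#'
#' Container for a continuous habitat-suitability surface, the usual output
#' of a species distribution model. Values live on a regular raster grid,
#' lie in \[0, 1\], and cells outside the study area are `NA` (nodata).
#'
#' @param values numeric matrix of suitability values in \[0, 1\]; `NA` marks
#'   nodata cells. Row 1 is the top line of the raster.
#' @param extent optional georeferencing as a named list or vector with
#'   `xll`, `yll`, `cellsize` (lower-left corner of the grid and square cell
#'   size). When absent the grid is addressed by (row, col) indices only.
#' @return an object of class `suitability_grid`: the matrix with attributes
#'   `n_valid` (count of non-`NA` cells) and optional `extent`.
#' @examples
#' g <- suitability_grid(matrix(runif(100), 10, 10))
#' n_valid(g)
#' @export
suitability_grid <- function(values, extent = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  v <- values[!is.na(values)]
  if (length(v) == 0L)
    stop("grid has no valid (non-NA) cells", call. = FALSE)
  if (any(v < 0 | v > 1)) {
    rng <- range(v)
    stop(sprintf(
      "suitability values must lie in [0, 1]; observed range [%g, %g]",
      rng[1], rng[2]), call. = FALSE)
  }
  if (!is.null(extent)) {
    extent <- as.list(extent)
    need <- c("xll", "yll", "cellsize")
    if (!all(need %in% names(extent)))
      stop("`extent` needs named entries xll, yll, cellsize", call. = FALSE)
    if (extent$cellsize <= 0) stop("cellsize must be positive", call. = FALSE)
    extent <- extent[need]
  }
  structure(values, class = c("suitability_grid", "matrix"),
            n_valid = length(v), extent = extent)
}

#' @rdname suitability_grid
#' @param x a `suitability_grid`
#' @export
n_valid <- function(x) {
  nv <- attr(x, "n_valid")
  if (is.null(nv)) sum(!is.na(x)) else nv
}

#' @export
print.suitability_grid <- function(x, ...) {
  v <- x[!is.na(x)]
  cat(sprintf("suitability_grid: %d x %d cells, %d valid\n",
              nrow(x), ncol(x), length(v)))
  cat(sprintf("  values: min %.4f, median %.4f, max %.4f\n",
              min(v), stats::median(v), max(v)))
  if (!is.null(attr(x, "extent"))) {
    e <- attr(x, "extent")
    cat(sprintf("  extent: xll %g, yll %g, cellsize %g\n",
                e$xll, e$yll, e$cellsize))
  }
  invisible(x)
}

as_suitability_grid <- function(x) {
  if (inherits(x, "suitability_grid")) x else suitability_grid(as.matrix(x))
}

#' Extract suitability values at presence points
#'
#' Looks up the grid value under each occurrence record. Points are given as
#' 1-based (row, col) cell indices (row 1 = top line). Points falling outside
#' the grid always raise an error identifying the offender; points on nodata
#' cells either raise an error or are dropped with a warning.
#'
#' @param grid a [suitability_grid()] (or bare matrix).
#' @param points a two-column matrix or data frame of (row, col) indices, or
#'   a data frame with columns `row` and `col`.
#' @param on_nodata `"error"` (default) or `"drop"`: what to do with points
#'   on nodata cells.
#' @return an object of class `presence_points`: a data frame with columns
#'   `row`, `col`, `suitability`, input order preserved.
#' @export
extract_suitability <- function(grid, points, on_nodata = c("error", "drop")) {
  grid <- as_suitability_grid(grid)
  on_nodata <- match.arg(on_nodata)
  pts <- as.data.frame(points)
  if (all(c("row", "col") %in% names(pts))) {
    pts <- pts[, c("row", "col")]
  } else if (ncol(pts) >= 2L) {
    pts <- pts[, 1:2]
    names(pts) <- c("row", "col")
  } else stop("`points` must have two columns (row, col)", call. = FALSE)
  if (nrow(pts) == 0L) stop("no points supplied", call. = FALSE)
  pts$row <- as.integer(pts$row); pts$col <- as.integer(pts$col)
  bad <- which(pts$row < 1L | pts$row > nrow(grid) |
               pts$col < 1L | pts$col > ncol(grid))
  if (length(bad))
    stop(sprintf("point %d at (row %d, col %d) is outside the %d x %d grid",
                 bad[1], pts$row[bad[1]], pts$col[bad[1]],
                 nrow(grid), ncol(grid)), call. = FALSE)
  s <- grid[cbind(pts$row, pts$col)]
  nod <- which(is.na(s))
  if (length(nod)) {
    if (on_nodata == "error")
      stop(sprintf("point %d at (row %d, col %d) lies on a nodata cell",
                   nod[1], pts$row[nod[1]], pts$col[nod[1]]), call. = FALSE)
    warning(sprintf("dropping %d point(s) on nodata cells", length(nod)),
            call. = FALSE)
    pts <- pts[-nod, , drop = FALSE]
    s <- s[-nod]
    if (nrow(pts) == 0L) stop("all points fell on nodata cells", call. = FALSE)
  }
  pts$suitability <- s
  structure(pts, class = c("presence_points", "data.frame"))
}

#' @export
print.presence_points <- function(x, ...) {
  cat(sprintf("presence_points: %d records, suitability in [%.4f, %.4f]\n",
              nrow(x), min(x$suitability), max(x$suitability)))
  invisible(x)
}

#' Apply a threshold to a suitability grid
#'
#' Classifies every valid cell as habitat (1) when its suitability is greater
#' than or equal to the threshold, non-habitat (0) otherwise. Nodata cells
#' stay `NA`.
#'
#' @param grid a [suitability_grid()] or matrix.
#' @param threshold classification threshold in \[0, 1\].
#' @return an integer matrix of 0/1/`NA` with the grid's dimensions and
#'   extent attribute preserved.
#' @export
apply_threshold <- function(grid, threshold) {
  grid <- as_suitability_grid(grid)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    stop("`threshold` must be a single value in [0, 1]", call. = FALSE)
  out <- matrix(NA_integer_, nrow(grid), ncol(grid))
  ok <- !is.na(grid)
  out[ok] <- as.integer(grid[ok] >= threshold)
  attr(out, "extent") <- attr(grid, "extent")
  out
}
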