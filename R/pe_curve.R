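#' Predicted-to-expected (P/E) curve
#'
#' Builds the Boyce predicted-to-expected frequency curve from a continuous
#' suitability surface and presence records. Suitability in \[0, 1\] is split
#' into `1/window` classes of width `window`; for class i,
#' \deqn{P_i = p_i / \sum_j p_j, \quad E_i = a_i / \sum_j a_j, \quad
#'       F_i = P_i / E_i,}
#' where \eqn{p_i} counts validation presences in the class and \eqn{a_i}
#' counts valid grid cells. \eqn{F_i > 1} means the class holds more
#' presences than a uniform random distribution over the study area would
#' put there. For a model that ranks habitat correctly, F increases with
#' suitability.
#'
#' Classes are contiguous half-open bins `[lo, hi)`, the last bin closed at 1
#' so that a suitability of exactly 1 is counted. Classes with no grid cells
#' (`a_i = 0`) carry no information and are dropped from the retained curve;
#' classes with cells but no presences keep `F_i = 0`. The per-class
#' abscissa `hs_mean` is the mean suitability of the cells in the class, not
#' the bin midpoint. Presences are counted per record: two records on one
#' cell contribute 2.
#'
#' An optional overlapping-window mode (`stride < window`) smooths the curve
#' by sliding the window in steps of `stride`; overlapping classes are not a
#' partition, so the P and E columns then no longer sum to 1 and the result
#' is for plotting, not for [btqr()].
#'
#' @param grid a [suitability_grid()] or numeric matrix in \[0, 1\].
#' @param presences a `presence_points` object from [extract_suitability()]
#'   or [read_points()], or a bare numeric vector of suitability values at
#'   the presence records.
#' @param window class width W in (0, 1\]; `1/window` must be a whole number.
#'   The default 0.01 gives a curve resolution of 100 classes.
#' @param stride optional stride for the overlapping-window mode; must be
#'   positive and at most `window`. `NULL` (default) gives the partition.
#' @return an object of class `pe_curve`: a data frame of retained classes
#'   with columns `class_index`, `hs_lo`, `hs_hi`, `hs_mean`, `p_count`,
#'   `a_count`, `P`, `E`, `F`, plus attributes `window`, `n_classes`,
#'   `n_presence`, `n_valid`, and `dropped` (indices of zero-area classes).
#' @examples
#' g <- suitability_grid(matrix(runif(2500), 50, 50))
#' pres <- extract_suitability(g, cbind(sample(50, 200, TRUE),
#'                                      sample(50, 200, TRUE)))
#' pe <- pe_curve(g, pres, window = 0.1)
#' pe
#' @export
pe_curve <- function(grid, presences, window = 0.01, stride = NULL) {
  grid <- as_suitability_grid(grid)
  hs_pres <- if (is.numeric(presences)) presences else {
    if (!inherits(presences, "presence_points"))
      stop("`presences` must be presence_points or a numeric vector",
           call. = FALSE)
    presences$suitability
  }
  if (length(hs_pres) == 0L) stop("no presence records", call. = FALSE)
  if (any(is.na(hs_pres) | hs_pres < 0 | hs_pres > 1))
    stop("presence suitabilities must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(window) || length(window) != 1L || window <= 0 || window > 1)
    stop("`window` must be a single value in (0, 1]", call. = FALSE)
  b <- 1 / window
  if (abs(b - round(b)) > 1e-8)
    stop("1/window must be a whole number of classes", call. = FALSE)
  b <- as.integer(round(b))
  cells <- grid[!is.na(grid)]

  if (!is.null(stride)) {
    if (stride <= 0 || stride > window)
      stop("`stride` must be in (0, window]", call. = FALSE)
    lo <- seq(0, 1 - window, by = stride)
    if (max(lo) < 1 - window - 1e-12) lo <- c(lo, 1 - window)
    hi <- lo + window
    p_count <- a_count <- integer(length(lo))
    hs_mean <- numeric(length(lo))
    for (k in seq_along(lo)) {
      last <- abs(hi[k] - 1) < 1e-12
      in_a <- cells >= lo[k] & (if (last) cells <= hi[k] else cells < hi[k])
      in_p <- hs_pres >= lo[k] &
        (if (last) hs_pres <= hi[k] else hs_pres < hi[k])
      a_count[k] <- sum(in_a); p_count[k] <- sum(in_p)
      hs_mean[k] <- if (a_count[k]) mean(cells[in_a]) else NA_real_
    }
    idx <- seq_along(lo)
  } else {
    # partition: class i = floor(hs / W) + 1, clamped so hs = 1 lands in b
    bin_of <- function(v) pmin(as.integer(floor(v / window)) + 1L, b)
    a_count <- tabulate(bin_of(cells), nbins = b)
    p_count <- tabulate(bin_of(hs_pres), nbins = b)
    hs_sum <- vapply(split(cells, bin_of(cells)), sum, 0)
    hs_mean <- rep(NA_real_, b)
    hs_mean[as.integer(names(hs_sum))] <-
      hs_sum / a_count[as.integer(names(hs_sum))]
    lo <- (seq_len(b) - 1L) * window
    hi <- lo + window
    idx <- seq_len(b)
  }

  P <- p_count / sum(p_count)
  E <- a_count / sum(a_count)
  F_ <- ifelse(E > 0, P / E, NA_real_)
  keep <- a_count > 0L
  out <- data.frame(class_index = idx, hs_lo = lo, hs_hi = hi,
                    hs_mean = hs_mean, p_count = p_count, a_count = a_count,
                    P = P, E = E, F = F_)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = c("pe_curve", "data.frame"),
            window = window, stride = stride, n_classes = b,
            n_presence = length(hs_pres), n_valid = length(cells),
            dropped = idx[!keep])
}

#' @export
print.pe_curve <- function(x, ...) {
  cat(sprintf(
    "P/E curve: %d retained classes (window %.4g, %d dropped empty)\n",
    nrow(x), attr(x, "window"), length(attr(x, "dropped"))))
  cat(sprintf("  %d presences over %d valid cells; F in [%.3f, %.3f]\n",
              attr(x, "n_presence"), attr(x, "n_valid"),
              min(x$F), max(x$F)))
  invisible(x)
}

#' @describeIn pe_curve plot F against the per-class mean suitability.
#' @param x,y,... standard plot arguments (`y` is ignored).
#' @export
plot.pe_curve <- function(x, y, ...) {
  graphics::plot(x$hs_mean, x$F, type = "b", pch = 16, cex = 0.6,
                 xlab = "habitat suitability (class mean)",
                 ylab = "P/E ratio F", ...)
  graphics::abline(h = 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Write a P/E curve to CSV
#'
#' @param curve a [pe_curve()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pe_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
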