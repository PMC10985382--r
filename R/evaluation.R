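#' Kappa of a binary map against a truth map
#'
#' Assembles the cellwise confusion matrix between a thresholded habitat map
#' and a known presence-absence truth map over the shared valid cells and
#' returns [cohen_kappa()]. Optionally the comparison uses a prevalence-
#' stratified sample of cells instead of every cell: `n_sample * p` cells
#' from the truth presences and `n_sample * (1 - p)` from the absences,
#' `p` being the truth prevalence.
#'
#' @param binary_map 0/1/`NA` matrix, e.g. from [apply_threshold()].
#' @param truth_map 0/1/`NA` matrix of the same shape and mask.
#' @param n_sample optional number of test cells to sample; `NULL` (default)
#'   compares every valid cell.
#' @param seed seed for the sampled comparison.
#' @return Cohen's kappa.
#' @export
kappa_vs_truth <- function(binary_map, truth_map, n_sample = NULL,
                           seed = 1) {
  b <- unclass(binary_map); t_ <- unclass(truth_map)
  if (!identical(dim(b), dim(t_)))
    stop("maps have different shapes", call. = FALSE)
  if (!identical(is.na(b), is.na(t_)))
    stop("maps have different validity masks", call. = FALSE)
  ok <- which(!is.na(b))
  if (!is.null(n_sample)) {
    set.seed(seed)
    pres <- ok[t_[ok] == 1L]; abs_ <- ok[t_[ok] == 0L]
    p <- length(pres) / length(ok)
    np <- min(round(n_sample * p), length(pres))
    na_ <- min(n_sample - np, length(abs_))
    ok <- c(sample(pres, np), sample(abs_, na_))
  }
  cm <- c(tp = sum(b[ok] == 1L & t_[ok] == 1L),
          fp = sum(b[ok] == 1L & t_[ok] == 0L),
          fn = sum(b[ok] == 0L & t_[ok] == 1L),
          tn = sum(b[ok] == 0L & t_[ok] == 0L))
  cohen_kappa(cm)
}

#' Prevalence implied by a threshold
#'
#' Fraction of valid cells whose suitability is at or above the threshold —
#' the species prevalence the binary map implies.
#'
#' @param grid a [suitability_grid()] or matrix.
#' @param threshold threshold in \[0, 1\].
#' @return prevalence in \[0, 1\].
#' @export
estimate_prevalence <- function(grid, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  v <- unclass(grid)
  mean(v[!is.na(v)] >= threshold)
}

#' One-way ANOVA F-test of threshold consistency
#'
#' Tests whether the mean threshold differs between groups of repeated runs
#' (groups are typically validation-set sizes). A small F means the rule is
#' insensitive to the composition of the validation data. Degenerate cases
#' follow a documented convention: zero within-group variance with unequal
#' means gives `F = Inf, p = 0`; zero variance within and between gives
#' `F = 0, p = 1`.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values), e.g. thresholds by validation-set size.
#' @return list with `f`, `p`, `df` (numerator, denominator degrees of
#'   freedom).
#' @export
anova_f_consistency <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 0L) < 2L))
    stop("each group needs at least 2 values", call. = FALSE)
  k <- length(groups)
  n <- vapply(groups, length, 0L)
  N <- sum(n)
  gm <- vapply(groups, mean, 0)
  grand <- sum(unlist(groups)) / N
  ssb <- sum(n * (gm - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df <- c(k - 1L, N - k)
  if (ssw == 0) {
    if (ssb == 0) return(list(f = 0, p = 1, df = df))
    return(list(f = Inf, p = 0, df = df))
  }
  f <- (ssb / df[1]) / (ssw / df[2])
  list(f = f, p = stats::pf(f, df[1], df[2], lower.tail = FALSE), df = df)
}

#' Benchmark threshold rules on a known-truth landscape
#'
#' Replicates the comparative experiment at configurable scale: for each
#' validation-set size and repeat, presences and background points are
#' resampled from the realized presence-absence map, each rule selects a
#' threshold from the suitability surface, and the resulting binary map is
#' scored by Cohen's kappa against the truth map and by the prevalence it
#' implies. Per rule, a one-way ANOVA F-test across the size groups
#' measures threshold consistency.
#'
#' @param species a [virtual_species()], or a list with components
#'   `suitability` (a [suitability_grid()]), `pa_map` (0/1 truth matrix) and
#'   `realized_prevalence`.
#' @param methods character vector of rules for [select_threshold()]
#'   (plus `"BTQR"`).
#' @param sizes validation-set presence-count ladder.
#' @param repeats random resamples per size (>= 2 for the F-test).
#' @param n_background pseudo-absence points per validation set.
#' @param window,trimming [btqr()] settings.
#' @param kappa_sample optional cell count for sampled kappa scoring;
#'   `NULL` scores every cell.
#' @param meanprob_over `"validation"` (default): MeanProb averages the
#'   predictions of the validation records, so its threshold responds to
#'   the validation set, as in the comparative study; `"area"`: average
#'   over all study-area cells (then the rule is deterministic and its
#'   consistency F is trivially 0).
#' @param equalprev_prevalence `"validation"` (default): EqualPrev matches
#'   the prevalence of the validation dataset itself,
#'   presences / (presences + background), as in the comparative study;
#'   `"truth"`: match the known realized prevalence of the truth map.
#' @param seed master seed; every draw derives from it.
#' @return an object of class `btqr_benchmark`: list with `results` (data
#'   frame: method, size, repeat, threshold, kappa, est_prevalence),
#'   `consistency` (data frame: method, f_value, p_value) and the
#'   configuration.
#' @export
run_benchmark <- function(species,
                          methods = c("BTQR", "MSS", "ESS", "MaxKappa",
                                      "EqualPrev", "MeanProb", "MinROC",
                                      "Se0.5", "Se0.75", "Se0.9"),
                          sizes = c(250, 500, 1000, 2000), repeats = 5,
                          n_background = 2500, window = 0.01,
                          trimming = 0.10, kappa_sample = NULL,
                          meanprob_over = c("validation", "area"),
                          equalprev_prevalence = c("validation", "truth"),
                          seed = 1) {
  if (repeats < 1) stop("repeats must be >= 1", call. = FALSE)
  meanprob_over <- match.arg(meanprob_over)
  equalprev_prevalence <- match.arg(equalprev_prevalence)
  suit <- as_suitability_grid(species$suitability)
  pa <- unclass(species$pa_map)
  prev <- species$realized_prevalence
  if (is.null(prev)) prev <- mean(pa, na.rm = TRUE)
  grid_vals <- suit[!is.na(suit)]
  rows <- list(); ri <- 0L
  for (si in seq_along(sizes)) for (rep_ in seq_len(repeats)) {
    draw_seed <- seed + 1000L * si + rep_
    pts <- sample_points(pa, n_presence = sizes[si],
                         n_background = n_background, seed = draw_seed)
    pres_hs <- suit[cbind(pts$presences$row, pts$presences$col)]
    abs_hs <- suit[cbind(pts$background$row, pts$background$col)]
    obs_prev <- if (equalprev_prevalence == "validation")
      length(pres_hs) / (length(pres_hs) + length(abs_hs)) else prev
    for (m in methods) {
      gp <- if (tolower(m) == "meanprob" && meanprob_over == "validation")
        NULL else grid_vals
      th <- select_threshold(m, presence_preds = pres_hs,
                             absence_preds = abs_hs, grid_preds = gp,
                             observed_prevalence = obs_prev, grid = suit,
                             window = window, trimming = trimming)$threshold
      bin <- apply_threshold(suit, th)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        method = m, size = sizes[si], rep = rep_, threshold = th,
        kappa = kappa_vs_truth(bin, pa, n_sample = kappa_sample,
                               seed = draw_seed),
        est_prevalence = estimate_prevalence(suit, th))
    }
  }
  results <- do.call(rbind, rows)
  consistency <- NULL
  if (repeats >= 2) {
    consistency <- do.call(rbind, lapply(methods, function(m) {
      g <- split(results$threshold[results$method == m],
                 results$size[results$method == m])
      ft <- anova_f_consistency(g)
      data.frame(method = m, f_value = ft$f, p_value = ft$p)
    }))
  } else {
    warning("repeats = 1: F-test of consistency skipped (needs >= 2 per ",
            "group)", call. = FALSE)
  }
  structure(list(results = results, consistency = consistency,
                 sizes = sizes, repeats = repeats,
                 n_background = n_background, window = window,
                 trimming = trimming, seed = seed,
                 truth_prevalence = prev),
            class = "btqr_benchmark")
}

#' @export
print.btqr_benchmark <- function(x, ...) {
  cat(sprintf(
    "threshold benchmark: %d rules x sizes (%s) x %d repeats (seed %d)\n",
    length(unique(x$results$method)),
    paste(x$sizes, collapse = ", "), x$repeats, x$seed))
  agg <- stats::aggregate(cbind(threshold, kappa, est_prevalence) ~ method,
                          data = x$results, FUN = stats::median)
  if (!is.null(x$consistency))
    agg <- merge(agg, x$consistency, by = "method")
  print(agg, digits = 3, row.names = FALSE)
  cat(sprintf("truth prevalence: %.4f\n", x$truth_prevalence))
  invisible(x)
}

#' Write benchmark outputs as tidy CSV
#'
#' @param bench a [run_benchmark()] result.
#' @param dir output directory (created if needed); writes
#'   `benchmark_results.csv` and, when present, `benchmark_consistency.csv`.
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bench$results,
                   file.path(dir, "benchmark_results.csv"),
                   row.names = FALSE)
  if (!is.null(bench$consistency))
    utils::write.csv(bench$consistency,
                     file.path(dir, "benchmark_consistency.csv"),
                     row.names = FALSE)
  invisible(dir)
}
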