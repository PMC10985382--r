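#' Confusion matrix at a threshold
#'
#' Classifies predictions at presence and (pseudo-)absence records with the
#' inclusive rule: a prediction greater than or equal to the threshold is
#' "presence". Pseudo-absences may be empty for sensitivity-only use.
#'
#' @param threshold classification threshold in \[0, 1\].
#' @param presence_preds predictions at presence records, in \[0, 1\].
#' @param absence_preds predictions at (pseudo-)absence records.
#' @return an object of class `confusion_matrix`: named integer vector with
#'   `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_at <- function(threshold, presence_preds,
                         absence_preds = numeric(0)) {
  if (length(presence_preds) == 0L)
    stop("`presence_preds` must be non-empty", call. = FALSE)
  stopifnot(threshold >= 0, threshold <= 1)
  cm <- c(tp = sum(presence_preds >= threshold),
          fp = sum(absence_preds >= threshold),
          fn = sum(presence_preds < threshold),
          tn = sum(absence_preds < threshold))
  structure(as.integer(cm), names = names(cm), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(x[c("tp", "fn", "fp", "tn")], 2, 2, byrow = TRUE,
              dimnames = list(truth = c("presence", "absence"),
                              predicted = c("presence", "absence")))
  print(m)
  invisible(x)
}

sensitivity_of <- function(cm) unname(cm["tp"] / (cm["tp"] + cm["fn"]))
specificity_of <- function(cm) unname(cm["tn"] / (cm["fp"] + cm["tn"]))

#' Cohen's kappa of a confusion matrix
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' observed agreement \eqn{p_o = (tp+tn)/n} and chance agreement
#' \eqn{p_e = ((tp+fp)(tp+fn) + (fn+tn)(fp+tn))/n^2}. When all mass sits in
#' one marginal cell (\eqn{p_e = 1}) agreement is indistinguishable from
#' chance and kappa is returned as 0 with a warning.
#'
#' @param cm a [confusion_at()] result, or any named vector/list with `tp`,
#'   `fp`, `fn`, `tn`.
#' @return kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(cm) {
  cm <- unlist(cm)[c("tp", "fp", "fn", "tn")]
  if (anyNA(cm) || any(cm < 0)) stop("invalid confusion counts", call. = FALSE)
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  po <- (cm["tp"] + cm["tn"]) / n
  pe <- ((cm["tp"] + cm["fp"]) * (cm["tp"] + cm["fn"]) +
         (cm["fn"] + cm["tn"]) * (cm["fp"] + cm["tn"])) / n^2
  if (pe >= 1) {
    warning("degenerate marginals (p_e = 1); kappa set to 0", call. = FALSE)
    return(0)
  }
  unname((po - pe) / (1 - pe))
}

#' Select a classification threshold by a named rule
#'
#' The nine classical rules used alongside the P/E mutation point, and the
#' mutation point itself:
#' \describe{
#'   \item{MSS}{maximize sensitivity + specificity}
#'   \item{ESS}{minimize |sensitivity - specificity|}
#'   \item{MaxKappa}{maximize Cohen's kappa}
#'   \item{MinROC}{minimize the distance from the ROC point to (0, 1),
#'     \eqn{\sqrt{(1-sens)^2 + (1-spec)^2}}}
#'   \item{EqualPrev}{match the predicted prevalence (fraction of the study
#'     area at or above the threshold) to a supplied observed prevalence}
#'   \item{MeanProb}{the mean prediction over the study area when
#'     `grid_preds` is supplied, otherwise the mean over the validation
#'     records (presences plus any pseudo-absences)}
#'   \item{Se0.5 / Se0.75 / Se0.9 (or `method = "se"` with `sens`)}{the
#'     largest threshold retaining at least the target sensitivity}
#'   \item{BTQR}{the P/E-curve mutation point, via [btqr_threshold()]}
#' }
#' MSS, ESS, MaxKappa and MinROC need pseudo-absence predictions; EqualPrev
#' needs the study-area predictions and an observed prevalence (for virtual
#' species, the known realized prevalence — there is no silent default);
#' MeanProb needs the study-area predictions; the fixed-sensitivity rules
#' use presences only. The criterion functions are step functions that
#' change only at observed prediction values, so the optimizing rules search
#' the sorted unique observed values plus 0 and 1, which makes the search
#' exact; ties go to the smallest threshold.
#'
#' @param method one of `"MSS"`, `"ESS"`, `"MaxKappa"`, `"EqualPrev"`,
#'   `"MeanProb"`, `"MinROC"`, `"Se0.5"`, `"Se0.75"`, `"Se0.9"`, `"se"`,
#'   `"BTQR"` (case-insensitive).
#' @param presence_preds predictions at presence records.
#' @param absence_preds predictions at pseudo-absence records (MSS, ESS,
#'   MaxKappa, MinROC).
#' @param grid_preds predictions over all valid study-area cells (EqualPrev,
#'   MeanProb), as a numeric vector or a [suitability_grid()].
#' @param observed_prevalence observed prevalence in (0, 1) for EqualPrev.
#' @param sens target sensitivity in (0, 1) when `method = "se"`.
#' @param grid,window,trimming for `method = "BTQR"`: the suitability grid
#'   and the [btqr()] settings.
#' @return an object of class `threshold_result`: list with `method`,
#'   `threshold`, `criterion_value` (the optimized statistic at the
#'   threshold).
#' @examples
#' select_threshold("Se0.5", presence_preds = c(0.2, 0.4, 0.6, 0.8))
#' @export
select_threshold <- function(method, presence_preds = NULL,
                             absence_preds = NULL, grid_preds = NULL,
                             observed_prevalence = NULL, sens = NULL,
                             grid = NULL, window = 0.01, trimming = 0.10) {
  m <- tolower(method)
  if (grepl("^se0?\\.", m)) {
    sens <- as.numeric(sub("^se", "", m))
    m <- "se"
  }
  need <- function(arg, name)
    if (is.null(arg)) stop(sprintf("method %s requires `%s`", method, name),
                           call. = FALSE)
  if (inherits(grid_preds, "suitability_grid") || is.matrix(grid_preds))
    grid_preds <- grid_preds[!is.na(grid_preds)]

  result <- function(threshold, criterion)
    structure(list(method = method, threshold = unname(threshold),
                   criterion_value = unname(criterion)),
              class = "threshold_result")

  if (m %in% c("mss", "ess", "maxkappa", "minroc")) {
    need(presence_preds, "presence_preds")
    need(absence_preds, "absence_preds")
    cand <- sort(unique(c(0, presence_preds, absence_preds, 1)))
    stats_ <- vapply(cand, function(t) {
      cm <- confusion_at(t, presence_preds, absence_preds)
      se <- sensitivity_of(cm); sp <- specificity_of(cm)
      switch(m,
             mss = se + sp,
             ess = -abs(se - sp),
             maxkappa = cohen_kappa(cm),
             minroc = -sqrt((1 - se)^2 + (1 - sp)^2))
    }, 0)
    k <- which.max(stats_)   # first max = smallest threshold on ties
    crit <- stats_[k]
    if (m %in% c("ess", "minroc")) crit <- -crit
    return(result(cand[k], crit))
  }

  switch(m,
    meanprob = {
      if (is.null(grid_preds) && !is.null(presence_preds)) {
        # fallback: mean over the supplied records when no area predictions
        v <- c(presence_preds, absence_preds)
        return(result(mean(v), mean(v)))
      }
      need(grid_preds, "grid_preds")
      result(mean(grid_preds), mean(grid_preds))
    },
    equalprev = {
      need(grid_preds, "grid_preds")
      need(observed_prevalence, "observed_prevalence")
      cand <- sort(unique(c(0, grid_preds, 1)))
      # fraction of cells >= t at each candidate, via one sort
      s <- sort(grid_preds)
      n <- length(s)
      frac <- (n - findInterval(cand, s, left.open = TRUE)) / n
      gap <- abs(frac - observed_prevalence)
      k <- which.min(gap)
      result(cand[k], gap[k])
    },
    se = {
      need(presence_preds, "presence_preds")
      need(sens, "sens")
      if (sens <= 0 || sens >= 1)
        stop("target sensitivity must lie in (0, 1)", call. = FALSE)
      n <- length(presence_preds)
      if (n < 1 / (1 - sens))
        message(sprintf(
          "only %d presences: sensitivity resolution is coarser than %g",
          n, 1 - sens))
      cand <- sort(unique(c(0, presence_preds, 1)))
      sens_at <- vapply(cand, function(t) mean(presence_preds >= t), 0)
      ok <- which(sens_at >= sens)
      k <- ok[length(ok)]   # largest threshold still meeting the target
      result(cand[k], sens_at[k])
    },
    btqr = {
      need(grid, "grid")
      need(presence_preds, "presence_preds")
      g <- btqr_threshold(grid, presence_preds, window = window,
                          trimming = trimming)
      result(g, g)
    },
    stop("unknown method: ", method, call. = FALSE)
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("%s threshold: %.4f (criterion %.4f)\n",
              x$method, x$threshold, x$criterion_value))
  invisible(x)
}
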