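#' Trimmed candidate thresholds
#'
#' The grid search of [btqr()] only considers thresholds that are observed
#' values of the threshold variable (the per-class mean suitabilities) lying
#' between the empirical `trimming` and `1 - trimming` quantiles, so that
#' each region retains a workable number of observations. Quantiles use the
#' standard continuous convention (`stats::quantile` type 7) with inclusive
#' bounds.
#'
#' @param hs numeric vector of observed threshold-variable values.
#' @param trimming trimming fraction in \[0, 0.5); default 0.10 keeps values
#'   between the 10th and 90th percentiles.
#' @return sorted vector of unique candidate thresholds.
#' @export
candidate_thresholds <- function(hs, trimming = 0.10) {
  if (!is.numeric(hs) || length(hs) < 2L)
    stop("`hs` must be a numeric vector with at least 2 values", call. = FALSE)
  if (any(is.na(hs))) stop("`hs` contains NA", call. = FALSE)
  if (trimming < 0 || trimming >= 0.5)
    stop("`trimming` must lie in [0, 0.5)", call. = FALSE)
  q <- stats::quantile(hs, c(trimming, 1 - trimming), names = FALSE, type = 7)
  cand <- sort(unique(hs[hs >= q[1] & hs <= q[2]]))
  if (length(cand) < 2L)
    stop("insufficient curve support: fewer than 2 candidate thresholds ",
         "survive trimming", call. = FALSE)
  cand
}

# Per-region fit. loss "ls": least squares; "quantile": check-loss at tau.
# Without intercept the model is pe = hs * delta (through the origin).
# Returns list(coef = c(intercept, slope), loss) or NULL when infeasible.
.region_fit <- function(hs, pe, w, intercept, loss, tau) {
  n <- length(hs)
  if (n < 1L || (intercept && n < 2L)) return(NULL)
  if (loss == "ls") {
    if (intercept) {
      X <- cbind(1, hs)
      fit <- stats::lm.wfit(X, pe, w)
      cf <- fit$coefficients
      if (anyNA(cf)) return(NULL)          # collinear (e.g. constant hs)
      res <- pe - X %*% cf
      list(coef = c(cf[1], cf[2]), loss = sum(w * res^2))
    } else {
      shs2 <- sum(w * hs^2)
      if (shs2 == 0) return(NULL)
      d <- sum(w * hs * pe) / shs2
      list(coef = c(0, d), loss = sum(w * (pe - d * hs)^2))
    }
  } else {
    rho <- function(r) sum(w * r * (tau - (r < 0)))
    if (intercept) {
      # optimum interpolates two observations; enumerate basic solutions
      best <- NULL
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        if (hs[i] == hs[j]) next
        sl <- (pe[j] - pe[i]) / (hs[j] - hs[i])
        ic <- pe[i] - sl * hs[i]
        val <- rho(pe - ic - sl * hs)
        if (is.null(best) || val < best$loss - 1e-12)
          best <- list(coef = c(ic, sl), loss = val)
      }
      best
    } else {
      if (all(hs == 0)) return(NULL)
      cand <- sort(unique(pe[hs != 0] / hs[hs != 0]))
      vals <- vapply(cand, function(d) rho(pe - d * hs), 0)
      k <- which.min(vals)
      list(coef = c(0, cand[k]), loss = vals[k])
    }
  }
}

.two_region_fit <- function(hs, pe, gamma, intercept = FALSE, loss = "ls",
                            tau = 0.5, weights = NULL) {
  hs_max <- max(hs)
  r1 <- hs > 0 & hs <= gamma
  r2 <- hs > gamma & hs <= hs_max
  w <- if (is.null(weights)) rep(1, length(hs)) else weights
  f1 <- .region_fit(hs[r1], pe[r1], w[r1], intercept, loss, tau)
  f2 <- .region_fit(hs[r2], pe[r2], w[r2], intercept, loss, tau)
  if (is.null(f1) || is.null(f2)) return(NULL)
  list(ssr = f1$loss + f2$loss,
       delta1 = unname(f1$coef[2]), delta2 = unname(f2$coef[2]),
       intercept1 = unname(f1$coef[1]), intercept2 = unname(f2$coef[1]))
}

#' Two-region regression at a tentative threshold
#'
#' Splits the curve observations at `gamma` into region 1
#' (\eqn{0 < hs \le \gamma}) and region 2 (\eqn{\gamma < hs \le hs_{max}}),
#' fits `pe = hs * delta` separately in each region by least squares through
#' the origin (\eqn{\delta = \sum hs \cdot pe / \sum hs^2}), and returns the
#' total squared residual. This is the objective the [btqr()] grid search
#' minimizes over candidate thresholds.
#'
#' @param hs,pe numeric vectors: threshold variable (per-class mean
#'   suitability) and response (P/E ratio).
#' @param gamma tentative threshold.
#' @param intercept add per-region intercepts (then each region needs at
#'   least 2 observations).
#' @param loss `"ls"` (default, the estimator's definition) or `"quantile"`
#'   for the check-loss at quantile `tau`; with the quantile loss the `ssr`
#'   component is the summed check loss.
#' @param tau quantile level for `loss = "quantile"`.
#' @param weights optional observation weights.
#' @return list with `ssr`, `delta1`, `delta2` (and `intercept1`,
#'   `intercept2` when `intercept = TRUE`).
#' @export
two_region_ssr <- function(hs, pe, gamma, intercept = FALSE,
                           loss = c("ls", "quantile"), tau = 0.5,
                           weights = NULL) {
  loss <- match.arg(loss)
  if (length(hs) != length(pe))
    stop("`hs` and `pe` must have equal length", call. = FALSE)
  fit <- .two_region_fit(hs, pe, gamma, intercept, loss, tau, weights)
  if (is.null(fit))
    stop(sprintf(
      "gamma = %g is infeasible: a region has too few observations", gamma),
      call. = FALSE)
  if (!intercept) fit$intercept1 <- fit$intercept2 <- NULL
  fit
}

#' Boyce-threshold regression: locate the mutation point of a P/E curve
#'
#' Fits a two-region threshold regression to the predicted-to-expected curve
#' of a species distribution model and returns the estimated mutation point
#' \eqn{\hat\gamma} — the suitability value at which the curve's slope
#' changes abruptly — as an objective presence-only classification
#' threshold. The model is
#' \deqn{pe_t = hs_t\,\delta_1 + \epsilon_t \;\; (0 < hs_t \le \gamma),
#'   \qquad pe_t = hs_t\,\delta_2 + \epsilon_t \;\;
#'   (\gamma < hs_t \le hs_{max}),}
#' with the threshold estimated by grid search:
#' \eqn{\hat\gamma = \arg\min_{\gamma \in \Gamma} S(\gamma)} where
#' \eqn{S(\gamma)} is the sum of squared residuals of the two no-intercept
#' fits and \eqn{\Gamma} is the set of observed `hs` values between the
#' `trimming` and `1 - trimming` empirical quantiles
#' (see [candidate_thresholds()]). Ties are broken toward the smallest
#' candidate, favouring the more inclusive habitat map. Under source-sink
#' theory the mutation point marks the transition from sink habitat
#' (presence maintained by immigration) to source habitat (self-sustaining),
#' so cells with suitability at or above \eqn{\hat\gamma} are classified as
#' habitat.
#'
#' @param x a [pe_curve()], a [suitability_grid()] (then `presences` is
#'   required and the curve is built first), or a numeric vector of
#'   threshold-variable values (then `y` holds the responses).
#' @param ... passed between methods.
#' @return an object of class `btqr` with components `gamma` (the estimated
#'   threshold \eqn{\hat\gamma}), `delta1`, `delta2` (region slopes),
#'   `ssr` (minimized loss), `ssr_profile` (data frame of candidate
#'   \eqn{\gamma} and \eqn{S(\gamma)}, `NA` for infeasible candidates),
#'   `candidates`, `trimming`, `hs_max`, `model` (the curve observations)
#'   and the fitting options. Methods: `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' hs <- seq(0.005, 0.995, by = 0.01)
#' pe <- ifelse(hs <= 0.5, 0.3 * hs, 4 * hs)
#' fit <- btqr(hs, pe)
#' coef(fit)
#' @export
btqr <- function(x, ...) UseMethod("btqr")

#' @rdname btqr
#' @param y response vector (P/E ratios) for the default method.
#' @param trimming trimming fraction for the candidate set, default 0.10.
#' @param intercept fit per-region intercepts (non-default; the estimator's
#'   definition is regression through the origin).
#' @param loss `"ls"` (default) or `"quantile"`.
#' @param tau quantile level when `loss = "quantile"`.
#' @param weights optional per-observation weights.
#' @export
btqr.default <- function(x, y, trimming = 0.10, intercept = FALSE,
                         loss = c("ls", "quantile"), tau = 0.5,
                         weights = NULL, ...) {
  loss <- match.arg(loss)
  hs <- as.numeric(x); pe <- as.numeric(y)
  if (length(hs) != length(pe))
    stop("`x` and `y` must have equal length", call. = FALSE)
  ord <- order(hs)
  hs <- hs[ord]; pe <- pe[ord]
  if (!is.null(weights)) weights <- weights[ord]
  .btqr_fit(hs, pe, trimming, intercept, loss, tau, weights,
            window = NULL, call = match.call())
}

#' @rdname btqr
#' @export
btqr.pe_curve <- function(x, trimming = 0.10, intercept = FALSE,
                          loss = c("ls", "quantile"), tau = 0.5,
                          weights = NULL, ...) {
  loss <- match.arg(loss)
  if (!is.null(attr(x, "stride")) )
    stop("btqr() needs a partition P/E curve (stride = NULL)", call. = FALSE)
  if (nrow(x) < 5L)
    stop("P/E curve has fewer than 5 retained classes; threshold ",
         "regression is not identifiable", call. = FALSE)
  hs <- x$hs_mean; pe <- x$F
  if (is.unsorted(hs, strictly = TRUE))
    stop("malformed curve: class mean suitabilities are not strictly ",
         "increasing", call. = FALSE)
  .btqr_fit(hs, pe, trimming, intercept, loss, tau, weights,
            window = attr(x, "window"), call = match.call())
}

#' @rdname btqr
#' @param presences presence records for the grid method (see [pe_curve()]).
#' @param window class width for the P/E curve, default 0.01 (100 classes).
#' @export
btqr.suitability_grid <- function(x, presences, window = 0.01,
                                  trimming = 0.10, ...) {
  btqr(pe_curve(x, presences, window = window), trimming = trimming, ...)
}

.btqr_fit <- function(hs, pe, trimming, intercept, loss, tau, weights,
                      window, call) {
  if (length(hs) < 5L)
    stop("need at least 5 observations for threshold regression",
         call. = FALSE)
  if (anyNA(hs) || anyNA(pe)) stop("NA in curve observations", call. = FALSE)
  cand <- candidate_thresholds(hs, trimming)
  fits <- lapply(cand, function(g)
    .two_region_fit(hs, pe, g, intercept, loss, tau, weights))
  ssr <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$ssr, 0)
  if (all(is.na(ssr)))
    stop("no feasible candidate threshold: every split leaves an empty ",
         "region", call. = FALSE)
  # smallest gamma among minima; ties are judged within a numerical
  # tolerance so exactly proportional data (SSR ~ 0 everywhere up to
  # round-off) resolves to the smallest candidate
  min_ssr <- min(ssr, na.rm = TRUE)
  tol <- 1e-8 * (1 + abs(min_ssr))
  k <- which(!is.na(ssr) & ssr <= min_ssr + tol)[1]
  best <- fits[[k]]
  structure(list(
    gamma = cand[k], delta1 = best$delta1, delta2 = best$delta2,
    intercept1 = if (intercept) best$intercept1,
    intercept2 = if (intercept) best$intercept2,
    ssr = best$ssr,
    ssr_profile = data.frame(gamma = cand, ssr = ssr),
    candidates = cand, trimming = trimming, hs_max = max(hs),
    window = window, intercept = intercept, loss = loss,
    tau = if (loss == "quantile") tau,
    model = data.frame(hs = hs, pe = pe),
    call = call), class = "btqr")
}

#' @export
print.btqr <- function(x, digits = 4, ...) {
  cat("Boyce-threshold regression (mutation point of the P/E curve)\n")
  cat(sprintf("  threshold gamma^ = %.*g\n", digits, x$gamma))
  cat(sprintf("  region slopes: delta1 = %.*g (hs <= gamma), delta2 = %.*g\n",
              digits, x$delta1, digits, x$delta2))
  cat(sprintf("  %s = %.*g over %d candidates (trimming %.0f%%)\n",
              if (x$loss == "ls") "SSR" else "check loss",
              digits, x$ssr, length(x$candidates), 100 * x$trimming))
  invisible(x)
}

#' @export
coef.btqr <- function(object, ...) {
  cf <- c(gamma = object$gamma, delta1 = object$delta1,
          delta2 = object$delta2)
  if (object$intercept)
    cf <- c(cf, intercept1 = object$intercept1,
            intercept2 = object$intercept2)
  cf
}

#' @export
predict.btqr <- function(object, newdata = NULL, ...) {
  hs <- if (is.null(newdata)) object$model$hs
        else if (is.data.frame(newdata)) newdata$hs
        else as.numeric(newdata)
  i1 <- if (object$intercept) object$intercept1 else 0
  i2 <- if (object$intercept) object$intercept2 else 0
  ifelse(hs <= object$gamma, i1 + hs * object$delta1,
         i2 + hs * object$delta2)
}

#' @export
fitted.btqr <- function(object, ...) predict(object)

#' @export
residuals.btqr <- function(object, ...) object$model$pe - fitted(object)

#' @export
summary.btqr <- function(object, ...) {
  r1 <- sum(object$model$hs > 0 & object$model$hs <= object$gamma)
  r2 <- sum(object$model$hs > object$gamma)
  res <- residuals(object)
  structure(list(fit = object, n = nrow(object$model), n1 = r1, n2 = r2,
                 resid_sd = stats::sd(res),
                 profile_range = range(object$ssr_profile$ssr, na.rm = TRUE)),
            class = "summary.btqr")
}

#' @export
print.summary.btqr <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  observations: %d (%d in region 1, %d in region 2)\n",
              x$n, x$n1, x$n2))
  cat(sprintf("  residual sd %.*g; SSR profile range [%.*g, %.*g]\n",
              digits, x$resid_sd, digits, x$profile_range[1],
              digits, x$profile_range[2]))
  invisible(x)
}

#' @describeIn btqr plot the curve, the two fitted regression lines and the
#'   estimated threshold; optionally the SSR profile.
#' @param which `1` for the fitted curve, `2` for the SSR profile, `1:2`
#'   for both.
#' @export
plot.btqr <- function(x, which = 1, ...) {
  if (1 %in% which) {
    graphics::plot(x$model$hs, x$model$pe, pch = 16, cex = 0.6,
                   xlab = "habitat suitability", ylab = "P/E ratio", ...)
    h1 <- seq(min(x$model$hs), x$gamma, length.out = 50)
    h2 <- seq(x$gamma, x$hs_max, length.out = 50)
    graphics::lines(h1, predict(x, h1), col = "steelblue", lwd = 2)
    graphics::lines(h2, predict(x, h2 + 1e-12), col = "firebrick", lwd = 2)
    graphics::abline(v = x$gamma, lty = 2, col = "grey40")
  }
  if (2 %in% which) {
    graphics::plot(x$ssr_profile$gamma, x$ssr_profile$ssr, type = "b",
                   pch = 16, cex = 0.5, xlab = "candidate gamma",
                   ylab = "S(gamma)")
    graphics::abline(v = x$gamma, lty = 2, col = "grey40")
  }
  invisible(x)
}

#' One-call presence-only threshold
#'
#' Convenience composition: builds the P/E curve and fits the threshold
#' regression, returning just the estimated threshold.
#'
#' @inheritParams pe_curve
#' @inheritParams btqr.default
#' @return the estimated threshold \eqn{\hat\gamma}, a single number.
#' @export
btqr_threshold <- function(grid, presences, window = 0.01, trimming = 0.10,
                           ...) {
  btqr(pe_curve(grid, presences, window = window),
       trimming = trimming, ...)$gamma
}

#' Serialize a btqr fit to JSON
#'
#' @param fit a [btqr()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_btqr <- function(fit, path) {
  jsonlite::write_json(list(
    gamma_hat = fit$gamma, delta1 = fit$delta1, delta2 = fit$delta2,
    trimming = fit$trimming, window_width = fit$window,
    loss = fit$loss, intercept = fit$intercept,
    ssr_profile = fit$ssr_profile), path, auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(path)
}
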