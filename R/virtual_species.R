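#' Response function of a species to an environmental gradient
#'
#' Building block for [build_suitability()]. Three shapes are available:
#' `gaussian` (optimum at `mean`, tolerance `sd`), `linear`
#' (`slope * x + intercept`) and `logistic`
#' (`1 / (1 + exp((x - beta) / alpha))`; `alpha < 0` makes the response
#' increase with the gradient).
#'
#' @param kind `"gaussian"`, `"linear"` or `"logistic"`.
#' @param ... shape parameters: `mean`, `sd` (gaussian); `slope`,
#'   `intercept` (linear); `alpha`, `beta` (logistic).
#' @return an object of class `response_function` (callable on numerics).
#' @export
response_function <- function(kind = c("gaussian", "linear", "logistic"),
                              ...) {
  kind <- match.arg(kind)
  p <- list(...)
  defaults <- switch(kind,
    gaussian = list(mean = 0, sd = 1),
    linear   = list(slope = 1, intercept = 0),
    logistic = list(alpha = -0.05, beta = 0))
  p <- utils::modifyList(defaults, p)
  if (kind == "gaussian" && p$sd <= 0)
    stop("gaussian response needs sd > 0", call. = FALSE)
  if (kind == "logistic" && p$alpha == 0)
    stop("logistic response needs alpha != 0", call. = FALSE)
  f <- switch(kind,
    gaussian = function(x) exp(-(x - p$mean)^2 / (2 * p$sd^2)),
    linear   = function(x) p$slope * x + p$intercept,
    logistic = function(x) 1 / (1 + exp(pmin(pmax((x - p$beta) / p$alpha,
                                                  -700), 700))))
  structure(f, class = c("response_function", "function"),
            kind = kind, params = p)
}

#' @export
print.response_function <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("%s response (%s)\n", attr(x, "kind"),
              paste(names(p), unlist(p), sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Generate smooth synthetic environmental layers
#'
#' Stand-ins for principal-component layers of real environmental
#' predictors: Gaussian white noise smoothed with a separable Gaussian
#' kernel of standard deviation `smoothness` (in cell units, truncated at 3
#' sd and renormalized at the edges), then standardized to zero mean and
#' unit variance. Larger `smoothness` gives stronger spatial
#' autocorrelation.
#'
#' @param n_layers number of layers (the study design uses 3).
#' @param shape `c(rows, cols)`, at least 10 x 10.
#' @param smoothness Gaussian kernel sd in cells, > 0.
#' @param seed integer seed; the output is a deterministic function of it.
#' @return list of `n_layers` numeric matrices.
#' @export
generate_environment <- function(n_layers = 3, shape = c(100, 100),
                                 smoothness = 5, seed = 1) {
  if (n_layers < 1) stop("n_layers must be >= 1", call. = FALSE)
  if (any(shape < 10)) stop("shape must be at least 10 x 10", call. = FALSE)
  if (smoothness <= 0) stop("smoothness must be > 0", call. = FALSE)
  set.seed(seed)
  lapply(seq_len(n_layers), function(k) {
    z <- matrix(stats::rnorm(shape[1] * shape[2]), shape[1], shape[2])
    z <- gaussian_blur(z, smoothness)
    (z - mean(z)) / stats::sd(z)
  })
}

# Separable Gaussian blur by banded smoothing matrices; rows renormalized so
# edge cells average over the truncated kernel.
gaussian_blur <- function(m, sigma) {
  smoother <- function(n) {
    r <- ceiling(3 * sigma)
    idx <- seq_len(n)
    K <- outer(idx, idx, function(i, j) {
      d <- abs(i - j)
      ifelse(d <= r, exp(-d^2 / (2 * sigma^2)), 0)
    })
    K / rowSums(K)
  }
  smoother(nrow(m)) %*% m %*% t(smoother(ncol(m)))
}

#' Environmental suitability from additive response functions
#'
#' Applies one response function per layer, sums the responses, and
#' min-max-rescales the total to \[0, 1\].
#'
#' @param layers list of numeric matrices (see [generate_environment()]).
#' @param responses list of [response_function()]s, one per layer.
#' @return a [suitability_grid()] with minimum 0 and maximum 1.
#' @export
build_suitability <- function(layers, responses) {
  if (length(layers) != length(responses))
    stop("need exactly one response function per layer", call. = FALSE)
  raw <- Reduce(`+`, Map(function(f, l) f(l), responses, layers))
  rng <- range(raw, na.rm = TRUE)
  if (rng[2] - rng[1] < .Machine$double.eps^0.5)
    stop("degenerate species: summed response is constant over the ",
         "landscape", call. = FALSE)
  suitability_grid((raw - rng[1]) / (rng[2] - rng[1]))
}

#' Logistic conversion of suitability to occurrence probability
#'
#' \deqn{\Pr = 1 / (1 + \exp((suitability - \beta) / \alpha)).}
#' With \eqn{\alpha < 0} the probability increases with suitability;
#' \eqn{\beta} is the suitability at which \eqn{\Pr = 0.5}; \eqn{|\alpha|}
#' controls the steepness (the study design fixes \eqn{\alpha = -0.05}).
#'
#' @param suitability a [suitability_grid()] or matrix in \[0, 1\].
#' @param alpha logistic shape, non-zero; default -0.05.
#' @param beta logistic inflection point.
#' @return matrix of occurrence probabilities in \[0, 1\] (`NA` preserved).
#' @export
logistic_probability <- function(suitability, alpha = -0.05, beta) {
  if (alpha == 0) stop("alpha must be non-zero", call. = FALSE)
  s <- unclass(suitability)
  attributes(s) <- list(dim = dim(s))
  1 / (1 + exp(pmin(pmax((s - beta) / alpha, -700), 700)))
}

#' Calibrate the logistic inflection to a target prevalence
#'
#' Finds \eqn{\beta} such that the expected prevalence — the mean occurrence
#' probability over valid cells — matches `target` to within `tol`, by
#' bisection. For \eqn{\alpha < 0} the expected prevalence is continuous and
#' strictly decreasing in \eqn{\beta}, so the root is unique.
#'
#' @param suitability a [suitability_grid()] or matrix.
#' @param alpha logistic shape (see [logistic_probability()]).
#' @param target target prevalence in (0, 1); the study design uses 0.1,
#'   0.25, 0.5 and 0.75.
#' @param tol tolerance on the achieved expected prevalence, default 1e-4.
#' @param bracket search interval for beta, default \[-1, 2\].
#' @return the calibrated `beta`.
#' @export
calibrate_beta <- function(suitability, alpha = -0.05, target,
                           tol = 1e-4, bracket = c(-1, 2)) {
  if (target <= 0 || target >= 1)
    stop("target prevalence must lie in (0, 1)", call. = FALSE)
  g <- function(beta) mean(logistic_probability(suitability, alpha, beta),
                           na.rm = TRUE)
  sgn <- if (alpha < 0) 1 else -1   # g decreasing in beta when alpha < 0
  lo <- bracket[1]; hi <- bracket[2]
  if (sgn * (g(lo) - target) < 0 || sgn * (g(hi) - target) > 0)
    stop(sprintf("target prevalence %g unreachable for beta in [%g, %g]",
                 target, lo, hi), call. = FALSE)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    val <- g(mid)
    if (abs(val - target) <= tol) return(mid)
    if (sgn * (val - target) > 0) lo <- mid else hi <- mid
  }
  stop("beta calibration did not reach the requested tolerance", call. = FALSE)
}

#' Bernoulli realization of a probability surface
#'
#' Each valid cell draws an independent uniform \eqn{x \in (0,1)} and is
#' assigned presence (1) when \eqn{x < \Pr}, absence (0) otherwise.
#'
#' @param prob matrix of occurrence probabilities in \[0, 1\].
#' @param seed integer seed; the map is a deterministic function of it.
#' @return integer 0/1 matrix (`NA` preserved).
#' @export
realize_presence_absence <- function(prob, seed = 1) {
  prob <- unclass(prob)
  if (any(prob < 0 | prob > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  x <- matrix(stats::runif(length(prob)), nrow(prob), ncol(prob))
  out <- matrix(NA_integer_, nrow(prob), ncol(prob))
  ok <- !is.na(prob)
  out[ok] <- as.integer(x[ok] < prob[ok])
  out
}

#' Sample presence and background points from a realized map
#'
#' Presences are drawn uniformly without replacement from cells with
#' `y = 1` (minus `exclude`, e.g. points already spent on model training);
#' background (pseudo-absence) points are drawn uniformly from all valid
#' cells except the presence points just drawn.
#'
#' @param pa_map 0/1/`NA` matrix from [realize_presence_absence()].
#' @param n_presence,n_background sample sizes.
#' @param exclude optional two-column (row, col) matrix/data frame of cells
#'   excluded from the presence draw.
#' @param seed integer seed.
#' @return list with data frames `presences` and `background`, each with
#'   columns `row`, `col`.
#' @export
sample_points <- function(pa_map, n_presence, n_background = 0,
                          exclude = NULL, seed = 1) {
  pa_map <- unclass(pa_map)
  pres_idx <- which(pa_map == 1L)
  valid_idx <- which(!is.na(pa_map))
  if (!is.null(exclude)) {
    ex <- as.matrix(as.data.frame(exclude)[, 1:2])
    ex_idx <- (ex[, 2] - 1L) * nrow(pa_map) + ex[, 1]
    pres_idx <- setdiff(pres_idx, ex_idx)
  }
  if (length(pres_idx) < n_presence)
    stop(sprintf("only %d presence cells available, %d requested",
                 length(pres_idx), n_presence), call. = FALSE)
  set.seed(seed)
  p <- sample(pres_idx, n_presence)
  bg_pool <- setdiff(valid_idx, p)
  if (length(bg_pool) < n_background)
    stop("not enough cells for the background sample", call. = FALSE)
  b <- if (n_background > 0) sample(bg_pool, n_background) else integer(0)
  ij <- function(idx) data.frame(row = ((idx - 1L) %% nrow(pa_map)) + 1L,
                                 col = ((idx - 1L) %/% nrow(pa_map)) + 1L)
  list(presences = ij(p), background = ij(b))
}

#' Simulate a virtual species with known prevalence
#'
#' Full pipeline: smooth synthetic environmental layers, additive response
#' functions, min-max rescaling to a suitability surface, logistic
#' conversion to occurrence probability with \eqn{\beta} calibrated so the
#' expected prevalence hits `prevalence`, and a Bernoulli realization into a
#' presence-absence truth map. Defaults follow the comparative study
#' design: three layers on a 100 x 100 landscape, \eqn{\alpha = -0.05},
#' and prevalence levels of interest 0.1, 0.25, 0.5, 0.75.
#'
#' @param prevalence target prevalence in (0, 1).
#' @param shape landscape dimensions, default `c(100, 100)`.
#' @param n_layers number of environmental layers, default 3.
#' @param smoothness layer autocorrelation scale in cells, default 5.
#' @param responses list of [response_function()]s, one per layer; default
#'   is a gaussian response (optimum 0, tolerance 1) on each standardized
#'   layer.
#' @param alpha logistic shape, default -0.05.
#' @param seed integer master seed for layers and realization.
#' @return an object of class `virtual_species`: list with `env_layers`,
#'   `suitability` (a [suitability_grid()]), `prob`, `pa_map`, `alpha`,
#'   `beta`, `target_prevalence`, `expected_prevalence`,
#'   `realized_prevalence`, `seed`.
#' @examples
#' vs <- virtual_species(prevalence = 0.25, shape = c(40, 40), seed = 7)
#' vs$realized_prevalence
#' @export
virtual_species <- function(prevalence, shape = c(100, 100), n_layers = 3,
                            smoothness = 5, responses = NULL, alpha = -0.05,
                            seed = 1) {
  layers <- generate_environment(n_layers, shape, smoothness, seed = seed)
  if (is.null(responses))
    responses <- replicate(n_layers,
                           response_function("gaussian", mean = 0, sd = 1),
                           simplify = FALSE)
  suit <- build_suitability(layers, responses)
  beta <- calibrate_beta(suit, alpha, prevalence)
  prob <- logistic_probability(suit, alpha, beta)
  pa <- realize_presence_absence(prob, seed = seed + 1L)
  structure(list(
    env_layers = layers, suitability = suit, prob = prob, pa_map = pa,
    alpha = alpha, beta = beta, target_prevalence = prevalence,
    expected_prevalence = mean(prob, na.rm = TRUE),
    realized_prevalence = mean(pa, na.rm = TRUE), seed = seed),
    class = "virtual_species")
}

#' @export
print.virtual_species <- function(x, ...) {
  cat(sprintf("virtual species: %d x %d landscape, %d layers\n",
              nrow(x$pa_map), ncol(x$pa_map), length(x$env_layers)))
  cat(sprintf(
    "  alpha %.3g, beta %.4f; prevalence target %.3f, expected %.4f, realized %.4f\n",
    x$alpha, x$beta, x$target_prevalence, x$expected_prevalence,
    x$realized_prevalence))
  invisible(x)
}
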