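# Independent brute-force oracles and small fixture builders.

# Threshold regression by plain enumeration: trimmed candidates, per-region
# least squares written out directly, global SSR minimum, smallest-gamma tie
# break. Kept deliberately naive.
brute_btqr <- function(hs, pe, trimming = 0.10) {
  q <- stats::quantile(hs, c(trimming, 1 - trimming), names = FALSE)
  cand <- sort(unique(hs[hs >= q[1] & hs <= q[2]]))
  profile <- rep(NA_real_, length(cand))
  for (k in seq_along(cand)) {
    g <- cand[k]
    i1 <- hs > 0 & hs <= g
    i2 <- hs > g
    if (!any(i1) || !any(i2)) next
    d1 <- sum(hs[i1] * pe[i1]) / sum(hs[i1]^2)
    d2 <- sum(hs[i2] * pe[i2]) / sum(hs[i2]^2)
    ssr <- sum((pe[i1] - d1 * hs[i1])^2) + sum((pe[i2] - d2 * hs[i2])^2)
    profile[k] <- ssr
  }
  min_ssr <- min(profile, na.rm = TRUE)
  k <- which(!is.na(profile) & profile <= min_ssr + 1e-8 * (1 + min_ssr))[1]
  list(gamma = cand[k], ssr = profile[k], candidates = cand,
       profile = profile)
}

# Exhaustive criterion search for the confusion-matrix rules.
brute_threshold <- function(method, pres, abs_) {
  cand <- sort(unique(c(0, pres, abs_, 1)))
  crit <- sapply(cand, function(t) {
    tp <- sum(pres >= t); fn <- sum(pres < t)
    fp <- sum(abs_ >= t); tn <- sum(abs_ < t)
    se <- tp / (tp + fn); sp <- tn / (fp + tn)
    n <- tp + fp + fn + tn
    po <- (tp + tn) / n
    pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
    switch(method,
           mss = se + sp,
           ess = -abs(se - sp),
           maxkappa = if (pe >= 1) 0 else (po - pe) / (1 - pe),
           minroc = -sqrt((1 - se)^2 + (1 - sp)^2))
  })
  k <- which.max(crit)
  list(threshold = cand[k], criterion = crit[k])
}

# A noiseless / noisy two-slope P/E-style curve on 100 classes.
piecewise_curve <- function(d1 = 0.3, d2 = 4, break_at = 0.5, sigma = 0,
                            n = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hs <- seq(1 / (2 * n), 1 - 1 / (2 * n), length.out = n)
  pe <- ifelse(hs <= break_at, d1 * hs, d2 * hs)
  if (sigma > 0) pe <- pe + stats::rnorm(n, 0, sigma)
  list(hs = hs, pe = pe)
}

# Uniform-suitability landscape with uniformly placed presences.
uniform_landscape <- function(n_cells = 10000, n_pres = 5000, seed = 1) {
  set.seed(seed)
  side <- round(sqrt(n_cells))
  g <- suitability_grid(matrix(stats::runif(side * side), side, side))
  pts <- cbind(sample(side, n_pres, TRUE), sample(side, n_pres, TRUE))
  list(grid = g, presences = extract_suitability(g, pts))
}
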