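test_that("candidate set keeps observed values between trimming quantiles", {
  hs <- seq(0.1, 1, by = 0.1)
  expect_equal(candidate_thresholds(hs, 0.10),
               seq(0.2, 0.9, by = 0.1))
  expect_equal(candidate_thresholds(hs, 0), hs)
  expect_error(candidate_thresholds(rep(0.5, 10)), "insufficient")
  expect_error(candidate_thresholds(hs, 0.5), "trimming")
})

test_that("two-region fit recovers exact slopes and residuals", {
  hs <- seq(0.05, 0.95, by = 0.05)
  fit <- two_region_ssr(hs, 2 * hs, gamma = 0.5)
  expect_equal(fit$ssr, 0)
  expect_equal(fit$delta1, 2)
  expect_equal(fit$delta2, 2)
  # single-point regions, closed form delta = sum(hs*pe)/sum(hs^2)
  f2 <- two_region_ssr(c(0.2, 0.8), c(0.1, 1.6), gamma = 0.5)
  expect_equal(f2$delta1, 0.5)
  expect_equal(f2$delta2, 2.0)
  expect_equal(f2$ssr, 0)
  # a no-intercept line cannot fit a nonzero constant
  for (g in c(0.3, 0.5, 0.7))
    expect_gt(two_region_ssr(hs, rep(1, length(hs)), g)$ssr, 0)
  expect_error(two_region_ssr(hs, 2 * hs, gamma = 0.99), "infeasible")
})

test_that("noiseless two-slope curves are located exactly", {
  cv <- piecewise_curve(0.3, 4, 0.5, sigma = 0)
  fit <- btqr(cv$hs, cv$pe)
  expect_equal(fit$gamma, max(cv$hs[cv$hs <= 0.5]))
  expect_equal(fit$delta1, 0.3, tolerance = 1e-8)
  expect_equal(fit$delta2, 4, tolerance = 1e-8)
  expect_equal(fit$ssr, 0, tolerance = 1e-12)
  # globally proportional curve: flat zero profile, smallest candidate wins
  flat <- btqr(cv$hs, 2.5 * cv$hs)
  expect_equal(flat$ssr_profile$ssr, rep(0, length(flat$candidates)),
               tolerance = 1e-12)
  expect_equal(flat$gamma, min(flat$candidates))
})

test_that("grid search equals brute-force enumeration on random curves", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(20:120, 1)
    hs <- sort(runif(n))
    pe <- abs(ifelse(hs <= runif(1, 0.3, 0.7), runif(1, 0, 1) * hs,
                     runif(1, 2, 6) * hs) + rnorm(n, 0, 0.1))
    fit <- btqr(hs, pe)
    oracle <- brute_btqr(hs, pe)
    expect_identical(fit$gamma, oracle$gamma)
    expect_equal(fit$ssr, oracle$ssr)
    expect_equal(fit$candidates, oracle$candidates)
    expect_equal(fit$ssr_profile$ssr, oracle$profile)
    expect_true(all(fit$ssr <= fit$ssr_profile$ssr[!is.na(fit$ssr_profile$ssr)]))
  }
})

test_that("breakpoint recovery survives noise", {
  hits <- 0L
  for (seed in 1:20) {
    cv <- piecewise_curve(0.3, 4, 0.5, sigma = 0.05, seed = seed)
    fit <- btqr(cv$hs, cv$pe)
    hits <- hits + (abs(fit$gamma - 0.5) <= 0.05)
  }
  expect_gte(hits, 18L)
})

test_that("fit methods are mutually consistent", {
  cv <- piecewise_curve(0.3, 4, 0.5, sigma = 0.05, seed = 11)
  fit <- btqr(cv$hs, cv$pe)
  expect_s3_class(fit, "btqr")
  expect_named(coef(fit), c("gamma", "delta1", "delta2"))
  expect_true(fit$gamma %in% fit$candidates)
  expect_equal(residuals(fit), cv$pe - predict(fit, cv$hs))
  expect_equal(predict(fit, c(0.1, 0.9)),
               c(0.1 * fit$delta1, 0.9 * fit$delta2))
  s <- summary(fit)
  expect_equal(s$n, 100L)
  expect_output(print(fit), "threshold gamma")
  expect_output(print(s), "region 1")
})

test_that("intercept and quantile-loss variants behave sanely", {
  cv <- piecewise_curve(0.3, 4, 0.5, sigma = 0)
  # exact data: every mode finds the construction break and zero loss
  fi <- btqr(cv$hs, cv$pe, intercept = TRUE)
  expect_equal(fi$gamma, max(cv$hs[cv$hs <= 0.5]))
  expect_equal(fi$ssr, 0, tolerance = 1e-12)
  expect_equal(unname(coef(fi)[c("intercept1", "intercept2")]), c(0, 0),
               tolerance = 1e-8)
  fq <- btqr(cv$hs, cv$pe, loss = "quantile", tau = 0.5)
  expect_equal(fq$gamma, max(cv$hs[cv$hs <= 0.5]))
  expect_equal(fq$ssr, 0, tolerance = 1e-12)
  expect_equal(fq$delta1, 0.3, tolerance = 1e-8)
  # asymmetric check loss shifts the fit toward the tau quantile
  set.seed(3)
  hs <- seq(0.1, 1, by = 0.02)
  pe <- hs * 2 + rexp(length(hs), 2)
  d9 <- btqr(hs, pe, loss = "quantile", tau = 0.9)$delta2
  d1 <- btqr(hs, pe, loss = "quantile", tau = 0.1)$delta2
  expect_gt(d9, d1)
})

test_that("threshold is stable under validation-set resampling", {
  vs <- virtual_species(prevalence = 0.5, shape = c(80, 80), seed = 5)
  shift <- sapply(1:8, function(s) {
    p1 <- sample_points(vs$pa_map, 400, seed = 100 + s)$presences
    p2 <- sample_points(vs$pa_map, 1600, seed = 200 + s)$presences
    g1 <- btqr_threshold(vs$suitability,
                         extract_suitability(vs$suitability, p1),
                         window = 0.02)
    g2 <- btqr_threshold(vs$suitability,
                         extract_suitability(vs$suitability, p2),
                         window = 0.02)
    abs(g1 - g2)
  })
  expect_lt(median(shift), 0.02)
})

test_that("degenerate inputs are rejected with clear errors", {
  g <- suitability_grid(matrix(0.42, 20, 20))
  expect_error(btqr_threshold(g, rep(0.42, 10)), "5 retained classes")
  cv <- piecewise_curve(n = 100)
  expect_error(btqr(cv$hs, sample(cv$pe)), NA)  # default method sorts by hs
  bad <- data.frame(hs = c(0.1, 0.2), pe = c(1, 2))
  expect_error(btqr(bad$hs, bad$pe), "at least 5")
  # repeated calls with identical inputs agree
  d <- uniform_landscape(2500, 500, seed = 2)
  t1 <- btqr_threshold(d$grid, d$presences)
  t2 <- btqr_threshold(d$grid, d$presences)
  expect_identical(t1, t2)
})

test_that("fit serializes to JSON with the profile intact", {
  cv <- piecewise_curve(sigma = 0.05, seed = 4)
  fit <- btqr(cv$hs, cv$pe)
  path <- withr::local_tempfile(fileext = ".json")
  write_btqr(fit, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(j$gamma_hat, fit$gamma)
  expect_equal(j$delta1, fit$delta1)
  expect_equal(nrow(j$ssr_profile), length(fit$candidates))
})
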