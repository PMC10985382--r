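test_that("environmental layers are deterministic, standardized, smooth", {
  a <- generate_environment(3, c(40, 40), smoothness = 5, seed = 9)
  b <- generate_environment(3, c(40, 40), smoothness = 5, seed = 9)
  expect_identical(a, b)
  expect_length(a, 3L)
  for (l in a) {
    expect_equal(mean(l), 0, tolerance = 1e-6)
    expect_equal(sd(l), 1, tolerance = 1e-6)
  }
  # lag-1 spatial autocorrelation grows with the smoothness scale
  lag1 <- function(m) cor(as.numeric(m[, -ncol(m)]), as.numeric(m[, -1]))
  ac <- sapply(c(1, 5, 25), function(s)
    lag1(generate_environment(1, c(60, 60), s, seed = 2)[[1]]))
  expect_true(all(diff(ac) > 0))
  expect_error(generate_environment(1, c(40, 40), smoothness = 0), "smooth")
  expect_error(generate_environment(1, c(5, 5)), "10 x 10")
})

test_that("additive responses rescale to [0, 1] and reject constants", {
  l <- generate_environment(1, c(30, 30), 3, seed = 1)[[1]]
  s <- build_suitability(list(l), list(response_function("linear")))
  expect_equal(min(s), 0)
  expect_equal(max(s), 1)
  expect_equal(as.numeric(s), as.numeric((l - min(l)) / (max(l) - min(l))))
  # rescaling is idempotent
  s2 <- build_suitability(list(unclass(s)), list(response_function("linear")))
  expect_equal(as.numeric(s2), as.numeric(s))
  # gaussian response peaks where the layer sits at the optimum
  g <- response_function("gaussian", mean = 0.3, sd = 0.5)
  expect_equal(g(0.3), 1)
  expect_lt(g(1.2), g(0.3))
  expect_error(
    build_suitability(list(l, -l),
                      list(response_function("linear"),
                           response_function("linear"))),
    "degenerate")
  expect_error(build_suitability(list(l), list()), "one response")
})

test_that("logistic conversion has the documented shape", {
  s <- suitability_grid(matrix(seq(0, 1, length.out = 100), 10, 10))
  p <- logistic_probability(s, alpha = -0.05, beta = 0.5)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(logistic_probability(matrix(0.5), -0.05, 0.5)[1], 0.5)
  expect_equal(logistic_probability(matrix(0.55), -0.05, 0.5)[1],
               1 / (1 + exp(-1)))
  # alpha < 0: probability increases with suitability
  expect_true(all(diff(p[order(as.numeric(s))]) >= 0))
  # near-zero alpha approaches a step function at beta
  p0 <- logistic_probability(matrix(c(0.49, 0.51), 1, 2), -1e-9, 0.5)
  expect_equal(as.numeric(p0), c(0, 1))
  expect_error(logistic_probability(s, 0, 0.5), "non-zero")
})

test_that("beta calibration reaches every study prevalence level", {
  set.seed(4)
  s <- suitability_grid(matrix(runif(10000), 100, 100))
  betas <- sapply(c(0.1, 0.25, 0.5, 0.75), function(tgt) {
    b <- calibrate_beta(s, -0.05, tgt)
    expect_lte(abs(mean(logistic_probability(s, -0.05, b)) - tgt), 1e-4)
    b
  })
  expect_true(all(diff(betas) < 0))   # higher prevalence, lower beta
  # near-uniform suitability and symmetric target puts beta near 0.5
  expect_equal(betas[3], 0.5, tolerance = 0.02)
  expect_error(calibrate_beta(s, -0.05, 1.5), "\\(0, 1\\)")
})

test_that("Bernoulli realization tracks the probability surface", {
  expect_true(all(realize_presence_absence(matrix(1, 20, 20), 1) == 1L))
  expect_true(all(realize_presence_absence(matrix(0, 20, 20), 1) == 0L))
  pr <- matrix(0.3, 100, 100)
  y <- realize_presence_absence(pr, seed = 8)
  se <- sqrt(0.3 * 0.7 / 1e4)
  expect_lt(abs(mean(y) - 0.3), 3 * se)
  expect_identical(y, realize_presence_absence(pr, seed = 8))
})

test_that("point sampling honors exclusions and determinism", {
  pa <- matrix(0L, 20, 20)
  pa[1:10, 1:10] <- 1L
  all_pres <- sample_points(pa, 100, seed = 1)$presences
  expect_equal(nrow(all_pres), 100L)
  expect_true(all(pa[as.matrix(all_pres)] == 1L))
  s <- sample_points(pa, 50, n_background = 200, seed = 3)
  expect_equal(nrow(merge(s$presences, s$background)), 0L)
  expect_identical(s, sample_points(pa, 50, n_background = 200, seed = 3))
  expect_false(identical(s$presences,
                         sample_points(pa, 50, 200, seed = 4)$presences))
  ex <- sample_points(pa, 60, exclude = all_pres[1:40, ], seed = 5)$presences
  expect_equal(nrow(merge(ex, all_pres[1:40, ])), 0L)
  expect_error(sample_points(pa, 101), "available")
})

test_that("end-to-end virtual species hit their target prevalence", {
  for (tgt in c(0.1, 0.25, 0.5, 0.75)) {
    vs <- virtual_species(prevalence = tgt, shape = c(100, 100), seed = 21)
    expect_lte(abs(vs$expected_prevalence - tgt), 1e-4)
    se <- sqrt(tgt * (1 - tgt) / 1e4)
    expect_lt(abs(vs$realized_prevalence - tgt), 3 * se)
    expect_true(all(vs$prob >= 0 & vs$prob <= 1))
    expect_true(all(vs$pa_map %in% c(0L, 1L)))
    expect_equal(min(vs$suitability), 0)
    expect_equal(max(vs$suitability), 1)
  }
})
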