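test_that("confusion counts follow the inclusive >= rule", {
  cm <- confusion_at(0.5, c(0.2, 0.8), c(0.3, 0.6))
  expect_equal(unclass(cm)[c("tp", "fp", "fn", "tn")],
               c(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  all_pres <- confusion_at(0, c(0.2, 0.8), c(0.3, 0.6))
  expect_equal(all_pres[["fn"]] + all_pres[["tn"]], 0L)
  at_one <- confusion_at(1, c(0.5, 1), c(0.99, 1))
  expect_equal(at_one[["tp"]], 1L)   # only predictions equal to 1 pass
  expect_equal(at_one[["fp"]], 1L)
  expect_error(confusion_at(0.5, numeric(0), c(0.3)), "non-empty")
})

test_that("Cohen's kappa matches its closed form", {
  expect_equal(cohen_kappa(c(tp = 50, fp = 0, fn = 0, tn = 50)), 1)
  expect_equal(cohen_kappa(c(tp = 40, fp = 10, fn = 10, tn = 40)), 0.6)
  expect_equal(cohen_kappa(c(tp = 25, fp = 25, fn = 25, tn = 25)), 0)
  expect_warning(k <- cohen_kappa(c(tp = 10, fp = 0, fn = 0, tn = 0)),
                 "degenerate")
  expect_equal(k, 0)
})

test_that("worked examples for the named rules", {
  expect_equal(select_threshold("Se0.5", c(0.2, 0.4, 0.6, 0.8))$threshold,
               0.6)
  expect_equal(select_threshold("MeanProb",
                                grid_preds = c(0, 0.5, 1))$threshold, 0.5)
  set.seed(1)
  gp <- c(runif(75, 0, 0.69), runif(25, 0.7, 1))
  gp[76] <- 0.7
  eq <- select_threshold("EqualPrev", grid_preds = gp,
                         observed_prevalence = 0.25)
  expect_equal(eq$threshold, 0.7)
  # perfectly separated validation data: all four confusion rules reach
  # sens = spec = 1 at some threshold in (0.1, 0.9]
  pres <- rep(0.9, 20); abs_ <- rep(0.1, 20)
  for (m in c("MSS", "ESS", "MaxKappa", "MinROC")) {
    r <- select_threshold(m, pres, abs_)
    expect_gt(r$threshold, 0.1)
    expect_lte(r$threshold, 0.9)
    cm <- confusion_at(r$threshold, pres, abs_)
    expect_equal(cm[["tp"]], 20L)
    expect_equal(cm[["tn"]], 20L)
  }
  ess <- select_threshold("ESS", c(0.2, 0.8), c(0.3, 0.6))
  expect_equal(ess$threshold, brute_threshold("ess", c(0.2, 0.8),
                                              c(0.3, 0.6))$threshold)
})

test_that("optimizing rules equal brute-force search on random sets", {
  for (seed in 1:30) {
    set.seed(seed)
    pres <- runif(sample(20:200, 1), 0.2, 1)
    abs_ <- runif(sample(20:200, 1), 0, 0.8)
    for (m in c("mss", "ess", "maxkappa", "minroc")) {
      got <- suppressWarnings(select_threshold(m, pres, abs_))
      want <- brute_threshold(m, pres, abs_)
      expect_identical(got$threshold, want$threshold)
      crit <- if (m %in% c("ess", "minroc")) -got$criterion_value
              else got$criterion_value
      expect_equal(crit, want$criterion)
    }
  }
})

test_that("fixed-sensitivity thresholds sit exactly at the quantile edge", {
  for (seed in 1:10) for (s in c(0.5, 0.75, 0.9)) {
    set.seed(seed)
    pres <- runif(sample(30:300, 1))
    r <- select_threshold(sprintf("Se%g", s), pres)
    expect_gte(mean(pres >= r$threshold), s)
    cand <- sort(unique(c(0, pres, 1)))
    above <- cand[cand > r$threshold]
    if (length(above))
      expect_lt(mean(pres >= above[1]), s)
  }
  expect_message(select_threshold("se", c(0.5, 0.6), sens = 0.9),
                 "resolution")
  expect_error(select_threshold("se", c(0.5, 0.6), sens = 1.2), "\\(0, 1\\)")
})

test_that("sensitivity falls and specificity rises with the threshold", {
  set.seed(5)
  pres <- runif(100, 0.3, 1); abs_ <- runif(100, 0, 0.7)
  ts <- seq(0, 1, by = 0.05)
  sens <- sapply(ts, function(t) mean(pres >= t))
  spec <- sapply(ts, function(t) mean(abs_ < t))
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))
})

test_that("MaxKappa dominates every other rule's kappa on shared data", {
  vs <- virtual_species(prevalence = 0.25, shape = c(50, 50), seed = 13)
  pts <- sample_points(vs$pa_map, 150, 300, seed = 77)
  pres <- vs$suitability[as.matrix(pts$presences)]
  abs_ <- vs$suitability[as.matrix(pts$background)]
  kmax <- NULL
  ks <- sapply(c("MaxKappa", "MSS", "ESS", "MinROC", "Se0.5", "Se0.9"),
               function(m) {
    t <- select_threshold(m, pres, abs_)$threshold
    cohen_kappa(confusion_at(t, pres, abs_))
  })
  expect_true(all(ks["MaxKappa"] >= ks - 1e-12))
  # every rule, including BTQR, stays inside [0, 1]
  tb <- select_threshold("BTQR", presence_preds = pres,
                         grid = vs$suitability, window = 0.02)$threshold
  expect_true(all(c(ks >= -1), tb >= 0, tb <= 1))
})

test_that("missing inputs are named in errors", {
  expect_error(select_threshold("MSS", c(0.5)), "absence_preds")
  expect_error(select_threshold("EqualPrev", grid_preds = runif(10)),
               "observed_prevalence")
  expect_error(select_threshold("BTQR", presence_preds = runif(10)), "grid")
  expect_error(select_threshold("nope", runif(5)), "unknown method")
})
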