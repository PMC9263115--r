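test_that("Kaplan-Meier equals the empirical survivor function without censoring", {
  fit <- km_curves(c(1, 2, 3), c(1, 1, 1))
  expect_equal(summary(fit)$surv, c(2 / 3, 1 / 3, 0))
  # all censored: survival stays at 1
  fit2 <- km_curves(c(4, 6, 9), c(0, 0, 0))
  expect_true(all(fit2$surv == 1))
})

test_that("Kaplan-Meier matches a hand product-limit table with censoring", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 0, 1, 0, 1, 1)
  fit <- km_curves(time, event)
  hand <- oracle_km(time, event)
  expect_equal(summary(fit, times = hand$time)$surv, hand$surv)
  expect_equal(hand$surv, c(5 / 6, 0.625, 0.3125, 0))
  # non-increasing, starts at 1
  expect_true(all(diff(fit$surv) <= 0))
  expect_lte(fit$surv[1], 1)
})

test_that("log-rank: identical groups give a null statistic, separation a large one", {
  time <- c(2, 4, 6, 8, 10)
  event <- c(1, 1, 0, 1, 1)
  lr <- logrank_test(rep(time, 2), rep(event, 2), rep(1:2, each = 5))
  expect_lt(lr$statistic, 1e-10)
  expect_equal(lr$p_value, 1, tolerance = 1e-6)
  expect_equal(lr$df, 1)

  sep <- logrank_test(c(1, 2, 3, 20, 21, 22), rep(1, 6), rep(1:2, each = 3))
  expect_gt(sep$statistic, 5)
  expect_lt(sep$p_value, 0.05)

  expect_error(logrank_test(time, event, rep(1, 5)), "at least 2 groups")
  # common delayed entry is accepted, subject-specific entry is not
  expect_silent(logrank_test(rep(time, 2) + 5, rep(event, 2),
                             rep(1:2, each = 5), entry = 5))
  expect_error(logrank_test(rep(time, 2) + 5, rep(event, 2),
                            rep(1:2, each = 5), entry = seq(0.1, 1, 0.1)),
               "delayed entry")
})

test_that("the generator's endotype mortality gradient is detected by the log-rank", {
  ps <- vapply(1:60, function(s) {
    co <- simulate_ht_cohort(seed = s)
    m <- cohort_metrics(co)
    a <- assign_endotypes(m, derive_thresholds(m, dpvh_cut = 75))
    logrank_test(co$time_years, co$event, a$endotype, entry = 5)$p_value
  }, numeric(1))
  # significant in the majority of study-sized replicates
  expect_gt(mean(ps < 0.05), 0.5)
  expect_lt(median(ps), 0.05)
})

test_that("Cox fit recovers a planted hazard ratio and validates its inputs", {
  d <- simulate_cox_cohort(2000, hr = 2, seed = 42)
  fit <- cox_fit(d, "x")
  expect_s3_class(fit, "flow_cox")
  expect_gt(fit$summary$ci_upper, 2)
  expect_lt(fit$summary$ci_lower, 2)
  expect_equal(fit$summary$hr, exp(fit$summary$coef))
  expect_true(fit$summary$ci_lower < fit$summary$hr &
                fit$summary$hr < fit$summary$ci_upper)

  d$z <- 1
  expect_error(cox_fit(d, "z"), "constant")
  expect_error(cox_fit(d, "nope"), "not found")
  d0 <- d
  d0$event <- 0
  expect_error(cox_fit(d0, "x"), "at least one event")
  # complete separation raises an error instead of silent divergence
  dsep <- data.frame(time_years = c(1:5, 101:105),
                     event = 1,
                     x = rep(1:0, each = 5))
  expect_error(cox_fit(dsep, "x"), "Cox fit failed")
})

test_that("null-covariate p-values are approximately uniform", {
  set.seed(99)
  ps <- replicate(200, {
    d <- simulate_cox_cohort(300, hr = 2)
    d$noise <- rnorm(nrow(d))
    cox_fit(d, "noise")$summary$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_equal(mean(ps), 0.5, tolerance = 0.1)
})

test_that("univariable screen keeps candidates below alpha in input order", {
  set.seed(7)
  d <- simulate_cox_cohort(400, hr = 3)
  d$noise1 <- rnorm(400)
  d$noise2 <- rnorm(400)
  sc <- univariable_screen(d, c("noise1", "x", "noise2"), alpha = 0.10)
  expect_equal(sc$term, c("noise1", "x", "noise2"))
  expect_true(sc$selected[sc$term == "x"])
  expect_true("x" %in% attr(sc, "selected"))

  # strong predictor selected across seeds
  always <- vapply(1:10, function(s) {
    d <- simulate_cox_cohort(400, hr = 3, seed = s)
    "x" %in% attr(suppressWarnings(univariable_screen(d, "x")), "selected")
  }, logical(1))
  expect_true(all(always))

  # nothing selected -> empty list with a warning
  d$pure <- rep(c(0.4, 0.6), 200)
  expect_warning(sc2 <- univariable_screen(d, "pure", alpha = 1e-6),
                 "multivariable step")
  expect_length(attr(sc2, "selected"), 0)
})

test_that("Harrell's C matches the exhaustive pair-count oracle", {
  # perfectly inversely ordered risk, no censoring
  time <- sort(runif(20, 1, 10))
  risk <- -time   # higher risk score = earlier death
  expect_equal(harrell_c(risk, time, rep(1, 20)), 1.0)
  expect_equal(harrell_c(-risk, time, rep(1, 20)), 0.0)

  for (seed in c(11, 23)) {
    set.seed(seed)
    n <- 30
    time <- rexp(n) + runif(n, 0, 1e-3)       # continuous, no ties
    event <- rbinom(n, 1, 0.7)
    risk <- rnorm(n)
    expect_equal(harrell_c(risk, time, event),
                 oracle_concordance(risk, time, event))
    # negation flips the concordance
    expect_equal(harrell_c(-risk, time, event),
                 1 - harrell_c(risk, time, event))
  }

  # tied risks count one half
  set.seed(5)
  risk_tied <- sample(1:3, 25, replace = TRUE)
  time <- runif(25)
  expect_equal(harrell_c(risk_tied, time, rep(1, 25)),
               oracle_concordance(risk_tied, time, rep(1, 25)))

  # risk independent of survival: C near one half
  set.seed(17)
  expect_equal(harrell_c(rnorm(4000), rexp(4000), rbinom(4000, 1, 0.7)),
               0.5, tolerance = 0.03)
})

test_that("likelihood-ratio test: zero for self-comparison, chi-square under the null", {
  d <- simulate_cox_cohort(500, hr = 2, seed = 8)
  d$noise <- rnorm(500)
  base <- cox_fit(d, "x")
  self <- likelihood_ratio_test(base, base)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)

  ext <- cox_fit(d, c("x", "noise"))
  lrt <- likelihood_ratio_test(base, ext)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$df, 1)

  # nesting is enforced
  other <- cox_fit(d, "noise")
  expect_error(likelihood_ratio_test(base, other), "not nested")
  d2 <- d[1:400, ]
  expect_error(likelihood_ratio_test(cox_fit(d2, "x"), ext), "identical records")

  # a strongly prognostic addition is detected in most replicates
  small_ps <- vapply(1:20, function(s) {
    dd <- simulate_cox_cohort(300, hr = 2.5, seed = 100 + s)
    dd$noise <- rnorm(300)
    likelihood_ratio_test(cox_fit(dd, "noise"),
                          cox_fit(dd, c("noise", "x")))$p_value
  }, numeric(1))
  expect_gt(mean(small_ps < 0.05), 0.5)
})

test_that("continuous NRI: extremes, identity, antisymmetry, permutation null", {
  ev <- c(rep(TRUE, 5), rep(FALSE, 5))
  base <- rep(0.5, 10)
  best <- ifelse(ev, 0.9, 0.1)
  expect_equal(continuous_nri(base, best, ev)$nri, 2.0)
  expect_equal(continuous_nri(base, base, ev)$nri, 0.0)

  set.seed(31)
  b <- runif(100)
  e <- runif(100)
  ev2 <- rbinom(100, 1, 0.4)
  expect_equal(continuous_nri(b, e, ev2)$nri,
               -continuous_nri(e, b, ev2)$nri)

  # random relabelling of risks has mean NRI near zero
  nris <- replicate(300, continuous_nri(b, sample(b), ev2)$nri)
  expect_lt(abs(mean(nris)), 0.05)

  expect_error(continuous_nri(b, e, rep(1, 100)), "non-events")
})

test_that("model comparison reports C, LRT and NRI for separately added markers", {
  set.seed(12)
  d <- simulate_cox_cohort(400, hr = 2.5)
  d$age <- rnorm(400, 50, 10)
  d$marker2 <- rnorm(400)
  mc <- model_comparison(d, base_covariates = "age",
                         added_markers = c("x", "marker2"))
  expect_equal(mc$model, c("base", "base + x", "base + marker2"))
  expect_true(all(mc$c_index > 0 & mc$c_index < 1))
  expect_true(all(mc$lrt_chisq[-1] >= 0))
  # the informative marker improves fit far more than noise
  expect_lt(mc$lrt_p[2], 0.01)
  expect_gt(mc$nri[2], mc$nri[3])
  fits <- attr(mc, "fits")
  expect_equal(fits$base$covariates, "age")
  expect_equal(fits$x$covariates, c("age", "x"))
})
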