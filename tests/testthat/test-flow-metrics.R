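test_that("CFVR and CCFVR reproduce the velocity-domain worked examples", {
  expect_equal(round(compute_cfvr(25, 50), 1), 2.0)
  expect_equal(compute_cfvr(30, 30), 1.0)
  expect_equal(compute_cfvr(26, 92), 92 / 26)
  expect_equal(round(compute_ccfvr(25, 50), 1), 55.9)
  expect_equal(round(compute_ccfvr(40, 80), 1), 89.4)
  expect_equal(compute_ccfvr(3, 4), 5.0)
})

test_that("non-positive velocities are rejected with the offending position", {
  expect_error(compute_cfvr(0, 50), "dpv_r")
  expect_error(compute_cfvr(c(25, -1), c(50, 60)), "position 2")
  expect_error(compute_ccfvr(25, 0), "dpv_h")
})

test_that("mean arterial pressure follows the cuff formula and its domain", {
  expect_equal(mean_arterial_pressure(120, 80), 280 / 3)
  expect_equal(mean_arterial_pressure(150, 75), 100)
  expect_error(mean_arterial_pressure(90, 90), "sap > dap")
  expect_error(mean_arterial_pressure(90, 95), "sap > dap")
})

test_that("microvascular resistance and ARI are the stated quotient and difference", {
  expect_equal(microvascular_resistance(280 / 3, 25), 280 / 75)
  expect_equal(microvascular_resistance(100, 80), 1.25)
  expect_error(microvascular_resistance(100, 0), "velocity")
  expect_equal(arteriolar_resistance_index(5.0, 1.5), 3.5)
  expect_equal(arteriolar_resistance_index(2.0, 2.0), 0.0)
  # negative ARI is allowed, not rejected
  expect_equal(arteriolar_resistance_index(1.0, 1.5), -0.5)
})

test_that("rate-pressure product and rpCFVR", {
  expect_equal(rate_pressure_product(70, 120), 8400)
  expect_equal(rate_pressure_product(82, 135), 11070)
  expect_equal(compute_rpcfvr(2.9, 8400), 2.9 / 8400 * 1e4)
  expect_equal(compute_rpcfvr(1.0, 10000), 1.0)
  expect_error(compute_rpcfvr(2, 0), "positive")
})

test_that("delta DPV in absolute and percent terms", {
  d <- delta_dpv(c(25, 30, 20), c(50, 30, 62))
  expect_equal(d$delta_dpv_abs, c(25, 0, 42))
  expect_equal(d$delta_dpv_pct, c(100, 0, 210))
})

test_that("polar mapping: angle encodes CFVR, radius is CCFVR, round-trip is exact", {
  p <- to_polar(25, 25)
  expect_equal(p$angle_deg, 45)
  expect_equal(p$radius, 25 * sqrt(2))
  p2 <- to_polar(25, 50)
  expect_equal(p2$angle_deg, atan(2) * 180 / pi)
  expect_equal(round(p2$radius, 1), 55.9)
  # angle tends to 0 as the hyperemic velocity vanishes
  expect_lt(to_polar(1, 1e-9)$angle_deg, 1e-6)

  pairs <- random_velocity_pairs(500, seed = 101)
  pol <- to_polar(pairs$dpv_r, pairs$dpv_h)
  back <- from_polar(pol$angle_deg, pol$radius)
  expect_equal(back$dpv_r, pairs$dpv_r, tolerance = 1e-9)
  expect_equal(back$dpv_h, pairs$dpv_h, tolerance = 1e-9)
  expect_true(all(pol$angle_deg > 0 & pol$angle_deg < 90))
})

test_that("algebraic invariants hold across random velocity pairs", {
  pairs <- random_velocity_pairs(2000, seed = 7)
  cf <- compute_cfvr(pairs$dpv_r, pairs$dpv_h)
  cc <- compute_ccfvr(pairs$dpv_r, pairs$dpv_h)
  # norm bounds
  expect_true(all(cc >= pmax(pairs$dpv_r, pairs$dpv_h)))
  expect_true(all(cc <= pairs$dpv_r + pairs$dpv_h))
  # ccfvr = dpv_r * sqrt(1 + cfvr^2)
  expect_equal(cc, pairs$dpv_r * sqrt(1 + cf^2), tolerance = 1e-12)
  # quadratic-mean relation
  qm <- sqrt((pairs$dpv_r^2 + pairs$dpv_h^2) / 2)
  expect_equal(qm / cc, rep(1 / sqrt(2), nrow(pairs)), tolerance = 1e-12)
  # homogeneity: scaling both velocities by k preserves cfvr, scales ccfvr
  for (k in c(0.5, 2, 7.3)) {
    expect_equal(compute_cfvr(k * pairs$dpv_r, k * pairs$dpv_h), cf)
    expect_equal(compute_ccfvr(k * pairs$dpv_r, k * pairs$dpv_h), k * cc,
                 tolerance = 1e-12)
  }
})

test_that("cohort_metrics composes the single-index operations consistently", {
  cohort <- data.frame(subject_id = "P1", dpv_r = 25, dpv_h = 50,
                       sap_r = 120, dap_r = 80, sap_h = 110, dap_h = 70,
                       hr_r = 70, hr_h = 90)
  m <- cohort_metrics(cohort)
  expect_equal(m$cfvr, 2.0)
  expect_equal(round(m$ccfvr, 1), 55.9)
  expect_equal(m$bmr, (280 / 3) / 25)
  expect_equal(m$hmr, (250 / 3) / 50)
  expect_equal(m$ari, m$bmr - m$hmr)
  expect_equal(round(c(m$bmr, m$hmr, m$ari), 3), c(3.733, 1.667, 2.067))
  expect_equal(m$rpp_r, 70 * 120)
  expect_equal(m$subject_id, "P1")
  expect_false(m$ari_negative)

  # identical rest/hyperemia vitals give equal mean pressures
  same <- within(cohort, {sap_h <- sap_r; dap_h <- dap_r; hr_h <- hr_r})
  ms <- cohort_metrics(same)
  expect_equal(ms$map_r, ms$map_h)

  # a missing vital is reported by name
  expect_error(cohort_metrics(cohort[setdiff(names(cohort), "hr_h")]), "hr_h")
  cohort$dap_r <- NA
  expect_error(cohort_metrics(cohort), "dap_r")
})

test_that("ARI equals MAP_r/DPVr - MAP_h/DPVh compositionally", {
  set.seed(33)
  n <- 200
  cohort <- data.frame(
    dpv_r = runif(n, 15, 45), dpv_h = runif(n, 40, 110),
    sap_r = runif(n, 110, 150), dap_r = runif(n, 70, 95),
    sap_h = runif(n, 105, 145), dap_h = runif(n, 65, 90),
    hr_r = runif(n, 60, 100), hr_h = runif(n, 75, 115))
  m <- cohort_metrics(cohort)
  expect_equal(m$ari, m$map_r / cohort$dpv_r - m$map_h / cohort$dpv_h,
               tolerance = 1e-12)
})

test_that("rpCFVR can be normalised to the hyperemic rate-pressure product", {
  cohort <- make_cohort_rows(3)
  m_rest <- cohort_metrics(cohort)
  m_hyp <- cohort_metrics(cohort, rpp_condition = "hyperemia")
  expect_equal(m_rest$rpcfvr, m_rest$cfvr / (cohort$hr_r * cohort$sap_r) * 1e4)
  expect_equal(m_hyp$rpcfvr, m_hyp$cfvr / (cohort$hr_h * cohort$sap_h) * 1e4)
})
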