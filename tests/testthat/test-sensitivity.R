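test_that("Cochran Q matches hand evaluation and its degenerate cases", {
  # ratios 0.2 and 0.3 with weights bx^2/sy^2 = 100 each
  h <- harmonizedSet(bx = c(1, 1), by = c(0.2, 0.3), sx = 0.01, sy = 0.1)
  q <- cochranQ(h)
  expect_equal(q@Q, 0.5)
  expect_equal(q@df, 1L)
  expect_equal(q@pvalue, pchisq(0.5, 1, lower.tail = FALSE))

  # identical ratios: no heterogeneity
  h0 <- harmonizedSet(bx = c(1, 2, 3), by = 0.4 * c(1, 2, 3), sx = 0.01, sy = 0.1)
  q0 <- cochranQ(h0)
  expect_equal(q0@Q, 0, tolerance = 1e-20)
  expect_equal(q0@pvalue, 1)

  expect_error(cochranQ(harmonizedSet(1, 0.2, 0.01, 0.1)), "at least 2")

  # Egger reference uses J - 2 df
  qe <- cochranQ(h0, "egger")
  expect_equal(qe@df, 1L)
  expect_equal(qe@Q, 0, tolerance = 1e-20)
})

test_that("Egger intercept test flags directional pleiotropy only", {
  h0 <- harmonizedSet(bx = c(0.1, 0.2, 0.3, 0.4), by = 0.4 * c(0.1, 0.2, 0.3, 0.4),
                      sx = 0.01, sy = 0.05)
  t0 <- eggerInterceptTest(h0)
  expect_equal(t0$intercept@beta, 0, tolerance = 1e-12)
  expect_false(t0$significant)

  # strong directional pleiotropy on every SNP is detected
  tp <- truthParams(J = 50, causalEffect = 0.2, invalidFraction = 1,
                    pleioMean = 0.1, pleioSd = 0.01, seed = 17L)
  p <- simulatePair(tp)
  h <- harmonize(exposureStats(p), outcomeStats(p))
  t1 <- eggerInterceptTest(h)
  expect_true(t1$significant)
  expect_lt(abs(t1$intercept@beta - 0.1), 3 * t1$intercept@se)
})

test_that("MR-PRESSO is quiet on collinear data and reproducible", {
  h <- harmonizedSet(bx = seq(0.1, 0.4, length.out = 6),
                     by = 0.5 * seq(0.1, 0.4, length.out = 6),
                     sx = 1e-4, sy = 1e-4)
  pr <- mrPresso(h, nSim = 200, seed = 3)
  expect_gte(pr@globalP, 0.05)
  expect_length(pr@removedIds, 0)
  expect_null(pr@correctedEstimate)

  pr2 <- mrPresso(h, nSim = 200, seed = 3)
  expect_identical(pr@globalP, pr2@globalP)
  expect_identical(pr@outlierPvalues, pr2@outlierPvalues)

  expect_error(mrPresso(harmonizedSet(c(1, 2, 3), c(1, 2, 3), 0.1, 0.1)),
               "at least 4")
})

test_that("MR-PRESSO removes planted outliers and never lowers p to 0", {
  tp <- truthParams(J = 30, causalEffect = 0.5, outlierIds = c(5L, 20L),
                    seed = 23L)
  p <- simulatePair(tp)
  h <- harmonize(exposureStats(p), outcomeStats(p))
  pr <- mrPresso(h, nSim = 1000, seed = 1)
  expect_true(all(c("rs5", "rs20") %in% pr@removedIds))
  expect_gte(pr@globalP, 1 / 1001)
  # corrected estimate sits closer to the simulated truth
  pre <- mrIVW(h)
  expect_lt(abs(pr@correctedEstimate@beta - 0.5), abs(pre@beta - 0.5))

  # removing a flagged SNP cannot increase Cochran Q
  kept1 <- subsetHarmonized <- mrpipe:::subsetHarmonized(
    h, !variantIds(h) %in% pr@removedIds[1])
  expect_lt(cochranQ(kept1)@Q, cochranQ(h)@Q)
})

test_that("doubling nSim moves the global p by Monte-Carlo error only", {
  tp <- truthParams(J = 15, causalEffect = 0.3, invalidFraction = 0.3,
                    pleioMean = 0, pleioSd = 0.05, seed = 41L)
  p <- simulatePair(tp)
  h <- harmonize(exposureStats(p), outcomeStats(p))
  p1 <- mrPresso(h, nSim = 1000, seed = 2)@globalP
  p2 <- mrPresso(h, nSim = 2000, seed = 2)@globalP
  expect_lt(abs(p2 - p1), 3 * sqrt(p1 * (1 - p1) / 1000) + 2e-3)
})

test_that("leave-one-out returns J + 1 rows with the expected reductions", {
  # identical ratios: every row equals the full estimate
  h <- harmonizedSet(bx = c(1, 2, 3), by = 0.4 * c(1, 2, 3), sx = 0.01, sy = 0.1)
  loo <- leaveOneOut(h)
  expect_equal(nrow(loo), 4L)
  expect_equal(loo$excluded[4], "All")
  expect_true(all(abs(loo$beta - 0.4) < 1e-12))

  # J = 2: each row is the other SNP's Wald ratio
  h2 <- harmonizedSet(bx = c(0.1, 0.2), by = c(0.05, 0.04), sx = 0.01, sy = 0.1)
  loo2 <- leaveOneOut(h2)
  expect_equal(loo2$beta[1], 0.04 / 0.2)
  expect_equal(loo2$beta[2], 0.05 / 0.1)

  expect_error(leaveOneOut(harmonizedSet(1, 0.4, 0.01, 0.1)), "at least 2")
})
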