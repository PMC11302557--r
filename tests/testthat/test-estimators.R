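test_that("Wald ratio matches the arithmetic and its symmetries", {
  h <- harmonizedSet(bx = 0.1, by = 0.05, sx = 0.01, sy = 0.1)
  est <- waldRatio(h)
  expect_equal(est@beta, 0.5)
  expect_equal(est@se, 1.0)

  expect_equal(waldRatio(harmonizedSet(0.1, 0, 0.01, 0.1))@beta, 0)
  # negating both betas leaves the ratio unchanged
  expect_equal(waldRatio(harmonizedSet(-0.1, -0.05, 0.01, 0.1))@beta, 0.5)
  expect_error(waldRatio(harmonizedSet(0, 0.05, 0.01, 0.1)), "degenerate")
})

test_that("IVW reproduces the closed-form WLS oracle and reduces to Wald", {
  h <- harmonizedSet(bx = c(0.1, 0.2), by = c(0.02, 0.06),
                     sx = 0.01, sy = c(0.01, 0.02))
  est <- mrIVW(h)
  expect_equal(est@beta, 0.25)
  expect_equal(est@details$seFixed, 1 / sqrt(200))

  h1 <- harmonizedSet(0.1, 0.05, 0.01, 0.1)
  expect_equal(mrIVW(h1)@beta, waldRatio(h1)@beta)
  expect_equal(mrIVW(h1)@se, waldRatio(h1)@se)
})

test_that("IVW equals the inverse-variance meta-analysis of Wald ratios", {
  set.seed(8)
  for (rep in 1:5) {
    J <- sample(3:12, 1)
    h <- harmonizedSet(bx = rnorm(J, 0, 0.2) + 0.3, by = rnorm(J, 0, 0.1),
                       sx = runif(J, 0.005, 0.02), sy = runif(J, 0.02, 0.1))
    s <- harmonizedTable(h)
    theta <- s$by / s$bx
    wm <- 1 / (s$sy / abs(s$bx))^2          # first-order ratio weights
    metaBeta <- sum(wm * theta) / sum(wm)   # brute-force meta-analysis
    metaSe <- sqrt(1 / sum(wm))
    est <- mrIVW(h)
    expect_equal(est@beta, metaBeta)
    expect_equal(est@details$seFixed, metaSe)
  }
})

test_that("Egger recovers exact fits and the two-point line", {
  h <- harmonizedSet(bx = c(0.1, 0.15, 0.2, 0.3), by = 0.4 * c(0.1, 0.15, 0.2, 0.3),
                     sx = 0.01, sy = 0.05)
  eg <- mrEgger(h)
  expect_equal(eg$slope@beta, 0.4)
  expect_equal(eg$intercept@beta, 0, tolerance = 1e-12)

  # two-point internal regression (below the J >= 3 public floor)
  f <- mrpipe:::eggerFit(harmonizedSet(bx = c(0.1, 0.2), by = c(0.03, 0.05),
                                       sx = 0.01, sy = 0.05))
  expect_equal(f$slope, 0.2)
  expect_equal(f$intercept, 0.01)

  expect_error(mrEgger(harmonizedSet(c(0.1, 0.2), c(0.1, 0.2), 0.01, 0.05)),
               "at least 3")
})

test_that("forcing the Egger intercept to zero reproduces fixed-effect IVW", {
  set.seed(13)
  J <- 10
  h <- harmonizedSet(bx = abs(rnorm(J, 0.2, 0.1)) + 0.05,
                     by = rnorm(J, 0.06, 0.04),
                     sx = 0.01, sy = runif(J, 0.02, 0.1))
  s <- harmonizedTable(h)
  through0 <- lm(by ~ bx - 1, data = s, weights = 1 / s$sy^2)
  expect_equal(unname(coef(through0)[["bx"]]), mrIVW(h)@beta)
})

test_that("weighted median interpolates the 50% point of the weight stack", {
  # equal weights: midpoint weights {1/6, 1/2, 5/6} hit 0.5 at the middle ratio
  h <- harmonizedSet(bx = c(1, 1, 1), by = c(0.1, 0.2, 0.3), sx = 0.01, sy = 1)
  expect_equal(mrWeightedMedian(h, nBoot = 50, seed = 1)@beta, 0.2)

  # all ratios equal c regardless of weights
  h2 <- harmonizedSet(bx = c(1, 2, 4), by = 0.7 * c(1, 2, 4),
                      sx = 0.01, sy = c(1, 0.5, 2))
  expect_equal(mrWeightedMedian(h2, nBoot = 50, seed = 1)@beta, 0.7)

  # seeded bootstrap SE is reproducible
  a <- mrWeightedMedian(h, nBoot = 200, seed = 9)
  b <- mrWeightedMedian(h, nBoot = 200, seed = 9)
  expect_identical(a@se, b@se)
})

test_that("weighted median is invariant to duplicating a SNP at half weight", {
  theta <- c(0.1, 0.25, 0.3, 0.5)
  w <- c(2, 1, 4, 3)
  a <- mrpipe:::weightedMedianPoint(theta, w)
  b <- mrpipe:::weightedMedianPoint(c(theta, 0.25), c(2, 0.5, 4, 3, 0.5))
  expect_equal(a, b)
})

test_that("weighted median converges to truth with minority invalid weight", {
  tp <- truthParams(J = 200, causalEffect = 0.5, invalidFraction = 0.3,
                    pleioMean = 0.05, pleioSd = 0.02, seed = 31L)
  p <- simulatePair(tp)
  h <- harmonize(exposureStats(p), outcomeStats(p))
  est <- mrWeightedMedian(h, nBoot = 200, seed = 1)
  expect_lt(abs(est@beta - 0.5), 3 * est@se)
})

test_that("mode estimators find the majority cluster", {
  h <- harmonizedSet(bx = rep(1, 4), by = c(0.5, 0.5, 0.5, 2.0),
                     sx = 0.01, sy = 1)
  est <- mrMode(h, weighted = FALSE, phi = 0.3, nBoot = 50, seed = 1)
  expect_equal(est@beta, 0.5, tolerance = 0.02)

  # all ratios identical
  h2 <- harmonizedSet(bx = c(1, 2, 3), by = 0.7 * c(1, 2, 3), sx = 0.01, sy = 1)
  expect_equal(mrMode(h2, nBoot = 50, seed = 1)@beta, 0.7)

  # equal weights make weighted and simple modes agree
  h3 <- harmonizedSet(bx = c(1, 1, 1, 1), by = c(0.2, 0.25, 0.3, 0.8),
                      sx = 0.01, sy = 1)
  sm <- mrMode(h3, weighted = FALSE, nBoot = 50, seed = 2)
  wm <- mrMode(h3, weighted = TRUE, nBoot = 50, seed = 2)
  expect_equal(sm@beta, wm@beta)
})

test_that("odds-ratio conversion matches published worked examples", {
  expect_equal(unname(round(toOrCi(log(1.354), 0.121), 3)),
               c(1.354, 1.068, 1.716))
  expect_equal(unname(round(toOrCi(log(0.731), 0.139), 3)),
               c(0.731, 0.557, 0.960))
  expect_equal(unname(toOrCi(0, 0)), c(1, 1, 1))
})

test_that("estimators are scale-equivariant in the outcome", {
  set.seed(3)
  J <- 12
  bx <- abs(rnorm(J, 0.2, 0.05)) + 0.05
  by <- 0.3 * bx + rnorm(J, 0, 0.02)
  sx <- rep(0.01, J); sy <- runif(J, 0.02, 0.06)
  k <- 3.7
  h1 <- harmonizedSet(bx, by, sx, sy)
  h2 <- harmonizedSet(bx, k * by, sx, k * sy)

  for (f in list(mrIVW, function(h) mrEgger(h)$slope)) {
    e1 <- f(h1); e2 <- f(h2)
    expect_equal(e2@beta, k * e1@beta)
    expect_equal(e2@se, k * e1@se)
  }
  m1 <- mrWeightedMedian(h1, nBoot = 100, seed = 5)
  m2 <- mrWeightedMedian(h2, nBoot = 100, seed = 5)
  expect_equal(m2@beta, k * m1@beta)
  expect_equal(m2@se, k * m1@se)
  d1 <- mrMode(h1, nBoot = 50, seed = 5)
  d2 <- mrMode(h2, nBoot = 50, seed = 5)
  expect_equal(d2@beta, k * d1@beta, tolerance = 1e-8)
})
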