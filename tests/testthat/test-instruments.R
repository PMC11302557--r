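test_that("significance screen keeps strictly sub-threshold variants", {
  x <- SummaryStats(recordFrame(3, pvalue = c(1e-6, 1e-4, 1e-5)))
  part <- filterByPvalue(x, 1e-5)
  expect_identical(variantIds(part$kept), "rs1")   # boundary 1e-5 dropped
  expect_partition(part, x)
  expect_true(all(part$dropped$reason == "pvalue"))

  # 20-row fixture: exactly the 7 planted sub-threshold rows survive
  pv <- rep(1e-3, 20); pv[c(2, 5, 6, 9, 13, 17, 20)] <- 1e-7
  x20 <- SummaryStats(recordFrame(20, pvalue = pv))
  expect_equal(nVariants(filterByPvalue(x20)$kept), 7L)
})

test_that("MAF screen uses min(eaf, 1-eaf) and keeps missing eaf with warning", {
  x <- SummaryStats(recordFrame(3, eaf = c(0.995, 0.5, NA)))
  expect_warning(part <- filterByMaf(x), "without eaf")
  expect_setequal(variantIds(part$kept), c("rs2", "rs3"))
  expect_equal(part$dropped$variant_id, "rs1")
  expect_partition(part, x)
})

test_that("F statistic is the squared Wald z and screens at 10", {
  x <- SummaryStats(recordFrame(3, beta = c(0.05, 0.01, 0),
                                se = c(0.005, 0.01, 0.01)))
  f <- fStatistic(x)
  expect_equal(unname(f), c((0.05 / 0.005)^2, 1, 0))
  part <- filterByFStat(x)
  expect_identical(variantIds(part$kept), "rs1")
  expect_true(all(part$dropped$reason == "weak"))
})

test_that("r2-based F needs frequency and sample size and is positive", {
  x <- SummaryStats(recordFrame(3))
  f <- fStatistic(x, method = "r2")
  expect_true(all(f > 0))
  x2 <- SummaryStats(recordFrame(2, eaf = c(0.3, NA)))
  expect_error(fStatistic(x2, method = "r2"), "eaf and n")
})

test_that("greedy clumping keeps the most significant variant per region", {
  ids <- c("rs1", "rs2")
  m <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(ids, ids))
  x <- SummaryStats(recordFrame(2, pvalue = c(1e-6, 1e-8), pos = c(1e6, 1e6)))
  part <- ldClump(x, LDMatrix(m))
  expect_identical(variantIds(part$kept), "rs2")  # smaller p wins

  # same r2 but 20,000 kb apart: outside the window, both kept
  x2 <- SummaryStats(recordFrame(2, pvalue = c(1e-6, 1e-8),
                                 pos = c(1e6, 1e6 + 2e7)))
  expect_equal(nVariants(ldClump(x2, LDMatrix(m))$kept), 2L)
})

test_that("clumping a 5-SNP block plus 2 independents keeps 3", {
  tp <- truthParams(J = 7, ldBlocks = list(c(5, 0.9), c(1, 0), c(1, 0)),
                    seed = 2L)
  pair <- simulatePair(tp)
  ld <- simulateLD(tp)
  part <- ldClump(exposureStats(pair), ld)
  expect_equal(nVariants(part$kept), 3L)
  # kept set is independent: no surviving pair has r2 >= threshold
  keptIds <- variantIds(part$kept)
  r2 <- ldValues(ld)[keptIds, keptIds]
  expect_true(all(r2[upper.tri(r2)] < 0.01))
  expect_true(all(part$dropped$reason == "clumped"))
})

test_that("clumping without an LD matrix is a warned no-op", {
  x <- SummaryStats(recordFrame(4))
  expect_warning(part <- ldClump(x, NULL), "clumping skipped")
  expect_equal(nVariants(part$kept), 4L)
})

test_that("clumping errors when ids are missing from the LD matrix", {
  ids <- c("rs1", "rs2")
  m <- diag(2); dimnames(m) <- list(ids, ids)
  x <- SummaryStats(recordFrame(3))
  expect_error(ldClump(x, LDMatrix(m)), "absent from LD matrix")
})

test_that("independent screens commute", {
  set.seed(42)
  df <- recordFrame(30,
                    pvalue = 10^runif(30, -8, -3),
                    eaf = runif(30, 0.001, 0.999),
                    beta = rnorm(30, 0, 0.05))
  x <- SummaryStats(df)
  a <- filterByFStat(suppressWarnings(filterByMaf(filterByPvalue(x)$kept))$kept)
  b <- filterByFStat(filterByPvalue(suppressWarnings(filterByMaf(x))$kept)$kept)
  expect_setequal(variantIds(a$kept), variantIds(b$kept))
})

test_that("selectInstruments conserves records and logs one reason each", {
  tp <- truthParams(J = 12, ldBlocks = list(c(4, 0.8), c(4, 0), c(4, 0)),
                    seed = 9L)
  pair <- simulatePair(tp)
  sel <- selectInstruments(exposureStats(pair), simulateLD(tp))
  expect_equal(nVariants(sel$kept) + nrow(sel$dropLog), 12L)
  expect_false(any(duplicated(sel$dropLog$variant_id)))
  expect_length(intersect(variantIds(sel$kept), sel$dropLog$variant_id), 0)
})
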