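mkStats <- function(ids, ea, oa, beta, eaf = 0.3, p = 1e-6) {
  SummaryStats(data.frame(variant_id = ids, effect_allele = ea,
                          other_allele = oa, eaf = eaf, beta = beta,
                          se = 0.05, pvalue = p, stringsAsFactors = FALSE))
}

test_that("the allele case table is applied as specified", {
  ex <- mkStats(c("rs1", "rs2", "rs3", "rs4", "rs5"),
                ea = c("A", "A", "A", "A", "A"),
                oa = c("G", "G", "T", "G", "G"),
                beta = 0.1)
  out <- mkStats(c("rs1", "rs2", "rs3", "rs4", "rs5"),
                 ea = c("A", "G", "A", "T", "A"),
                 oa = c("G", "A", "T", "C", "C"),
                 beta = 0.05, eaf = 0.3)
  h <- harmonize(ex, out)
  s <- harmonizedTable(h)
  excl <- exclusionLog(h)

  expect_equal(s$by[s$variant_id == "rs1"], 0.05)    # identical: copied
  expect_equal(s$by[s$variant_id == "rs2"], -0.05)   # swapped: negated
  expect_equal(s$eaf_y[s$variant_id == "rs2"], 0.7)  # frequency reflected
  expect_equal(excl$reason[excl$variant_id == "rs3"], "palindrome")  # A/T
  expect_equal(s$by[s$variant_id == "rs4"], 0.05)    # strand flip: sign kept
  expect_equal(excl$reason[excl$variant_id == "rs5"], "unmatched")
})

test_that("complement-and-swap negates the outcome beta", {
  ex <- mkStats("rs1", "A", "G", 0.1)
  out <- mkStats("rs1", "C", "T", 0.05)   # complement of G/A = C/T swapped
  h <- harmonize(ex, out)
  expect_equal(harmonizedTable(h)$by, -0.05)
})

test_that("ids missing from either side are logged, conserving counts", {
  ex <- mkStats(c("rs1", "rs2"), c("A", "C"), c("G", "T"), 0.1)
  out <- mkStats(c("rs2", "rs9"), c("C", "A"), c("T", "G"), 0.05)
  h <- harmonize(ex, out)
  expect_identical(variantIds(h), "rs2")
  excl <- exclusionLog(h)
  expect_setequal(excl$variant_id[excl$reason == "missing"], c("rs1", "rs9"))
  # conservation: harmonized + excluded covers every id seen
  expect_equal(nVariants(h) + nrow(excl), 3L)
})

test_that("duplicate ids keep the smallest-p instance", {
  ex <- SummaryStats(data.frame(variant_id = c("rs1", "rs1"),
                                effect_allele = "A", other_allele = "G",
                                beta = c(0.1, 0.2), se = 0.05,
                                pvalue = c(1e-4, 1e-8)))
  out <- mkStats("rs1", "A", "G", 0.05)
  h <- harmonize(ex, out)
  expect_equal(harmonizedTable(h)$bx, 0.2)  # the p = 1e-8 instance
  expect_true("duplicate" %in% exclusionLog(h)$reason)
})

test_that("harmonization is an involution", {
  p <- simulatePair(truthParams(J = 25, causalEffect = 0.4,
                                palindromeFraction = 0.2, seed = 5L))
  h1 <- harmonize(exposureStats(p), outcomeStats(p))
  back <- statsFromHarmonized(h1, exposureStats(p))
  h2 <- harmonize(back$exposure, back$outcome)
  expect_equal(harmonizedTable(h2)[c("variant_id", "bx", "by", "sx", "sy")],
               harmonizedTable(h1)[c("variant_id", "bx", "by", "sx", "sy")])
})

test_that("double allele swap restores the original outcome beta", {
  ex <- mkStats("rs1", "A", "G", 0.1)
  out <- mkStats("rs1", "G", "A", 0.05, eaf = 0.3)
  h1 <- harmonize(ex, out)  # by = -0.05 on the A allele
  s1 <- harmonizedTable(h1)
  # swap the harmonized outcome again: back to G effect allele
  out2 <- mkStats("rs1", "G", "A", -s1$by, eaf = 1 - s1$eaf_y)
  s2 <- harmonizedTable(harmonize(ex, out2))
  expect_equal(s2$by, s1$by)
  expect_equal(s2$eaf_y, s1$eaf_y)
})

test_that("negating an exposure's coding flips bx and by together", {
  p <- simulatePair(truthParams(J = 10, causalEffect = 0.4, seed = 6L))
  ex <- statsTable(exposureStats(p))
  h1 <- harmonize(exposureStats(p), outcomeStats(p))
  flipped <- ex
  flipped$effect_allele <- ex$other_allele
  flipped$other_allele <- ex$effect_allele
  flipped$beta <- -ex$beta
  flipped$eaf <- 1 - ex$eaf
  h2 <- harmonize(SummaryStats(flipped), outcomeStats(p))
  s1 <- harmonizedTable(h1); s2 <- harmonizedTable(h2)
  expect_equal(s2$bx, -s1$bx)
  expect_equal(s2$by, -s1$by)
  expect_equal(s2$by / s2$bx, s1$by / s1$bx)
})
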