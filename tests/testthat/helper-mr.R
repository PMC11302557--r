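# shared fixture builders

# a well-formed record data.frame; override any column via ...
recordFrame <- function(J = 5, ...) {
  df <- data.frame(
    variant_id = sprintf("rs%d", seq_len(J)),
    chrom = rep("1", J),
    pos = seq_len(J) * 1e5,
    effect_allele = rep_len(c("A", "C", "G", "T"), J),
    other_allele = rep_len(c("G", "T", "A", "C"), J),
    eaf = seq(0.2, 0.8, length.out = J),
    beta = seq(0.05, 0.1, length.out = J),
    se = rep(0.01, J),
    pvalue = rep(1e-8, J),
    n = rep(10000, J),
    stringsAsFactors = FALSE)
  override <- list(...)
  for (nm in names(override)) df[[nm]] <- override[[nm]]
  df
}

# turn a HarmonizedSet back into exposure/outcome SummaryStats with the
# exposure's allele coding, for involution-style checks
statsFromHarmonized <- function(h, exposure) {
  s <- harmonizedTable(h)
  ex <- statsTable(exposure)
  ex <- ex[match(s$variant_id, ex$variant_id), , drop = FALSE]
  out <- ex
  out$beta <- s$by
  out$se <- s$sy
  out$eaf <- s$eaf_y
  out$pvalue <- pmin(1, pmax(2 * pnorm(-abs(s$by / s$sy)), 1e-300))
  list(exposure = SummaryStats(ex), outcome = SummaryStats(out))
}

expect_partition <- function(part, x) {
  expect_identical(nVariants(part$kept) + nrow(part$dropped), nVariants(x))
  expect_length(intersect(variantIds(part$kept), part$dropped$variant_id), 0)
}
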