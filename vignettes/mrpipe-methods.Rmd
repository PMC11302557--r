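---
title: "Two-sample Mendelian randomization with mrpipe: models and methods"
author: "mrpipe maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrpipe: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The causal model

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure (here, typically the relative abundance of a gut-microbiota taxon)
on an outcome (a disease) from two independent GWAS: one providing per-SNP
exposure effects $\hat\beta_{Xj}$ with standard errors $\sigma_{Xj}$, one
providing outcome effects $\hat\beta_{Yj}$ with $\sigma_{Yj}$. A genetic
variant is a valid instrument when three assumptions hold: (1) it is
robustly associated with the exposure, (2) it is independent of
confounders of the exposure–outcome relationship, and (3) it affects the
outcome only through the exposure (no horizontal pleiotropy). Under these
assumptions each SNP yields a Wald ratio
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ estimating the same causal
effect $\beta$, and the estimators below combine the ratios with different
robustness trade-offs. For binary outcomes the effects are log odds ratios,
and estimates are reported as OR = $e^\beta$ with Wald 95% intervals
$e^{\beta \pm 1.96\,\mathrm{se}}$.

Assumption (1) is enforced by the instrument screens; assumptions (2) and
(3) cannot be enforced, only probed, which is what the sensitivity battery
does.

## Instrument selection

`selectInstruments()` applies, in order:

* **Significance**: keep $p < 10^{-5}$ (strict inequality; the
  genome-wide-suggestive threshold conventional for microbiome exposures,
  whose per-taxon GWAS rarely reach $5\times10^{-8}$).
* **MAF**: keep $\min(\mathrm{eaf}, 1-\mathrm{eaf}) \ge 0.01$. Records
  without a frequency are kept with a warning rather than discarded,
  because several consortium exports omit frequency columns; the warning is
  deliberate and loud.
* **LD clumping**: greedy index selection at $r^2 < 0.01$ within a
  10,000 kb window — candidates are ranked by p-value, the best remaining
  becomes an index SNP, and everything correlated with it inside the window
  is dropped. The package consumes a supplied $r^2$ matrix; it does not
  compute LD from a reference panel, and with no matrix the step degrades
  to a warned no-op instead of failing.
* **F statistic**: keep $F \ge 10$, with $F = (\hat\beta_X/\sigma_X)^2$,
  the single-SNP squared Wald z. The alternative $R^2(N-2)/(1-R^2)$ form is
  available when frequency and sample size are present
  (`fStatistic(method = "r2")`).

The screens on p-value, MAF and F are logically independent, so their order
cannot change the final set (a property the test suite asserts); clumping
is placed after the marginal screens so index SNPs are chosen among
variants that could survive anyway. Every dropped variant carries exactly
one drop reason, and kept + dropped always reconstitutes the input.

## Harmonization

`harmonize()` matches exposure and outcome records by variant id and aligns
them to a shared effect allele. Palindromic SNPs (A/T or C/G pairs) are
excluded unconditionally: their strand cannot be resolved from alleles
alone, and no frequency-based rescue is attempted. For the remainder the
case table is: identical alleles — copy; swapped — negate the outcome beta
and reflect its frequency; strand-complemented — relabel, sign preserved;
complemented and swapped — relabel and negate; anything else — excluded as
unmatched. Duplicate ids keep the smallest-p instance. Harmonization is an
involution (re-harmonizing aligned data changes nothing), which the suite
checks across seeds.

## Estimators

With weights $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$ (first-order Wald-ratio
weights):

* **IVW** — weighted least squares of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$
  through the origin with weights $1/\sigma_{Yj}^2$, identical to the
  inverse-variance meta-analysis of the Wald ratios. The reported SE is the
  fixed-effect SE inflated by $\max(1, \sqrt{Q/(J-1)})$ — the
  multiplicative random-effects convention dominant in two-sample MR, which
  penalizes heterogeneity without letting it shrink the SE. The
  fixed-effect SE and Q are retained in `details` for transparency.
  P-values use the normal reference.
* **MR-Egger** — the same regression with a free intercept, each SNP
  oriented so $\hat\beta_{Xj} \ge 0$ (orientation changes the intercept's
  meaning, so it is fixed explicitly). The slope estimates $\beta$ under
  InSIDE (pleiotropy independent of instrument strength); the intercept
  estimates average directional pleiotropy. SEs carry multiplicative
  overdispersion $\max(1, \hat\sigma)$ and p-values use the t reference
  with $J-2$ degrees of freedom, appropriate for the small instrument
  counts typical here.
* **Weighted median** — order the ratios, normalize the weights, form
  cumulative midpoint weights $p_j = \sum_{k\le j} w_k - w_j/2$, and
  interpolate $\theta$ against $p$ at $p = 0.5$. Consistent when valid
  instruments carry at least half the weight.
* **Simple and weighted mode** — the argmax of a normal-kernel density over
  the ratios with uniform or normalized inverse-variance weights. Bandwidth
  is the modified Silverman rule
  $h = \varphi \cdot 0.9 \min(\mathrm{sd}, \mathrm{MAD}) J^{-1/5}$ (the MAD
  scaled to be consistent for the normal), evaluated exactly on a 512-point
  grid spanning the ratios plus three bandwidths; tied maxima are averaged.
  $\varphi$ defaults to 1 and is exposed. Consistent when the largest
  cluster of instruments is valid.

Median and mode SEs come from a seeded parametric bootstrap (default 1000
replicates) that perturbs both $\hat\beta_{Xj}$ and $\hat\beta_{Yj}$ by
their SEs and recomputes the point estimate; the same seed always
reproduces the same SE. These choices — bootstrap size, seeding policy,
bandwidth rule, normal vs t references — are the package's own, stated
here because conventions differ across implementations.

## Sensitivity battery

* **Cochran's Q** (`cochranQ`): $Q = \sum_j w_j(\hat\theta_j -
  \hat\beta_{\mathrm{IVW}})^2$ on $J-1$ df against the fixed-effect IVW
  estimate, or the weighted residual sum of squares about the Egger line on
  $J-2$ df; upper-tail chi-square p. $p > 0.05$ is read as no material
  heterogeneity.
* **Egger intercept test** (`eggerInterceptTest`): a nonzero intercept with
  $p < 0.05$ flags directional pleiotropy.
* **MR-PRESSO** (`mrPresso`): the observed statistic is
  $\mathrm{RSS} = \sum_j (\hat\beta_{Yj} -
  \hat\beta_{(-j)}\hat\beta_{Xj})^2/\sigma_{Yj}^2$ with $\hat\beta_{(-j)}$
  the leave-one-out IVW slope. Its null distribution is simulated by
  redrawing outcome effects about the leave-one-out predictions (and, by
  default, redrawing exposure effects about their estimates too —
  `fixExposure = TRUE` treats them as fixed, since published descriptions
  of the procedure are ambiguous on this point). Empirical p-values use the
  add-one rule $(1 + \#\{\mathrm{RSS}^* \ge \mathrm{RSS}\})/(n_{sim}+1)$,
  so they are never exactly zero; per-SNP outlier p-values are computed
  from each SNP's simulated residual distribution and
  Bonferroni-multiplied by $J$. While the global test is significant and an
  outlier call is available, the SNP with the smallest outlier p is removed
  — one at a time, a deterministic reading of "sequential" removal — and
  everything is recomputed; the loop stops at non-significance or when
  fewer than four instruments would remain, and the corrected estimate is
  IVW on the survivors. Note the smallest attainable adjusted outlier p is
  $J/(n_{sim}+1)$: at the default significance of 0.05, $n_{sim}$ must
  exceed $20J$ for any removal to be possible, which the default
  $n_{sim} = 1000$ satisfies for $J \le 49$.
* **Leave-one-out** (`leaveOneOut`): IVW recomputed with each instrument
  excluded, plus the all-SNP row — $J+1$ rows ready for a forest plot.

`runPair()` chains selection, harmonization, the five estimators and the
battery; when MR-PRESSO removes instruments the estimates are recomputed on
the survivors and the pre-removal IVW is kept alongside. Pairs left with
fewer than two instruments are marked `insufficient_instruments` rather
than erroring, so multi-pair studies run to completion.

## Multiple testing and reporting

Study-level summaries count exposures with IVW $p < 0.05$ per outcome,
split by direction of the odds ratio (an OR of exactly 1 — a measure-zero
event — is classified positive by a documented tie rule). Because
microbiome exposures are tested at five taxonomic ranks, Bonferroni
correction is applied per rank as $0.05/n$ with $n$ the number of taxa at
that rank; when a results table contains only significant rows the in-table
taxon count understates $n$, so `summarizeStudy()` accepts the true
per-rank counts explicitly. `renderTables()` emits the conventional
publication layout (Group, Bacterial, Nsnp, Methods, SE, "OR (95% CI)",
P-value, all to three decimals) and `readResultTable()` parses it back;
the suite asserts that counts computed from rendered tables match those
from in-memory results.

The package bundles transcriptions of published result tables for five
geriatric-syndrome outcomes (`bundledResultTables()`), used by the tests
as fixed reference input for the counting and interval-reconstruction
checks. A few cells are typographically garbled in the printed originals
and are kept as printed; none affects an IVW row used for counting.

## The synthetic generator: what it emulates and what it does not

`simulatePair()` draws, per SNP: a true exposure effect
$b_{Xj} \sim N(0, \mathrm{bxSd}^2)$ resampled until it clears a relevance
floor (|z| beyond the $10^{-5}$ screen plus two, so the realized instrument
set behaves like a pre-selected one without modelling winner's curse); an
observed exposure effect $N(b_{Xj}, \mathrm{seX}^2)$; a true outcome effect
$\beta b_{Xj} + \alpha_j$; and an observed outcome effect with SE seY.
Pleiotropy $\alpha_j$ is zero for valid SNPs and, for the invalid fraction,
drawn with mean pleioMean **on the exposure-increasing allele
orientation** — the orientation MR-Egger adopts — so that directional
pleiotropy is exactly what the Egger intercept measures; a fixed-sign
$\alpha$ on symmetric $b_X$ would cancel under that orientation and
"directional" would be meaningless. An optional `corPleio` couples
$\alpha$ to instrument strength to violate InSIDE on demand, planted
outliers add a shift of `outlierShift` (default ten outcome-SEs) on the
same orientation, and a palindromic fraction assigns A/T or C/G pairs so
harmonization paths are exercised.

Defaults — J = 30, bxSd = 0.1, seX = 0.005, seY = 0.05, frequencies
uniform on (0.05, 0.95), exposure n ≈ 18,000 and outcome n = 450,000 —
describe a strong-instrument microbiome-exposure/biobank-outcome design;
the exposure-side SE is small relative to bxSd so that regression dilution
is negligible against the Monte-Carlo resolution of the validation runs.
`simulateLD()` provides the companion block-diagonal $r^2$ matrix for
clumping tests. One integer seed drives a single stream and fixes the
output bitwise.

The generator deliberately does **not** model winner's curse, realistic
minor-allele-frequency spectra, individual-level genotypes, sample overlap
between the two GWAS, or LD beyond exchangeable blocks. Tests passing on
synthetic data therefore certify the estimators' statistical behaviour
under the stated model, not robustness to those real-data complications.

## Numerical choices and degenerate inputs

P-values of exactly 0 on ingest are floored at the smallest positive
double (log/quantile safety) with a warning. Zero-noise simulations write
a vanishingly small positive SE so record invariants and downstream
weights remain defined while betas stay exact. All-identical ratios give
the mode estimator that value directly (bandwidth would be zero);
`stats::mad` degenerating to zero falls back to the SD. Empirical p-values
use the add-one rule. Asymmetric LD input is averaged only within 1e-8,
else rejected. Estimator preconditions (J ≥ 2 for IVW, 3 for
Egger/median/mode, 4 for MR-PRESSO) raise informative errors; the pipeline
converts only the "fewer than two instruments" case into a status.

## Validation scale

The repository's checks exercise the generator at the study's design
points: 500-replicate null batteries at J = 30 for the size of the IVW,
Cochran-Q, Egger-intercept and MR-PRESSO global tests (each within three
binomial SEs of 0.05); 500-replicate recovery at J = 50, $\beta = 0.5$
(bias within three Monte-Carlo SEs, coverage within three binomial SEs of
95%); and 100-replicate outlier robustness with two planted ten-sigma
outliers at J = 30 (both removed in at least 95% of runs, corrected IVW
closer to truth). `scripts/acceptance.R` recomputes all of these from
scratch together with the bundled-table counts.

## Known limitations

Single-exposure, single-outcome MR only: no multivariable MR, no Steiger
directionality filtering, no penalized or robust IVW variants, no
reverse-direction analysis. LD must be supplied, not computed. The
bundled reference tables are transcriptions of printed values and inherit
their rounding (and a few typographical defects, kept as printed).
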