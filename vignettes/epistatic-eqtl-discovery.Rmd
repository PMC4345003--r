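---
title: "Methods: two-stage epistatic eQTL discovery"
author: "epiqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage epistatic eQTL discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiqtl)
```

## The problem and the model

Exhaustive scans for pairwise genetic interactions on expression traits are
dominated by their own multiple-testing burden: testing every SNP pair
against every transcript requires so many tests that only enormous effects
survive correction.  `epiqtl` implements the restricted two-stage design:
an interaction between two SNPs is tested for a transcript only when *both*
SNPs already show an independent marginal association with that transcript
at a deliberately liberal false discovery rate (FDR < 0.5).  Two search
spaces are supported:

* **cis-trans** — one partner within 1 Mb of the probe midpoint, the other
  further away or on another chromosome;
* **cis-cis** — both partners within 10 Mb of the probe midpoint, at least
  100 kb apart from each other.

For a transcript with expression $y$ and two loci with additive genotype
codes $g_A, g_B \in \{0, 1, 2\}$ (counts of the minor allele), the
interaction model fitted on the rank-transformed response is

$$\mathrm{rank}(y) = \beta_0 + \beta_1 g_A + \beta_2 g_B +
  \beta_3\, (g_A \times g_B) + \gamma^\top \mathrm{PC} + \varepsilon ,$$

where the product term takes the values 0, 1, 2 or 4 across the nine
two-locus genotype combinations and PCs are genotype principal components
controlling population stratification.  Interaction significance is the
two-sided t-test of $\beta_3$, Bonferroni-corrected across all interaction
tests actually fitted in the run.  Ranking the response (and only the
response — covariates stay on their raw scale) makes the test robust to the
heavy-tailed, skewed distributions typical of expression data; effects are
reported in rank units.

Only the additive-by-additive term is fitted.  A full dominance
parameterisation would need four main effects and four interaction terms
and correspondingly many well-populated genotype cells; with cohorts of a
few hundred individuals the single product term maximises power, at the
cost of missing purely dominant epistasis.

## Pipeline stages and their parameters

`runPipeline()` executes the stages in a fixed order.  All thresholds live
in `pipelineConfig()`:

* **SNP QC** (`filterSnps`): autosomes only; MAF strictly greater than 0.2
  (the high floor keeps the nine two-locus cells populated downstream);
  missingness at most 20%; Hardy-Weinberg equilibrium chi-squared
  (1 df, expectations from the observed allele frequency, no continuity
  correction) with removal below p = 0.05.  Monomorphic SNPs carry no HWE
  evidence and are assigned p = 1 — they fail the MAF filter instead.
* **Probe screening**: probes whose genomic interval contains a catalogued
  variant are blacklisted (a 1-based SNP position $p$ is inside the BED
  interval $[s, e)$ iff $s \le p - 1 < e$); the top 5% of probes by
  interquartile range are carried forward.  The IQR uses type-7
  (linear-interpolation) quartiles, the ceiling rule guarantees a non-empty
  selection on small panels, and ties at the cutoff resolve by probe id so
  reruns are reproducible.
* **Stratification** (`genotypePca`, `tracyWidomTest`, `detectOutliers`):
  SNP columns are centred and scaled by $\sqrt{p(1-p)}$, missing entries
  become zeros after centring (mean imputation used for the PCA only —
  regressions stay complete-case), and the individual-by-individual
  covariance is eigendecomposed.  Components are declared significant
  sequentially with the Tracy-Widom statistic, using the effective marker
  number estimated from eigenvalue moments and the standard TW$_1$
  quantiles (0.9793, 2.0234, 3.2724 at $\alpha$ = 0.05, 0.01, 0.001).
  Outliers beyond 6 SD on any of the top 10 components are removed over up
  to 5 PCA recomputation rounds, after which the SNP filters are re-checked
  on the trimmed cohort.  The number of PC covariates defaults to the
  TW-significant count but can be overridden per run (`nPcs`), since
  analysts sometimes carry extra components on external grounds.
* **Marginal scan** (`marginalScan`): every selected probe against every
  surviving SNP, complete-case per test; tests with fewer than
  (covariates + 3) individuals are skipped and logged.  BH q-values are
  computed separately within the cis list and the trans list — the two
  families have very different sizes and base rates, and pooling them would
  let the cis signal mask trans discoveries.  The gate keeps q strictly
  below the threshold.
* **Pair enumeration and filters** (`enumeratePairsCisTrans`,
  `enumeratePairsCisCis`, `cellCountFilter`): intra-chromosomal pairs must
  have LD $r^2 < 0.01$; inter-chromosomal pairs are exempt (LD is
  undefined across chromosomes).  $r^2$ comes from maximum-likelihood
  haplotype frequencies fitted by EM on the 3x3 genotype table
  (tolerance $10^{-10}$, at most 1000 iterations; only the
  double-heterozygote cell is phase-ambiguous).  A composite estimator
  (squared genotype correlation) is available behind `ldMethod` for
  sensitivity analysis.  The EM needs at least 20 complete pairs; a
  monomorphic margin leaves $r^2$ undefined and is reported as 0 with a
  warning.  Every one of the nine genotype cells must hold at least 10
  individuals; distance bounds are inclusive at both ends ("within" and
  "at least" read as $\le$ and $\ge$).
* **Refinement** (`groupRedundant`, `stepwiseAic`, `compareModels`,
  `distanceDistributionTest`): significant interactions for a probe merge
  into one group when their cis SNPs are in LD ($r^2 \ge 0.5$ by default —
  configurable, since observed redundant groups show $r^2$ well above any
  sensible cutoff), their partners are identical or in LD, and the
  interaction signs agree; groups are the transitive closure.  Stepwise
  AIC ($n\log(\mathrm{RSS}/n) + 2k$) starts from the full model holding
  all mains and interactions and takes the best single add/drop move until
  none improves; by default an interaction may only stay alongside both of
  its main effects (`hierarchy = FALSE` reproduces unconstrained
  selection).  Model comparison reports adjusted $R^2$ with and without
  the product term and the Gaussian likelihood-ratio statistic
  $n \log(\mathrm{RSS_{main}}/\mathrm{RSS_{full}})$ on 1 df.
* **Enrichment** (`mapPairToHic`, `enrichmentSweep`, `hicEnrichment`): a
  SNP pair maps to a Hi-C contact when its SNPs lie one each within
  ±5 kb (inclusive) of the two fragment alignment starts; SNPs map to
  promoter/enhancer tracks by half-open interval containment.  The 2x2
  tables (significant vs remaining tested pairs, or epistatic vs remaining
  tested SNPs with set semantics) are tested with the Pearson chi-squared
  test of independence, 1 df, no continuity correction; the
  Haldane-Anscombe +0.5 correction is applied to the odds ratio only, never
  to the statistic, so the test stays exact to its definition while the OR
  stays finite.  Sweeps over several tracks and tissues Bonferroni-correct
  across the whole comparison family (e.g. 0.05/21 ≈ 2.4 × 10⁻³ for seven
  tracks in three tissues).

## What the synthetic generator emulates

`simulateGenotypes` draws biallelic SNPs with a configurable MAF spectrum,
block LD from a first-order copying process (each allele copies its left
neighbour with probability `ldRho`, giving direct control of LD decay
without an external coalescent simulator), Balding-Nichols population
structure (subpopulation frequencies from
$\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$) and uniform missingness.
`simulateExpression` plants effects on the *raw* expression scale —
$\beta_1 g_A + \beta_2 g_B + \beta_3 g_A g_B$ plus gaussian, lognormal or
$t_3$ noise — so the rank transform is exercised non-trivially.
Individuals missing a causal genotype keep a noise-only value and are
flagged; complete-case handling is deliberately left to the scan.

The generator does **not** attempt to match real cohorts: no realistic
allele-frequency spectrum or array design, no disease-status mixtures, no
cryptic relatedness, and LD is stationary within blocks.  Passing tests on
this synthetic data demonstrate the statistical machinery is correct and
calibrated under its stated assumptions — not that the pipeline's
discoveries on any particular tissue are reproduced.

### Calibration of planted interaction strength

The study-level generator `simulateEpistasisStudy` plants one cis-trans
pair in a 500-individual cohort.  Its `share` parameter is the fraction of
*rank-scale* phenotypic variance attributable to the product term — the
scale on which the fitted models report variance explained (around 3–5% is
a realistic magnitude for detectable expression epistasis).  Because
ranking attenuates a raw-scale interaction by roughly a factor of two (and
the attainable rank-scale share saturates near 7% for common alleles —
ranks are bounded), `calibrateInteractionShare` finds $\beta_3$ by
bisection against a 20,000-individual reference population;
`interactionEffectForShare` supplies the closed-form raw-scale solution
used to seed the bracket.  Planted causal SNPs receive MAFs in 0.45–0.5:
with $n = 500$, the expected double-minor-homozygote cell is
$n q_A^2 q_B^2 \approx 20$, comfortably above the nine-cell minimum of 10,
mirroring the reason the pipeline's MAF floor is high in the first place.

Problem sizes used by the packaged simulations: 500 individuals, 40 SNPs
on two chromosomes (a 4 Mb gene-dense region plus a trans chromosome), 10
probes with the top-IQR gate selecting one.  These sizes give the
end-to-end recovery study a search space of a few dozen pair tests per
run, which is where the two-stage design operates after gating.

## Numerical choices and degenerate inputs

* Genotypes always code the minor allele after loading; columns coded
  against the major allele are flipped and logged.  PED allele-count ties
  resolve to the alphabetically first allele as minor.
* Coordinates: SNP positions are 1-based (MAP/VCF); intervals and probe
  annotations are BED 0-based half-open; probe midpoints use
  `floor((start + end)/2)`.
* OLS is QR-based; aliased columns surface as skipped tests
  (interaction scan), as up-front removals (stepwise selection), or as
  identical nested models (model comparison, LRT = 0).
* A saturated full model (RSS below $10^{-10}$ of the total sum of
  squares) leaves the LRT undefined with a warning rather than reporting
  an infinite statistic.
* PCA eigenvector signs follow a deterministic convention (the
  largest-magnitude entry of each component is positive); eigenvalue
  spectra flatter than the Marchenko-Pastur null terminate Tracy-Widom
  testing immediately, so an all-equal spectrum yields zero significant
  components.
* The KS distance test uses the asymptotic two-sample distribution;
  inter-chromosomal (undefined) distances are dropped before testing.

## Known limitations

* The rank-transform interaction test is mildly conservative when main
  effects are present: with $\beta_1 = \beta_2 = 0.5$ noise-SD mains
  (about 20% of phenotypic variance) its measured type-I error at
  $\alpha = 0.05$, $n = 500$ is about 0.041 under both gaussian and
  lognormal noise.  Ranking an additive signal is a non-linear distortion,
  so exact nominality cannot be expected; the deviation is in the safe
  (under-rejecting) direction and shrinks with weaker mains.  The test
  suite's calibration checks document this behaviour.
* Stepwise AIC retains a 1-df pure-noise interaction with probability
  $P(\chi^2_1 > 2) \approx 0.157$ — an inherent property of the AIC
  penalty, not a defect; the hierarchy rule cannot suppress a term whose
  main effects start in the full model.
* LD pruning before PCA is not performed, so strong local LD can surface
  as Tracy-Widom-significant components on otherwise unstructured cohorts;
  these extra PC covariates are harmless to the downstream regressions.
* No VCF/BGEN input, no genome-build conversion, no imputation, no mixed
  models or kinship correction, and no dominance-coded epistasis.
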