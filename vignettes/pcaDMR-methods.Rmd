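---
title: "Region-level methylation analysis with principal components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-level methylation analysis with principal components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcaDMR)
```

## The problem

Epigenome-wide association studies on Illumina EPIC-style arrays usually
test ~850,000 CpG sites one at a time. Methylation at nearby CpGs is
correlated, so a phenotype that shifts an entire genomic region can be
easier to detect by testing the region jointly — a differentially
methylated region (DMR) analysis. The difficulty is doing this without
inflating the genome-wide false-positive rate: with hundreds of thousands
of candidate regions, even mild per-region miscalibration produces spurious
"significant" DMRs somewhere on the array in nearly every dataset.

pcaDMR summarizes each candidate region by the principal components (PCs)
of its covariate-adjusted methylation residuals and tests those components
against the phenotype. PCs capture the dominant co-methylation patterns in
the region, so distinct clusters of correlated probes are represented by
separate components and no probe has to be discarded for being imperfectly
correlated with its neighbours.

## The procedure

1. **Regions** (`buildRegions()`). Autosomal probes are split into genic
   (per annotated gene) and intergenic (per chromosome) strata. Within a
   stratum, probes sorted by position stay in one cluster while
   consecutive gaps are at most `maxGap = 200` bp; clusters with fewer
   than `minProbes = 3` probes are discarded. The gap threshold is
   inclusive: a gap of exactly 200 bp does not split. A probe annotated to
   several genes can seed a region in each gene's stratum
   (`collapseGenic = TRUE` merges coordinate-identical duplicates).
   Coordinates are 1-based inclusive everywhere except the BED export,
   which converts at the boundary.

2. **Residualization** (`residualizeMethylation()`). Beta-values
   (proportions in (0,1)) are mapped to M-values, `M = log2(beta/(1-beta))`,
   the standard scale for linear modelling. Each probe is regressed on the
   covariate design by OLS — one shared QR factorization, numerically
   identical to per-probe fits — and the residuals are standardized to
   mean 0, SD 1 (n−1 denominator; the convention is ours, the choice is
   immaterial downstream because PCA of standardized columns is
   correlation-based either way). A probe with zero variance would make
   standardization undefined, so such columns receive a tiny uniform
   perturbation (±1e-6 × max(1, |mean|), drawn from the seeded RNG) before
   fitting; the same perturb-and-refit is attempted once if a residual
   column degenerates, then it is an error. Residuals are recomputed for
   every analysis subject set rather than subset from a cache, because OLS
   residuals do not commute with subsetting.

3. **Per-region PCA** (`computeRegionPCA()`, `selectK()`). PCA of the
   standardized residual block is equivalent to the eigen-decomposition of
   the probes' correlation matrix. PC signs are arbitrary; for
   reproducibility the largest-|loading| entry of every component is made
   positive, and all regional p-values are invariant to sign flips (this
   is tested). The number of components tested is the smallest k whose
   cumulative variance fraction reaches `varThreshold` (0.80 by default;
   0.90/0.95/0.99 are the studied alternatives), capped at `kMax = 10` to
   avoid overfitting and at the number of nonzero-variance components
   when the block is rank-deficient (p > n − 1).

4. **MAC filter** (`computeMAC()`, `filterRegions()`). The maximum
   absolute pairwise Pearson correlation among a region's probes is the
   region-inclusion statistic: regions without even one weakly correlated
   probe pair are better served by single-CpG analysis. The default
   cut-off is 0.3, inclusive; it requires a minimal level of
   co-methylation without inflating false-positive rates, and it shrinks
   the multiple-testing burden. The MAC is computed on the
   covariate-adjusted standardized residuals — the objects the analysis
   actually operates on — rather than raw M-values; since correlation is
   scale-free the standardization itself is irrelevant, but covariate
   adjustment can matter, so `regionMACs()` accepts any block if a user
   prefers the raw convention.

5. **Association** (`analyseRegions()`). Two families of regional tests:

   * *Per-PC meta-analysis* (`method = "fisher"` or `"stouffer"`): each of
     the k component score vectors is regressed on the phenotype
     (`PC ~ phenotype`; for simple regression the two-sided slope p-value
     is identical in either direction, which is asserted in the tests, and
     for a 0/1 phenotype it equals a pooled-variance two-sample t-test).
     The k p-values are combined by Fisher
     (`X = -2 Σ log p ~ χ²(2k)`) or Stouffer
     (`Z = Σ qnorm(1-p)/√k ~ N(0,1)`). When k = 1 the PC1 regression
     p-value *is* the regional significance — no meta-analysis is applied,
     and both combiners honour this identity exactly.
   * *Joint nested-model test* (`method = "joint"`): the phenotype is
     regressed on all k components at once and compared to the
     intercept-only model — the overall F-test for continuous phenotypes,
     the k-df likelihood-ratio χ² from logistic regression for dichotomous
     ones. A non-converged or separated logistic fit has its deviance drop
     capped at the null deviance and the region flagged.

   `firstPCOnly = TRUE` restricts either family to PC1. Dichotomous
   phenotypes default to the linear per-PC regression in the meta-analysis
   family (`binaryPerPC = "logistic"` switches to per-PC logistic Wald
   tests); the joint test is the only place a logit link is required.
   Across retained regions, Benjamini–Hochberg q-values are computed with
   `stats::p.adjust` and regions with q < 0.05 are reported as DMRs.

   The per-PC regressions + Fisher combination at the 80% threshold with
   MAC ≥ 0.3 is the recommended default: in our calibration it controls
   the genome-wide false-positive rate for all phenotype types while the
   joint logistic test inflates at small n, and it retains power whether
   the signal loads on PC1, PC2 or both.

6. **Guard rails**. The phenotype must never be part of the covariate set
   used for residualization — otherwise its signal is removed before
   testing — and `analyseRegions()`/`runDMRAnalysis()` enforce this by
   name. P-values are floored at 1e-300 before logs and normal quantiles.

## Simulation framework

`estimateGFP()` estimates the genome-wide false-positive (GFP) rate: the
probability that a phenotype simulated *independently* of the methylation
data still yields at least one FDR-significant region. Four null phenotype
types are built in (standard normal; χ²₁ as a skewed continuous case;
Bernoulli with 50% and with 25% cases). Because the null phenotype is
never a covariate, residuals and per-region PCA are computed once and
reused across replicates; replicate r seeds the RNG with `baseSeed + r`,
so any replicate is reproducible in isolation. `resampleSubjects = TRUE`
additionally draws a fresh subject subset per replicate (the small-sample
design), in which case residuals and PCA are recomputed per replicate. We
default to re-drawing the subset every replicate rather than once per
batch; the subset is part of the replicate's randomness.

`estimateTP()` estimates power on a single region carrying a constructed
signal: the phenotype is the M-value of the region's *causal probe* — the
probe with the largest absolute PC1 (or PC2) loading, ties broken toward
the lower index — plus independent normal noise; `cts_pc1pc2` averages the
standardized PC1- and PC2-anchored draws, and the `dts_*` variants split
at the median. A replicate counts as a true positive when the region's
uncorrected p-value is below 0.05. `calibrateNoiseSD()` inverts
`cor(M + e, M) = sd(M)/√(sd(M)² + sd²)` to target a phenotype/causal-probe
correlation; calibrations around 0.13–0.16 put power in the informative
middle of the scale, which is the regime our power checks use.

## The synthetic genome

`simulateMethylationDataset()` generates the study conditions used
throughout the tests and the acceptance script: 2,000 regions of 3–40
probes (within-region gaps 20–150 bp, clusters 5,000 bp apart, so region
building recovers the layout exactly), 20% intergenic, with per-region
correlation from a latent-factor model on the standardized M-value scale —
60% equicorrelated regions with ρ ~ U(0.05, 0.95), 40% two-factor regions
whose second factor is deliberately weaker and loads the complementary
probe half, so the PC1 and PC2 causal probes are separated. Baseline
probe means come from a bimodal mixture (N(−2.5, 0.4) and N(+2.5, 0.4)
with equal weight), matching the U-shaped beta marginals of real arrays;
per-probe scales are U(0.25, 1) in M-value units. Covariates (age, sex, a
cell-proportion analogue, a smoking-score analogue) act additively on the
M-value scale with per-probe effect sizes drawn from small normal
distributions; they exist so residualization has real work to do, and
their removal is verified in the tests. M-values map to beta through the
inverse logit, so betas are strictly inside (0,1) by construction.

What the generator does *not* emulate: probe-type chemistry (Type I/II),
batch and chip-position effects, cell-composition deconvolution, genuine
biological covariate-methylation confounding, or the heavy-tailed
measurement error of low-intensity probes. Passing calibration on this
genome therefore shows the *method* is sound under clean, complete,
well-adjusted data — the regime it is designed for — and says nothing
about upstream QC, normalization or batch correction, which remain the
user's responsibility.

## Numerical and design choices

* Gap rule inclusive (`gap ≤ maxGap` keeps probes together); probes at
  identical positions are kept with gap 0.
* `selectK` treats the threshold with a 1e-9 slack so an exact cumulative
  hit counts; variance fractions below 1e-12 count as zero rank.
* Equality of the shared-QR residualizer with per-probe fits is asserted
  at 1e-10; PCA spectra against brute-force eigen-decomposition at 1e-8.
* The Stouffer transform uses the one-sided `z = qnorm(1 - p)` convention
  on two-sided input p-values.
* The DMR call threshold q < 0.05 is configurable but is the conventional
  genome-wide criterion.
* Problem sizes in the test suite were chosen as desk-scale stand-ins for
  a full array: 2,000 regions × 200 replicates for false-positive
  calibration (binomial MC SE ≈ 0.015 at a true rate of 0.05), 500
  replicates for power contrasts, and ≥ 5,000 region-replicates for the
  null-uniformity check.

## Known limitations

* Per-PC p-values combined by Fisher/Stouffer assume independent
  components; PCA scores are orthogonal but, at small n, orthogonality
  induces slight negative dependence among the per-PC tests, making the
  combination mildly conservative (GFP estimates run at or below the
  nominal 0.05, never above, in our calibration).
* The joint logistic likelihood-ratio test inflates with many components
  and few cases (this small-sample behaviour is reproduced in the tests);
  prefer the meta-analysis family for dichotomous phenotypes.
* Regions are as good as the annotation: the builder trusts the supplied
  probe-to-gene map and analyses autosomes only.
* Cohorts below ~100 subjects estimate within-region correlation poorly;
  no attempt is made to stabilize PCA there.

## A worked example

```{r example, eval = FALSE}
ds <- simulateMethylationDataset(nSubjects = 100, nRegions = 300, seed = 1)
regions <- buildRegions(ds)
pheno <- simulateNullPhenotype("normal", 100, colnames(ds), seed = 2)
res <- analyseRegions(ds, regions, pheno)
head(as.data.frame(res))
gfp <- estimateGFP(ds, regions, "normal", nReplicates = 100, baseSeed = 10)
gfp
```
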