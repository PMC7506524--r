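---
title: "Methods: cross-disorder polygenic risk, regional ALFF and emotion recognition"
author: "crossprs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-disorder polygenic risk, regional ALFF and emotion recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossprs)
```

## The question the pipeline answers

Schizophrenia and autism spectrum disorder (ASD) share part of their common
genetic architecture. One way to ask *how* ASD-associated polygenic risk acts
in a schizophrenia cohort is to build each subject's ASD polygenic risk score
(PRS) from discovery GWAS summary statistics and test whether it tracks
intermediate phenotypes: regional spontaneous brain activity at rest
(amplitude of low-frequency fluctuation, ALFF) and facial-emotion-recognition
performance. `crossprs` implements that design as a reusable, fully testable
pipeline:

1. genotype quality control and ancestry principal components,
2. PRS construction over a high-resolution P-value threshold grid with
   P-value-informed LD clumping,
3. a case–control scan (logistic regression, Nagelkerke pseudo-$R^2$)
   selecting the ten most associated thresholds,
4. partition of the ASD SNP set into SNPs shared with schizophrenia versus
   ASD-specific SNPs,
5. region-wise ALFF from 90-region BOLD time series,
6. covariate-adjusted association and interaction tests with Bonferroni
   correction, and
7. a generic gene-set over-representation engine.

Because the cohort such a study uses is not distributable, the package ships
a synthetic-cohort generator that plants known effects, so every downstream
claim can be checked against ground truth.

## PRS model

For subject $i$ at threshold $P_T$, the score is the PRSice-style additive
sum $\mathrm{PRS}_i(P_T) = \sum_{j \in S(P_T)} d_{ij}\,\hat\beta_j$, where
$d_{ij} \in [0,2]$ is the aligned effect-allele dosage, $\hat\beta_j$ the
discovery log-odds effect, and $S(P_T)$ the set of clump-retained SNPs with
discovery $P \le P_T$. Clumping is greedy: SNPs are visited by ascending
discovery $P$ (ties: position, then id); each unclaimed SNP becomes an index
and claims unclaimed SNPs on its chromosome within 250 kb with squared
dosage correlation above 0.1. LD comes from the target-sample dosages
themselves — the design has no external reference panel.

Allele alignment: exact match uses the dosage, swapped alleles use
$2 - d$, strand-ambiguous A/T and C/G SNPs are dropped (counted and
reported), and anything else is dropped as unresolvable. Missing dosages are
replaced by the SNP's mean dosage. Scores are raw sums, not per-SNP
averages; every association statistic downstream is invariant to that scale
choice.

The threshold grid contains the multiples of 0.005 in $(0, 0.5]$ plus
$10^{-5}$, $10^{-4}$ and $10^{-3}$ — 103 values. A zero threshold would
select no SNPs, so the grid excludes it; this is the only reading consistent
with a 103-value grid that "ranges from 0 to 0.5".

The scan fits, per threshold, logistic case–control status on the score plus
covariates (age, sex, education and four ancestry PCs), takes the Wald P of
the score coefficient, and computes Nagelkerke's
$R^2 = \dfrac{1 - \exp\{2(\ell_0 - \ell_1)/n\}}{1 - \exp\{2\ell_0/n\}}$
against the covariates-only model. The ten smallest-P thresholds are
selected (ties resolved toward the smaller threshold); non-converged fits
are flagged and excluded.

**Partition.** At a threshold, the ASD selection splits into SNPs "shared"
with the comparison disorder and "ASD-specific" SNPs. The source material
does not pin down the SCZ-side criterion; the default here is presence in
the SCZ table with SCZ $P \le P_T$ (the same threshold applied to both
disorders), with mere presence available via `scz_rule = "present"`. The
partition is exactly additive: the ASD score equals the shared-subset score
plus the specific-subset score for every subject and threshold (tested to
1e-10). A single clumping pass on the ASD statistics is reused for all
thresholds and both partition pieces; an SCZ PRS would be clumped
independently on SCZ statistics.

## Genotype QC

Variant filters: minor allele frequency $\ge$ 1% (MAF from mean dosage / 2,
folded), call rate $\ge$ 95%, Hardy–Weinberg equilibrium $P \ge 10^{-5}$.
HWE uses the 1-df chi-square goodness-of-fit on hard-called genotypes
(dosage rounded to the nearest integer) — not the exact test; the design
names only a threshold, and the chi-square matches a brute-force
$\sum (O-E)^2/E$ oracle in the tests. Sample filters: missingness $\le$ 5%,
no flagged sex mismatch (the pipeline carries no X-chromosome data model,
so mismatch arrives as a precomputed flag), and pairwise identity-by-descent
$\hat\pi \le 0.90$ via the PLINK-style method-of-moments estimator on
identity-by-state counts. Of an over-related pair, the member with higher
missingness is removed; on a tie, the lexicographically smaller id — the
source is silent, so the rule is fixed and documented here.

Ancestry PCs standardize each SNP by $\sqrt{2p(1-p)}$ (the
population-genetics convention; the choice affects component scale only,
not covariate adjustment), order components by variance explained, and sign
them so the largest-magnitude loading is positive.

## ALFF

Each subject contributes a timepoints × 90 matrix of region-wise BOLD
series (AAL order; region 41 is the left amygdala). Subjects exceeding
3 mm translation or 3° rotation on any axis are excluded (strictly greater
than; exactly 3.0 is kept). Nuisance regression removes an intercept, a
linear trend and any supplied regressors by OLS, leaving mean-zero columns
orthogonal to every regressor.

ALFF is computed spectrally: with $N$ timepoints at repetition time
$\mathrm{tr}$, the amplitude at Fourier frequency $k/(N\,\mathrm{tr})$ is
$a_k = 2\,|X_k|/N$, and ALFF is the mean of $a_k$ over the bins with
$0.01 \le k/(N\,\mathrm{tr}) \le 0.08$ Hz, endpoints inclusive. The scaling
makes the contract checkable in closed form: a pure in-band tone of
amplitude $A$ at an exact Fourier bin yields ALFF $= A/n_\text{bins}$
(for $N = 200$, $\mathrm{tr} = 2$ s the band holds bins $k = 4..32$, i.e.
29 bins), and ALFF is positively homogeneous of degree one in signal
amplitude. A band-pass-filter-then-power implementation would differ only
by filter leakage; the spectral definition is adopted as the contract, and
the fixed order is nuisance regression first, spectral ALFF second.
Normalization divides each region by the subject's mean across the 90
regions ("within-brain" at region resolution — voxel-level normalization
would need images that are out of scope), so normalized values average
exactly 1 per subject.

## Association statistics

Associations are ordinary least squares of the outcome on intercept, score
and covariates (age, sex, education, disease status, four PCs), complete
cases per outcome. The reported correlation is the signed partial
correlation $r = t/\sqrt{t^2 + \mathrm{df}}$ of the score coefficient; by
the Frisch–Waugh theorem this equals the plain correlation of the two
covariate-adjusted residual vectors (tested to 1e-10), which makes it the
natural reading of a "correlation coefficient" attached to a regression
slope. Interaction with disease status adds score × status and reports the
product term's P; status coding is normalized internally so any two-level
coding gives identical results.

Bonferroni families: 90 for the region-wise ALFF analysis, 4 for the
emotion scores (positive, neutral, negative, total). The family sizes are
recoverable from the worked pairs $1.20\times10^{-4} \to 1.08\times10^{-2}$
(× 90) and $4.54\times10^{-6} \to 1.82\times10^{-5}$ (× 4); thresholds are
not counted in the family. Group comparisons use the pooled-variance t test
(pooled recomputation reproduces the published cohort table's t values from
its printed summaries; Welch does not) and Pearson chi-square without
continuity correction (which reproduces the printed 2.1365 for the 2×2
gender table exactly).

## Over-representation

`overrepresent()` is a generic engine over user-supplied gene intervals and
GMT gene sets: one-sided hypergeometric (Fisher exact) tail per set, fold
enrichment $(k/n)/(K/N)$, Bonferroni over the number of tested sets
(significance threshold 0.01 by default). The background defaults to all
genes in the supplied interval table — an annotation-service default
background cannot be reproduced without its database, and term-list
reproduction is explicitly out of scope. The EASE variant subtracts one
overlapping gene before the test ($k \to k-1$, margins unchanged; the
jackknife description in the literature is ambiguous about whether margins
shrink too, so the simplest monotone choice is used: EASE P $\ge$ Fisher P
always). It is off by default. SNP-to-gene mapping is strict containment in
1-based inclusive gene bodies; a `--flank`-style extension is deliberately
not a default because the source material does not state one.

## The synthetic-cohort generator

`simulate_cohort()` draws everything the pipeline consumes. Defaults are
the study conditions: 328 subjects (116 cases, 212 controls), discovery
GWAS with effective sizes 46,350 (ASD) and 65,967 (SCZ), 90-region series
of 170 volumes at TR = 2 s, and planted effects sized to the published
associations (below).

**Genotypes.** SNPs live in contiguous LD blocks. Within a block each
subject's latent Gaussian vector is equicorrelated with correlation
`block_r2` and cut at the binomial(2, p) genotype quantiles of the SNP's
allele frequency (uniform on \[0.05, 0.5\]), so marginals are exactly
Hardy–Weinberg; blocks are independent, laid out 1 Mb apart with 1 kb SNP
spacing so a 250 kb clumping window spans one block and never two. Quantile
thresholding attenuates correlation: a latent 0.8 yields mean dosage
correlation near 0.6 (the tests freeze the empirically verified band
0.55–0.9). Only strand-unambiguous allele pairs are emitted, mirroring
array QC; ambiguous-SNP handling is exercised by crafted fixtures instead.

**Summary statistics.** A `causal_fraction` of SNPs (default 10%) carries
planted effects $\sim N(0, \texttt{effect\_sd}^2)$; the comparison disorder
has an equal-sized causal set sharing `overlap_fraction` of the ASD SNPs.
Reported effects add sampling noise of scale
$\texttt{effect\_sd}/\sqrt{n_\text{eff}}$ and P values come from the
corresponding two-sided z-test, so null SNPs are exactly uniform. With the
default effective sizes the planted SNPs are overwhelmingly significant —
deliberate: it makes threshold membership of causal SNPs stable and the
planted-score recovery analytically tractable.

**Phenotypes.** The true score is the dosage-weighted sum of planted
effects, standardized. The planted region's series is white noise
(SD `noise_sd`) plus a sinusoid at 0.04 Hz (snapped to the nearest Fourier
bin, so its ALFF contribution is exactly amplitude / n_bins) with amplitude
$1 + \texttt{planted\_beta} \cdot \mathrm{score}_i$; all other regions are
pure noise. The negative-emotion score is
$\mathrm{round}(\text{base} - \texttt{emotion\_beta}\cdot\mathrm{score} +
\varepsilon)$ clipped to \[0, 20\] — emotion scores are counts of correctly
identified items, and 20 items per category is a stand-in (the instrument's
per-category item counts are not published). Age, sex and education are
drawn with case–control differences in the directions seen in the cohort
(controls older and more educated), so covariate confounding is genuinely
exercised.

**Calibration of the planted effect sizes.** The planted conditions are
stated on the *measured* effect: a covariate-adjusted partial correlation
near the published +0.21 (ALFF) and −0.23 (negative emotions) at n = 328.
Two attenuation steps sit between `planted_beta` and the measured
correlation. First, the spectral noise floor: a white-noise region's ALFF
has mean $\sigma\sqrt{\pi/N}$ and SD $\approx \sqrt{(4-\pi)\sigma^2/(N B)}$
over $B$ band bins (for $N=170$, TR = 2 s: $B = 24$, SD $\approx 0.0146$),
so a true-score correlation $r_0$ needs amplitude slope
$\texttt{planted\_beta} = B \cdot \mathrm{SD} \cdot r_0/\sqrt{1-r_0^2}$.
Second, the estimated PRS is not the true score: clumping absorbs causal
SNPs that share a block (measured corr(PRS, true score) ≈ 0.83 under the
defaults). Solving backwards gives the defaults `planted_beta = 0.095` and
`emotion_beta = 0.73` (emotion noise SD 2.5 plus rounding variance).
With them the pipeline's measured partial correlations center on +0.21 and
−0.21.

**What the generator does not emulate:** realistic haplotype/coalescent
structure, imputation uncertainty, voxel-level images, scanner drift or
physiological noise spectra, missing genotypes or phenotypes by default,
and genuine case–control PRS differences (none are planted, matching the
null case–control scan result the design anticipates). Passing tests
therefore demonstrate that the machinery recovers what was planted under
the stated noise model — not that any particular real-data result would
replicate.

## Numerical choices and degenerate inputs

* Monomorphic sites: HWE P is 1 by convention (logged); monomorphic SNPs
  are excluded from PCA standardization and IBD expectations.
* A threshold selecting zero SNPs scores as `NA` with `n_snps = 0` and is
  excluded from the scan; `prs_score()` errors instead, naming the
  threshold, and an empty `snp_subset` errors as "all SNPs dropped".
* Band endpoints are inclusive with a 1e-12 tolerance against binary
  representation of 0.01 and 0.08.
* `nagelkerke_r2` rejects `ll_null = 0` (degenerate denominator) and
  `ll_full < ll_null`.
* Collinear designs error, naming the columns, rather than silently
  dropping terms.
* P values in synthetic summary statistics are floored at 1e-300 to respect
  the open-interval contract.

## Problem sizes used by the test suite

The suite runs the full pipeline at the study's subject count (n = 328)
with 600 SNPs in 60 LD blocks — enough for ~60 causal SNPs and realistic
clumping behavior while keeping 100-seed recovery and calibration loops in
the minutes range. Null-uniformity checks use 5,000 SNPs; LD-structure
checks use 2,000 subjects; PCA uses two 200-subject subpopulations with
0.2 allele-frequency divergence. These sizes are the package's chosen
trade-off between statistical resolution and turnaround.

## Known limitations

* No shrinkage or continuous-weight PRS methods; threshold grids only.
* No reference-panel LD; clumping always uses target dosages.
* No X/Y chromosome handling, no imputation, no batch-effect modeling.
* Region-wise only: no voxel-level maps, no spatial preprocessing, no
  fALFF.
* Over-representation has no GO-graph propagation and no annotation
  downloads; results depend entirely on the supplied interval and set
  files.
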