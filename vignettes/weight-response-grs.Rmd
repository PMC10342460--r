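---
title: "Genetic risk scores for long-term weight response after bariatric surgery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic risk scores for weight response: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bariGRS)
```

## The scientific problem

Bariatric surgery produces large but heterogeneous weight loss: patients
differ both in the maximum weight loss they reach (the *nadir*, usually one
to two years after surgery) and in how much of it they later regain. Part of
that heterogeneity is genetic. bariGRS implements a candidate-gene analysis
of this problem for a panel of 48 common variants in 13 genes (gene
families) encoding gastrointestinal peptides, their receptors, or proteins
involved in their expression — GHSR, WFS1, BDNF, MC4R, GIPR, DPP-IV, the
NPY receptors, CLOCK, GLP1R, TCF7L2, KCNJ11, FTO and PYY — and aggregates
the significant variants into unweighted, phenotype-specific genetic risk
scores.

## Phenotypes

From each patient's longitudinal weight record (annual visits, years 0–8,
year 0 = pre-surgery weight $W_0$) the package derives:

* **%TWL** (total weight lost): $100\,(W_0 - W_t)/W_0$, at the nadir and at
  the end of follow-up;
* **%EWL** (excess weight lost): $100\,(W_0 - W_t)/(W_0 - 25h^2)$, where
  $25h^2$ is the ideal weight at BMI 25 kg/m² for height $h$;
* **%WR_MWL** (weight regain as a percentage of maximum weight lost):
  $100\,(W_6 - W_{nadir})/(W_0 - W_{nadir})$;
* binary codings %EWL$_{6y}>50$ and %WR_MWL$>20$ (strict inequalities;
  boundary values fall in the negative class).

The nadir is the minimum over *all* postoperative visits, earliest year on
ties. The end of follow-up is year 6; because a missing-visit rule was
needed and none is prescribed by convention, the package takes the visit
closest to year 6 within years [5, 7], ties toward the later visit.
Patients without a window visit are excluded from year-6 phenotypes but
retained for nadir phenotypes, with the exclusion reason recorded.

## Per-SNP association model

Each SNP is tested against each phenotype under five inheritance encodings
relative to the reference-allele homozygote: codominant (two indicators),
dominant, recessive, over-dominant and log-additive (allele dose 0/1/2).
Fits are linear (quantitative phenotypes) or logistic (binary codings),
always adjusted for sex, age, initial BMI, T2D, hypertension and surgery
type (two indicators against a restrictive baseline). Per SNP, quality
control requires a call rate of at least 0.95; the Hardy–Weinberg exact
test (full enumeration of the conditional heterozygote distribution) is
reported but is not exclusionary, since no exclusion rule is prescribed.

Numerical choices worth knowing:

* **Genetic-term p-value.** A likelihood-ratio test of the model with
  versus without the genetic column(s). For Gaussian models the exact
  finite-sample form of the LRT is used (the F statistic is a monotone
  transform of the Gaussian likelihood ratio), so the per-model test is
  exactly calibrated; logistic models use the asymptotic chi-square LRT.
* **AIC.** $2k - 2\log L$ with $k$ counting fitted regression
  coefficients (intercept and covariates included). For linear models the
  residual-variance parameter is a constant offset shared by all five
  encodings and cannot affect the argmin.
* **Ties.** AIC ties (to $10^{-6}$) break toward fewer genetic parameters,
  then a fixed order: log-additive, dominant, recessive, over-dominant,
  codominant.
* **Degenerate encodings** (e.g. recessive at a SNP with no
  alternate-allele homozygotes) are skipped and recorded, not silently
  fitted.
* **Missing data.** Complete-case analysis throughout; no imputation.
* **Multiplicity.** No correction by default, replicating the original
  single-cohort convention; a Benjamini–Hochberg gate is available
  (`fdr = TRUE`).

**Post-selection caveat.** Selecting the best-AIC encoding and then reading
that model's p-value is anticonservative: under the null the selected
model's LRT p is the most extreme of five correlated tests, and the
realized type-I error of the `significant` gate is roughly 0.14 at
$\alpha = 0.05$ (measured by simulation in this package's acceptance
suite). Each *per-model* p-value is calibrated; the selected-model gate is
not, and the same caveat applies to any analysis using this widespread
select-then-test convention. The acceptance suite therefore asserts
calibration of the per-model tests and documents (rather than hides) the
gate's inflation.

## Risk scores

For each phenotype with significant SNPs, the *risk allele* of each SNP is
the allele associated with lower weight loss or higher weight regain: for
loss phenotypes a negative best-model contrast against the
reference-homozygote baseline makes the alternate allele the risk allele,
a positive contrast the reference allele; for regain phenotypes the rule is
reversed. Patients score 2 points per risk-allele homozygote, 1 per
heterozygote, 0 otherwise — an unweighted score, deliberately ignoring
effect sizes. An over-dominant winner has no allele-dose direction, so the
adverse genotype class scores 1 point and the entry is flagged (no genotype
can contribute 2). Missing genotypes contribute 0 by default (conservative,
biases toward the low class) and are counted per patient.

Scores are split at the cohort 75th percentile (linear-interpolation
convention, `quantile` type 7); the high class is *strictly above* the
cutoff, and the realized integer threshold (the smallest score in the high
class) is reported so the grouping can be compared with a published
"at least 7 points" rule. Applying the 2/1/0 rule to the published SNP sets
gives maxima of 12 points (six SNPs, %TWL at year 6) and 6 points (three
SNPs, %TWL at nadir); the published regain-score range of 0–12 is
inconsistent with its three listed SNPs, and this package follows the
$2m$ rule (maximum 6).

Score–outcome effects are estimated by the same adjusted linear/logistic
models with the high/low category as exposure; for odds ratios below 1 the
reciprocal is also reported, as the "times more likely to miss the target"
restatement. Pre-surgery profiles across categories are compared by Welch's
t-test (continuous) and chi-square tests without continuity correction
(categorical); no test is prescribed by convention for such tables, and
Welch's test is the safer default under unequal variances.

## The synthetic cohort

No patient-level data from the original cohort were deposited, so the
package ships a generator that emulates the cohort's *statistical
structure*; all calibration and recovery claims are claims about this
stated world:

* **Genotypes** are drawn i.i.d. per SNP under Hardy–Weinberg proportions
  at the manifest MAF, independent across SNPs (the analysis is marginal
  per SNP, and tag-SNP selection is out of scope — no linkage
  disequilibrium is simulated). The published panel gives reference alleles
  only; alternate alleles in the packaged manifest are the transition
  partner of the reference (pinned by the published risk allele where one
  differs from the reference), and MAFs were drawn once, uniformly in
  [0.1, 0.45] (the panel was restricted to common variants), and frozen.
  Both are labelled synthetic. Missing calls default to 2%, below the 5%
  QC threshold, so missingness handling is exercised without triggering
  exclusion.
* **Covariates** match the published marginals: 69% female, BMI
  44.87 ± 6.59 (truncated to [35, 70] with the location recentred so the
  truncated mean equals the target), age 44.79 ± 11.99 (truncated to
  [18, 65], likewise recentred), 35.7% T2D, 49% hypertension, surgery mix
  16/54.66/29.34%. Height, needed only for the ideal weight, is
  Normal(1.65, 0.09) truncated to [1.40, 2.10] m — the study reports no
  heights.
* **Trajectories** follow a nadir-anchored piecewise curve: exponential
  decline from $W_0 = \mathrm{BMI}_0 h^2$ to the nadir at year 1 or 2, then
  linear regain through follow-up. The latent nadir %TWL is a
  covariate-driven baseline (mean ≈ 38.8%, modest fixed effects of surgery
  type, age, BMI, sex, T2D, HTN) plus planted genetic shifts plus Gaussian
  noise (`noise_sd`, default 8 percentage points); latent regain is
  log-normal with median 15.76% and log-sd 0.77, matching the published
  median and IQR shape. Planted effects shift the latent phenotype by
  `effect × encoding(genotype)` *exactly* before noise, which is what makes
  parameter-recovery tests sharp.
* **Visit noise** (kg-scale measurement error) defaults to 0 and is
  exposed as `visit_noise_sd`: taking a minimum over noisy visits biases
  the observed nadir downward, which would contaminate the recovery
  invariants the generator exists to support. Users wanting realistic
  measurement error can switch it on, accepting that bias.

What a green test does *not* establish: the generator has no linkage
disequilibrium, no population stratification, no genotyping-error model,
no informative missingness, and its trajectory family is far smoother than
real weight curves. Green calibration/recovery results validate the
statistical machinery, not the biological effect sizes, which are not
reproducible without the original data.

Determinism: every random draw flows through one seeded path
(Mersenne-Twister, set locally and restored), so a configuration plus seed
reproduces outputs bit-for-bit.

## Parameter-recovery design

The acceptance suite plants a dominant −5 percentage-point effect on
%TWL at year 6 (n = 375, 500 replicates) and checks ~95% CI coverage of −5
*under the generating (dominant) encoding*, not under the AIC-selected
model: when the log-additive encoding happens to win the selection, its
per-allele coefficient is a biased estimator of a carrier-group shift, so
post-selection CIs are not nominally calibrated (same phenomenon as the
gate inflation above). Sign correctness and risk-score membership are
checked on the selected model, where they are robust.

The recovery experiment runs with the regain dispersion switched off
(`wr_sdlog = 0`), so the Gaussian phenotype noise (`noise_sd = 8`) is the
only stochastic term and exact-t coverage theory applies. Under the full
generator defaults the log-normal regain noise makes the year-6 %TWL error
skewed, and measured coverage of the same interval drops to about 93% —
a genuine property of heavy-tailed phenotype noise worth knowing when
interpreting CIs on real cohorts, not a defect of the interval
construction.

## Known limitations

* Positions are not tracked; variants are keyed by rsid and allele letters
  (the source panel publishes no coordinates), so the VCF writer emits
  synthetic coordinates.
* Haplotype-level analysis, kinship/mixed models and genome-wide scanning
  are out of scope.
* The per-plate call-rate QC of the original protocol cannot be replicated
  without plate layout; QC is per SNP at the same 0.95 threshold.
* The published cohort's effect sizes are not recoverable; packaged tables
  of published summary statistics are inputs used for score construction
  and structural checks only.
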