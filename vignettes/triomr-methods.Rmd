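---
title: "Methods: two-sample and trio Mendelian randomization in triomr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample and trio Mendelian randomization in triomr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomr)
```

## The causal question

Observational associations between maternal nutrient levels in pregnancy
(vitamin D, the omega-3 fatty acid DHA) and offspring neurodevelopmental
traits (ADHD- and autism-related scores) are vulnerable to genetic
confounding and reverse causation. `triomr` implements the full battery of
genetically informed designs used to probe such questions:

1. **Two-sample MR** — SNP-exposure effects from a nutrient GWAS combined
   with SNP-outcome effects from an independent sample, via the
   inverse-variance weighted (IVW) estimator and its sensitivity suite.
2. **Trio-MR** — regression of the child outcome on the maternal polygenic
   score (PGS), with and without adjustment for the child and paternal PGS,
   isolating maternal-specific (e.g. intrauterine) paths from transmitted
   genetic predisposition.
3. **Paternal negative control** — a paternal PGS association implicates
   postnatal/household paths or bias rather than intrauterine effects.
4. **Reverse-direction MR** — genetic liability to the neurodevelopmental
   condition as the exposure and the nutrient as the outcome.

Because individual-level trio cohorts and large GWAS are access-restricted,
the package ships a first-class synthetic-data module whose generative
model encodes each competing mechanism, so every stage of the pipeline has
a ground-truth acceptance surface.

## Two-sample MR estimators

For harmonized per-variant effects $(\hat\beta_{Xj}, \hat\beta_{Yj})$ with
standard errors $(\sigma_{Xj}, \sigma_{Yj})$:

* **Wald ratio** $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with
  first-order standard error $\sigma_{Yj}/|\hat\beta_{Xj}|$ (a second-order
  version adding the exposure term is available by flag).
* **IVW**: $\hat\theta = \sum_j w_j\hat\theta_j / \sum_j w_j$ with
  $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$, identical to weighted regression
  of $\hat\beta_Y$ on $\hat\beta_X$ through the origin. The default error
  model is multiplicative random effects: the fixed-effect standard error
  $(\sum_j w_j)^{-1/2}$ is inflated by $\max(1, \sqrt{Q/(J-1)})$, where $Q$
  is Cochran's statistic. The floor makes the interval deliberately
  conservative under homogeneity; for calibration studies under a
  correctly specified null the fixed-effect interval is the exact model,
  which is what the package's own calibration checks assess (both type-I
  rates are reported by `scripts/acceptance.R`).
* **MR-Egger**: weighted least squares of $\hat\beta_Y$ on $\hat\beta_X$
  with a free intercept after orienting every variant to
  $\hat\beta_X \ge 0$; the intercept estimates directional horizontal
  pleiotropy. Standard errors use the classical WLS residual scaling with
  $t_{J-2}$ inference (no floor), matching the estimator as published and
  keeping the intercept test at nominal size.
* **Weighted median**: the 50% point of the inverse-variance-weighted
  empirical distribution of ratio estimates, consistent when at least half
  the weight comes from valid instruments. Standard errors by seeded
  parametric bootstrap (default 1000 draws).
* **Weighted mode**: argmax of a weighted Gaussian kernel density of the
  ratios; bandwidth is $\varphi\, h_0$ with $h_0$ the MAD (normal
  consistency constant 1.4826) and $\varphi = 1$ by default, on a 10 000
  point grid spanning the ratios ± 3 bandwidths. Ties in a zero-MAD
  configuration fall back to the standard deviation; a degenerate panel
  (all ratios equal) returns that value exactly.

Diagnostics: Cochran's $Q$ (heterogeneity; $J-1$ df around the IVW centre,
$J-2$ around Egger), per-SNP $F = (\hat\beta_X/\sigma_X)^2$ (mean $F > 10$
is the usual weak-instrument heuristic), and
$I^2_{GX} = \max\{0, (Q_{GX} - (J-1))/Q_{GX}\}$ quantifying measurement
error in the SNP-exposure estimates. When $I^2_{GX}$ falls below the
configurable trigger (default 0.9, flagged in reports — the trigger is an
implementation default, not an assertion about any particular study),
the pipeline runs SIMEX-corrected Egger: noise
$N(0, \lambda\sigma_{Xj}^2)$ is added for
$\lambda \in \{0, 0.5, 1, 1.5, 2\}$, the mean slope per $\lambda$ is fitted
with a quadratic, and the fit is extrapolated to $\lambda = -1$; the
standard error is a leave-one-SNP-out jackknife with shared seeds.

Steiger filtering computes per-variant variance explained from the t
statistic, $r^2 = t^2/(t^2 + n - 2)$, on both sides and keeps a variant iff
it explains strictly more variance in the exposure; the same formula is
applied to binary traits on the observed scale (a documented
approximation). The orientation summary `direction_ok` is defined as a
majority of variants kept.

Reverse-direction estimates with a binary exposure on the log-odds scale
are multiplied by $\ln 2 \approx 0.693$ so they read per doubling of the
odds of liability.

## Harmonization and clumping

Harmonization aligns the outcome to the exposure's effect allele: direct
match, allele swap (sign flip), strand complement, and palindromic (A/T,
C/G) resolution by allele frequency. Palindromes are dropped when either
frequency is missing or falls within ±0.08 of 0.5 (`palindrome_eaf_tol`,
configurable; the band is an implementation default since source studies
rarely state their policy). Indels and multi-allelic records are rejected
at read time — the instrument sets in the GWAS this package targets are
biallelic SNPs.

Clumping is greedy by ascending p-value: the best remaining variant
becomes an index and discards correlated neighbours
($r^2 \ge$ threshold within ± window). Ties break deterministically by
(chromosome, position, id). Two parameterisations matter: instrument
selection for MR ($r^2 < 0.001$, 10 000 kb) and PGS construction
($r^2 = 0.25$, 500 kb), both at genome-wide significance
($p < 5\times10^{-8}$); reverse-direction MR relaxes selection to
$p < 5\times10^{-6}$ because diagnosis GWAS yield few genome-wide
significant loci.

## Trio models

All trio regressions are ordinary least squares with classical standard
errors, adjusted for child sex, the first 10 principal components and
genotype batch (one-hot, first-level reference; a single-level batch is
dropped as collinear). Outcomes are z-standardized per outcome before
fitting, so effects read per SD of the outcome per SD of PGS; complete
cases only, with dropped counts logged. The battery:

* maternal PGS alone (`fit_maternal_unadjusted`) — mixes causal and
  transmitted paths;
* maternal + child + paternal PGS (`fit_trio_adjusted`) — adjusting for the
  child PGS alone would open a back-door path through the paternal
  genotype, so the paternal score is always included;
* child models and the paternal negative control, each before and after
  adjusting for the other family members;
* sex-stratified fits and the maternal-paternal PGS correlation
  (Pearson, Fisher-z CI) as an assortative-mating check.

Per-variant SNP-outcome regressions (the individual-level outcome "GWAS"
feeding two-sample MR) are implemented by Frisch-Waugh-Lovell
residualization against the covariates, which is numerically identical to
looped per-variant OLS and validated against it in the tests.

## The generative model

`sim_config()` describes a trio cohort: unlinked SNPs with MAF uniform on
[0.05, 0.5], parental genotypes in Hardy-Weinberg equilibrium, children by
Mendelian transmission (one Bernoulli(dosage/2) allele per parent per
locus). Assortative mating is induced by rank-matching couples on their
instrument score to a noisy target, reaching a configurable score
correlation. Each role's nutrient is
$\sqrt{h^2} Z + \sqrt{1-h^2}\,\varepsilon$ with $Z$ the standardized
genetic score, so the instruments explain exactly $h^2$ of its variance.

**Parameterisation choice.** The causal path coefficients
(`theta_maternal`, `theta_child`, `theta_dynastic`) act on the
*standardized genetic nutrient scores* — the component a polygenic score
measures — rather than on the noisy nutrient itself. This makes the trio
regression coefficients directly unbiased for the configured thetas (the
package's parameter-recovery checks exploit this), at the price that the
implied effect per unit of *nutrient* is $\theta/\sqrt{h^2}$; with desk-scale
$h^2$ and $\theta$ values this can exceed the per-SD-of-exposure effects a
real study would report. Residual outcome noise is chosen so the outcome
has unit variance by default, keeping estimates on the per-SD reporting
scale.

Defaults emulate the vitamin-D arm of the motivating design: 38 instrument
SNPs explaining 3.1% of variance, exposure GWAS of N = 401 460, outcome
GWAS of N = 23 713, 16 298 trios. The liability (diagnosis) panel defaults
to 34 SNPs explaining 5% of a latent liability, thresholded at a 40% case
fraction in a GWAS of N = 46 350 with per-SNP logistic fits — numbers
chosen to mirror a case-enriched autism diagnosis GWAS at a size where the
relaxed threshold retains a usable instrument set. The reverse path
defaults to −0.2: large enough to be detectable at these sample sizes,
whereas effects of a few hundredths of an SD per doubling (the scale real
studies report) would require GWAS two orders of magnitude larger than a
desk-scale simulation can carry.

Scenario presets activate one mechanism each: `null`, `maternal_causal`
(θ_m = 0.2), `genetic_confounding` (θ_c = 0.3 and no maternal path, which
produces a spurious unadjusted maternal association of ≈ θ_c/2 through
transmission), `pleiotropic`, `reverse_causation`, `assortative`
(parental score correlation 0.3). One master seed expands into per-stage
child seeds via a counter scheme (`child_seed`), so any stage reproduces
independently.

What the generator does *not* emulate: linkage maps (SNPs are unlinked, so
clumping exercises use explicit r² fixtures), imputation uncertainty,
ancestry admixture, and the skewed count distributions of real
questionnaire scores (outcomes are Gaussian). Passing tests therefore
validate the estimators and the logic of the designs, not robustness to
those data features.

## Numerical choices and edge cases

* Wald ratios error on `beta_exp = 0`; single-instrument IVW falls back to
  the Wald ratio with a warning; Egger and the median/mode require ≥ 3
  instruments.
* Bootstrap and SIMEX draws require an explicit seed and are bit
  reproducible; bootstrap default 1000 draws, SIMEX default 1000
  simulations per λ.
* The Bonferroni threshold for the primary grid (α = 0.05, 19 outcomes ×
  2 exposures) is 0.05/38 ≈ 0.00132, displayed as 0.001; comparisons
  always use the raw value.
* Monomorphic variants yield no SNP-outcome row (recorded with a reason);
  missing dosages are mean-imputed within variant for regression and
  imputed at 2·eaf (or excluded, by policy) for scoring.
* PGS are standardized within role, since trio regressions mix roles.

## Problem sizes used in the checks

The package's own acceptance checks run at: 1000 null replicates of 50
instruments for calibration; 500 replicates of 10 000 trios per scenario
for parameter recovery; single 10 000-trio cohorts for the attenuation
signature; one reverse-direction run at the default GWAS sizes. These
sizes give Monte-Carlo errors comfortably below the effect sizes being
recovered while completing in minutes on one CPU.

## Worked example

```{r example, eval = FALSE}
cfg <- list(scenario = "genetic_confounding", seed = 11,
            sim = list(n_trios = 10000))
rep2 <- run_analysis2(cfg)
subset(rep2$tables$trio, term == "pgs_mother" & stratum == "all")
```

Under genetic confounding the unadjusted maternal coefficient is ≈ 0.15
(half the child direct effect, via transmission) and the trio-adjusted
coefficient is compatible with zero — the attenuation signature that
distinguishes transmitted predisposition from a maternal causal effect.
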