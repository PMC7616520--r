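---
title: "Methods: contrasting behavioral and biomarker exposures in drug-target MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrasting behavioral and biomarker exposures in drug-target MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
```

## Overview

`targetmr` implements a two-sample Mendelian randomization (MR) workflow
built around a specific failure mode of drug-target MR: using a
*behavioral proxy* (caffeinated-drink consumption) in place of the
*biomarker* it is meant to stand in for (plasma caffeine). Two mechanisms
make the proxy treacherous. First, **titration feedback**: fast
metabolizers have lower circulating caffeine and drink more to
compensate, so metabolism variants associate positively with the
biomarker but negatively with consumption, and the sign of an MR estimate
depends on which exposure the same variants are "weighted" by. Second,
**behavioral pleiotropy**: variants that genuinely act on drinking
behavior do so through latent lifestyle traits with their own outcome
effects, violating the exclusion restriction.

This vignette documents the statistical methods, the tunable parameters,
the numerical choices, and what the synthetic validation does and does
not establish.

## Harmonization

All estimation operates on a `harmonized_set`: per-variant effects of one
or two exposures and an outcome aligned to the exposure's effect allele.
Outcome records with swapped alleles have their beta negated (and allele
frequency reflected); strand complements are resolved first.
Palindromic (A/T, C/G) variants cannot be strand-resolved from alleles,
so by default (`palindrome_policy = "infer"`) they are kept only when
both effect-allele frequencies fall outside `0.5 ± eaf_window` (default
window 0.08, mirroring common two-sample MR practice) and are aligned by
frequency concordance; `"drop"` removes them outright, and a palindromic
variant with a missing frequency on either side is always dropped,
because nothing can disambiguate it. Every removal is recorded with a
reason, making any policy auditable after the fact. Indels and
multi-allelic records are rejected at parse time; the workflow is defined
for biallelic SNPs.

Harmonization is involution-safe (an aligned pair passes through
unchanged) and sign-coherent (negating all exposure betas while swapping
their allele labels leaves downstream estimates invariant); both are
enforced by property tests.

## Instrument selection and strength

Selection retains variants with `p < p_threshold` (strict inequality;
default `5e-7`). Greedy clumping walks candidates in ascending p-value
order (ties broken lexically by rsid, for determinism) and keeps a
variant only if its LD r² with every previously kept variant is at most
`clump_r2` (default 0.001). LD is supplied as a matrix — estimating LD
from a reference panel is out of scope, and the simulator emits the
matrix it implies.

Variance explained per variant is available in two forms:
`2·eaf·(1−eaf)·beta²` (requires SD-unit betas and frequencies) and the
frequency-free `t²/(t² + n − 2)`, which is the package default since
outcome meta-analyses often lack usable allele frequencies. The joint
instrument F statistic is `F = (r²/(1−r²))·(n−k−1)/k`, with the combined
r² taken as the sum of per-variant values — an approximation that is
accurate exactly when instruments are clumped to near-zero pairwise LD,
which is the only regime in which the workflow uses it. A mean per-SNP F
can be obtained by calling `f_statistic()` per variant; the joint form is
the default report because it reflects the multi-instrument fit.

## Univariable estimators

With aligned per-variant effects, the IVW estimate is the
inverse-variance weighted mean of Wald ratios, algebraically the
zero-intercept weighted least-squares slope of outcome betas on exposure
betas with weights `1/se_y²`. The default standard error is
multiplicative random-effects: the fixed-effect SE inflated by
`max(1, sqrt(Q/(k−1)))`, the common default in two-sample MR software
(the source workflow states only "inverse-variance weighted"). MR-Egger
adds an intercept (average directional pleiotropy) after orienting all
variants to non-negative exposure betas — the orientation is applied
internally and does not change the slope. Its SEs carry an
overdispersion factor bounded below by 1, and p-values use the t
distribution with `k − 2` degrees of freedom.

The weighted median sorts ratio estimates, forms normalized
inverse-variance weights, and interpolates the cumulative weight
midpoints at probability one half. The mode estimators place a Gaussian
kernel of bandwidth `phi · 0.9 · min(sd, IQR/1.349) · k^(−1/5)` over the
ratios (unit weights for the simple mode, IVW weights for the weighted
mode) and take the density argmax on a fixed 512-point grid spanning
`min(ratio) − h` to `max(ratio) + h`; the fixed grid makes the argmax
deterministic. If all ratios coincide the common value is returned.
Median and mode SEs come from a parametric bootstrap (per-variant betas
resampled from their sampling distributions; default 1000 replicates,
seed supplied by the caller and restored afterwards, so identical seeds
give identical SEs to full precision). All reported 95% intervals are
`beta ± 1.96·se` by construction.

## Steiger stratification and exposure re-weighting

A variant's proximal trait is decided by comparing the variance it
explains in each: correlations are Fisher-transformed and compared by
`z = (atanh r₁ − atanh r₂)/sqrt(1/(n₁−3) + 1/(n₂−3))`. The default
stratification policy is the *point* rule — strict r² comparison, which
is the definition the workflow is built around — with a
significance-gated variant (`policy = "significant"`) available because
the underlying test is a Z test; exact ties are excluded rather than
arbitrarily assigned, so the point-rule strata always partition the
non-tied variants. `reweight_exposure()` swaps the primary and second
exposure columns, so "the consumption estimate scaled by the biomarker"
is literally the IVW of the same variants after the swap; the swap is an
involution.

## Multivariable MR by Q minimization

The two-exposure objective
`Q(β₁,β₂) = Σⱼ (β̂ᵧⱼ − β₁β̂ₓⱼ − β₂β̂ₓ₂ⱼ)² / (seᵧⱼ² + β₁²seₓⱼ² + β₂²seₓ₂ⱼ²)`
propagates exposure-side sampling error through its denominator, which is
what protects the minimizer against conditionally weak instruments. The
minimizer is found by Nelder-Mead (relative tolerance 1e-14, up to 2000
iterations) started from per-exposure IVW slopes plus four
coordinate-perturbed restarts, keeping the best minimum; the descent
property (final Q never above Q at the initialization) is tested. An
exhaustive lattice search (step 1e-3) serves as the independent oracle on
small instances. Exposure–exposure sampling covariance is taken as zero:
the two exposure GWASs come from different cohorts in the intended use.

Profile confidence intervals are the default: the 95% bound for one
coordinate is where the profile Q (minimized over the other coordinate by
golden-section search on an interval expanded until the minimum is
interior) crosses `q_min + qchisq(0.95, 1)`; the crossing is located by
outward stepping and bisection until the profile Q is within 1e-5 of the
target. A percentile parametric bootstrap is provided as the alternative
— the asymmetry of profile intervals is one plausible reading of
published MVMR intervals whose bounds are not symmetric about the point
estimate, and having both makes the choice explicit.

## Two-way fixed effects

The consumption index is built per visit: z-score coffee cups and tea
cups separately across the individuals observed at that visit (sample
SD), sum, and re-standardize within visit. A row missing one beverage
falls back to the other (counted and reported); a beverage with zero
variance at a visit is an error naming the visit. The combination rule
("sum then re-standardize", within-visit) is one of two defensible
readings of a combined standardized measure; the mean variant and global
re-standardization are exposed as options so the choice is explicit
rather than silent.

`twfe()` estimates the exposure coefficient under additive individual
and visit effects by alternating demeaning over the two factors, iterated
until the slope changes by less than 1e-10 (error after 10,000 sweeps);
this handles unbalanced panels naturally. The variance is two-way
cluster-robust by inclusion–exclusion: individual-clustered plus
visit-clustered minus intersection-clustered sandwich variances on the
demeaned regression. Each one-way component carries the small-sample
correction `G/(G−1) · (N−1)/(N−k)` with `k` the dummy-variable model
dimension (slope, intercept and absorbed effects); when the
inclusion–exclusion combination turns non-positive the variance is
clamped to the individual-clustered component with a warning. When a
clustering dimension is fully degenerate (singleton clusters), the
combination collapses exactly to the other one-way variance.

## The synthetic generator

`sim_config()` encodes the causal architecture as a linear-Gaussian
structural model over genotypes `g ~ Binomial(2, maf)`:

```
L = Σ c_j g_j + ε_L                    latent lifestyle
D = λ_L L − λ_M Σ a_j g_j + ε_D        consumption (titration feedback)
P = π_D D + Σ a_j g_j + ε_P            plasma biomarker
B = θ_P P + θ_L L + θ_S D + ε_B        outcome
```

A linear model was chosen over an explicit pharmacokinetic titration
model because it reproduces every qualitative signature of interest —
the consumption/biomarker sign flip, the Steiger split, the MVMR direct
effect — while keeping all reduced forms analytically checkable: a
metabolism variant's effect on consumption is `−λ_M a_j` and on the
biomarker `a_j (1 − π_D λ_M)` (opposite signs whenever
`π_D λ_M < 1`, the stability condition enforced at construction).
`ground_truth()` returns these reduced forms, the implied phenotype
SDs, the standardized causal parameters, and per-variant Steiger labels.

Default calibration (chosen once, from the closed forms):

* 16 metabolism + 8 behavioral variants — the instrument count and
  mechanism split the workflow is designed around.
* Allele effects specified per genotype SD (`a_scale = 0.075`,
  `c_scale = 0.094` with `λ_L = 0.4`), so every variant's association
  with consumption has a noncentrality around 70 at the default cohort
  size and passes `p < 5e-7` with high probability — instruments are
  deliberately strong, matching settings where instrument F statistics
  sit far above conventional weak-instrument thresholds.
* `λ_M = 0.5`, `π_D = 0.25`: metabolism variants explain about three
  times as much variance in the biomarker as in consumption, a clear but
  not degenerate Steiger separation.
* `θ_P = −0.15` (biomarker lowers the outcome), `θ_L = 0.6` (lifestyle
  pleiotropy raises it), `θ_S = 0.075` (a direct consumption path of
  half the biomarker magnitude).
* Noise SDs set so all phenotypes have unit variance, making raw and
  SD-unit effects interchangeable at the defaults.
* Three GWAS cohorts of 50,000 — large enough that estimator biases, not
  sampling noise, dominate the validation, small enough that hundreds of
  replicates run in minutes. The panel defaults to 1,000 individuals
  over 4 visits with later-visit attendance below 1 (an unbalanced
  design), confounding `ρ = 0.5` between the individual effect and the
  consumption propensity, and a true index effect of −0.1.

Variants are simulated in linkage equilibrium (the emitted LD matrix is
exactly the identity); an optional block mode induces within-block LD
through a Gaussian copula purely to exercise clumping — the realized
genotype r² is attenuated relative to the latent correlation, which is
expected threshold-model behavior. Phenotypes are standardized within
cohort before scanning, so summary statistics are in SD units; per-SNP
p-values use the t distribution.

### An identifiability point

With a nonzero direct consumption effect `θ_S`, the biomarker-weighted
IVW on the metabolism stratum converges to
`θ_P − θ_S λ_M/(1 − π_D λ_M)`, not to `θ_P`: the direct path travels
with the instruments and cannot be separated by re-weighting alone.
Exact recovery of `θ_P` by this estimator is therefore assessed in the
identified case `θ_S = 0`, while the multivariable analysis — whose job
is precisely to detect `θ_S` — is assessed at the default
`θ_S = |θ_P|/2`. This mirrors the substantive point of the workflow:
re-weighting corrects exposure misidentification, but only MVMR speaks
to exclusion-restriction violations.

### What the generator does not emulate

Real allele-frequency spectra, realistic LD structure, effect-size
distributions, assortative mating, population stratification, dynastic
effects, selection into the cohort, or feedback of the outcome on
consumption. Passing the validation therefore shows that the estimators
are correct under the stated structural model, not that the assumptions
hold in any particular real data set; the known threats listed above are
exactly the ones the real workflow cannot rule out either.

## Validation design

The test suite validates every estimator against an independent oracle
(closed-form arithmetic, `lm` fits, exhaustive grid search, dense-grid
kernel densities) and then runs replicated end-to-end checks on the
generator: the consumption/biomarker sign flip on the metabolism stratum
(100 replicates), recovery of the standardized biomarker effect (200),
Steiger label accuracy (50), MVMR direct-effect detection (200) and null
calibration (300), and TWFE versus pooled OLS under confounding (200).
`scripts/acceptance.R` recomputes all of these from scratch with every
random stream derived from a single `--seed`.

## Limitations

Two exposures only in MVMR (no MVMR-Egger); no MR-PRESSO or
contamination-mixture estimators; no distance-based clumping or
reference-panel management; no VCF input or liftover; the TWFE estimator
fits a static two-way model without event-study dynamics. These are
boundaries of the implemented workflow, not oversights.
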