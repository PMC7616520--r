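# targetmr

Drug-target Mendelian randomization (MR) with behavioral and biomarker
exposures.

## The scientific problem

Drug-target MR estimates the effect of perturbing a pharmacological target
by instrumenting a biomarker of target engagement with genetic variants.
When the biomarker is expensive to measure, a tempting substitute is a
*behavioral proxy* — for caffeine, the self-reported number of cups of
coffee or tea per day instead of fasting plasma caffeine. The two choices
can give *opposite* answers with the very same variants. The reason is a
titration feedback: variants that speed up caffeine metabolism lower
circulating caffeine, so carriers drink **more** to obtain the same
physiological effect. A metabolism allele therefore raises the biomarker
while lowering consumption, and an MR estimate "weighted" by consumption
flips sign relative to one weighted by the biomarker. On top of that,
variants that truly act on drinking behavior tend to do so through latent
lifestyle traits that also affect downstream outcomes — classic exclusion-
restriction violations.

`targetmr` implements the complete workflow for diagnosing and resolving
this contrast:

* **Instrument handling** — summary-statistic input with configurable
  column maps, allele harmonization (strand complements, palindromic SNP
  policies, full drop-logs), p-value selection, greedy LD clumping, and
  instrument-strength statistics (per-SNP r², joint F).
* **Univariable estimators** — for harmonized per-SNP effects
  (β̂ₓⱼ, β̂ᵧⱼ), the IVW estimate is
  β̂ = Σⱼ wⱼ(β̂ᵧⱼ/β̂ₓⱼ) / Σⱼ wⱼ with wⱼ = β̂ₓⱼ²/se(β̂ᵧⱼ)², plus MR-Egger,
  weighted median, and weighted/simple mode.
* **Mechanism stratification** — per-SNP Steiger directionality tests
  (Fisher-transformed r² comparison) split instruments into
  biomarker-proximal ("metabolism") and behavior-proximal strata, and
  `reweight_exposure()` re-expresses a stratum's estimate per SD of the
  alternative exposure.
* **Multivariable MR** — direct effects of consumption and the biomarker
  by minimizing the heterogeneity statistic
  Q(β₁,β₂) = Σⱼ (β̂ᵧⱼ − β₁β̂ₓⱼ − β₂β̂ₓ₂ⱼ)² / (seᵧⱼ² + β₁²seₓⱼ² + β₂²seₓ₂ⱼ²),
  with profile or bootstrap confidence intervals (MVMR-Qhet).
* **Triangulation** — a two-way fixed-effects (TWFE) panel estimator with
  two-way cluster-robust standard errors, including the visit-wise
  standardization that builds a combined consumption index from coffee
  and tea cups.
* **A structural simulator** — `sim_config()` encodes the full causal
  architecture (titration feedback, lifestyle pleiotropy, direct
  consumption effects) with closed-form ground truth for every reduced-
  form effect, so every estimator can be validated against analytic
  truth.

## Worked example

```r
library(targetmr)

report <- run_workflow_synthetic(sim_config(), seed = 7)
print(report)
```

```
Drug-target MR workflow report
  instruments: 24 (p < 5e-07, clump r2 <= 0.001); strata: 8 behavior / 16 metabolism (0 excluded)
            analysis    exposure     outcome method    f_stat n_snp                estimate
      genome-wide MR consumption     outcome    IVW  76.29842    24    0.667 (0.433, 0.902)
biologically-motivated MR biomarker  outcome    IVW 202.71378     2 -0.186 (-0.318, -0.054)
                TWFE consumption index   bmi   TWFE        NA    NA -0.104 (-0.147, -0.061)
  metabolism stratum consumption     outcome    IVW  78.44338    16    0.296 (0.229, 0.362)
  metabolism stratum   biomarker     outcome    IVW 218.10739    16 -0.180 (-0.222, -0.137)
  metabolism stratum   biomarker consumption    IVW 218.10739    16 -0.608 (-0.648, -0.568)
    behavior stratum consumption     outcome    IVW  68.55091     8    1.506 (1.405, 1.607)
    ...
```

Reading the rows: the genome-wide consumption-weighted estimate is
**positive** (+0.67 SD outcome per SD consumption) while the
biologically-motivated biomarker estimate is **negative** (−0.19), and
TWFE sides with the biomarker (−0.10). Steiger filtering assigns 16 of
the 24 instruments to the metabolism stratum; on that stratum the
consumption weighting stays positive (+0.30) but re-weighting the same
SNPs by the biomarker flips the sign (−0.18), and the biomarker→
consumption estimate (−0.61) exposes the titration feedback directly.
The multivariable Q-minimization additionally finds a positive direct
consumption effect, i.e. the behavioral instruments violate the
exclusion restriction for a plasma-caffeine target question.

Individual estimators work on any harmonized set:

```r
trio <- simulate_gwas_trio(sim_config(), seed = 7)
hs <- harmonize(trio$consumption, trio$outcome)
mr_ivw(hs)
mr_egger(hs)
mr_weighted_median(hs, n_boot = 1000, seed = 1)
```

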