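---
title: "Methods: longitudinal variant screening for post-exercise hypotension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal variant screening for post-exercise hypotension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pehgene)
```

## The phenotype

Post-exercise hypotension (PEH) is the sustained reduction in blood pressure
that follows a single bout of aerobic exercise. The phenotype modelled here
is the *hourly BP response*: for each subject, exercise intensity
(MODERATE or VIGOROUS) and phenotype (SBP or DBP),

\[ r_{it} = (E_{it} - \bar E_i^{base}) - (C_{it} - \bar C_i^{base}), \qquad t = 1, \dots, 19, \]

the change from pre-experiment baseline under ambulatory monitoring after
exercise, minus the same change after a seated-rest control session.
Differencing against the subject's own control removes any stable
subject-level BP shift — the reason a shared subject effect in the synthetic
generator cancels from the phenotype by construction.

Reading-level processing (`qc_filter()`, `hourly_bin()`, `baseline_mean()`,
`bp_response()`) follows the ambulatory-device conventions: readings with
SBP above 220 or below 80 mmHg, or DBP above 130 or below 40 mmHg, are
excluded (strict inequalities; boundary values retained); a report is
acceptable when at least 80% of the potential readings — three per waking
hour, two per sleeping hour — were obtained, compared as an exact fraction.
Two conventions the device literature leaves open are fixed here and
documented: hour $h$ spans elapsed minutes $[60(h-1), 60h)$ (half-open, so
a reading at exactly 60 minutes belongs to hour 2), and hours with no
retained readings propagate as missing rather than zero (the screening
model then simply uses each subject's available hours — an unbalanced
design, with no imputation). The ambulatory arterial stiffness index
(`aasi()`) is one minus the OLS slope of DBP on SBP across the retained
readings of a monitoring period; readings, not hourly means, enter the
regression (the aggregation level is switchable), and values outside
$[0, 1]$ warn rather than error.

## The screening model

Stage 1 fits, per variant, ethnic stratum, phenotype and intensity, the
generalized least squares model

\[ r_{it} = \beta_0 + \beta_1 t + \beta_2 t^2 + \beta_3 t^3 + \gamma_0 g_i + \gamma_1 g_i t + \gamma_2 g_i t^2 + \gamma_3 g_i t^3 + \varepsilon_{it}, \]

with $g_i$ the minor-allele dosage (additive coding, oriented so the
whole-cohort minor-allele frequency is at most 0.5; frequency ties keep the
ALT allele as minor) and within-subject errors AR(1):
$\mathrm{cor}(\varepsilon_{is}, \varepsilon_{it}) = \rho^{|s-t|}$ on the hour
index, independent across subjects. Missing hours contribute $\rho^{gap}$.
The engine (`fit_gls()`) profiles the likelihood over $\rho$: at each
candidate $\rho$ the coefficients and residual variance have closed forms
after whitening each subject block by the inverse Cholesky factor of its
correlation matrix, so the optimisation is one-dimensional (grid bracketing,
Brent search to tolerance $10^{-9}$, then a few Newton steps on a
central-difference score to pin the optimum near machine precision —
Brent alone is limited to about $\sqrt{\epsilon}$). $\rho$ is searched in
$(-0.999, 0.999)$ (compound symmetry: bounded below by $-1/(k_{max}-1)$ for
positive definiteness). Blocks sharing an hour pattern share one
factorisation per likelihood evaluation.

The variant p-value is the joint test of the four SNP terms: by default a
4-df likelihood-ratio test against the time-only model (both ML), with a
Wald F on residual degrees of freedom ($N_{obs}$ minus mean parameters) as
the alternative — the latter is what the power simulation uses, matching
the residual-df convention. For ML fits the Wald covariance is rescaled to
the unbiased residual variance $rss/(N-p)$, the classical convention implied
by $t/F$ references on $N-p$ degrees of freedom. Variants monomorphic
within a stratum are skipped; if a lone carrier observed at too few hours
makes the SNP-by-time columns singular, the model falls back to the SNP
main effect only and the record is flagged.

Multiple testing corrects over the number $m$ of *unique genotype profiles*
in the stratum: variants with identical dosage vectors over the stratum's
subjects are tested once (the group p-value is copied to every member), and
monomorphic profiles do not count. Bonferroni ($\min(1, pm)$) and
Benjamini–Yekutieli (step-up with the $\sum_{k \le m} 1/k$ dependence
factor, via `stats::p.adjust`) adjusted p-values are both computed; a
variant is a hit when the Bonferroni value is below 0.05 *or* the BY value
is below 0.25 (strict). The adjustment family is one stratum by phenotype
by intensity; phenotypes are not pooled, since the correction the analysis
defines is per-stratum profile count.

## Final models and variance explained

For each hit, stage 2 (`select_model()`) builds a multivariable model:

1. *Eligibility*: each candidate covariate (age, gender, BMI, log AASI,
   orientation 19-h SBP, log triglycerides, log endothelin, log insulin) is
   tested alone under the AR(1) ML model; marginal association at p < 0.05
   makes it eligible. Natural logs are applied before centering; all
   covariates are centered at the stratum sample mean (the polymorphism is
   not centered). Gender is coded 0/1 (configurable; the coding convention
   is not dictated by the data).
2. *Forward AIC selection* over eligible covariates and the order of the
   time polynomial (powers entered sequentially, order 0–3), by ML. AIC
   ties within $10^{-6}$ prefer the smaller model, then the earlier
   candidate in a fixed order — selection is deterministic.
3. *Genetic coding* (additive #MA vs dominant carrier indicator) and
   SNP-by-time interactions (only with the selected time powers) are chosen
   by ML AIC; the interactions enter only when they win.
4. *Correlation structure* among independence, compound symmetry and AR(1),
   by ML AIC at the selected mean model.
5. Reported estimates come from a REML refit; the variant's p-value is the
   joint ML likelihood-ratio test of its terms against the covariate-only
   model.

Variance explained uses the likelihood-ratio pseudo-R²
$R^2_m = 1 - (L_R/L_U)^{2/n}$ with $L_R$ the intercept-only ML likelihood,
$L_U$ the model's ML likelihood and $n$ the number of subjects. The
intercept-only restricted model keeps the same correlation structure and
estimation method, so the ratio contrasts mean models only. The partial PVE
of a variant is $R^2_m(\text{full}) - R^2_m(\text{covariates only})$; all
PVE quantities use ML likelihoods (REML likelihoods are not comparable
across mean models).

## Power by simulation

`estimate_power()` reproduces the screening test's detection probability:
each simulated dataset draws genotype classes from the observed class
proportions (or Hardy–Weinberg proportions from a MAF), simulates 19 hourly
responses per subject from the screening-model mean structure with AR(1)
errors, refits the screening model, and applies the joint Wald F on
residual df at $\alpha$ (default $0.05/300$, the Bonferroni level for 300
unique profiles). Power is the significant fraction among converged
simulations; monomorphic genotype draws are redrawn up to 100 times and
then counted as non-converged, with the count disclosed alongside the
Monte-Carlo standard error. Covariates are not simulated — only the
time-and-genotype structure of the screening model, which is also what the
test statistic sees.

## The synthetic cohort generator

`simulate_cohort()` produces complete study inputs: reading-level
ambulatory records for CONTROL, MODERATE and VIGOROUS (plus 20-minute
baselines at one reading per 2 minutes), a VCF of biallelic genotypes, and
a covariate table. Defaults mirror the study population this pipeline
targets: two ethnic strata of 14 and 9 subjects; covariate means and SDs
from the cohort description (hypertensive, obese, middle-aged adults);
a variant panel with per-stratum genotype counts matching the published
group sizes (positions and alleles synthetic). Skewed positive covariates
(AASI, insulin, triglycerides, endothelin) are drawn log-normally with
matched moments, the rest normally; HOMA-IR (`glucose * insulin / 405`) and
Friedewald LDL (`TC - HDL - TG/5`, invalid at TG >= 400 mg/dL) are derived,
with their constants from the standard definitions of those indices.

The hourly response of subject $i$ at hour $t$ is the configured genetic
effect (per-minor-allele shift, optionally cubic in time, per intensity)
plus AR(1) noise with parameters `rho` and `sigma_hour`; the noise is split
between the exercise and control series so the differenced phenotype has
exactly the configured AR(1) structure. A subject-level shift (`subject_sd`)
enters every condition and cancels in the difference. Reading-level records
add measurement noise (`sigma_reading`), a configurable fraction of QC-bound
violations (`outlier_rate`) and missing readings (`missing_rate`).

Values not derivable from the cohort description were fixed once at
plausible magnitudes for hourly ambulatory BP: `rho = 0.6` (hour-to-hour
tracking of BP responses), `sigma_hour = 10` mmHg (consistent with the
published 19-h-mean response SDs of roughly 8–19 mmHg), `sigma_reading = 8`
mmHg (oscillometric single-reading error), `subject_sd = 8` mmHg,
16 awake + 3 asleep hours for a 19-h wear ending at waking, 5% missing
readings and 2% QC outliers.

### What the generator does and does not emulate

It reproduces the monitoring schedule, QC-relevant artefacts, the AR(1)
response structure, Hardy–Weinberg or fixed-count genotypes, and covariate
marginals. It does not emulate circadian physiology beyond a fixed
sleep-dip profile (which cancels in differencing), BP-informative missing
data, linkage disequilibrium between variants, or assay error in
covariates. Passing tests therefore demonstrate that the pipeline recovers
truth under its own assumptions plus realistic measurement artefacts — not
that those assumptions hold in any particular real cohort.

## Calibration regimes, and two findings worth knowing

Two properties discovered while validating the pipeline shape how the
calibration tests are designed; both are properties of the method, not of
the implementation (with the correlation parameter fixed at truth, the
screening F test is exactly calibrated in simulation).

*Measurement remnant.* Averaging three readings per hour and subtracting a
20-minute baseline mean leaves a small per-subject constant variance
component in the response (about $2\sigma_{reading}^2/10$, i.e. ~13 mmHg²
at the default reading noise). The screening model — like the analysis it
implements — represents within-subject correlation as AR(1) only, so
between-subject terms such as the genotype are tested against a slightly
understated variance, independent of sample size. Null-calibration tests
therefore simulate at the hourly-response level (`sigma_reading = 0`),
where the generated null matches the model's error structure; the remnant
is a documented limitation for real data.

*Small-sample anticonservatism.* The residual-df Wald and likelihood-ratio
tests are asymptotic in the information available for $\rho$; at very small
subject counts (the motivating study had 14 per stratum) the empirical size
at $\alpha = 0.05$ runs modestly above nominal, shrinking toward nominal as
subjects are added. Calibration tests therefore use 100-subject cohorts;
inference at n = 14 should lean on the conservative Bonferroni/BY
thresholds rather than nominal test size. Effect-size *recovery* tests, by
contrast, run under the full reading-level defaults (noise, outliers,
missingness) at 200 subjects with 50 replicates per effect, using
carrier-only variants for large effects: at −30 mmHg per allele a
homozygote's systolic readings would sit at the device's 80 mmHg exclusion
floor, and the resulting truncation is a property of the QC rule, not of
the estimator.

## Problem sizes used by the test suite

Worked examples and algebraic identities run on fixtures in well under a
second. The stochastic checks use: 1000 null screening p-values from 50
fresh 100-subject cohorts (uniformity); 100 null 100-subject cohorts of 15
variants (family-wise error); 50 replicates of 200 subjects at each of
−10/−20/−30 mmHg (recovery); 25 replicates of 100 subjects at
$\rho \in \{0.3, 0.6, 0.8\}$ (correlation recovery); 2000 simulations for
the null rejection rate and 250 per point for power monotonicity.

## Known limitations

- Complete-case handling per variant; no dosage imputation.
- No linkage-disequilibrium-aware effective-test count beyond profile
  collapsing; no cross-stratum meta-analysis.
- The final-model search is greedy forward AIC, not exhaustive; with few
  subjects and many eligible covariates it can overfit, as any
  small-sample multivariable selection can.
- Dominant recoding is implemented as the carrier indicator; a recessive
  recode exists behind the same interface but is not part of the default
  search.
- The time polynomial is left uncentered (raw hours 1..19), so its
  coefficients are correlated; this affects interpretability of individual
  time terms, not the fits.

## A short example

```{r example, eval = TRUE}
cfg <- cohort_config(
  effect_map = list(list(variant = "rs867225", sbp = -15, dbp = -9,
                         intensity = "VIGOROUS")),
  seed = 42)
co <- simulate_cohort(cfg)
ph <- compute_responses(co$readings, intensities = "VIGOROUS")
scr <- screen_variants(ph$responses, ph$mean_19h, co$genotypes$dosages,
                       co$strata, phenotypes = "SBP",
                       intensities = "VIGOROUS")
scr[order(scr$p_raw), c("variant_id", "stratum", "p_raw", "p_bonferroni",
                        "p_by", "effect_extreme")][1:3, ]
```
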