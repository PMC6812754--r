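---
title: "Sex-stratified Mendelian randomization with genetic risk scores: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-stratified Mendelian randomization with genetic risk scores: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexmr)
```

## The question the package addresses

Observational associations between obesity traits (BMI, waist-hip ratio) and
disease are confounded by lifestyle, socioeconomic position, and reverse
causation. Mendelian randomization (MR) sidesteps this by using genetic
variants as instrumental variables: alleles are assigned at conception,
before any confounder can act. `sexmr` implements the full sex-stratified
form of this design — separate instruments, separate exposures, separate
causal estimates for women and men, and a formal test of whether the two
sexes' causal effects differ.

The core statistical objects are:

* a **genetic risk score (GRS)** $S_i = \sum_j w_j d_{ij}$, the weighted sum
  of trait-increasing allele dosages over a pruned, quality-controlled
  variant set, with sex-specific weights $w_j = |\hat\beta_j^{(sex)}|$;
* the **Wald ratio** $\hat\theta = \hat\beta_{GY} / \hat\beta_{GX}$, where
  $\hat\beta_{GY}$ is the GRS-outcome regression coefficient (log-odds for
  diseases) and $\hat\beta_{GX}$ the GRS-exposure coefficient, with the
  two-term delta-method variance
  $\mathrm{se}^2 = \mathrm{se}_{GY}^2/\hat\beta_{GX}^2 +
  \hat\beta_{GY}^2\,\mathrm{se}_{GX}^2/\hat\beta_{GX}^4$;
* summary-data estimators for outcomes with no individual-level data:
  inverse-variance weighting of per-SNP ratios, MR-Egger regression (whose
  intercept estimates average directional pleiotropy), and the weighted
  median;
* **Cochran's Q** across the two sexes,
  $Q = \sum_s w_s(\hat\theta_s - \hat\theta_{pooled})^2$ with
  $w_s = 1/\mathrm{se}_s^2$, referred to $\chi^2_1$.

All estimates are expressed per 1 SD of the exposure so that traits and
strata are comparable, and every screening step uses Bonferroni-corrected
families (0.05/51 for trait-disease combinations, 0.05/15 for risk factors,
0.05/48 for sex comparisons of disease estimates, 0.05/21 for instrument
comparisons) — the exact ratios are used for decisions, the
one-significant-figure forms for reporting.

## Pipeline structure and conventions

The pipeline (`run_pipeline()`) mirrors the standard workflow:

1. **Variant QC** (`qc_filter_variants`): keep imputation info score > 0.3,
   minor allele frequency >= 0.01%, Hardy-Weinberg p >= 1e-6 (when a
   per-variant HWE column is supplied; the test itself belongs to upstream
   genotype QC), missing call rate <= 0.05, biallelic only. Each exclusion
   is logged with exactly one reason, the first failing rule in that order,
   so flowchart-style accounting can be reconstructed from the log.
2. **Window pruning** (`merge_and_window_prune`): the union of the women,
   men, and combined-sexes index lists is pruned so that only the variant
   with the lowest combined-sexes p-value survives within 1 Mb. "Sliding
   window" is ambiguous between greedy exclusion radii and fixed tiling; we
   implement the greedy form (visit variants by ascending combined p, retain
   unless a retained variant sits within the radius on the same chromosome)
   because it directly expresses "keep the SNP with the lowest combined
   p-value", and it is the variant whose output is characterized by a simple
   fixed-point property that the tests verify independently.
3. **LD pruning** (`ld_prune`): among listed pairs with r² > 0.05, the
   member with the larger combined p is dropped, iterating to a fixpoint;
   ties drop the larger position, for determinism. One variant is removed
   per iteration (the worst offender), which resolves chains A–B–C the way a
   manual curation would: the middle variant goes, its partners stay.
4. **Orientation and weighting** (`orient_to_trait_increasing`,
   `build_instrument`): every variant is flipped so the effect allele raises
   the trait in the weighting stratum; flipping negates all three strata's
   betas together and complements the allele frequency, so a single stored
   polarity serves all strata. Weights are the stratum's absolute effect
   sizes (sex-specific for the sex-stratified scores), 1 for unweighted
   sensitivity scores, or re-oriented external estimates.
5. **Scoring** (`score_individuals`): the sum-of-weighted-dosages
   convention; missing dosages are mean-imputed with twice the effect-allele
   frequency, so scores are defined for all individuals and the score's
   expectation is unchanged. Dosages stored for the opposite allele enter as
   $2 - d$; the tests verify that stored polarity cannot change any
   downstream association coefficient.
6. **Phenotype preparation** (`adjust_blood_pressure`, `residualize_rint`,
   `derive_smoking_status`, `resolve_outcome`): +15/+10 mmHg is added to
   measured SBP/DBP of medicated individuals; traits are residualized on
   age, age², assessment centre (plus sex in combined-sexes runs, plus BMI
   for BMI-adjusted traits) and rank inverse-normal transformed.
7. **Screening and MR** (`fit_linear`, `fit_logistic`, `screen_for_mr`,
   `individual_level_mr`): GRS-outcome regressions adjusted for age, age²,
   array, centre, 10 PCs, and sex where applicable (array and PCs only for
   already-transformed traits); combinations passing their family threshold
   go to MR, with a hit in either sex escalating to both sexes so
   heterogeneity can always be assessed, and smoking-status MRs always run.
   For binary outcomes, the GRS-exposure regression uses controls only, so
   the exposure arm of the ratio is not distorted by case status.
8. **Heterogeneity** (`cochran_q`, `compare_sexes`): computed on the
   log-odds scale — the only scale on which normal approximations and
   printed CIs cohere — for both regression and MR estimates, with the same
   kernel.

### Numerical conventions

* RINT uses the rankit offset $\Phi^{-1}((r - 0.5)/n)$ with average ranks
  for ties: symmetric, standard in GWAS practice, and deterministic for
  discrete traits.
* The 95% z-quantile is fixed at 1.959964 for bit-stable intervals; p-values
  are two-sided normal for logistic and ratio estimates, two-sided t for
  linear fits.
* Logistic fits run IRLS to a relative deviance change below 1e-10 (at most
  100 iterations); quasi-complete separation is flagged, not penalized —
  failures should be visible, not silently repaired.
* Collinear covariate columns are dropped by pivoted QR and logged; a score
  collinear with the covariates is an error, because the association of
  record would otherwise be undefined.
* The weighted median interpolates the sorted ratios at cumulative weight
  0.5 (midpoint convention); a single SNP carrying more than half the
  weight returns its own ratio, the estimator's defining majority-valid
  property. Its SE is a parametric bootstrap (default 1000 resamples, fixed
  seed); the original publication's procedure, made deterministic.
* MR-Egger re-orients SNPs to non-negative exposure effects (required for
  its identifying assumption) and uses multiplicative random-effects
  standard errors with the residual dispersion floored at 1.
* The Wald SE keeps exactly the first two delta-method terms and omits the
  covariance cross-term: the exposure regression runs on controls only, so
  the two coefficients come from (partially) disjoint samples.

## What the synthetic cohort emulates — and what it does not

Real individual-level biobank genotypes and the external glycemic summary
statistics are access-restricted, so the package ships a generator
(`make_variant_panel`, `simulate_genotypes`, `simulate_cohort`,
`emit_sumstats`, `simulate_snp_triples`) whose ground truth makes every
downstream stage testable.

The generating model: biallelic variants in Hardy-Weinberg equilibrium with
independent dosages; per-allele exposure effects drawn bivariate-normal
across the sexes (correlation 0.8 by default — sex-specific but strongly
shared genetics); a standard-normal unobserved confounder loading on both
exposure and outcome; a latent exposure centred and scaled to SD 1 so the
causal parameters are exactly per-SD; a binary disease through a logistic
link with sex-specific causal effects; a binary smoking mediator whose
propensity rises with the exposure; SBP/DBP with a deterministic medication
rule (true SBP above 160 mmHg is treated, and measured values carry the
-15/-10 mmHg treatment effect so the downstream correction recovers the
pre-treatment values exactly); and optional per-variant direct effects on
the outcome (pleiotropy), drawn with a configurable mean (directional) or
mean zero (balanced).

Default conditions, chosen once as a realistic desk-scale regime: causal
effects 0.6 (women) and 0.3 (men) log-odds per SD; confounder loadings 0.5
on each side; baseline disease log-odds -1.5 (prevalence near 20%, giving
informative case counts at n in the tens of thousands); per-SNP effect SD
0.07 with 100 variants, yielding instrument R² around 0.15-0.20 — stronger
than a real single-trait GRS (2-7% in biobank data) precisely so that
recovery and heterogeneity tests are informative at n = 50,000 rather than
n = 400,000; residual exposure SD 0.8; smoking mediation disabled by
default (`beta_smoking_y = 0`) so the default model satisfies the MR
identifying assumptions and the causal parameter is cleanly recoverable.

Deliberately not emulated: linkage disequilibrium (variants are spaced >= 2
Mb and independent; LD enters only through the explicit pair table, keeping
the simulator analytically tractable), imputation uncertainty, relatedness,
population structure, age-varying effects, and the ICD-based case
adjudication that produces the case/control/excluded labels (the labels are
inputs here). Passing tests therefore demonstrate the statistical machinery
under clean identifying assumptions; they do not certify robustness to LD
misspecification or phenotype misclassification in real data.

One systematic gap is intentional and documented rather than removed:
because the disease is generated through a logistic link, marginalizing
over the exposure's non-genetic variation makes the estimable log-odds
effect slightly smaller than the generating parameter (non-collapsibility).
At the default conditions the attenuation is about 5-8% of the effect for
the larger (women's) parameter. Recovery checks therefore compare the mean
estimate across replicates to truth within three estimated standard errors
instead of asserting bias-free recovery per replicate, and the same
attenuation acts on both sexes so the heterogeneity tests are essentially
unaffected.

## Problem sizes used by the validation suites

The test and acceptance runs use: 50 replicates at n = 50,000 and 100
variants for sex-specific recovery and heterogeneity power; 1000 replicates
at n = 5,000 and 30 variants (minimal covariates) for type-I calibration of
the sex comparison; 20 replicates at n = 50,000 for confounding immunity;
50 replicates at n = 20,000 for mediation attenuation; and 200 summary-level
replicates for two-sample estimator coverage. These sizes were chosen so
each property is measured with useful Monte-Carlo precision while the whole
suite completes in minutes on one core.

## Worked example

The heterogeneity kernel can be pointed directly at published results. For
the effect of BMI on type 2 diabetes, the published sex-specific estimates
are OR 3.77 (95% CI 3.38-4.20) in women and OR 2.79 (2.58-3.03) in men:

```{r worked-example}
se_w <- se_from_ci(3.38, 4.20)
se_m <- se_from_ci(2.58, 3.03)
h <- cochran_q(c(log(3.77), log(2.79)), c(se_w, se_m))
h
```

The recomputed p-value (about 1.3e-5) agrees with the published 1.4e-5 up to
the rounding of the printed confidence limits.

## Known limitations

* The window pruning implements one defensible reading of "1 Mb sliding
  window"; fixed tiling would retain slightly different sets.
* The HWE filter consumes a precomputed per-variant p-value when present;
  the package does not recompute the exact test from genotypes.
* Two-sample harmonization handles allele alignment and palindrome
  ambiguity only; rsID merges, liftover, and unit conversions of external
  files are out of scope.
* Case/control/excluded adjudication, ancestry confirmation, and genotype
  imputation are consumed as inputs, never reimplemented.
* `weighted_median` standard errors require the bootstrap; no analytic
  approximation is provided.
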