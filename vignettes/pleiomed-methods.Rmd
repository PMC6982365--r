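---
title: "Methods: family-based pleiotropy and mediation analysis with pleiomed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based pleiotropy and mediation analysis with pleiomed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiomed)
```

`pleiomed` analyses the joint effect of one biallelic SNP on a panel of
six serum lipids and on type 2 diabetes (T2DM) status in a
family-structured case-control cohort, and decomposes the
genotype-disease effect into direct and lipid-mediated components. This
vignette is the package's own account of the statistical methods, the
synthetic-data generator used to validate them, and the design choices
made where the design was genuinely open.

## 1. Genotype model and QC

The genotype is coded additively, `G` = number of risk-allele copies
(0/1/2), via `code_additive()`; the additive model asserts a linear
per-allele effect on each linear predictor. Hardy-Weinberg equilibrium
is tested with the 1-df Pearson chi-square of observed genotype counts
against `(q²N, 2pqN, p²N)`, where the allele frequency is estimated by
gene counting from the same table (`hwe_test()`). Two deliberate
choices:

* **No continuity correction.** At the cohort sizes this package
  targets (thousands of individuals) the correction is negligible, and
  the uncorrected statistic is what reproduces reference values
  computed from published genotype distributions.
* **Pooled sample by default.** Whether HWE should be checked in
  controls only or in the pooled sample is a perennial ambiguity;
  `pleiomed` computes it on whatever counts it is given, and the
  pipeline reports pooled, controls-only and founders-only P values
  side by side. A monomorphic SNP raises an error rather than
  reporting chi-square 0: the test is undefined, not perfectly passed.

## 2. Association models and percent-change reporting

Lipids are modelled on the natural-log scale:
`ln L = β G + γ'X + ε`, ordinary least squares on complete cases.
The log transform is an inference, not a convention: reporting a
*percent change* per allele is only coherent for a multiplicative
effect, and a log-scale slope is the coefficient for which
`PC = 100·(e^β − 1)` is exact. The raw-scale alternative is retained
behind `log_scale = FALSE` for sensitivity analysis.

Disease models are logistic: Model 1 adjusts for age, sex, smoking,
drinking, hypertension, coronary heart disease and BMI; Model 2 adds
TC, TG, LDL-C and HDL-C as covariates. The same percent-change map is
applied to the log-OR, i.e. `PC = 100·(OR − 1)`. The Wald interval uses
the fixed multiplier 1.96 on the coefficient scale, transformed through
the same map, so `ci_low ≤ pc ≤ ci_high` holds by construction.

**Standard errors.** Although the cohort is family-structured, plain
model-based SEs are the default, with cluster-robust (family) SEs one
flag away (`robust = "family"`, via `sandwich::vcovCL`). With the
default generator settings (family intercept SD 0.12 against residual
SDs around 0.3, mostly two-person families), the design effect on the
genotype coefficient is a few percent — visible in coverage
simulations (see §5) but small; the robust option is the conservative
choice for strongly clustered data.

**Missing data** are handled complete-case per fitted model; Model 2
therefore only loses observations relative to Model 1 if the lipid
covariates themselves are missing. No multiplicity correction is
applied across the six lipids by default.

**Subgroups.** `subgroup_analysis()` dichotomises BMI at 24 kg/m²
(the overweight cutpoint for East Asian populations) or splits on
smoking/drinking, removes the stratifier from the adjustment set, and
refits the supplied model per stratum; empty or degenerate strata are
skipped with a warning rather than aborting.

## 3. Counterfactual mediation

For a designated mediator lipid `M`, two regressions are fitted on the
identical complete-case set:

* mediator: `M = β₀ + β₁G + β₂'X + ε`, `ε ~ N(0, σ²)`, raw mmol/L;
* outcome: `logit P(Y=1) = θ₀ + θ₁G + θ₂M + θc'X`, optionally with a
  `G×M` interaction `θ₃`.

Under the no-interaction closed form with the rare-outcome
approximation, the per-allele natural effects on the OR scale are
`OR^d = exp(θ₁)`, `OR^i = exp(θ₂β₁)`, `OR^t = OR^d·OR^i` (exactly
multiplicative by construction). With interaction, the standard
normal-mediator closed forms are used, conditioning on covariate means
by default. The proportion mediated on the excess-odds scale is

&nbsp;&nbsp;&nbsp;&nbsp;`PM = OR^d (OR^i − 1) / (OR^d OR^i − 1)`.

A variant with `OR^d` in place of `OR^i` in the numerator circulates in
the applied literature. It is internally inconsistent — it does not
vanish when the mediated path is null, and for a direct-dominated
decomposition (direct OR ≈ 1.05, indirect OR ≈ 1.001) it returns ~82%
where the consistent form returns ~3% — so the standard form is the
default and the variant is available as `pm_formula = "as_printed"`
for auditing analyses that used it.

**Mediator scale.** The mediator enters both models in raw mmol/L.
`PM` is invariant to the mediator's units because `θ₂β₁` is
scale-free; the unit choice only affects the interpretation of `θ₂`.

**Confidence intervals** are nonparametric bootstrap percentiles
(`bootstrap_mediation()`), resampling whole families as the exchangeable
unit so within-family correlation survives resampling;
individual-level resampling is available for comparison. Replicates
with degenerate designs (constant genotype, one-class outcome, rank
deficiency, separation) are redrawn up to a retry cap. The delta-method
alternative was not implemented: percentile intervals need no
derivative bookkeeping for the `PM` ratio and behave acceptably at the
package's target sizes.

**The Monte-Carlo oracle.** `mc_counterfactual_oracle()` estimates
`E[Y(a, M(a*))]` directly: it draws covariates from the supplied
sample, draws each counterfactual regime's mediator independently from
its fitted normal law, averages the outcome-model risks, and forms
empirical odds ratios, with delta-method MC standard errors using the
full covariance of the three mean risks. Two regimes of interest:

* *Rare outcome* (prevalence below 1%): the closed forms are valid and
  the oracle agrees within Monte-Carlo error — this is the package's
  correctness check for `natural_effects()`.
* *Common outcome* (prevalence ~0.38, the regime this analysis
  actually inhabits): logistic ORs are not risk ratios and the
  closed-form ORs differ measurably from the oracle's marginal
  contrasts. The package follows the field's convention of reporting
  the closed-form ORs at face value, and ships the oracle so the
  approximation error can be quantified rather than ignored (for the
  default effect sizes it is below 0.05 on the log-OR scale).

## 4. The cohort simulator

`sim_config()` / `simulate_cohort()` generate the kind of cohort the
analysis assumes, with every generating quantity explicit:

* **Families.** Sizes drawn from `{1, 2, 3}` with probabilities
  (0.10, 0.78, 0.12), mean ≈ 2.02 members — matching a design of
  ~5840 individuals in ~2885 families. Two-member families are an
  even mix of full-sib pairs (parents simulated internally for
  transmission, then dropped; `PID`/`MID` = 0) and parent-offspring
  pairs; three-member families are parent-parent-child trios. Founder
  genotypes are binomial(2, p); offspring receive one allele per
  parent by Mendelian transmission, which yields the classical 0.5
  additive-code correlation between first-degree relatives.
* **Covariates** are drawn independently from truncated-normal (age:
  N(57, 10²) ≥ 40; BMI: N(26.2, 4.3²) ≥ 15) and Bernoulli marginals
  (male 0.49, smoker 0.46, drinker 0.35, hypertension 0.70, CHD 0.28)
  chosen to echo a middle-aged northern-Chinese family cohort. No
  covariate correlation matrix is imposed — the marginals are
  reported in descriptive tables, but joint covariate structure is a
  documented non-goal.
* **Lipids.** `ln L = μ₀ + β_g G + c'X + u_f + ε`, with a shared
  family intercept `u_f ~ N(0, 0.12²)` (inducing both within-family
  and between-lipid correlation) and per-lipid residual SDs
  (0.30–0.55 on the log scale, set from the coefficients of variation
  of published lipid summaries). Intercepts are calibrated so the
  marginal raw-scale means match targets (TC 3.18, TG 1.58, LDL-C
  2.29, HDL-C 0.98, Apo-A 1.12, Apo-B 0.77 mmol/L), using the
  lognormal moment correction and first-order covariate centring.
* **Disease.** `logit P(Y=1) = θ₀ + θ_d G + θ_m M + c'X`, with one
  designated mediator lipid at a time (matching the one-mediator
  analysis structure; a multi-mediator generator is deliberately out
  of scope). `θ₀` is calibrated by root-finding on the realized linear
  predictors so expected prevalence equals the target (0.38 by
  default), making the realized prevalence match within binomial
  error at any cohort size.
* **Seeds are mandatory** — `sim_config()` and `make_scenario()`
  refuse to run without one — and a fixed seed yields a bit-identical
  cohort and TSV.

Three scenarios are canned. `paper_like` encodes the magnitudes of the
motivating single-SNP family study: risk-allele frequency 0.34,
per-allele lipid effects from −0.018 (TG) to 0.049 (TC) on the log
scale, direct disease log-OR 0.154 per allele, TC-mediated path
log(1.06) per mmol/L, prevalence 0.38. Its implied decomposition
(available from `simulation_truth()`) is OR^d 1.167, OR^i 1.009,
PM ≈ 6%. `null` zeroes every genotype and mediator effect.
`strong_mediation` routes about half the total effect through TC
(implied PM ≈ 0.53).

**What the simulator does not emulate.** Families are drawn at random:
the proband-initiated ascertainment of real family studies is not
modelled because no quantitative sampling scheme is available, so
recovery results certify the estimators under random sampling, not
robustness to ascertainment. Covariates are mutually independent;
there is no linkage structure, no multi-SNP haplotypes, no
genotype-by-environment interaction in the default generator. Passing
validation on these cohorts shows the estimators are correct for the
assumed data-generating process — not that the process matches any
particular real cohort.

## 5. Validation design and problem sizes

The test suite validates each stage against independent oracles
(brute-force enumeration for sib-pair genotype correlation,
hand-computed chi-squares, the Monte-Carlo potential-outcome oracle)
and then checks frequentist calibration by simulation. The simulation
sizes are the package's chosen trade-off between Monte-Carlo precision
and suite runtime:

* *Effect recovery*: 200 replicates of the full-size `paper_like`
  design (2885 families); per-lipid mean bias below 0.005 on the log
  scale and pooled 95% CI coverage inside [92%, 98%]. The marginal
  disease log-OR is compared against the mediation-consistent total
  effect `θ_d + θ_m β₁` — at these effect sizes logistic
  noncollapsibility attenuates the marginal estimate by well under
  0.001, far inside the tolerance.
* *Type-I error*: 2000 null replicates of ~2000 individuals;
  rejection at α = 0.05 within 5% ± 1.5% for lipid and disease models.
* *Bootstrap calibration*: 500 replicates × 500 bootstrap draws at 400
  families with a reduced (age, sex) adjustment set. The
  mediation-null design keeps the genotype→mediator path active
  (β_g = 0.10) and sets θ_m = 0: the true indirect OR is then 1 and
  percentile intervals should cover it ~95% of the time. At the
  complete double-null (both paths zero) product-of-coefficients
  intervals are *conservative* — coverage approaches 100% because the
  product's sampling distribution degenerates — which is a property
  of the estimand, not an implementation defect; the package's
  calibration check is therefore run at the single-path null where
  nominal coverage is theoretically attainable.
* *HWE calibration*: 2000 binomial cohorts of n = 2000 (test size
  0.05 ± 0.02) and 1000 simulated founder sets of n = 5000 (P > 0.01
  in at least 98%).

## 6. Numerical choices and degenerate inputs

* Null total effects: `proportion_mediated()` declares `PM` undefined
  (with a warning, returning `NA`) when `|log OR^t| ≤ 1e-8` — never a
  silent 0.
* Degenerate designs (constant genotype or mediator, one-class
  outcome, separation detected via the fitted-probability warning)
  raise errors with the offending term named; inside the bootstrap
  they trigger a redraw (cap 25, then error).
* The disease-model intercept calibration solves
  `mean(plogis(θ₀ + lp)) = target` by `uniroot` on [−50, 50] at
  tolerance 1e-10; ties in family-size sampling are avoided by
  drawing sizes by index (`sample.int`), which is well-defined for
  single-size distributions.
* Bootstrap refits use prebuilt design matrices with `.lm.fit` and
  warm-started `glm.fit` (coefficients capped at |50| as a separation
  guard), keeping 500 × 500 bootstrap studies tractable on one CPU.
* JSON outputs are written at full precision (`digits = NA`);
  human-readable TSVs round to the field's reporting convention
  (β to 3 decimals, PC/OR to 2, PM to 1).

## 7. Known limitations

* The OR-scale decomposition inherits the rare-outcome approximation;
  at prevalence 0.38 the reported ORs are conditional logistic ORs,
  not risk ratios, and `PM` should be read as an excess-odds share.
  The oracle quantifies the gap.
* No mixed-effects or kinship-matrix association models: family
  structure is handled by cluster-robust SEs and family-level
  resampling, not by explicit variance components.
* One mediator at a time; joint multi-mediator path decomposition,
  exposure-induced confounding and ascertainment modelling are out of
  scope.
* Descriptive-table comparisons default to unpaired tests; the paired
  variants (paired t, McNemar) require an explicit case-control
  pairing, since no within-family matching rule is imposed by the
  package.
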