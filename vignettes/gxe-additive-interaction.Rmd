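---
title: "Additive gene-environment interaction in frequency-matched case-control studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additive gene-environment interaction in frequency-matched case-control studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxematch)
```

## The design and the scientific question

`gxematch` implements the analysis pipeline of a 1:c frequency-matched
case-control study of gene-environment interaction: obese cases
(BMI >= 28 kg/m^2, the Chinese adult criterion) are contrasted with
normal-weight controls (BMI < 24), with controls frequency-matched to
cases on age band and sex at a 1:2 ratio. The environmental exposure is
a binary urbanization indicator (rural farmer vs rural-to-urban
migrant); the genetic exposures are diallelic SNPs coded as risk-allele
counts and analysed under the four standard inheritance models.

The central quantity is *additive* interaction between a binary
genotype recode G and the environment E. With the joint-indicator
logistic parameterization

$$\operatorname{logit} P(D=1) = \beta_0 + \beta_1 I_{10} + \beta_2 I_{01} +
\beta_3 I_{11} + \gamma^\top Z,$$

the odds-ratio grid is $OR_{10} = e^{\beta_1}$, $OR_{01} = e^{\beta_2}$,
$OR_{11} = e^{\beta_3}$ against the doubly-unexposed reference, and the
three additive-scale measures are

* RERI $= OR_{11} - OR_{10} - OR_{01} + 1$ (0 under additivity),
* AP $= \mathrm{RERI}/OR_{11}$ (proportion of the doubly-exposed risk
  attributable to interaction),
* SI $= (OR_{11}-1)/[(OR_{10}-1)+(OR_{01}-1)]$ (1 under additivity).

These treat the odds ratios as risk-ratio approximations, which is the
conventional usage for a rare-ish outcome in case-control data.
Multiplicative interaction is assessed separately by the Wald test on a
$G \times E$ product term.

## Inference for the interaction measures

Confidence intervals for RERI, AP and SI follow the Hosmer-Lemeshow
delta method: each measure is a smooth function of
$(\beta_1, \beta_2, \beta_3)$, so its variance is $g^\top \Sigma g$
with $g$ the analytic gradient and $\Sigma$ the 3x3 submatrix of the
fitted covariance. RERI and AP get symmetric intervals; SI is handled
on the log scale,
$\ln SI = \ln(e^{\beta_3}-1) - \ln(e^{\beta_1}+e^{\beta_2}-2)$, and the
interval exponentiated, which is why published SI intervals are
asymmetric. The SI interval is undefined, and flagged rather than
extrapolated, when $OR_{11} \le 1$ or $OR_{10}+OR_{01} \le 2$; the
point estimate of SI is undefined only at $OR_{10}+OR_{01} = 2$.

The conventional significance rule is applied to the delta intervals:
additive interaction is declared when the RERI and AP intervals exclude
0 *and* the SI interval excludes 1.

As a cross-check, `bootstrap_ci()` resamples individuals with
replacement *within* case and control strata (the case and control
sample sizes are fixed by the design, so resampling preserves them),
refits the joint model per replicate, and takes percentile intervals.
The default is B = 2000 replicates; replicates with an empty joint
category or a non-convergent fit are dropped and counted, with a
warning above 20% attrition. Whether to resample within strata or from
the pooled sample is a genuinely open choice in this literature; the
stratified variant was chosen because it respects the fixed margins of
a case-control design.

## The logistic engine

`fit_logistic()` is a Newton/IRLS maximum-likelihood fitter with
step-halving, run until the log-likelihood changes by less than 1e-8
(at most 100 iterations). The step-halving guarantees a monotone
log-likelihood trace, which the test suite asserts; the covariance is
the inverse observed information at the optimum, verified against a
finite-difference Hessian and against `stats::glm` in the tests.
Separation is flagged deterministically when any coefficient exceeds 15
on the log-odds scale — joint-exposure cells in this design can be as
small as 3-4 subjects, where separation is a live possibility — and a
flagged fit is never reported as converged. Wald (not likelihood-ratio)
intervals are used throughout, consistent with the delta-method
machinery that consumes the same covariance matrix.

Covariates are dummy-coded against the first listed category of each
factor; age enters as decade-band dummies by default (matching how a
frequency-matched design stratifies age), with continuous age as an
option. A covariate that is constant in the analysed subset is dropped
with a warning rather than silently producing a singular design.

## Sample-size calculation

`required_sample_size()` implements the 1:c matched-design formula with
$p_1 = p_0\,OR/(1+p_0(OR-1))$, $\bar p = (p_1 + c\,p_0)/(1+c)$ and
two-sided $z_\alpha$. Both the pooled-variance form
$(1+1/c)\bar p\bar q(z_\alpha+z_\beta)^2/(p_1-p_0)^2$ and the unpooled
form
$[z_\alpha\sqrt{(1+1/c)\bar p\bar q} + z_\beta\sqrt{p_1q_1+p_0q_0/c}]^2/(p_1-p_0)^2$
are implemented, with the unpooled form as the default: at the
reference parameterization (p0 = 0.2, OR = 2, c = 2, alpha = 0.05,
power = 0.8) the unpooled form gives n1 = 126 where the pooled form
gives 123, and the 126-case requirement is the one consistent with the
published account of this design. `n1` is rounded up before
multiplying by c, in keeping with "minimum sample size" semantics.

## The synthetic cohort generator

Because the individual-level survey data behind this design are not
publicly deposited, every downstream stage is exercised on synthetic
cohorts from `simulate_cohort()`. The generator emulates:

* two residence groups (farmer / migrant) with group-specific
  covariate category distributions (defaults patterned on the control
  distributions of the published characteristics table: farmers less
  educated, lower income, heavier occupational activity);
* two diallelic markers drawn as two independent haplotypes per
  individual, so each marker is in Hardy-Weinberg equilibrium and any
  between-marker dependence comes only from the haplotype frequencies.
  The default haplotype frequencies are independent (no LD) with
  risk-allele frequencies 0.165 and 0.16 — illustrative values, since
  LD between the two markers in the source population is unreported;
* obesity from a logistic model with joint-indicator odds ratios
  `(or_g, or_e, or_ge)` defaulting to (2, 2.5, 10) under recessive
  coding, and a baseline farmer prevalence of 8%;
* the normal/overweight split of non-obese participants (default 30%
  overweight), needed because overweight participants are ineligible
  as controls. BMI itself is not simulated continuously: every
  analysis step consumes only the weight class, so records carry a
  class-representative BMI (22/26/30) that keeps the class a
  deterministic function of BMI.

Default group sizes are 2000 farmers and 1000 migrants — the order of
magnitude at which every joint-exposure cell under recessive coding is
reliably occupied. One master seed drives all stages through derived
substreams, so a configuration is fully reproducible and matching,
simulation and bootstrap never share a random stream.

What the generator deliberately does *not* emulate: the survey's
stratified cluster sampling, measurement error in anthropometry,
covariate-genotype dependence (covariates are independent of genotype
given group unless explicit `covariate_effects` are supplied), and
more than two markers. Passing tests on this generator therefore
validate the statistical machinery, not the field study's sampling
design.

`fixture_from_printed_counts()` is the complement for published-data
checks: it expands a case/control x group x genotype count table into
individual records whose tabulations reproduce the counts exactly, so
chi-square, HWE and crude joint-model results can be verified against
published tables without the raw data. Its covariates are placeholders
and the records are flagged synthetic.

## Numerical and reporting conventions

* All chi-square tests are plain Pearson statistics without continuity
  correction — the variant that reproduces the published genotype,
  allele and HWE p-values (0.0004, 0.0002, 0.0018, 0.0016, 0.8919) at
  printed precision. A zero expected cell is an error naming the cell;
  an expected cell below 5 warns but still computes, since published
  tables include such cells.
* The HWE statistic uses expected counts from the sample allele
  frequency with df = 1. One published control-group HWE cell (0.9611
  for the second marker) is not reproduced by this statistic, which
  gives 0.9304 with the very same formula that reproduces the 0.8919
  cell for the first marker; the discrepancy is documented rather than
  chased with an alternative test.
* Interaction measures are computed from unrounded odds ratios and
  reported to 2 decimals; p-values render to 4 decimals, percentages
  to 2. Recomputing the measures from *rounded* published ORs can
  therefore differ in the last digit (e.g. RERI 6.55 vs a published
  6.54), which the tests assert at a 2-decimal tolerance.
* Frequency matching uses seeded simple random sampling without
  replacement within joint age-band x sex strata — the stricter
  reading of "matched for age and sex", and equivalent in effect to
  unequal-probability sampling with stratum-specific fractions. A
  stratum with too few eligible controls either takes all of them
  with a recorded deficit (default) or fails, by policy.

## Problem sizes used in validation

The test suite validates parameter recovery on cohorts of 50,000 per
group, calibration of the delta RERI interval and the product-term
Wald test on 500 replicates of 5,000 per group under the additive and
multiplicative nulls (dominant coding, where every joint cell is well
occupied), delta-vs-bootstrap agreement at 8,000 per group, and the
nominal rejection rate of the HWE test on 500 replicates of 1,000
genotypes. These sizes were chosen so Monte-Carlo error is small
relative to the tolerance being asserted.

## Known limitations

* Unconditional (not conditional) logistic regression is used, which
  matches the published analysis of this frequency-matched design but
  relies on the matching factors being adjusted in the model.
* The adjusted odds ratios behind published interaction tables cannot
  be reproduced without the original individual-level data; the
  package reproduces their *arithmetic* exactly and validates the
  modelling pipeline on synthetic data with known truth.
* Delta-method intervals for RERI/AP are known to be anticonservative
  in small samples; the stratified bootstrap is provided as the
  companion check rather than a replacement.
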