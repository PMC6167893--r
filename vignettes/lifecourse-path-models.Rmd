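---
title: "Survey-weighted life-course path models for genotype, BMI and type 2 diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survey-weighted life-course path models for genotype, BMI and type 2 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Risk alleles at *TCF7L2* (rs7903146-T) raise the odds of type 2 diabetes
(T2D) yet associate with *lower* body mass index — an apparent paradox that
could reflect selection bias, reverse causation through diagnosis-related
weight change, or genuine pleiotropy. Distinguishing these explanations
requires following both traits across adulthood in a population-based
sample, and respecting that such samples come from complex survey designs
with strata, clusters (primary sampling units, PSUs) and unequal sampling
weights.

`svypath` implements the full analysis chain for this setting:

1. a **synthetic cohort generator** reproducing the statistical structure
   the analysis assumes, so every stage can be validated against known
   truth without restricted data;
2. **weight-history quality control**: unit standardization, lb/kg
   confusion detection, BMI plausibility bounds, and a conservation-checked
   exclusion-flow ledger;
3. **genetics**: additive allele coding, Hardy–Weinberg testing, kinship
   pruning, single-variant VCF ingestion;
4. **design-based estimation**: survey-weighted pseudo-maximum-likelihood
   linear and logistic regression with Taylor-linearization (sandwich)
   variance and subpopulation (domain) analysis;
5. a **recursive path model** over genotype, BMI at ages 21/45/65 and
   period T2D indicators, with effect decomposition.

# The model

Let $G \in \{0,1,2\}$ be the risk-allele dosage, $B_{21}, B_{45}, B_{65}$
the BMI at ages 21, 45 and 65, and $D_1, D_2$ indicators of a first T2D
diagnosis in ages 22–45 and 46–65. With covariates $C$ (age at
examination — the age at recall — sex, education, ancestry proportions,
genetic analysis group) on every node, the default structural system is

$$
\begin{aligned}
B_{21} &= \alpha_1 + \beta_{G1} G + \gamma_1' C + \varepsilon_1 \\
\operatorname{logit} P(D_1 = 1) &= \alpha_2 + \theta_{G1} G + \theta_B B_{21} + \gamma_2' C \\
B_{45} &= \alpha_3 + \beta_{G2} G + \lambda_1 B_{21} + \delta_1 D_1 + \gamma_3' C + \varepsilon_2 \\
\operatorname{logit} P(D_2 = 1 \mid D_1 = 0) &= \alpha_4 + \theta_{G2} G + \theta_B B_{45} + \gamma_4' C \\
B_{65} &= \alpha_5 + \beta_{G3} G + \lambda_2 B_{45} + \delta_2 D_2 + \gamma_5' C + \varepsilon_3
\end{aligned}
$$

Because the graph is a recursive DAG with no latent variables, the joint
likelihood factorizes into node-given-parents terms, and each equation can
be maximized separately (`method = "factorized"`). Every equation is fit
by survey-weighted pseudo-maximum likelihood; the joint covariance of all
coefficients stacks the per-record score contributions across equations
*before* PSU aggregation, so cross-equation covariances — required for the
delta-method standard errors of indirect effects — are design-consistent.

## Missing data

Period indicators are **age-censored by design**: $D_1$ is defined only
for participants at least 45 at examination, $D_2$ only for those at least
65, and recalled weights exist only for attained ages. This missingness is
*monotone in age*: whenever a node is missing, so are all later nodes. The
missing factors of the likelihood then integrate to one, so the factorized
available-case fit **is** full-information maximum likelihood under
missing-at-random. The package also provides `method = "fiml_mc"`, a
Monte-Carlo EM that recovers information from *non-monotone* patterns (a
BMI mediator missing while a descendant is observed) by integrating the
missing mediator over importance draws from its conditional given its
parents (64 draws by default, fixed substream seed, common random numbers
across EM iterations, convergence when the largest coefficient change
falls below $10^{-6}$). Its sandwich uses Fisher-identity expected scores
with the complete-data information as bread, which is mildly
anticonservative; factorized fits are the primary inference method.

## The later diagnosis period is a hazard

$D_1$ and $D_2$ encode a single self-reported *first* diagnosis age, so a
diagnosis in 22–45 structurally precludes a new one in 46–65. The natural
formulation is a discrete-time hazard: the $D_2$ equation is fit on the
risk set $D_1 = 0$ (`hazard_risk_sets = TRUE`, the default, applied when
the earlier indicator is not an edge). The configurable $D_1 \to D_2$ edge
is retained in `default_path_spec()` for completeness, but fitting it on
first-diagnosis data meets quasi-complete separation ($D_1 = 1$ forces
$D_2 = 0$) and the fit aborts with a separation error naming the term —
which is the correct diagnosis, not a numerical accident. Analyses in this
package therefore use `d1_d2 = FALSE`. Fitting the marginal $D_2$ equation
without the risk-set restriction attenuates $\theta_{G2}$ and $\theta_B$
by roughly 30% (it estimates a mixture with the period-1 survivor
probability); the hazard restriction removes that misspecification.

A related reporting ambiguity: the per-allele odds ratio for "diagnosis
between 22 and 65" can be read either as the conditional $G \to D_2$ edge
or as a cumulative two-period effect. Both are computable from a fit
(`edge_odds_ratio()` for the edge; `effect_decomposition()` totals on the
linear-predictor scale for the cumulative reading); the package asserts
neither as canonical.

## Effect decomposition

Direct effects are edge coefficients; each indirect effect is the product
of coefficients along one directed path; totals are their sum, all on the
**linear-predictor scale**. Products through logit nodes follow the usual
structural-equation convention; odds ratios do not collapse over
mediators, and risk-scale mediation is out of scope. Standard errors use
the multivariate delta method with the joint sandwich covariance; on a
three-node chain with coefficients $a, b$ the indirect SE reduces to the
closed form $\sqrt{a^2\sigma_b^2 + b^2\sigma_a^2}$, which the tests verify
together with agreement (within 10%) against a parametric bootstrap.

# Design-based estimation

`fit_weighted_glm()` maximizes the weighted pseudo-likelihood and
estimates variance by Taylor linearization: per-record scores
$w_i (y_i - \mu_i) x_i$ are summed to PSU totals, their between-PSU
covariance within strata (with the $n_h/(n_h-1)$ factor) is sandwiched
between the inverse expected information. Domain (subpopulation) analyses
**zero the scores** of out-of-domain records instead of dropping rows, so
all PSUs keep contributing to the variance; the same applies to records
excluded by per-equation complete-case filtering. A stratum with a single
PSU is a hard error by default (silent centering hides design defects); a
documented `single_psu = "centered"` policy exists. Intervals use the
normal reference; a finite `df` switch (conventionally PSUs minus strata)
is available. Genotype-descriptive tables use dis-joint genotype coding
(two indicator contrasts, adjusted means at weighted covariate means, and
a joint 2-df Wald test) — no additive assumption.

# The synthetic cohort

The generator's defaults are the package's reference scenario and were
fixed once, on substantive grounds:

* **Design**: 10 strata × 4 PSUs × 226 persons (n = 9040, the analytic
  scale of the motivating study); stratum PSU-sampling fractions cycle
  1/2…1/5; persons aged 45+ are oversampled to 62% of the sample
  (population share 40%), with the 45+ age density shaped so ~8% of the
  sample is 65+; weights are products of inverse inclusion probabilities.
  `equal_weights = TRUE` gives a self-weighting design for recovery
  studies.
* **Genotype**: Hardy–Weinberg at risk-allele frequency 0.255, giving
  expected class shares 55.5 / 38.0 / 6.5%.
* **Structural truths**: direct per-allele BMI effects −0.20 / −0.18 /
  +0.01 kg/m² at 21/45/65 and −0.37 kg/m² on examination BMI; per-allele
  log-odds ln(1.32) in both diagnosis periods; BMI carryover 0.8; +2.8
  kg/m² on the BMI following a diagnosis; BMI→next-period diagnosis 0.10
  log-odds per kg/m². Logistic intercepts are calibrated so ~5% are
  diagnosed by 45 and ~20% in 46–65 among those old enough; linear
  intercepts so mean BMI runs ≈ 23.8 → 27.5 → 29.0 kg/m².
* **Noise**: BMI residual SDs 3.0/3.0/3.0 kg/m² — sized so well under 1%
  of generated BMIs fall outside the 16–70 plausibility bounds (real
  BMI-at-21 distributions put negligible mass below 16; a heavier tail
  would make the QC bounds truncate the response and shift every
  association, which is a property of the bounds, not of the estimator).
  Recall noise SD 2 kg on self-reported weights; independent PSU-level
  intercepts (SD 0.5 kg/m²) per BMI node create the within-cluster
  correlation the sandwich must absorb. (A *shared* PSU effect across
  nodes would sit in both a regressor and its outcome's residual and bias
  the carryover upward for any estimator, so the effects are drawn
  independently.)
* **Diagnosis ages** are drawn uniformly within the diagnosed period —
  the interval indicators leave the within-period placement unidentified —
  and are reportable at examination only if already received; a
  post-65 hazard populates late-life diagnoses.
* Heights are fixed per person (measured once at baseline and used for
  all BMIs); recall noise applies to weight only.

`inject_artifacts()` overlays QC stress: lb-for-kg self-reports (on the
examination self-report, where the concurrent measured weight makes the
ratio test identifiable; a separate rate exists for recalled weights),
pregnancy flags, out-of-range BMIs, pre-adult diagnosis ages, and
close-kin pairs — each logged with its hidden truth.

## What passing tests do and do not show

The generator emulates the *statistical* structure (design, HWE,
recursive system, censoring, recall noise), not real biology: no LD or
haplotype structure, no household clustering beyond the PSU, Gaussian BMI
residuals rather than skewed ones, linear covariate effects, and ancestry
proportions with null generative effects (they are adjustment covariates
only). Parameter-recovery results therefore validate the estimators under
the model's assumptions; they cannot certify behavior under model
misspecification in real cohorts.

Two recovery conditions deserve emphasis. Recovery runs disable recall
noise and score fits on the latent BMI trajectory: self-report noise is an
error-in-*regressor* for every downstream equation and attenuates the
carryover from 0.80 to ≈ 0.77 at the default 2 kg — for any estimator —
and even whole-unit rounding leaves ~0.5–1% attenuation. That attenuation
is a documented property of recalled weights (present equally in the real
instrument), distinct from estimator bias, which the recovery studies
isolate.

# Quality control choices

* Weights are standardized to whole kilograms, halves away from zero.
* The lb/kg confusion detector flags a self-report whose ratio to its
  reference lies within 5% of 2.2046. The tolerance separates the
  conversion factor from plausible true change; it presumes the reference
  tracks the same-age weight, which holds for the examination self-report
  (concurrent measured weight) but not for recalls decades apart, whose
  between-age drift (15–20% under the reference trajectory) hides the
  ratio. Staged outlier screening of recalls beyond this rule is out of
  scope.
* BMI bound violations drop the *value*, not the person; a person leaves
  only when no usable BMI remains.
* Exclusion rules run in a fixed order (pregnancy/amputation leaving
  nothing usable → diagnosis before 22 → no usable height/weight →
  missing analysis group → missing education → relatedness) with
  first-rule-wins accounting, and the ledger's conservation arithmetic is
  enforced programmatically.
* Relatedness pruning removes, within each connected component of pairs
  with $0.35 < \hat\pi < 0.98$ (open interval; $\hat\pi \ge 0.98$ routes
  to duplicate handling), an exact minimum-size set, preferring to drop
  members with fewer weight measurements, then lexicographically larger
  ids. Exact per-component minimization was chosen over greedy
  pair-by-pair resolution because greedy provably over-removes on
  star-shaped components (one central relative of many); for a single
  pair both reduce to the drop-the-fewer-weights rule. A `method =
  "greedy"` option (descending $\hat\pi$) is retained, and components
  larger than 24 fall back to it with a warning.

# Numerical notes and problem sizes

Point estimates use iteratively reweighted least squares
(`glm.fit`/`lm.wfit`); rank deficiency errors with the aliased columns
named; (quasi-)separation errors with the offending covariate. The
acceptance studies use 40–50 replicates at n = 50,000 for recovery,
300–500 design-based cohorts at n = 4,000 for CI calibration (target
coverage 0.93–0.97), 500-record fixtures for QC properties, and exhaustive
search on ≤ 8-node graphs for pruning equivalence; the test suite runs the
same checks at those sizes.

# Known limitations

* Indirect effects are defined on the linear-predictor scale; risk-scale
  mediation and odds-ratio noncollapsibility corrections are out of scope.
* `fiml_mc` handles missing *continuous* mediators only; missing binary
  mediators are not integrated.
* No replicate-weight (BRR/jackknife) variance, finite-population
  corrections, or weight calibration.
* The published coefficients of the motivating study were computed on
  restricted data; this package uses them as generative truths for
  validation, not as reproduction targets.
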