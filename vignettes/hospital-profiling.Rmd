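---
title: "Profiling hospital mortality from paired clinical and administrative registries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling hospital mortality from paired clinical and administrative registries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrprofiler)
```

## The problem

Voluntary clinical registries are the backbone of surgical quality
measurement, but participation is uneven: some hospitals enter every
case and outcome, others enter a fraction of their cases, miss deaths,
or leave risk factors uncoded.  When a risk-adjustment model is built on
such data and hospitals are ranked by their standardized mortality
ratio (SMR), data quality and care quality become confounded.

`smrprofiler` implements the full audit-and-profile pipeline for this
situation:

1. **Completeness audit** — link the clinical registry to an exhaustive
   administrative reference by facility code and compute, per hospital,
   the ratio of clinical to administrative case counts and death counts.
2. **Quality classification** — hospitals with both ratios in
   $[0.7,\, 1]$ form the good-quality-data (GQD) group; any ratio below
   0.7 puts a hospital in the low-quality-data (LQD) group.
3. **Case-mix modelling** — a logistic risk-adjustment model per group,
   built by univariate screening ($p \le 0.1$), linear-gradient checks
   for ordinal scores, backward step-down with the Akaike information
   criterion (AIC) as stopping rule, and a pairwise interaction search;
   missing lung function (FEV) is handled by multiple imputation and
   missing tumour staging by an explicit "Missing" category.
4. **SMR profiling** — per hospital, observed deaths $O$ against
   expected deaths $E = \sum_i \hat p_i$, in two ways: $E_1$ from the
   model fitted on the hospitals' own (LQD) group, and $E_2$ by
   *linear-predictor transfer* of the GQD model (coefficients applied
   as-is, no refitting).
5. **Outlier detection and agreement** — a normal-deviate test on
   $z = (O - E)/\sqrt{\operatorname{Var}(O)}$ flags low- and
   high-mortality outliers; the two estimators' verdicts are
   cross-classified and summarized by Cohen's kappa.

A synthetic two-registry generator with a known true mortality model
and known hospital-level degradation mechanisms supplies ground truth
for every stage.

## The model and its statistics

The death indicator combines death within 30 days of surgery with later
death during the same hospital stay, as a single binary endpoint.
Risk is modelled on the logit scale:

$$\operatorname{logit} p = \beta_0 + \beta_{age}(\text{age}-\bar a)
 + \beta_{sex}\,\mathbb 1[\text{female}] + \beta_{asa}\,\text{ASA} + \dots$$

with the coding fixed by `code_covariates()`: age centered at the
fitting sample's mean, ASA as a linear 1–3 score, performance status
dichotomized 0–1 vs ≥2, dyspnea 0–2 vs ≥3, BMI in three classes
(<24, 24–28, >28 kg/m²), procedure other vs pneumonectomy, approach
thoracotomy vs VATS, tumour/nodal stage and resection quality as
indicator sets whose levels include an explicit "Missing", and 28
binary comorbidity flags.  Because ASA enters as the raw score, the
intercept corresponds to an extrapolated ASA of 0; `true_model()`
documents this and the reference coefficient set (intercept −4.4,
age +0.044/yr, female −0.944, ASA +0.31, pneumonectomy +0.77,
VATS −0.59, …).

Model diagnostics follow standard practice: the C-statistic is the
rank-based probability that a death outranks a survivor (ties ½);
$R^2$ is Nagelkerke's rescaled Cox–Snell measure; calibration is the
Hosmer–Lemeshow test over deciles of predicted risk with $g-2 = 8$
degrees of freedom.  The df convention is pinned by a worked check:
an HL statistic of 4.47 with $g = 10$ must give $p = 0.81$, and 6.4
must give $p = 0.60$.

For a hospital with patients $i = 1,\dots,n_h$,

$$E = \sum_i \hat p_i,\qquad
  \operatorname{Var}(O) = \sum_i \hat p_i(1-\hat p_i),\qquad
  \widehat{se}(\text{SMR}) = \sqrt{\operatorname{Var}(O)}/E ,$$

the binomial-variance form standard for indirectly standardized SMRs
from logistic models.  The outlier test compares
$z = (O-E)/\sqrt{\operatorname{Var}(O)}$ with $\pm z_{1-\alpha/2}$ at
$\alpha = 0.05$ two-sided; an exact Poisson mid-p variant
(`method = "midp"`) is available for small $E$.  A hospital with no
recorded deaths has SMR 0 (consistent with dispersion summaries whose
lower quartile is 0), and a 0/0 death-completeness ratio counts as 1
(no evidence of under-reporting).  No multiplicity correction is
applied across hospitals by default; a Bonferroni option exists.

Cohen's kappa is unweighted — the three statuses low/non/high are
treated as nominal, which reproduces the published value of 0.46 from
the published cross-classification — with bands: >0.8 excellent,
0.6–0.8 satisfactory, 0.41–0.6 moderate, 0.21–0.4 low, else poor.

## What the generator emulates

`generate_hospitals()` draws, per hospital, a two-year expected volume
(log-normal, median 130 cases, log-sd 1, floor 10 — matching the
skewed caseload distributions seen in national audits), a type
(teaching / non-teaching / private), and four reporting mechanisms:

* `case_report_prob` — the patient is entered in the clinical registry
  at all;
* `death_report_prob` — an entered patient's death is recorded as a
  death (otherwise the record shows alive: outcome misclassification
  *on top of* omission — the two mechanisms are separately
  configurable because aggregate death ratios alone cannot distinguish
  them);
* `comorbidity_report_prob` — a true comorbidity flag survives coding;
* `tnm_missing_prob` — staging/resection fields are blanked in
  addition to their baseline missingness.

The `"paper-like"` scenario draws ~25% of hospitals as well-reporting
(all probabilities ≥ 0.93) and gives the rest at least one degraded
mechanism.  Its ranges were calibrated to the observed audit margins:
case-reporting U(0.25, 0.68) reproduces a median clinical/administrative
case ratio near 0.46, and the death-recording ranges put the joint
death ratio near 0.33, the observed median.  Staging blanking
U(0.10, 0.40) reproduces ~22–24% missing stage in degraded hospitals
versus ~10% baseline.

Case mix (`casemix_config()`) reproduces the published marginals of
the good-quality group — age 64 ± 10 y, 34% female, ASA 15.5/52/32.5%,
dyspnea 42.5/36/18/3.5%, FEV 83 ± 21% predicted with 10% missing,
BMI 25.45 ± 4.5 kg/m², 8.5% pneumonectomy, 28% VATS, staging
distributions with ~10% baseline "Missing", and 28 comorbidity
prevalences.  Covariates are drawn independently per patient; a single
optional positive ASA–comorbidity dependence
(`asa_comorbidity_dependence`) is provided because only marginals are
published.  Baseline FEV missingness and baseline "Missing" staging
belong to the case mix (they occur in well-reporting hospitals too)
and are therefore generated in the complete cohort, shared by both
registries; only hospital-specific under-reporting is applied by the
degradation step — this makes "all degradation probabilities 1 ⇒
clinical ≡ administrative" hold exactly.

What the generator does **not** emulate: correlated covariates beyond
the optional ASA link, hospital-specific case-mix differences (every
hospital draws from the same case mix, so between-hospital SMR spread
under a correct model is pure noise), coding errors other than
omission/blanking, transfers between hospitals, and any selectivity of
omission by default (an `omission_risk_coef` knob exists for
sensitivity analyses).  Passing tests therefore demonstrate the
pipeline's statistical correctness under known mechanisms, not that
real registries degrade this way.

## Numerical and design choices

* **Random streams** are split per hospital from the master seed
  (a fixed 31-bit mix), so adding hospitals never perturbs existing
  ones; every stochastic function takes an explicit seed.
* **Imputation**: m = 5 completed datasets by default; stochastic
  regression imputation from a linear model of FEV on the other coded
  covariates plus the outcome (including the outcome is standard MI
  practice), with coefficients and residual variance drawn from their
  large-sample posterior and draws truncated to [10, 160]% predicted.
  Chained equations are unnecessary with a single incomplete variable.
  Screening and selection votes are taken per completed dataset and
  pooled by majority; final coefficients and variances pool by Rubin's
  rules.  FEV does not enter the reference model, so in practice MI
  affects only the screening stage.
* **Selection** is at the level of coded-term groups (a categorical
  variable's indicators enter and leave together).  Backward AIC
  step-down is the default; a forward switch exists because study
  reports sometimes describe the build-up direction.  The univariate
  screen uses likelihood-ratio tests; separated univariate fits are
  retained with a warning rather than silently dropped; constant
  covariates are excluded with a warning.  The linear-gradient check
  compares score vs factor coding by LRT at the 0.05 level.
* **Degenerate inputs**: complete separation in the multivariate fit
  is an error; quasi-separation (|coef| > 15) is tolerated with large
  standard errors; empty Hosmer–Lemeshow deciles are merged with a
  warning; constant predictions collapse the HL test to a single cell
  with one degree of freedom.
* **Classification edge cases**: ratios above 1 + 0.05 are flagged
  anomalous and classed LQD ("between 1 and 0.7" read as an interval);
  the 0.7 boundary is closed; clinical-only facilities are linkage
  anomalies excluded from classification.
* **Ratio orientation** is clinical/administrative, so under-reporting
  gives ratios in [0, 1]; this matches the audit figures even though
  prose descriptions sometimes state the inverse.

## Problem sizes used in validation

The test suite exercises the pipeline at the study's own scale where
that matters and smaller where it does not: coefficient recovery uses
100 replicates of ~10,600 patients fitted with the fixed reference
term set; the outlier test's type-I error uses 600 clean hospitals
(~130,000 patients) under a correctly specified fitted model; the
qualitative degradation properties use 200 replicated 100-hospital
studies with selection switched off (screening, step-down and MI are
exercised separately at smaller n, and the replicate loops fix the
reference term set).  These sizes are the package's validation design;
the full selection pipeline on one 100-hospital study runs in seconds.

## Known limitations

* Expected-death uncertainty from the risk model itself is ignored by
  the Faris-style standard error (as is conventional); with few deaths
  per hospital the normal z approximation is crude — the mid-p option
  mitigates but does not remove this.
* The transferred-model route inherits any miscalibration between
  groups: its SMRs are not mean-one by construction, which is exactly
  the asymmetry the pipeline is designed to expose (expected deaths
  from the transferred model exceed the under-recorded observed
  deaths).
* Under this generator's non-selective, independent degradation
  mechanisms the transferred SMRs are *scale-compressed* relative to
  the internal ones (their denominators are uniformly larger), so the
  internal estimator shows the wider interquartile range in most
  replicates.  Real audits can show the opposite ordering, which
  requires between-hospital case-mix heterogeneity or reporting that
  is selective on severity — mechanisms outside the default generator
  (see `omission_risk_coef` for one sensitivity knob).
* No hierarchical shrinkage of SMRs and no funnel plots; the
  profiling statistics are the classical fixed-effects ones.

## A worked example

```{r example, eval = FALSE}
library(smrprofiler)

reg <- simulate_registries(simulation_config(n_hospitals = 100, seed = 11))
study <- run_study(reg$admin, reg$clinical, m = 5, seed = 11)
study
build_report(study, "report")
```

`run_study()` returns the hospital summaries, both fitted models, both
SMR tables, their dispersions, the 3×3 agreement matrix with kappa,
and the group mortality contrast; `build_report()` writes them as CSV/
JSON plus a plain-text report.
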