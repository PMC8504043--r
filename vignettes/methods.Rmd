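---
title: "Methods: scoring prescription documentation and modelling its change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring prescription documentation and modelling its change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxaudit)
```

## The assessment problem

A hospital drug order is *actionable* when the person administering it
needs no guesswork: the chart carries the relevant patient data, the order
itself is valid, legible and complete, and administration-critical details
(route spelling, body site, reason for as-needed use) are explicit.
`rxaudit` operationalises this as twenty criteria evaluated per
prescription, each rated **met**, **not met**, or **not applicable**. The
trichotomy matters: a criterion that cannot apply (a reason is only
required for as-needed orders; a body site only when one is needed) must
not count against the order, and a missing input that an applicable
criterion needs raises an error naming the criterion rather than silently
counting as "not met" — silent pessimism would bias every downstream score.

Criteria #1–#5 read patient-level flags (allergies, age, weight, renal
function with both eGFR and creatinine, drug history), #6–#15 formal
properties of the order (validity, electronic creation, legibility,
unabbreviated substance names, complete drug and dosage information),
#16–#20 administration safety (risky-route spelling, body site, an
upstream medication review's risk flags — consumed as an input, since
computing them is a clinical-decision-support task — the as-needed reason,
and overall completeness). Applicability rules for the tri-state inputs
follow the structure of the underlying recommendation: drug history is
inapplicable for patients without pre-admission medication;
substance-abbreviation checking applies only when the displayed name
carries a substance designation; dose fields can be inapplicable for
dosage forms without a countable dose. Where the published recommendation
leaves the exact gate ambiguous (#11, #13, #15 applicability; whether #20
is scored independently), the engine exposes both an explicit input flag
and, for #20, an optional derived mode (conjunction of #10–#14, #16, #17);
every predicate is replaceable, and the ruleset version is recorded into
each assessment.

Two aggregates summarise the ratings. The **prescription-Fscore** is met /
applicable within one order; the **criteria-Fscore** is met / applicable
for one criterion within a cohort. Percentages are printed to one decimal,
rounding half away from zero, matching clinical reporting style.

## Cohort comparison

Prescription-Fscores are compared between cohorts by the Mann–Whitney U
test in its normal approximation with tie correction — scores are ratios
of small integers, so ties are ubiquitous — and summarised by the effect
size r = |z|/sqrt(n). This is implemented directly (the standard R test
does not expose z); `wilcox.test` serves as a cross-check in the test
suite. Criteria-Fscores are compared by Pearson chi-squared on the 2x2
met/unmet table, without continuity correction by default (a switch
exists): at these sample sizes the uncorrected statistic is standard, and
it reproduces the reference worked example (646/820 vs 568/774 gives
p = 0.0115) more closely than the Yates-corrected one (p = 0.0136). A
degenerate table (zero margin) returns p = 1 with a flag rather than an
error, because criteria met by every order in both cohorts are a routine
occurrence. No multiplicity adjustment is applied across the twenty
criterion tests.

The matched-cohort rule keeps a post-implementation patient only when all
five per-patient counts (total, standard peroral, risky route, as needed,
other prescriptions) lie within one standard deviation of the
pre-implementation means. "Within" is read inclusively (closed interval);
boundary cases are integer counts hitting the bound exactly and are rare.
Sample SD (n−1) is used throughout for cohort description.

## The beta GLMM

Fulfilment scores are proportions: bounded, heteroskedastic, and skewed
near the boundaries, so a beta likelihood is the natural choice, and
prescriptions cluster within patients, so a patient random intercept is
required. With the boundary transformation y = [F(N−1) + 0.5]/N (N the
total number of observations; strictly increasing, fixes 0.5, never
returns 0 or 1):

$$\operatorname{logit}(\mu_{ij}) = x_{ij}^\top\beta + b_i,\qquad
  b_i \sim N(0, \sigma_b^2),\qquad
  y_{ij}\mid b_i \sim \mathrm{Beta}(\mu_{ij}\phi,\,(1-\mu_{ij})\phi).$$

The mean–precision parameterisation with a single constant precision
$\phi$ is used; no dispersion submodel. Fixed effects are the time point,
the prescription category (reference standard peroral), the comedication
count, and K−1 ward columns in **weighted effect coding**: an observation
on ward k scores 1 in column k, one on the reference ward scores
−w_k/w_ref, with w the ward's share of prescriptions. Each column then has
exactly zero mean, so ward coefficients are deviations from the
prescription-weighted grand mean — the natural contrast when wards differ
greatly in size. The omitted ward's coefficient is recovered from the
zero-sum constraint, with a delta-method SE treating the weights as fixed
functions of the design.

### Estimation

The marginal likelihood integrates $b_i$ out per patient. The integral is
approximated by **adaptive Gauss–Hermite quadrature**: for each patient a
safeguarded Newton search (analytic first and second derivatives,
patient-wise step halving) finds the posterior mode of $b_i$, the local
curvature scales the nodes, and the weighted kernel sum is accumulated in
log space. Fifteen nodes are the default (config-exposed; one node is the
Laplace approximation; refining 5 → 15 → 31 nodes changes the
log-likelihood by progressively less, and 15 → 31 by under 1e−5 on the
test fixtures, while dense brute-force integration agrees with the
quadrature to better than 1e−4 across a parameter grid). The
log-likelihood is maximised over $(\beta, \log\sigma_b, \log\phi)$ by
`nlminb` with an analytic score obtained from the Fisher identity (the
posterior expectation of the joint score, evaluated on the same nodes).
Starts are deterministic — $\beta$ from least squares on
$\operatorname{logit}(y)$, $\sigma_b = 0.1$, $\phi = 10$ — so a refit on
identical data is bitwise identical; seeds only ever affect simulation.
The covariance of the estimates is the inverse numerical Hessian. PORT's
"singular convergence" return at a genuine optimum (score norm below
1e−4·|logLik|) is accepted as converged. With $\sigma_b$ fixed at zero the
code path reduces exactly to a fixed-effects beta regression, which the
test suite verifies against an independent implementation to 1e−4.

Effects are reported as odds ratios $e^{\beta_k}$ with Wald 95% intervals,
interpreted as the change in the odds F/(1−F) of fulfilment.
**Covariate-adjusted predictions** are population-level,
$\operatorname{logit}^{-1}(x^\top\hat\beta)$ at $b_i = 0$: group contrasts
should not be diluted or inflated by individual intercepts. (Conditional
empirical-Bayes predictions are available behind a flag, since
"adjusted" could also be read that way.) The **net interventional
effect** per category is the difference in mean predicted scores, post
minus pre, in percentage points. The **E-value**
$E = \mathrm{OR} + \sqrt{\mathrm{OR}(\mathrm{OR}-1)}$ (applied to
1/OR for protective effects) states how strongly an unmeasured confounder
would have to be associated with both intervention and outcome to explain
the effect away; it is applied to the odds ratio directly, treating it as
a risk-ratio approximation, consistent with how such effect estimates are
usually screened.

## Change patterns

Per criterion, ward-level trajectories (criteria-Fscore pre → post within
ward) are classified into four qualitative patterns: **A** different
starts, ends and directions; **B** different starts and ends, same
direction; **C** different starts, same end and direction; **D** all the
same. Starts or ends count as "same" when their spread is at most a
tolerance (default 2 percentage points); a trajectory is "flat" within 1
percentage point, compatible with a single shared direction but not with
a mix of rising and falling. The tolerances are explicit parameters
because any published assignment of such patterns is ultimately visual;
the package's own guarantee is structural: classifications are invariant
under ward permutation, tolerance 0 demands exact equality, and growing
tolerance moves criteria monotonically toward D. Wards where a rare
criterion (e.g. body site) never applies at one time point are excluded
from that criterion's classification.

## The synthetic cohort generator

No patient-level data from the motivating study are publicly deposited,
so the generator is a first-class module that emulates the study design:
two cohorts of 160 patients over 7 wards (the largest ward double-sized,
20/40 patients per ward per time point), per-patient prescription counts
from a discretised gamma matched to mean ± SD (11.6 ± 5.6 pre,
10.0 ± 3.3 post, truncated at 1 — positive and overdispersed, as hospital
counts are), category mixtures per cohort (56.8 / 14.3 / 24.4 / 4.4% pre;
62.2 / 12.6 / 22.7 / 2.5% post), and comedications = own prescriptions − 1
(the convention is recorded in config).

**Record-level mode** draws the structured documentation fields so that
pushing the cohort through the criteria engine reproduces configured
per-criterion fulfilment probabilities (defaults: the observed cohort
criteria-Fscores, e.g. electronic creation exactly 0% pre / 100% post).
Within-patient correlation is induced by a shared patient-level logit
shift with SD 0.76, the scale of the reported random-intercept SD: because
all of a patient's criteria shift together, the induced score-level
intercept is approximately that shift. A logit-normal mean is attenuated
relative to `plogis` of its median, so each field's intercept is
calibrated (Gauss–Hermite + root finding) to keep the *marginal* met rate
exactly at its configured value — without this, rates near the boundaries
would be off by 1–2 percentage points by construction. Applicability
tri-states are drawn at the rates implied by the reference denominators
(drug history ≈ 94%, substance-name checking ≈ 44–49%, dose fields ≈ 99%,
single-dose present 76% / 95%, body site ≈ 0.5% — echoing its tiny
observed denominators); a share of as-needed orders (17.7% pre, 11.9%
post) carries a risky route so that risky-route spelling is assessed on
any schedule. What this mode does *not* emulate: real drug identities or
doses, criterion-specific correlation structure beyond the shared shift,
or any joint distribution of applicability states beyond their margins —
so passing tests demonstrate the pipeline's arithmetic and calibration,
not clinical realism.

**Score-level mode** draws transformed scores directly from the beta GLMM
at configured truth (defaults: the reported odds ratios, σ_b = 0.762, and
φ = 30, chosen once so conditional score SDs land in the 5–9 percentage
point range of the reported per-category SDs) — the ground truth for
estimator validation. The matched-study generator applies the cohort
matching filter to oversampled post-arm candidates until ward quotas are
met; the truncation of the matching box raises the post arm's realised
mean count slightly above its generating mean, which is faithful to the
procedure (the reported post-cohort moments describe the *matched* data).

## Problem sizes and numerical choices

Validation workloads are sized to what the properties need: likelihood
oracle checks use ≤ 5 patients × 4 observations against a 10,001-point
dense grid; estimator recovery uses 50 replicates of the full 320-patient
design at 7 quadrature nodes (the node reduction changes the
log-likelihood by ~1e−5, immaterial to bias or coverage, and keeps the
study to a few minutes); generator calibration is checked on full-size
cohorts (~1850 + ~1600 prescriptions) against 99% tolerances derived from
the generator's own clustered sampling design — the iid binomial bound
would be too narrow, since outcomes cluster within patients by
construction. Outcomes are clamped away from 0/1 at 1e−12 inside the beta
density; transformed scores are validated to lie strictly inside (0, 1)
before fitting; rank-deficient designs and wards without prescriptions
are errors, not warnings.

## Known limitations

The ruleset's ambiguous applicability gates are configurable defaults,
not a reconstruction of the full published assessment scheme; sites
should review them against their own documentation standards. The model
offers no dispersion submodel, no nested or crossed random effects, and
Wald-only inference (no profile likelihood), matching the reporting style
it supports. The E-value treats an odds ratio as a risk ratio, which
overstates robustness when the outcome is common. The generator's
calibration is marginal per criterion; joint behaviour across criteria
beyond the shared patient shift is not controlled.
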