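# rxaudit

Audit the documentation quality of hospital drug prescriptions, and quantify
what changes when paper charts are replaced by a computerized physician
order entry (CPOE) system.

Hospital prescriptions should satisfy a set of formal criteria — allergies,
age, weight and renal function on the chart; a valid, legible order with
full drug name, dose strength, single dose, unit and dosage interval;
clearly spelled risky administration routes; a stated reason for as-needed
orders; no identifiable clinical risks; overall unambiguity. `rxaudit`
codifies twenty such criteria as a configurable rule engine that rates every
prescription *met / not met / not applicable* per criterion, and aggregates
the ratings into two fulfilment scores:

- **prescription-Fscore** — per order: met criteria / applicable criteria;
- **criteria-Fscore** — per criterion and cohort: orders meeting it /
  orders where it applies.

For before/after evaluation the package provides Mann–Whitney U comparisons
(normal approximation with tie correction, effect size r = |z|/√n),
per-criterion 2×2 chi-squared tests, and the multivariable model at its
core: a **beta-distributed GLMM**. With y_ij the boundary-transformed score
of prescription j in patient i ( y = [F·(N−1)+0.5]/N ):

    logit(mu_ij) = x_ij' beta + b_i ,   b_i ~ N(0, sigma_b^2)
    y_ij | b_i   ~ Beta(mu_ij * phi, (1 - mu_ij) * phi)

with fixed effects for time point (post vs pre), prescription category
(reference: standard peroral), comedication count, and wards coded by
*weighted effect coding* (coefficients are deviations from the
prescription-weighted grand mean; the reference ward's effect is derived
from the zero-sum constraint with a delta-method SE). The marginal
likelihood integrates b_i out by adaptive Gauss–Hermite quadrature, written
in this package and maximized by an analytic-score quasi-Newton optimizer.
Effects are reported as odds ratios with Wald CIs, covariate-adjusted
predicted scores, net interventional effects per category, and the E-value
gauging robustness to unmeasured confounding. Ward-level pre→post
trajectories per criterion are classified into four qualitative change
patterns. A synthetic cohort generator (record-level and score-level)
emulates the two-cohort study design so the whole pipeline runs and is
testable without access to hospital data.

## Worked example

```r
library(rxaudit)

study <- simulate_pre_post_study(sim_config(seed = 3), out_dir = "bundle")
report <- run_pipeline("bundle/patients.csv", "bundle/prescriptions.csv",
                       out_dir = "bundle/run")
report
```

prints (abridged):

```
== Prescription documentation quality report ==

PRE   Cohort: 160 patients, 1958 prescriptions (12.2 +/- 5.6 per patient)
POST  Cohort: 160 patients, 1757 prescriptions (11.0 +/- 2.1 per patient)

Not-applicable criteria per prescription: 3.3 (+/- 0.9)

Prescription-Fscore: 57.0% (+/- 12.9%) pre vs 91.1% (+/- 8.1%) post,
  p = 0, r = 0.84

Beta GLMM odds ratios (patient random intercept):
  time_post          OR  14.50 [11.59;  18.14]  p <0.001
  cat_risky_route    OR   0.91 [ 0.88;   0.95]  p <0.001
  cat_as_needed      OR   0.86 [ 0.83;   0.88]  p <0.001
  ...
  random-intercept SD 0.994 [0.915; 1.079], phi 34.7
  E-value of the time-point OR: 28.5

Net interventional effects (percentage points):
  STANDARD_PERORAL   +36.5
  RISKY_ROUTE        +38.2
  AS_NEEDED          +39.4
  OTHER              +36.2

Change patterns: #1:A #2:C #3:B #4:A #5:B #6:C #7:D ...
```

Read it as: synthetic pre-implementation orders fulfil 57% of their
applicable criteria on average, post-implementation 91%; the Mann–Whitney
effect size r = 0.84 is large; after adjusting for category, ward and
comedications, electronic orders have ~14-fold higher odds of a better
score, the covariate-adjusted predicted score rises by 36–39 percentage
points depending on category, and only a confounder raising the odds of
improvement ~28-fold could explain the effect away. Every number traces
back to the generator seed and config hash recorded in the bundle
manifest.

A thin shell interface wraps the same functions:

```sh
Rscript inst/scripts/rxaudit.R simulate --seed 42 --out-dir bundle
Rscript inst/scripts/rxaudit.R report --patients bundle/patients.csv \
    --prescriptions bundle/prescriptions.csv --out-dir run
```

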