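---
title: "Modelling PIRA and EDSS change from baseline miRNA expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling PIRA and EDSS change from baseline miRNA expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piramir)
```

## The problem

In relapsing–remitting multiple sclerosis (RRMS), disability measured on
the Expanded Disability Status Scale (EDSS, 0–10 in 0.5-point steps) can
worsen in two distinct ways: relapse-associated worsening (RAW), where a
confirmed and sustained disability-worsening (CDW) event begins within
90 days of a relapse onset, and progression independent of relapse
activity (PIRA), where a CDW event has no relapse within the preceding
90 days (or no relapse at all).  PIRA in early disease carries a poor
prognosis, and no routine clinical or imaging marker predicts it well.
`piramir` models PIRA status (a binary outcome) and the 24-month EDSS
change (a continuous outcome) from baseline miRNA expression in
peripheral blood mononuclear cells, profiled on a 2549-miRNA microarray
panel in a 25-subject cohort observed at months 0, 6, 12, 18 and 24
(T0–T4).

## The modelling procedure

The pipeline has four statistical stages.

**Preprocessing.**  Raw intensities are median normalized — each sample
column is rescaled multiplicatively so its median equals the median of
the per-sample medians — and log2 transformed.  Only miRNAs with log2
value strictly greater than 0 in *every* sample are analyzed.  We apply
the filter after normalization (the order is switchable via
`require_log2`), since on the raw scale it simply means intensity above
1 everywhere.  Multiplicative scaling was chosen over subtracting the
median of log2 values because it is the standard microarray intensity
convention and keeps values positive for the transform; with an odd
feature count the two are equivalent up to the target constant.

**Candidate screening.**  For each feature, the Pearson correlation with
PIRA coded 0/1 (i.e. the point-biserial correlation) and with
EDSS~T4~ − EDSS~T0~ is tested two-sided via
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom.  A feature
passes when both p-values fall below $\alpha = 0.05$.  No
multiple-testing correction is applied at this stage — the screen is a
deliberate per-feature pre-selection rule, not an inferential claim —
but a Benjamini–Hochberg variant is available (`adjust = "BH"`) for
sensitivity analyses.  Shapiro–Wilk normality p-values are computed and
reported for every feature and for the EDSS-change vector; exclusion on
normality grounds is off by default (`strict_normality = FALSE`),
because the screen's correlations remain interpretable as effect sizes
either way and the strict gate can silently empty the candidate set at
n = 25.

**Exhaustive significance-constrained model search.**  Over every
$k$-subset of the screened candidates (default $k = 4$), every nonempty
subset of the $k$ main-effect terms and $\binom{k}{2}$ pairwise
interaction terms is fit — $2^{k + \binom{k}{2}} - 1$ term sets per
subset, 128,898 models for $k=4$ over nine candidates.  Marginality is
*not* enforced: an interaction may enter without its main effects,
because the model space of interest includes such forms (both packaged
reference models contain predictors that appear only inside products).
Logistic models are fit by iteratively reweighted least squares,
linear models by least squares with classical standard errors;
interaction columns are elementwise products of the uncentered
log2 expression values, so coefficients remain on the original
covariate scale.  Every coefficient, intercept included, gets a Wald
test against zero on the normal reference (a t reference with $n-p$
degrees of freedom is available for the linear family).  The
requirement that *all* coefficients be significant at 0.05 is the
primary, hard filter; the information criterion (AIC by default, AICc
and BIC switchable) only ranks the survivors.  We made the
all-significant constraint primary because the procedure's stated goal
is a model whose every term is defensible, not the best trade-off of
fit and complexity; when no model survives, the AIC-best model is
returned with a prominent warning rather than silently promoted.
Criterion ties break toward fewer terms, then lexicographic predictor
order, so the search is deterministic.

**Quasi-separation.**  At n = 25, logistic fits frequently approach
separation, where Wald statistics are meaningless.  A fit is excluded
from the all-significant pool when it fails to converge or when any
|coefficient| or standard error exceeds a guard (default $10^3$ on the
log2 scale).  The guard value is a scale judgement, not a tuned
constant: log2 expression values span roughly 0–15, so genuine effects
live orders of magnitude below it.

**Classification and robustness.**  The selected logistic model scores
subjects with $\sigma(Z) = e^Z/(1+e^Z)$; the ROC curve uses the unique
observed scores (descending, with a $+\infty$ sentinel) as thresholds,
predicting positive when score ≥ threshold.  AUC is computed by
trapezoid and equals the tie-corrected Mann–Whitney concordance; the
operating cutoff maximizes Youden's $J = \mathrm{TPR} - \mathrm{FPR}$,
ties resolved toward the smaller threshold (favouring sensitivity).
Three resampling procedures probe robustness, with reference replicate
counts 1000 / 1000 / 10,000:

* *bootstrap*: subjects resampled with replacement, the model structure
  refit, apparent AUC on the resample recorded (mean ± SD);
* *label permutation*: PIRA labels permuted uniformly, structure refit,
  apparent AUC recorded; the observed apparent AUC is compared against
  this null with the add-one empirical p-value
  $(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + R)$, which never
  reports zero;
* *predictor randomization*: as many distinct features as the model has
  predictors are drawn uniformly from the expressed panel excluding the
  model's own predictors, substituted positionally into the same term
  structure, and refit.

All three *refit* the term structure rather than rescoring frozen
coefficients (a fixed-coefficient reading of "evaluate the same model"
is possible; refitting is the default because only it explains a
bootstrap mean exceeding the apparent AUC through refitting optimism,
and the permutation null is only exchangeable under refitting).
Degenerate replicates — a vanished outcome class, a singular design, a
non-converged fit — are redrawn up to 100 times, then counted and
logged as failures so the requested replicate count is preserved.
The randomization pool defaults to all expressed features minus the
model's predictors; the plausible alternatives (whole panel,
non-candidates only) are a one-line configuration change.

## Clinical labelling rules

CDW magnitude thresholds are not universal; the package adopts the
standard MS-trial convention: an EDSS increase of ≥ 1.5 points from a
reference of 0, ≥ 1.0 from a reference ≤ 5.5, and ≥ 0.5 above 5.5,
confirmed at a later visit at least 3 months on (on a 6-month visit
grid every later visit qualifies) and sustained at all subsequent
visits.  The reference is the rolling minimum of prior observations,
which prevents the same worsening from being flagged twice;
consecutive qualifying visits collapse into one event with onset at the
first.  An event exactly 90 days after a relapse onset counts as RAW
(the window is a closed interval), since PIRA requires *more* than 90
days.  When a clinical table supplies precomputed PIRA/RAW flags they
are taken as ground truth; derivation from events is used otherwise and
in consistency tests.

The Mann–Whitney comparisons between PIRA groups use exact enumeration
of all $\binom{n_a+n_b}{n_a}$ group assignments when the pooled sample
is at most 12 (ties handled naturally by the enumeration), and the
tie-corrected normal approximation otherwise.

## What the synthetic generator emulates — and what it does not

The generator exists so that every downstream stage can be exercised
end-to-end, deterministically, without patient data.  Its defaults *are*
the study conditions: 25 subjects with exactly 8 PIRA-positive, 3 RAW
and 8 male (counts are fixed, not sampled, so cohort composition is
reproducible), a 2549-feature panel, baseline EDSS mean 2.2 (SD 1.78)
and 24-month mean 2.54 (SD 1.97) on the half-point grid.

* **EDSS trajectories.**  Baseline EDSS is drawn from a normal
  truncated to [0, 10] whose location is solved numerically
  (`uniroot`) so the *post-truncation* mean hits the target, then
  snapped to the 0.5 grid.  Per-interval increments are Gaussian with a
  PIRA-dependent drift: non-PIRA subjects drift 0, PIRA subjects carry
  the entire configured T4−T0 gap
  ($\Delta = n(\bar{T4}-\bar{T0})/n_\mathrm{PIRA}$ spread over four
  intervals), which reproduces the widening group separation over
  follow-up.  The increment SD is derived from the two target SDs and
  the between-group mean split, floored at 0.1.  Per-subject
  trajectories, relapse timings and CDW magnitudes are *not* observed
  in any source; these are modelling choices calibrated only to the
  reported moments and the qualitative trajectory pattern.
* **Event dates.**  PIRA subjects receive a CDW date at the month-12 or
  month-18 visit with any relapse pre-baseline (hence > 90 days prior);
  RAW subjects receive a relapse and a CDW within 0–90 days of it;
  22 subjects carry a pre-baseline relapse.  The generated dates
  round-trip through `label_progression()` to the assigned flags.  RAW
  subjects' EDSS series do not necessarily exhibit a detectable CDW
  rise — event dates, not trajectories, carry their label — a known
  simplification.
* **Expression.**  Feature baselines are uniform on
  `baseline_mean ± 2` log2 units with per-feature noise SD 1
  (`noise_sd`), values kept strictly positive so the expression filter
  is non-trivial.  In `exact` mode, each informative feature is
  constructed by two-constraint Gram–Schmidt projection: with
  orthonormalized outcome directions $u_1, u_2$, the feature is
  $r_1 u_1 + \beta u_2 + \gamma e$ where
  $\beta = (r_2 - r_1\rho)/\sqrt{1-\rho^2}$ and $e$ is seeded noise
  orthogonalized against both outcomes and the constant; the request is
  feasible iff $r_1^2 + \beta^2 \le 1$, and infeasible requests error
  with the feasible region.  Realized sample correlations equal the
  targets to ~1e−12.  `population` mode instead uses a linear-Gaussian
  factor model that hits the targets in expectation only.
* **Seeding.**  A master seed spawns fixed substreams (clinical /
  null-feature block / one per informative feature); the null block is
  filled row-wise, so enlarging the panel appends features without
  perturbing existing ones.

What the generator does **not** emulate: probe-level microarray
artifacts, batch or scanner effects, missing visits, co-expression
structure among null features (they are independent), and any real
biological correlation network among the nine informative miRNAs beyond
their marginal associations with the two outcomes.  Tests passing on
synthetic cohorts therefore validate the *statistical machinery* —
screening recovers embedded signal exactly, the search recovers
generating predictor sets, null calibration holds — not the biological
replicability of the reference findings.

A consequence worth stating plainly: because PIRA and EDSS change are
correlated outcomes, a genuinely null feature that correlates with one
by chance tends to correlate with the other, so on a 2549-feature null
panel the dual screen passes a handful of false candidates in most
draws.  "Exactly nine candidates" is deterministic only on an
informative-only panel; on the full default panel the nine embedded
miRNAs always pass with their exact correlations, alongside a few
chance passers.  The acceptance suite checks both statements.

## Frozen reference models

The two models reported for the clinical cohort are packaged as data
constants, never refit: a logistic PIRA classifier on
hsa-miR-4485-5p, hsa-miR-340-3p, hsa-miR-6126 and hsa-miR-223-3p (two
main effects, four interactions, intercept −425.78, decision threshold
0.277 chosen by maximum Youden) and a multilinear EDSS-change model on
hsa-miR-4466, hsa-miR-24-3p, hsa-miR-6090 and hsa-miR-223-3p (intercept
1183.40).  Two caveats are documented rather than resolved: the source
describes the linear model both as using "four other" predictors and as
using "the same four" as the logistic model — the printed equations,
which share only hsa-miR-223-3p, are taken as authoritative — and the
extreme logistic coefficient scale suggests near-separation at n = 25,
which is precisely why the package carries a separation guard and three
robustness procedures.  The frozen coefficients are meaningful only on
the original cohort's expression scale; applied to arbitrary synthetic
cohorts they saturate the sigmoid.

## Numerical choices

* Logistic IRLS converges on relative deviance change < 1e−10 (cap 100
  iterations); fitted probabilities are clamped to
  [1e−12, 1 − 1e−12].  The compiled fitter is cross-checked against
  `stats::glm` to 1e−8 and against a generic BFGS optimizer to 1e−6.
* The linear family inside the exhaustive search solves precomputed
  Gram systems, making its per-model cost independent of n; residual
  sums of squares are guarded against negative round-off.
* AIC counts the residual variance as a parameter in the linear family
  (matching `stats::AIC` on `lm`); families are never ranked against
  each other.
* Exact Mann–Whitney enumeration is used up to pooled n = 12
  ($\binom{12}{6} = 924$ assignments).
* Zero-variance features never pass the screen and error in
  `standardize_rows()`; single-sample matrices are handled throughout.

## Problem sizes in the test suite

The suite exercises the full default design (2549 × 25) where the claim
is about the design itself, and scales down elsewhere: generator
calibration averages 200 cohorts; model recovery uses 25 simulations of
n = 200 with four true predictors, five correlated decoys and k = 4
(the full 128,898-model search each time); null calibration of the
label-permutation p-value uses 200 null datasets with 99 permutations
each; ROC oracle equivalence uses 500 random instances.  End-to-end
pipeline tests run on 120-feature panels with reduced replicate counts.

## Known limitations

* No cross-validation or external-cohort validation machinery: the
  apparent AUC is an in-sample quantity, and the bootstrap/permutation
  procedures quantify but do not remove refitting optimism.
* No missing-EDSS imputation; subjects lacking T0/T4 are dropped
  listwise from the screen with a warning.
* The CDW confirmation interval and increment thresholds are
  field-standard defaults, not values asserted by the reference
  analysis, and are configurable.
* The predictor-randomization pool definition ("unrelated miRNAs") is
  ambiguous in the source; the default (all expressed features minus
  the model's own) is one defensible reading.
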