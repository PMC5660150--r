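---
title: "Methods: meta-analysis of large-animal MI control arms"
author: "metacontrol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-analysis of large-animal MI control arms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacontrol)
```

## Scope and data model

`metacontrol` analyses study-level summaries of the control arms of
large-animal myocardial-infarction experiments. The unit of analysis is one
control-arm comparison: a mean, SD and group size for one of three
percentage outcomes — infarct size over area at risk (IS/AAR), infarct size
over left ventricle (IS/LV), ejection fraction (EF) — together with design
moderators (species, sex, occlusion type, occluded vessel, open vs closed
chest, co-medication, immunosuppression, quantification method, follow-up
duration, ischemia duration, study quality, weight, age) and, separately,
death counts per procedural phase (peri-procedural: during infarct
induction; post-procedural: afterwards).

Two storage conventions matter enough to be fixed:

* Follow-up is stored in **hours** and ischemia duration in **minutes**, so
  slope coefficients read directly in points/hour and points/min — the
  units in which such effects are conventionally reported.
* "Unreported" is a **first-class level** of every categorical moderator
  (`unknown`, `unreported`), never silently dropped: unreported sex or
  occlusion status is itself a design property of the literature and is
  analysed as such. Missing *continuous* values (ischemia, weight, age) are
  empty cells, never 0, because 0 is a legal value in principle.

## The random-effects model

Outcomes enter as raw means: percentages are comparable across studies, so
no standardization is applied. For study $i$ with mean $y_i$, SD $s_i$ and
$n_i$ animals the sampling variance is taken as
$v_i = s_i^2 / n_i$ — the squared standard error of a mean. This is an
interpretation (study-level reports rarely state how their spread should be
converted into a weight), and it is exactly the rule the synthetic
generator uses, so every oracle test exercises the same convention the
analysis assumes.

The model is $y_i = x_i^\top \beta + u_i + e_i$ with
$u_i \sim N(0, \tau^2)$, $e_i \sim N(0, v_i)$. The between-study variance
$\tau^2$ is estimated by REML; $\beta$ by weighted least squares with
$w_i = 1/(v_i + \tau^2)$ and covariance $(X^\top W X)^{-1}$. Pooling
(`pool_random_effects()`) is the intercept-only case, reported with
Cochran's $Q$ (computed with fixed-effect weights $1/v_i$),
$I^2 = \max(0, (Q - (k-1))/Q)$, and a 95% interval $\mu \pm 1.959964\,SE$.

**Inference is z-based throughout** — normal reference for single
coefficients and contrasts, chi-square for the omnibus test of all
non-intercept terms — with no Knapp–Hartung small-sample adjustment and no
multiplicity correction of post-hoc contrasts by default (a
`p_adjust_method` argument exists for users who want one). This mirrors the
inferential style of the standard meta-analytic toolchain for this
literature. The cost is mild liberality: in our own calibration experiment
(1000 null datasets, $k = 100$, $\tau^2 = 25$) the omnibus test rejects at
about 6% for a nominal 5%.

A single remaining study does not error: subset analyses can shrink to
$k = 1$, in which case the study's own values are returned with
$\tau^2 = 0$ and a degenerate-fit flag.

## Numerical choices

REML is solved by root-finding on the analytic score
$\partial \ell_R / \partial \tau^2 = -\tfrac12\,(\mathrm{tr}\,P - y^\top P^2 y)$
with $P = W - WX(X^\top WX)^{-1}X^\top W$: the boundary $\tau^2 = 0$ is
accepted when the score is non-positive there, otherwise the root is
bracketed by doubling and solved to $10^{-10}$ (bounded scalar maximization
of the profiled likelihood is retained as a fallback). The tight tolerance
is not pedantry — pairwise contrasts are only invariant to the choice of
dummy-coding reference level if the two parameterizations converge to the
*same* $\tau^2$, and a looser optimizer leaves discrepancies around
$10^{-7}$ that a $10^{-10}$ invariance check rightly rejects. The search is
capped at $\tau^2 = 10^4$ points², far above anything a percentage outcome
can produce.

Rank deficiency is detected by singular values below
$10^{-10} \cdot \sigma_{\max}$ and reported as a collinearity error naming
the aliased terms; nothing is silently dropped.

## Meta-regression design

Categorical moderators are dummy-coded against pinned reference levels
(dog, female, temporary occlusion, LCX, closed chest, no co-medication), so
coefficients read "+21.6 if pig (vs dog)". Published meta-regression tables
in this field phrase each coefficient as "level (vs other level)" without
stating the fitted parameterization; since all pairwise contrasts are invariant to
the reference (a tested property), the pinning only affects labels.
Reference levels can be overridden per fit.

The **univariable battery** fits one model per moderator on that
moderator's available rows and reports per-level pooled means with CIs.
Those subgroup means come from subgroup random-effects pooling (each
level's studies pooled on their own), not from the regression fit — both
are defensible summaries; subgroup pooling is the default because it is the
more self-contained description of "what studies at this level showed".

The **multivariable fit** is complete-case over all moderators except those
marked `add_separately` (ischemia duration, weight, age — sparsely reported
in this literature). Each of those is refitted as the joint model plus that
single term on its complete-case subset, so a scarce covariate cannot
collapse the whole joint model's sample. Ischemia duration only exists for
temporary occlusions, so its subset fit is automatically a
temporary-occlusion analysis (and the occlusion factor collapses there,
with a warning rather than an error).

The pipeline (`analyze_outcome()`) applies a strict $p < 0.05$ gate: if the
multivariable omnibus test is not significant, post-hoc contrast testing is
skipped entirely and recorded as skipped.

## Mortality

Death fractions are analysed on the raw proportion scale — no logit or
arcsine transform by default — so that slopes read in percentage points per
unit (e.g. points/hour of follow-up). When one procedural setting reports
two sequential measurements (e.g. before and after randomization), the
overall proportion multiplies survival fractions,
$1 - p_{tot} = (1-p_1)(1-p_2)$, with effective $n = (n_1+n_2)/2$; the rule
is symmetric and associative, so multi-stage records are order-independent.

The weighting rule "one over the square root of the total number of
animals" admits two readings, and the package implements both explicitly:

* `se_inverse_sqrt_n` (default): $1/\sqrt{n}$ is a standard-error scale, so
  the inverse-variance weight is $\propto n$. This is the statistically
  conventional reading — down-weighting *large* studies, as the literal
  reading implies, is hard to justify.
* `weight_inverse_sqrt_n`: the weight itself is $1/\sqrt n$.

Every result records its convention. Weights are normalized to mean 1
within a dataset before being treated as inverse variances — only their
ratios are meaningful, and the normalization is what makes all fits
invariant to a global rescaling of the weights (a tested invariant; REML is
not scale-free on its own). Two further calibrations give the proxies a
meaningful scale: pooled mortality rescales them to the binomial variance
of the crude pooled proportion, and weighted meta-regression estimates a
WLS dispersion factor from a pilot fit (with the intercept-only null model
calibrated by its own dispersion, so $R^2$ compares like with like). Under
a binomial null this yields omnibus rejection rates close to nominal
(3–4% observed at $k = 100$).

Records with fewer than two animals are kept but flagged; confidence
intervals for pooled proportions are clipped to $[0, 1]$ and reported in
percent.

## Prediction

`predict_outcome()` evaluates a fitted model at a named design: point
$x^\top\hat\beta$, interval $\pm 1.959964\sqrt{x^\top \Sigma x}$ — a
confidence interval for the *conditional mean*, matching the use of such
tables for planning; a new-study interval (adding residual $\tau^2$) is
available by flag. Two flags qualify cells:

* `extrapolated_follow_up`: a continuous value outside the range the model
  was fitted on. Follow-up enters linearly, so such cells assume the linear
  trend continues; the rendered table shows them in parentheses with a `*`.
* `stunning_window`: EF measured very early after reperfusion reflects
  myocardial stunning more than remodeling. EF predictions below a
  configurable threshold — default 72 h, an interpretation rather than an
  established constant — are withheld from the rendered report (shown as a
  dagger).

The three shipped scenarios (pig and dog 60-minute temporary LAD occlusion,
pig permanent LAD ligation) fix the design-defining moderators; the
remaining ones (sex "both", open chest, no co-medication or
immunosuppression, quality 5) are documented assumptions of the scenario
file, not properties of the designs.

`ols_association()` covers the auxiliary checks (ordinary least squares
with a t-test on the slope): correlating a study's control-arm severity
with its therapeutic effect, and IS/AAR with EF measured in the same study.

## The synthetic generator

`synthetic_config()` describes the population the analysis assumes: study
means $\mu_i = \beta_0 + \sum \beta x_i + u_i$, $u_i \sim N(0, \tau^2)$,
observed means $\bar y_i \sim N(\mu_i, \sigma_w^2/n_i)$, with the per-arm
SD reported as $\sigma_w$ *exactly* — this keeps $v_i = s^2/n$ transparent
for oracle tests; a chi-square "noisy SD" option exists but is off by
default. Deaths are $\mathrm{Binomial}(n, p)$ with $p$ a logistic function
of moderator effects plus optional logit-normal study noise.

Defaults mirror a ~165-comparison control-arm literature: intercept 49.8%
(the IS/AAR regime), $\tau^2 = 25$ points², arms of 5–15 animals with
within-arm SD 12 points, strongly unbalanced moderator marginals (74% dogs,
25% pigs, ~1% sheep; 88% temporary occlusions; 66% LAD), follow-up drawn
from typical values between 1 day and 4 weeks, ischemia 60 ± 20 min for
temporary occlusions, weight and age distributed per species, and
missingness rates of 4% (weight), 97% (age) and 60% (ischemia among
temporary occlusions) — the sparse-reporting pattern that motivates the
`add_separately` mechanism. Mortality defaults to 16.7% peri- and 5.2%
post-procedural at reference, with 8–35 animals per record and 15% of
records carrying a second sequential measurement.

Missingness is completely at random (no mechanism being described for the
real literature, MCAR is the neutral choice). Observed means are clamped to
$[0, 100]$ with a logged count; simulations are kept in regimes where
clamping does not trigger, because clamping distorts the normal model the
estimators assume.

What the generator does **not** emulate: correlations between moderators
(real design choices co-occur — minipigs are lighter, permanent occlusions
have no ischemia time beyond the structural link), publication-level
clustering of multiple arms, selective reporting, or non-normal outcome
distributions. Passing tests therefore validate the estimators under the
stated model, not the faithfulness of any real-data coefficient.

## Validation strategy and problem sizes

The test suite checks every estimator against an independent route:
closed forms (two-study $Q$ and $I^2$, equal-variance pooling), dense
grid searches of the restricted likelihood (25 instances at $k \le 8$,
$10^{-4}$ grid, agreement within $10^{-3}$), a brute-force WLS oracle,
reparameterization invariance of contrasts to $10^{-10}$, and the
independent `metafor` implementation (agreement to $\sim 10^{-6}$ on
$\tau^2$, $\beta$, SEs and omnibus p-values). Simulation studies use 500
datasets at $k = 165$, $\tau^2 = 25$ for recovery/coverage (each true
coefficient within 2 SE in $\ge 90\%$, intercept coverage 93–97%), 1000
null datasets at $k = 100$ for omnibus size (accepted band 3–8%), and 300
binomial replicates for mortality pooling (within $\pm 2$ points of a
16.7% truth in $\ge 95\%$). These sizes keep the whole suite under a
minute on one core while leaving Monte-Carlo error well inside the
acceptance bands.

## Known limitations

* No clustering by publication: multiple control arms from one publication are
  treated as independent comparisons (the data model records `study_id`, so
  a clustered extension is possible downstream).
* z-based inference is mildly liberal at small $k$; users wanting
  small-sample calibration should interpret borderline p-values
  accordingly.
* The mortality weighting scheme is a convention, not a likelihood; the
  binomial-scale calibrations give its results meaningful units but the
  proportions are not modelled as binomial outcomes (no exact zero-count
  handling, no logit link by default).
* $R^2$ is a ratio of boundary-constrained variance estimates and is
  volatile when the null-model $\tau^2$ is near zero; it is reported as a
  descriptive, not an inferential, quantity.
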