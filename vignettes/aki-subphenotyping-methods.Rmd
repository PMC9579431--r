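---
title: "Methods: risk-factor-pattern subphenotyping of AKI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk-factor-pattern subphenotyping of AKI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(akiphen)
```

# The problem and the model

Acute kidney injury (AKI) is detected from serum creatinine by the KDIGO
criteria, but identical creatinine trajectories can arise from different
mechanisms — nephrotoxic drug exposure, low renal reserve, or the
hemodynamic consequences of critical illness. `akiphen` subphenotypes AKI
patients by the *pattern of risk factors that drive their predicted
risk*, in three steps.

**Step 1 — additive risk model.** The probability of AKI is modeled with
a logistic generalized additive model

$$\mathrm{logit}\, P(\text{AKI}_i = 1) = \beta_0 + \sum_{b} \beta_b x_{ib}
  + \sum_{s} f_s(x_{is}),$$

where binary factors enter linearly and numeric factors through penalized
cubic-regression smooths $f_s$ whose wiggliness is chosen by GCV (REML is
available). Candidates first pass a univariable screen: a logistic fit on
a restricted cubic spline basis (3 knots at the 10th/50th/90th
percentiles, 2 degrees of freedom), kept when the likelihood-ratio p over
the spline terms (Wald z for binary factors) is below 0.2. Backward
elimination then drops the least significant term until all remaining
terms have p < 0.05; the severity score is forced to stay so the final
model remains severity-adjusted. The screen reports complete separation
explicitly and falls back to a ridge-penalized likelihood-ratio p rather
than trusting a divergent fit.

**Step 2 — attribution and clustering.** Each patient's predicted
probability is attributed to the selected factors with exact Shapley
values: for feature set $F$ with $|F| = p \le 15$, all $2^p$ coalition
values $v(S)$ are enumerated (ascending bitmask order, each computed
once) and

$$\phi_{ij} = \sum_{S \subseteq F \setminus \{j\}}
  \frac{|S|!\,(p-|S|-1)!}{p!}\,[v_i(S \cup \{j\}) - v_i(S)].$$

$v_i(S)$ estimates $E[f(X) \mid X_S = x_{iS}]$ from a background
population (the full cohort, so the base value $\phi_0$ is the
cohort-level expected risk). Two value functions are provided:

* *marginal* (default): the coalition's columns are imposed on every
  background row and predictions averaged;
* *empirical conditional*: the same substitution, with background rows
  weighted by a Gaussian kernel
  $\exp(-d_S^2 / 2\sigma^2)$ on the scaled Euclidean distance restricted
  to the coalition ($\sigma = 0.1$ on standardized features).

Both satisfy efficiency exactly — $\phi_0 + \sum_j \phi_{ij}$ equals the
predicted probability — because the coalition values telescope. The
marginal value function is the default because conditional weighting
spreads credit across correlated factors: when phenotype groups are
defined by dominant factors that co-vary, conditional attributions blur
exactly the per-factor contrasts the downstream clustering relies on
(in development this reduced planted-group recovery from near-perfect
to chance). Attributions are reported on the probability scale, so the
rows of the attribution matrix sum to predicted probabilities; the link
scale is available.

The attribution matrix, restricted to AKI patients, is embedded with
UMAP (Euclidean metric, 15 neighbors, minimum distance 0.1, 2 output
dimensions) and clustered with DBSCAN (ε = 1, minPts = 5; minPts follows
the common clustering-package default and is exposed as configuration).
The UMAP implementation is self-contained: exact k-nearest neighbors,
smooth-kNN bandwidth calibration to log2(k), fuzzy simplicial-set union,
spectral initialization, and sequential stochastic gradient descent over
the edge set with uniform negative sampling (compiled; seeded through R's
RNG, so embeddings are reproducible). Batched gradient updates were
tried first and rejected: they tear moderately elongated clusters into
islands that the sequential scheme keeps whole. Cluster separability is
validated with one-vs-rest linear SVMs: a stratified 0.8:0.2 split, cost
tuned on the training side by 3x10 repeated cross-validation maximizing
AUC over a log-spaced grid (2^-5 to 2^3; larger costs add nothing for
linearly separable clusters and dominate runtime otherwise), and the
tuned model scored on 2000 bootstrap resamples of the test side.

**Step 3 — outcome comparison.** With cluster membership as the only
predictor, the Naive-Bayes posterior of a categorical outcome reduces to
the (optionally Laplace-smoothed) conditional frequency P(outcome |
cluster); confidence intervals and pairwise two-sided p-values come from
2000 patient-level bootstrap resamples. Renal recovery and mortality are
also compared with Cox proportional-hazards models (Breslow ties,
delegated to the survival package; a hand-solved three-subject partial
likelihood pins the implementation in the tests). The severity-mortality
association is estimated per cluster by a logistic regression of death on
the restricted-cubic-spline basis of the peak-to-baseline creatinine
ratio, with a likelihood-ratio test against the intercept-only model;
clusters with fewer than 10 patients or a single-class outcome are
suppressed with a warning.

# Clinical classifiers

**KDIGO detection.** AKI is flagged at the first measurement at least
1.5-fold above the minimum creatinine over the preceding 7 days, or at
least 26.4 µmol/L above the minimum over the preceding 48 h (windows
half-open, rolling minima — the reading consistent with a moving
reference; both reference series are returned for audit). Baseline
creatinine is the first value after hospital admission. Staging uses the
peak-to-baseline ratio: stage 1 for [1.5, 2) or an absolute-criterion-only
episode, stage 2 for [2, 3), stage 3 for ≥ 3 or a peak ≥ 353.6 µmol/L;
any renal replacement therapy dominates as "3-RRT". Recovery is the first
post-onset measurement below 1.5 × baseline without ongoing RRT ("1.5
times below baseline" is read as < 1.5 × baseline; the alternative
reading, < baseline / 1.5, was considered and rejected as clinically
implausible for a recovery definition). Urine output is not used.

**Metabolic patterns.** Five profiles are assigned from paired
lactate/glucose measurements against cohort-level pooled quantiles
(linear-interpolation definition; measurement-level pooling, not
per-patient means): stress response (lactate ≥ median, glucose ≥ q75),
impaired metabolism (lactate ≥ median, glucose < q75), isolated
hyperglycaemia (lactate < median, glucose ≥ q75), isolated hypoglycaemia
(lactate < median, glucose < q25), baseline (lactate < median, glucose in
[q25, q75)). As published, the baseline profile spans only [q25, q50),
leaving [q50, q75) unassigned; this package closes the gap into the
baseline profile so the rule is a total partition, and treats "above" as
≥. Per-patient occupancy is a step function — each measurement's profile
holds until the next measurement, the last until ICU discharge, and the
pre-first interval is assigned to the first profile — normalized by ICU
length of stay; the dominant pattern is the argmax, ties broken in the
listed profile order.

# The synthetic cohort generator

Real cohorts of this shape are not publicly deposited, so the generator
is a first-class module that emulates the structure the pipeline assumes,
with full ground truth:

* **Covariates.** Seven factors mirroring a severe-pneumonia ICU cohort:
  four binary (a nephrotoxic antiviral exposure `lpv_r`, diabetes, the
  protective steroid `dexamethasone`, mechanical ventilation) and three
  continuous truncated-normal (baseline eGFR, APACHE score, FiO2).
* **Risk mechanism.** Additive on the logit scale with a shape library:
  linear, u-shape (centered quadratic), and saturating (logistic ramp,
  plateaued beyond about 1.5 standardized units so that shifted phenotype
  groups sit on flat regions). The intercept is calibrated by bisection
  so the mean simulated probability matches the target AKI rate (default
  0.40, the typical ICU figure) to 1e-4.
* **Planted groups.** Three phenotype groups (prior weights
  0.40/0.33/0.27) shift covariate distributions: group 1 is dominated by
  the drug exposure (prevalence ~0.82 inside, ~0.02 outside), group 2 by
  low eGFR without dexamethasone, group 3 by high APACHE with
  dexamethasone — echoing the three clinical phenotypes the pipeline is
  designed to find. Effect sizes were chosen once so that the groups are
  separable (one-way ANOVA F > 10 on the true logit at n = 300) and sit
  on the saturated regions of their risk curves; diabetes and mechanical
  ventilation are null factors that exercise the screen.
* **Trajectories.** Creatinine every 12 h: baseline log-normal (capped at
  150 µmol/L so a stage-2 peak cannot cross the 353.6 µmol/L stage-3
  threshold), ±3% measurement noise, a linear rise to a stage-determined
  peak (ratios drawn within [1.55, 1.95], [2.05, 2.90], [3.10, 4.50] for
  stages 1/2/3, kept clear of the stage boundaries) at an onset 1-6 days
  after ICU admission, then a plateau at ≥ 1.6 × baseline, or for
  recoverers a decay crossing 1.5 × baseline at an exponential recovery
  time (base hazard 0.10/day, group hazard ratios 1/1/1.6 — the third
  group recovers faster). By construction, scoring the trajectories with
  the package's own KDIGO functions reproduces the planted AKI status and
  stage for every patient, which the tests assert at 100%.
* **Metabolic series and outcomes.** Paired lactate/glucose every 4 h
  (measurement frequency is not standardized in practice; 4 h is a
  typical ICU sampling interval and is configurable) from group-specific
  log-normal regimes, with the severe group shifted into the
  high-lactate (impaired metabolism) region; hospital mortality 0.20 /
  0.25 / 0.55 by group among AKI patients, echoing the contrast structure
  such cohorts report.

**What passing tests do and do not show.** The generator draws covariates
with clean parametric marginals, exact group structure and independent
noise; real cohorts have heavier tails, informative missingness, drifting
baselines and unmodeled confounding. Recovery of planted groups therefore
demonstrates correctness of the pipeline's machinery, not a guarantee
that clinical clusters found on real data are mechanistically real.

# Numerical choices and limitations

* Collinearity pruning is removal-only (the published alternative of
  "merging" correlated features is not a defined operation); the greedy
  rule drops, from the worst pair, the feature with the larger mean
  absolute correlation to everything else.
* Yeo-Johnson exponents are fitted by grid search on [-3, 3] (step 0.05)
  with golden-section refinement to 1e-4. Binary features pass through
  untransformed. Transformation precedes imputation, so the imputation
  trees see symmetric inputs; the order is configurable in principle but
  fixed here for reproducibility.
* Bagged-tree imputation uses 25 unlimited-depth CART trees (minimum leaf
  5) per incomplete feature, mean/majority aggregation, surrogate splits
  for missing predictors.
* Hosmer-Lemeshow uses 10 equal-count risk groups and 8 df; AUC ties are
  handled by midranks; AUC confidence intervals use a 2000-replicate
  stratified bootstrap, the same bootstrap engine as the rest of the
  package.
* The univariable screen's spline p-value is a likelihood-ratio test
  (the Wald alternative for smooth terms is less stable at screening
  sample sizes).
* Exact Shapley enumeration is limited to p ≤ 15 features (2^15
  coalitions); beyond that the function stops and points to sampling
  approximations, which are out of scope.
* DBSCAN border points attach to the cluster of their first core
  neighbor in index order, making labels permutation-stable up to
  renumbering.
* **End-to-end recovery rate.** On the default cohort (n = 300, three
  planted groups), the full chain recovers ≥ 3 clusters with adjusted
  Rand index ≥ 0.7 in roughly 55-70% of seeded runs (mean ARI ≈ 0.75),
  not more. The shortfall is intrinsic to the pinned back end at this
  scale: with ~110-130 AKI patients, the stepwise selection's composition
  varies run to run (occasionally admitting a null factor whose discrete
  attribution gap splits a cluster, or dropping a marker whose omission
  bends the remaining smooths), and the UMAP layout itself is a
  stochastic optimization whose local minima can split one group. Runs
  that fail the 0.7 bar are almost always near misses (one group split in
  two, ARI 0.5-0.69) rather than failures to find structure.
* Test problem sizes (cohort n = 300, 20 end-to-end replicates, 200 Cox
  replicates, 500 screening replicates at n = 10,000) were chosen as the
  smallest scales at which the asserted statistical properties are
  stable.
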