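# akiphen

Risk-factor-pattern subphenotyping of acute kidney injury (AKI) in
intensive-care cohorts.

AKI is defined by a rise in serum creatinine (KDIGO criteria), but the
definition lumps together patients whose kidneys fail for very different
reasons. `akiphen` implements a three-step analysis that separates AKI
patients by *why* the model thinks they were at risk, rather than by their
raw measurements:

1. **Risk modeling.** Candidate factors are screened with univariable
   spline-logistic models (restricted cubic splines, 3 knots / 2 df; keep
   if p < 0.2), then fitted jointly in a generalized additive logistic
   model with penalized cubic-regression smooths. Backward selection keeps
   factors with p < 0.05; the severity score (APACHE) is always retained
   so the model stays adjusted for illness severity. Discrimination and
   calibration are summarized by the AUROC (midrank Mann-Whitney, with a
   stratified-bootstrap CI) and the Hosmer-Lemeshow test. Sensitivity
   analyses refit the smooths by LOESS local scoring and re-select
   features with a cross-validated lasso and a permutation-importance
   gated random forest.

2. **Attribution and clustering.** For every patient, the predicted AKI
   probability is decomposed into per-factor Shapley values
   φ<sub>ij</sub> by exact coalition enumeration over the selected
   features (2^p coalitions, marginal or empirical-conditional value
   function), so that φ<sub>0</sub> + Σ<sub>j</sub> φ<sub>ij</sub> equals
   the predicted probability exactly. The attribution matrix of AKI
   patients is embedded in 2-D with UMAP (Euclidean metric, 15 neighbors,
   min_dist 0.1) and clustered with DBSCAN (ε = 1, minPts = 5). Cluster
   separability is validated with one-vs-rest linear SVMs tuned by
   repeated cross-validation and scored on 2000 bootstrap resamples of a
   held-out split.

3. **Outcome comparison.** Clusters are compared on KDIGO severity
   (stage 3 split by the need for renal replacement therapy), renal
   recovery (creatinine < 1.5 × baseline without ongoing RRT),
   lactate-glucose metabolic patterns (five cohort-quantile profiles and
   per-patient occupancy times), and mortality, using Naive-Bayes
   posteriors with bootstrap confidence intervals and Cox
   proportional-hazards models.

Because real ICU cohorts of this kind are not publicly deposited, the
package ships a synthetic-cohort generator (`generate_cohort()`) that
plants phenotype groups, KDIGO-consistent creatinine trajectories,
metabolic regimes and group-specific recovery/mortality hazards with full
ground truth, so every stage of the pipeline is testable.

## Worked example

```r
library(akiphen)

cohort <- generate_cohort(generator_config(n_patients = 300, seed = 5))
res <- run_pipeline(cohort, pipeline_config(seed = 5))

res$selected
#> [1] "egfr"   "apache" "lpv_r"

round(res$evaluation$auc, 2)
#> [1] 0.76

table(res$labels)
#>  1  2  3
#> 48 33 27

res$profiles$defining_factor
#>        1        2        3
#> "apache" "apache"   "egfr"

gt <- cohort$ground_truth$group[res$shap$row_ids]
round(adjusted_rand_index(res$labels[res$labels != 0],
                          gt[res$labels != 0]), 2)
#> [1] 0.97
```

The model keeps the planted risk factors (baseline kidney function,
severity, and the drug exposure), the attribution space yields three
clusters in near-perfect agreement with the planted groups (adjusted Rand
index 0.97), and the cluster profiles point at the factors that set each
cluster apart: the severe cluster's high APACHE contribution, the
low-kidney-function cluster's eGFR contribution, and (ranked within the
profiles) the drug-exposed cluster's attribution to the exposure.

## Command line

A thin CLI over the package functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/akiphen.R", package="akiphen"))')" \
  run --synthetic --n 300 --seed 5 --out run_dir --svm
```
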