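---
title: "Methods: expert-weighted TOPSIS risk scoring and leakage-safe benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expert-weighted TOPSIS risk scoring and leakage-safe benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalrisk)
```

## The problem

Thalassemia carriers typically present with microcytic, hypochromic red-cell
indices — low mean corpuscular volume (MCV) and mean cell hemoglobin (MCH),
elevated red-cell distribution width (RDW) — while hemoglobin may be only
mildly depressed. Screening programmes in high-prevalence, low-resource
settings need a transparent way to (i) decide which of the many survey and
blood-count variables matter, (ii) turn them into a per-patient risk score,
and (iii) check that any machine-learning layer built on top of that score is
evaluated honestly. `thalrisk` implements that workflow for tabular survey
cohorts under a fixed 16-variable schema (demographics, hereditary flags,
socioeconomic context, and the complete blood count indices).

## Expert weighting: the Analytic Hierarchy Process

Experts compare criteria pairwise on Saaty's 1–9 scale; judgment $a_{ij}$
states how strongly criterion $i$ is preferred to $j$, with $a_{ji} =
1/a_{ij}$ and $a_{ii} = 1$. From the reciprocal matrix $A$ the package
derives weights by column normalization and row averaging:

$$a'_{ij} = \frac{a_{ij}}{\sum_i a_{ij}}, \qquad
  w_i = \frac{1}{n}\sum_j a'_{ij}.$$

Consistency is diagnosed through the weighted-sum vector $AW$, the
ratio-average eigenvalue estimate
$\lambda_{\max} = \frac{1}{n}\sum_i (AW)_i / w_i$, the consistency index
$CI = (\lambda_{\max} - n)/(n - 1)$, and the consistency ratio $CR = CI/RI$
with the standard Random Index table ($RI = 1.49$ for $n = 10$). $CR < 0.1$
is acceptable; `ahp_weights()` treats this as a gate and refuses to proceed
otherwise unless explicitly overridden, because weights from incoherent
judgments are not defensible in a clinical audit.

Two numerical choices deserve a note:

* **Exact reciprocals.** Published judgment matrices print reciprocals
  rounded to three decimals (0.333, 0.143). `build_matrix()` reconstructs
  the lower triangle as exact fractions from the upper-triangle judgments;
  the packaged normalized-matrix checks only pass with exact reciprocals,
  confirming that is how such tables are computed.
* **Ratio averaging, not the principal eigenvalue.** $\lambda_{\max}$ is the
  mean of the component ratios $(AW)_i/w_i$. The principal eigenvalue (via
  power iteration) is used in the test suite only as a diagnostic
  cross-check; the two agree to about two decimals on the packaged matrix.
  This estimator is scale invariant in $w$ and bounded below by $n$ for
  reciprocal matrices, both of which are asserted as properties.

## Per-patient scoring: TOPSIS

With weights $w$ in hand, each patient's criterion values are min–max scaled
to $[0,1]$, multiplied by $w$, and compared with the cohort's ideal (columnwise
maximum) and anti-ideal (columnwise minimum) profiles. Euclidean distances
$D^+$ and $D^-$ to the two profiles give the relative closeness

$$C = \frac{D^-}{D^+ + D^-} \in [0, 1],$$

which is 1 at the ideal profile and 0 at the anti-ideal. Patients are ranked
by descending closeness (ties broken stably by input order, so output files
reproduce) and stratified by fixed thresholds: closeness $\ge 0.66$ is High
Risk, $< 0.33$ Low Risk, Medium between. The 0.66 boundary belongs to High
and the 0.33 boundary to Medium; the package pins both decisions with tests
because published category tables are only reproducible once boundary
ownership is fixed.

All criteria are treated as benefit-direction (larger weighted value, closer
to the ideal), which is the literal reading of the ideal/anti-ideal
definitions above. Clinically one might argue MCV and hemoglobin should be
cost-direction for carrier risk; the scoring functions accept externally
supplied ideals, so a cost-direction analysis can be performed by passing
inverted profiles, but the default follows the benefit formulation.

A known reproduction limit: recomputing closeness from a published
normalized table and weight table does not reproduce the corresponding
published closeness magnitudes (the worked example's first entry evaluates
to about 0.66 rather than the printed 0.7064), indicating an unprinted
variant upstream of the printed tables. The package therefore validates its
closeness arithmetic against an independent straight-line oracle at 1e-12
and uses published closeness values only to check category assignment, where
agreement is exact (10/10).

## Feature relevance and fusion

Two complementary relevance scores are provided. The impurity score
delegates to a random forest and renormalizes the mean decrease in Gini
impurity so scores sum to 1. The univariate score is a variance ratio
$F_j = S_B/S_W$ (between-class over within-class sum of squares); the
default is the plain ratio, with a `df_adjusted` variant equal to the
classical one-way ANOVA F via the factor $(n-k)/(k-1)$ — both induce the same
ranking at fixed $n$ and $k$, which is asserted as a property — and a
binned mutual-information variant for users who prefer an
information-theoretic filter. A feature with zero within-class variance but
separated means scores `+Inf` and is flagged rather than erroring, since it
is maximally informative, not degenerate.

`combine_importance()` min–max normalizes each score table to $[0,1]$ and
averages them; constant score tables normalize to 0 by convention (they
carry no ranking information). The fusion accepts any two or more tables
over the same features, so an attribution-derived table can be fused in the
same way. Ties in the combined ranking break by schema order for
reproducibility.

## Leakage-safe benchmarking

The harness compares classifiers on the stratified risk labels under
repeated use of one rule: **everything data-dependent is computed inside the
training fold**. Per fold it derives the min–max extremes, TOPSIS ideals and
strata labels from training rows only; held-out samples are scaled with the
frozen extremes (clipped to $[0,1]$), scored against the frozen ideals, and
stratified with the same thresholds. Feature scoring and top-$k$ selection
likewise run on training rows. `audit_fold()` recomputes every frozen
quantity from the recorded training indices so tests can assert the absence
of leakage rather than trust it.

The `with_mcdm` condition multiplies the selected feature columns by their
AHP weights before training; `without_mcdm` leaves them unweighted. Fold
assignment is identical across conditions at a fixed seed, making the
comparison paired. Because the labels are a deterministic function of the
same features (closeness thresholding), held-out accuracy is expected to be
near ceiling — the package reproduces this circularity qualitatively
(a boosted model exceeds 0.9 accuracy on a default synthetic cohort of
1000 under 20-fold CV) and documents it as a property of the label
construction, not evidence of clinical validity.

Averaging for multiclass metrics is macro by default (robust to the strongly
imbalanced strata; micro available); the overall Matthews correlation uses
the generalized contingency-table form, which reduces to the familiar binary
formula for two classes. Zero-denominator conventions (precision, recall,
F1, MCC all 0, with a flag) are applied for degenerate all-one-class
predictions. Backends are delegated: `randomForest` for bagged trees and
`xgboost` for gradient boosting, behind a registry accepting user backends
via `register_model_backend()`; an ordered-boosting (CatBoost-style) backend
is not shipped because no R implementation is available to the package, and
requesting it raises an informative error.

## Attribution and statistical validation

Global attributions delegate to the boosting backend's native tree-SHAP
(`predcontrib`), with the additivity identity (base value plus attribution
sum equals the prediction margin) recorded per call. Local explanations use
a kernel-weighted local linear surrogate written in-package: Gaussian
perturbations scaled to the background spread, exponential kernel in scaled
distance (width $0.75\sqrt{p}$ by default), weighted least squares on
standardized offsets, top-$k$ coefficients reported with supports/opposes
direction tags. It is deterministic under its seed.

Attribution distributions are validated with `kruskal.test` across risk
classes and pairwise two-sided `wilcox.test` between features (exact when
both groups have at most 8 tie-free observations, normal approximation with
tie correction otherwise; the exact small-sample path is cross-checked in
tests against full rank-sum enumeration). P-value matrices are symmetric
with unit diagonal; attributions are compared signed by default with an
absolute-value option, Benjamini–Hochberg adjustment is off by default and
the correction tag is always recorded. The heatmap export maps p
monotonically to gray level (darker = more significant).

## The synthetic cohort generator

Because real survey cohorts of this kind are private, the generator is a
first-class, tested module rather than a test fixture. It emulates the
structure the framework assumes: a carrier prevalence of 0.15 (between
population carrier rates reported for Bangladesh and the 2/10 observed in
the packaged worked example), truncated-normal hematologic indices whose
parameters shift between groups — carriers at MCV mean 66 fL versus 82 fL
for non-carriers (sd 5), lower MCH and hemoglobin, higher RDW and RBC
count — and categorical marginals typical of a community survey, with family
history six-fold odds-enriched among carriers. Ranges are clipped to
plausible clinical bounds that contain every value in the packaged
10-record example. Truncated normals are drawn by inverse CDF, so draws are
exactly reproducible under the seed; each feature consumes its own derived
substream, so adding a feature never perturbs the others.

What the generator does **not** emulate: correlations among indices beyond
the group structure (real MCV, MCH and MCHC are algebraically linked through
Hct, Hb and RBC count), measurement error, site effects, missing data, and
any dependence of socioeconomic variables on outcome. Passing tests on
synthetic cohorts therefore demonstrate the pipeline's correctness and its
leakage discipline, not clinical performance on real data.

## Problem sizes and runtime choices

The test suite exercises generation at up to 10,000 records for moment and
prevalence checks, benchmarking at 300–1000 records with 3–20 folds, and
boosting at 20–60 rounds; these sizes give stable assertions in seconds
while preserving the study conditions (1000 records, 20 folds) for the
headline circularity check. The acceptance script's quantities are all
derived from the packaged 10×10 expert matrix and are deterministic.

## Known limitations

* Closeness magnitudes from published worked examples are not reproducible
  (see above); only the arithmetic and category assignment are certified.
* The benefit-direction default may be clinically counterintuitive for
  individual indices; pass custom ideals for cost-direction analyses.
* Strata produced by thresholding are strongly imbalanced on realistic
  cohorts; very small High-risk strata can make large fold counts
  infeasible (stratified folding requires each class to have at least k
  members).
* The local surrogate explains the model's probability surface near one
  instance; it is a diagnostic aid, not a causal statement.
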