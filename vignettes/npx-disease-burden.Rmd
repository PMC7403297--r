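---
title: "Differential NPX analysis, disease-burden model selection and composite scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential NPX analysis, disease-burden model selection and composite scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npxburden)
```

# The analysis problem

`npxburden` implements a complete analysis pipeline for targeted plasma
proteomics reported on the log2 Normalized Protein eXpression (NPX) scale,
built around a four-group observational design: participants with comorbid
post-traumatic stress disorder and mild cognitive impairment (PTSD–MCI),
with either disorder alone, and unaffected controls. Group membership is
operationalized by symptom-severity cutoffs — a PTSD Checklist (PCL) total
above 44 for probable PTSD (below 22 for asymptomatic), and a Montreal
Cognitive Assessment (MoCA) below 22 for MCI (above 26 for normal
cognition). The pipeline answers three questions per protein panel:

1. Which proteins are differentially expressed in each case group relative
   to controls, adjusting for age and race?
2. For the comorbid-group hits, is the single-disorder group's expression
   *intermediary* between controls and the comorbid group (a disease-burden
   pattern), *collapsed onto the cases*, or *collapsed onto the controls*?
3. How well does a multiprotein composite separate cases from controls, and
   does it track symptom severity?

# Preprocessing model

NPX is a relative log2 abundance: a difference of one NPX unit is a doubling
of concentration. Two platform artefacts are handled before modeling:

* **Left-censoring at the limit of detection (LOD).** Values flagged below
  the assay LOD are set equal to the LOD (`impute_lod()`). The package
  accepts one LOD per protein or one per protein and batch; the flag wins
  over the recorded value. Imputation runs *before* batch correction, since
  correction shifts the NPX scale away from the scale on which the LOD is
  defined.
* **Additive batch shifts.** Reference ("bridging") samples run in every
  batch estimate the shift: for each protein and batch the adjustment is
  the median NPX of that batch's bridging samples, subtracted from every
  sample in the batch (`bridge_correct()`). The even-count median is the
  mean of the two central values. The correction is idempotent and leaves
  within-batch differences untouched; bridging samples are excluded from
  all downstream statistics (`drop_bridging()`).

Technical-duplicate reproducibility is summarized by the per-pair Pearson
correlation across proteins (`duplicate_qc()`).

# Differential model

For each protein, ordinary least squares of normalized NPX on an intercept,
the case indicator, age (years, entered linearly and uncentered — centering
does not change the case coefficient) and race (binary Caucasian/Other):

$$\mathrm{NPX}_i = \beta_0 + \beta_1\,\mathrm{case}_i + \beta_2\,\mathrm{age}_i
  + \beta_3\,\mathrm{race}_i + \varepsilon_i$$

with classical (non-robust) standard errors and two-sided t p-values.
Significance is reported at two levels: nominal $P < 0.05$, and
Benjamini–Hochberg FDR $< 0.1$ applied **separately within each 92-protein
panel** — three independent families, which changes the calls relative to a
global adjustment. Covariates that are constant in a subset are dropped
with a warning, never silently. A constant response returns $\beta = 0$,
$p = 1$.

Consistency of the calls is probed by a Monte-Carlo split-half experiment
(`replicate_mc()`): 100 random 50/50 discovery/replication partitions,
stratified by arm (an odd arm's extra sample goes to discovery, a choice the
design leaves open — unstratified splits can empty an arm); a protein
replicates in a partition when both halves reach $P < 0.10$ with same-sign
coefficients. Age and race stay in the half-sample fits because the
criterion references the same differential model. One master seed generates
the partition sequence deterministically.

Cross-contrast structure is summarized by the seven-region overlap of the
significant lists (`overlap_sets()`), the count of union proteins whose
coefficients share a sign in all three contrasts (`sign_consistency()`),
and the Pearson correlation of the full 276-protein coefficient vectors
between contrasts (`beta_correlation()`).

# Disease-burden model selection

For a protein and a chosen "middle" group (PTSD-only, then MCI-only), three
codings of the subgroup factor compete, all adjusted for age and race:

| model | coding | interpretation |
|-------|--------|----------------|
| H1 | 1 = control, 2 = middle, 3 = comorbid (numeric) | middle group intermediary |
| H2 | 0 = control, 1 = middle or comorbid | middle group resembles cases |
| H3 | 0 = control or middle, 1 = comorbid | middle group resembles controls |

H1 enters as a numeric 1/2/3 linear contrast — the minimal reading of an
ordinal predictor in a linear model. Selection is by BIC in the Gaussian
profile form $n\log(\mathrm{RSS}/n) + k\log n$ with $k$ counting all
coefficients plus the error variance. Because the three models estimate the
same number of parameters, ranking by BIC is ranking by RSS; the package
asserts this equivalence in its tests as an internal consistency oracle,
and the additive likelihood constant (which differs between BIC variants)
cancels in every comparison. Models within $\Delta = 2$ BIC units of the
minimum (the conventional "barely worth mentioning" evidence band;
configurable) are reported as *comparable*, and exact ties take the
deterministic label order H1 < H2 < H3.

# Multiprotein composite score

Candidate features are the proteins below a p-value threshold (0.1 or 0.05)
in a contrast's differential table, selected on the **full** dataset before
cross-validation — deliberately reproducing the source protocol, with its
known optimism; the evaluation protects against overfitting of the model
coefficients, not of the feature list. The classifier is elastic-net
penalized logistic regression (binomial deviance — the endpoint is binary
and AUC is the metric): for each sample in turn, the model is tuned on the
other $N-1$ samples by stratified inner fivefold cross-validation
maximizing AUC over a mixing grid $\alpha \in \{0.1, 0.25, 0.5, 0.75, 0.9,
1.0\}$ and an automatic 50-value penalty path, refitted, and used to
predict the held-out sample. Features are standardized inside each training
set only. The AUC of the $N$ out-of-fold scores is the rank (Mann–Whitney)
statistic with ties counted half; the same scores are correlated with PCL
and MoCA. Severity correlations use the out-of-fold scores (not a full-data
refit); age and race are not offered to the classifier, since the feature
sets under evaluation are protein panels. A single-candidate model is
fitted by unpenalized logistic regression — the penalty-free limit of the
same model — because the penalized path requires at least two columns.

On very small inner folds the cross-validation library falls back from AUC
to binomial deviance; the tuner detects the measure actually used and
minimizes or maximizes accordingly, so small test fixtures remain valid.

# The synthetic cohort generator

`simulate_dataset()` generates datasets with exactly the structure the
analyses assume, so every stage is testable against known ground truth:

$$\mathrm{NPX}_{ij} = b_j + g_{\mathrm{group}(i),j} + 0.02\,(\mathrm{age}_i
 - 55.1) + 0.2\,[\mathrm{race}_i = \mathrm{Other}] + s_{\mathrm{batch}(i),j}
 + \varepsilon_{ij}$$

* Group sizes default to 34/39/27/81 (comorbid/PTSD-only/MCI-only/control),
  276 proteins in three equal panels.
* Baselines $b_j \sim N(4, 2^2)$ NPX; noise $\varepsilon \sim N(0, 1)$ NPX
  i.i.d. — NPX is already log2 scale and the analyses fit ordinary linear
  models, so Gaussian noise is the matching assumption. One NPX of noise is
  a realistic inter-individual spread for plasma panels.
* Group effects follow a per-protein *burden pattern*: H1 places the
  single-disorder groups exactly halfway (the least-informative reading of
  "intermediary"), H2 at the full effect, H3 at zero; in addition `n_diff`
  contrast-specific proteins shift one case group only, with random sign.
  Default effect size is 1 NPX (a doubling), a moderate, plausibly
  detectable effect at these group sizes.
* Age is Gaussian (mean 55.1, SD 7.78) truncated to [30, 80], matching the
  cohort's printed mean and spread; race is Bernoulli with P(Other) =
  28/181, the cohort margin. Their NPX effects (0.02 NPX/year, 0.2 NPX)
  are small nuisance signals for the adjustment to remove.
* Batch shifts are additive $N(0, 0.5^2)$ per batch and protein. Samples
  are shuffled and then assigned round-robin to (by default) two batches
  with three bridging samples each — the batch and bridging counts are not
  pinned by the study design, and six bridging replicates give six
  technical-duplicate pairs for QC. Bridging samples are noise-free copies
  of the baseline profile plus the batch shift, which makes exact recovery
  of batch-free values a testable property.
* The lowest 2% of each protein's values are flagged below LOD
  (configurable).
* PCL and MoCA are truncated Gaussians inside each group's admissible
  range (PTSD: PCL in (44, 85], mean 60, SD 9; asymptomatic: (17, 22),
  mean 19; MCI: MoCA in [0, 22), mean 18; normal: (26, 30), mean 28),
  drawn by inverse-CDF from a latent normal correlated (default r = 0.5)
  with the sample's realized aggregate protein signal — so severity
  correlations of the composite score have a planted target. Scores are
  continuous, not integer-valued; this keeps strict cutoff consistency
  exact and has no bearing on any downstream statistic, which treat both
  scores as continuous.
* A single seed drives all randomness through one generator; identical
  seeds give bit-identical datasets.

What the generator does **not** emulate: assay chemistry (qPCR counts,
plate layouts, hook effects), heavy-tailed or heteroscedastic noise,
protein–protein correlation beyond the shared group/covariate structure,
missing metadata, and attrition. Passing tests therefore certify the
statistical machinery under the design's own assumptions, not robustness
to violations of them.

# Numerical choices and degenerate inputs

* OLS is QR-based with the classical $(X'X)^{-1}$ covariance; agreement
  with an explicit normal-equations solve is asserted to $10^{-8}$ in the
  tests.
* Perfect fits (zero residual with a nonzero coefficient) give $p \to 0$
  naturally; exactly constant responses are detected (total sum of squares
  below $10^{-20}$) and returned as $\beta = 0$, $p = 1$.
* BH adjustment is the standard step-up procedure with enforced
  monotonicity, capped at 1; permutation equivariance and $q \ge p$ are
  tested properties.
* The AUC uses midranks, so all-tied scores give exactly 0.5.
* Exact BIC ties take the model order H1 < H2 < H3 for reproducible
  labels; tie candidates remain visible through the comparable set.
* All Monte-Carlo machinery (partitions, folds) derives from explicit
  seeds; rerunning any stage with the same seed reproduces its output
  byte-identically.

# Problem sizes

The shipped analysis scripts and tests run the full study-sized design
(181 participants, 276 proteins) for the end-to-end stages, and smaller
cohorts (a dozen proteins, 40–60 participants) for unit-level properties;
the Monte-Carlo experiment uses the design's 100 partitions and the
composite evaluation the full leave-one-out loop at study size. These sizes
were chosen to mirror the design the generator emulates.

# Known limitations

* The burden-model selection's accuracy at a 1-NPX effect and these group
  sizes is approximately 0.85–0.90, with errors concentrated in H1 (whose
  mean pattern lies between H2 and H3); calls for individual proteins
  should be read together with the comparable set, not as certainties.
* The split-half replication rate of a protein, conditional on one
  realized cohort, depends on that cohort's chance associations; rates for
  proteins selected *because* they were significant in the full sample are
  optimistic by construction.
* Candidate-feature selection on the full data (the reproduced protocol)
  inflates composite AUCs relative to selection inside the loop; the
  evaluation quantifies coefficient overfitting only.
* The pipeline models two races and one linear age term because that is
  the design it reproduces; other confounders (trauma load, comorbidity)
  are out of scope.
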