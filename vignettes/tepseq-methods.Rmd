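---
title: "Methods: models, parameters and design choices in tepseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in tepseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`tepseq` implements a tumour-educated-platelet (TEP) RNA-seq classification
pipeline together with the diagnostics that expose its central failure
mode: hospital-of-origin batch effects confounded with case–control
status. This vignette is the package's own account of the models it fits,
the parameters that matter, and the design decisions taken where more than
one reasonable choice existed.

## The synthetic cohort generator

Every downstream module is exercised on synthetic data, so the generator
is first-class, tested code rather than a fixture.

**Count model.** Counts are gamma–Poisson (negative binomial with
Var = μ + μ²φ). For gene *g* in sample *s*,

> log2 relative abundance: b_g + h_{hospital(s),g} + c_g·[s is a case]

where `b_g` is a baseline drawn uniformly on `baseline_log_mean_range`
(default 1–8 log2 units; module genes are drawn from the upper half so
that the planted structure survives coverage filtering, as abundant
platelet transcripts do), `h` is a per-hospital effect vector supported
only on the *platelet-activation module*, and `c` a per-gene case effect
supported only on the disjoint *biomarker module* (overlap is rejected —
the two effects would otherwise not be identifiable). Relative abundances
are renormalised within each sample and scaled by a log-normal sequencing
depth (`depth_mean` 2×10⁶ intron-spanning reads, `libsize_log_sd` 0.4).
Optional contamination multiplies the haemoglobin/lymphocyte marker means
of a random sample fraction by `contamination_strength`, mimicking
erythrocyte or leukocyte carry-over in platelet preparations.

**Calibration.** The default effect magnitudes,
`hospital_effect_sd = 0.33` and `case_effect_sd = 0.38` (log2 scale), were
chosen once by simulation so that the package's own mixed-model variance
decomposition, applied to ~300 samples from the default skewed three-centre
design, attributes on average ≈19 % of module-gene variance to hospital
and ≈14 % to case–control status — the regime reported for real
multicentre platelet cohorts — with the rest residual. They were then
frozen; no test outcome fed back into them.

**The confounded design.** `confounded_design()` is a stylised skew (one
hospital dominates the controls, the other two the cases;
chi-square p ≪ 0.001), not a reconstruction of any real cohort, whose
per-centre counts are not published. Ages are uniform on 35–70; stages are
drawn with probabilities (0.14, 0.48, 0.13, 0.25), the stage mix of a
screening-age breast-cancer cohort.

**What the generator does *not* emulate** — and hence what passing tests
do and do not show about real data: library-preparation chemistry,
splice-junction structure, gene–gene correlation beyond the two planted
modules, per-gene dispersion trends, and any mechanistic platelet biology.
The generator demonstrates that the pipeline behaves correctly *given* its
assumed data-generating process; it cannot certify performance on real
cohorts.

## QC cascade

Filters follow the strict boundaries of the published protocol, in the
order gene filter → detected-RNA filter → cross-correlation filter:

* a gene is removed iff its count is `< 30` in **more than** 90 % of
  samples (a gene at exactly the 90 % boundary is kept);
* a sample is removed iff it has fewer than 750 genes with ≥1 read;
* each sample's log2(cpm+1) profile is Pearson-correlated with the
  *median* profile of the remaining samples; samples below 0.3 are
  removed in a single pass.

The published pipeline does not state the cross-correlation statistic; the
median-reference form was chosen because it is robust and order-
independent, and the per-sample values are reported so the decision is
auditable. An optional gene-exclusion list (e.g. mitochondrially encoded
RNAs) is applied before any statistic.

## Subset-aware TMM and the no-leakage contract

Classical TMM chooses its reference sample and rescales factors using the
whole cohort, which quietly couples validation samples to training
normalisation. `tepseq` computes both from a designated subset (the
training partition): the reference is the training sample whose
upper-quartile relative expression is closest to the training mean; each
sample's factor is `2^(weighted trimmed mean of M-values)` against that
fixed reference (trim 30 % of M-values and 5 % of A-values per tail,
inverse-variance weights); factors are divided by the geometric mean of
the *training* factors. Consequently adding or removing non-training
samples cannot change any training factor, the reference, or the centring
— asserted exactly in the tests. With the subset set to the whole cohort
the factors agree with `edgeR::calcNormFactors` to machine precision,
which is the package's cross-check that the estimator is the classical
one.

One caveat is documented rather than hidden: the precision weights depend
weakly on absolute counts, so multiplying one sample's counts by a
constant moves its factor by a fraction of a percent even though every
M-value is unchanged. This is a property of the classical weighted
estimator, and the scale-invariance test asserts it at 2 % tolerance.

Expression is `log2(count / (libsize × factor) × 10⁶ + 1)`; the
pseudo-count of 1 keeps zero counts at exactly 0.

## RUV factor estimation and the dual-threshold rule

Candidate unwanted-variation factors are the first *k* right singular
vectors of the gene-centred expression matrix (default
`k = min(10, n − 1)`; the published pipeline does not state its *k*).
Scores for *any* sample set are obtained by projecting the
training-mean-centred expression onto the stored loadings — never by
re-fitting — which makes correction an exact orthogonal projection
(applying it twice changes nothing) and prediction a pure function of the
stored model and the new counts.

A factor is removed iff (a) its association p-value with case–control
status exceeds `p_class_threshold` (default 0.01) **and** (b) its p-value
with at least one nuisance variable is below `p_confounder_threshold`
(default 0.01). Binary or categorical variables (case–control, each
hospital versus the rest) use a two-sample t-test; continuous nuisance
variables (age, library size) use the t-test of the regression slope,
since a grouping t-test is undefined for them. Constant factors are
skipped with a warning. The rule's intended asymmetry is worth stating
plainly: a batch factor *correlated with the class* fails test (a) and is
retained, which is precisely why RUV cannot rescue a design in which
hospital and case–control status are confounded.

## Partitioning

Cases are stratified by stage and allocated 40 % / 30 % / 30 % to
training / evaluation / internal validation by largest-remainder rounding,
with remainder ties broken in that partition order. This rule reproduces
the published per-stage allocations for stages I–III and the training
total of 106 cases out of 266; no deterministic rule reproduces the
published stage-IV row, so the rule is documented instead of tuned.
Controls are matched to training and evaluation cases by greedy
nearest-age matching without replacement (case order randomised by seed),
one control per case; unmatched controls form the internal-validation
control arm.

## Classifiers

**PSO-SVM.** A global-best particle swarm (inertia 0.72, cognitive and
social accelerations 1.49 — the standard constriction values, which the
published protocol does not state) searches five dimensions: the two RUV
thresholds (0.001–0.2), the number of top-ranked genes (5–200, rounded at
evaluation), and log2 SVM cost (−5–10) and gamma (−12–2). Position updates
are clamped to the bounds; objectives returning non-finite values are
penalised with fitness 1 (= AUC 0). Per particle: select/remove RUV
factors at the particle's thresholds, re-rank genes on the corrected
training expression by absolute Welch t (ties broken by gene id), fit an
RBF-SVM on the training partition and score 1 − AUC on the evaluation
partition. The full protocol uses 100 particles × 10 iterations;
experiments in the test suite use a reduced 20 × 5 swarm.

Probabilities come from an explicit Platt layer — a logistic regression of
training labels on the SVM decision values — rather than libsvm's built-in
calibration, whose sigmoid can invert its sign on separable data.

**Elastic net.** Penalised logistic regression over α ∈ {0, 0.1, …, 1}
(experiments use a coarser 5-point grid) with the λ path taken from a fit
on all samples. Folds are class-stratified; per fold the model is fitted
on the remainder (optionally after down-sampling the majority class
*inside* the loop) and held-out predictions are pooled into a single AUC
per (α, λ). LOOCV is the k = n special case — pooling makes a per-fold AUC
unnecessary. The winning coefficients are refitted on all provided
samples. By default the elastic net sees TMM-cpm-log2 expression without
RUV correction; an RUV model can be attached.

**Prediction.** A stored model carries its normalisation context and RUV
model; new samples are normalised against the stored reference, projected
onto the stored loadings, and scored. Labels are not accepted by the
interface, which is what makes the blinded-validation contract
enforceable: `predict_blinded()` emits only `sample_id` and `score`, and
`link_and_evaluate()` joins true labels in a separate invocation.

## Evaluation

AUC is the normalised Mann–Whitney statistic (midranks, so ties count one
half). DeLong intervals use the placement-value variance with a normal
interval truncated to [0, 1]; under perfect separation the variance is
zero and the interval collapses to the point estimate. The implementation
agrees with pROC draw-for-draw, and its empirical coverage for a binormal
AUC-0.8 model at n = 50 + 50 is ≈0.94, measured with 2000 Monte-Carlo
replicates in the acceptance suite (2000 rather than a few hundred so that
the Monte-Carlo error is negligible against the asserted 0.92–0.98 band).
Confusion metrics call `score ≥ 0.5` a case (the boundary convention is
unspecified upstream; ≥ is documented here). Stage-stratified evaluation
reuses the same operations on each stage group's cases plus all controls.

## Confounding diagnostics

**Variance partition.** Per gene, `lmer(y ~ age + (1|hospital) +
(1|cancer))` by REML; the hospital and cancer shares are their variance
components, the age share is the variance of the fitted fixed-term
contribution, and the residual completes the sum to 1. Singular
(boundary) fits are flagged but reported — a zero variance component *is*
the boundary solution. At the calibrated defaults the batch-module genes
average ≈0.19 hospital share and the biomarker genes ≈0.14 cancer share
(recovered within ±0.05 in the acceptance suite at ~300 samples ×
200 genes).

**Differential expression.** Gene-wise NB GLMs with TMM offsets and
quasi-likelihood F-tests via edgeR — the tool the step is standard for —
with BH adjustment; designs `~ age + group + hospital` for the adjusted
case–control contrast and `~ age + hospital` for within-stratum hospital
contrasts. Under the null simulation the test's type-I error at α = 0.05
falls within 0.03–0.07 (2000 genes). Hand-rolling a dispersion-shrinkage
pipeline would have duplicated edgeR less reliably; the module surface
hides the engine.

**ComBat.** `sva::ComBat` as an intercept model (no biological covariates
retained) on TMM-cpm-log2 expression; a single batch is returned unchanged
with a warning. On a location-shift fixture the mean residual batch
F-statistic drops more than ten-fold.

**Enrichment and contamination.** Over-representation is the
hypergeometric upper tail of the selected/set overlap within a stated
universe (gene sets are user input, e.g. from GMT files); the default
confounded simulation reproduces the qualitative finding that the
platelet-activation module is enriched among hospital-contrast DE genes.
Contamination scores are mean normalised marker expression per sample.

## Numerical choices and degenerate inputs

* Largest-remainder ties: fixed partition order, so splits are
  deterministic given the seed.
* PSO integer dimensions are rounded only at evaluation; positions stay
  continuous.
* Welch statistics with zero pooled variance are set to 0 (ranked last).
* All-genes-removed, all-samples-removed, single-class partitions,
  single-batch ComBat, constant RUV factors and gene-mismatched
  prediction inputs raise explicit errors or warnings rather than
  propagating NaNs.
* Every stochastic step takes an explicit seed; experiments derive
  per-stage seeds from one master seed.

## Problem sizes used by the test suite

Simulated cohorts in the tests use 150–1000 genes and 48–300 samples;
the transfer experiments run 10 seeds of the full pipeline (reduced
20 × 5 swarm) on ~280-sample cohorts with 1000 genes; variance-partition
recovery uses ~300 samples × 200 genes; calibration checks use 2000
Monte-Carlo replicates (DeLong) and 2000 null genes (type-I error). These
sizes were chosen as the smallest at which the asserted statistical
properties are stable.

## Known limitations

* The generator's independence assumptions (genes conditionally
  independent given the planted modules) make classification *easier*
  than on real platelet data at matched variance fractions; headline
  internal AUCs on synthetic data are therefore not comparable to real
  cohort AUCs.
* The RUV iteration scheme of the published pipeline ("iteratively
  corrects") is not specified upstream; `tepseq` performs one selection
  and one projection per fit.
* Greedy nearest-age matching stands in for the published `matchControls`
  call, whose algorithm is not described upstream.
* `nb_glm_de` inherits edgeR's behaviour exactly; no attempt is made to
  reproduce any specific published FDR value, which would require the
  controlled-access cohort.
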