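# perirad

Peritumoral CT radiomics for predicting non-small cell lung cancer (NSCLC)
recurrence.

Roughly a third of surgically resected NSCLC patients relapse within a few
years. `perirad` implements, as a tested R pipeline, a transfer-learning
approach to estimating that risk from material available at diagnosis: a
segmented pre-treatment CT image and routine clinical variables. Its
scientific question is spatial — does the *peritumoral* region, the tissue
annulus just outside the tumor boundary, carry recurrence information that
the tumor core does not? The pipeline answers it by growing the tumor crop
outward in controlled steps and measuring how classification performance
responds.

## Method

For each patient the axial slice with the largest segmented tumor area is
selected and a tight bounding box around the tumor's extremal points is
dilated by *d* ∈ {0, 10, 20} px per side (sweeps extend to 60 px). Each
crop is pushed through an early pooling layer of a declared feature
extractor, giving a flattened texture feature vector x ∈ R^p. On the 80%
hold-out training set, features pass a zero-variance filter and then a
stability rule: over r = 5 rounds of stratified k = 10-fold partitions,
feature j survives if

    freq_j = #{(r,k) : AUC_j(removed fold) > 0.7} / (r·k)  ≥  f

with the exceedance frequency threshold *f* set per extractor. Selected
features are z-scored (training statistics), fused with the encoded
clinical covariates — missing entries completed by an iterative
random-forest (MissForest-style) scheme fitted on training rows — and a
linear SVM (C = 1) is trained. Performance is reported as AUC, accuracy,
sensitivity and specificity at the Youden-index threshold
(argmax J = Sens + Spe − 1), for repeated cross-validation on the hold-out
training set and once on the 20% hold-out test set.

Three ImageNet extractors are declared with their pooling geometries
(AlexNet pool2, 13×13×256 → 43264 features; ResNet152V2 second max-pool,
28×28×256 → 200704; InceptionV3 second max-pool, 35×35×192 → 235200); they
require an inference backend this package does not depend on. `mock_bank`,
a deterministic seeded 16-filter convolution bank with 8×8 average
pooling (1024 features), is a first-class extractor that exercises the
identical pipeline end to end.

Because real cohort data are not redistributable, the package ships a
synthetic cohort generator that emulates the study's statistical
structure: ellipsoidal tumors in CT-like slices, a 20 px peritumoral
speckle annulus whose amplitude carries a patient latent, clinical
covariates matching the study population's marginals, and recurrence
labels drawn from a logistic model over the rim and clinical latents at
~28% prevalence. A ground-truth table and an annulus oracle statistic make
recovery tests possible against the planted truth.

## Worked example

```r
library(perirad)

cohort <- generate_cohort(synthetic_config(n_patients = 144, seed = 20260926))
res <- run_pipeline(cohort, run_config(dilations = c(0, 10, 20),
                                       extractors = list(mock_bank = 0.8)))
res$report[, c("dilation_px", "n_selected_features", "train_auc", "test_auc")]
```

```
 dilation_px n_selected_features train_auc test_auc
           0                   0     0.636    0.561
          10                 205     0.809    0.696
          20                 120     0.802    0.819
```

On this cohort no radiomic feature survives selection at dilation 0 and
the model falls back to clinical covariates alone (hold-out test AUC
0.56). Growing the crop by 20 px — enough to cover the signal-bearing
annulus — admits texture features and lifts the test AUC to 0.82. A
28-patient test set is noisy, so the shipped analysis replicates over
five simulated cohorts (`analysis/04_evaluate_models.R` prints mean test
AUC 0.576 / 0.723 / 0.660 at dilations 0/10/20, a mean peritumoral gain
of +0.084), and the dilation sweep (`analysis/05_sweep_dilations.R`)
shows the mean AUC rising as the crop covers the rim and falling again
once it reaches patient-specific confounding structure — the behavior the
peritumoral hypothesis predicts.

The numbered scripts under `analysis/` run the whole study on simulated
cohorts — simulate, extract, select, evaluate, and the dilation and
pooling-depth sweeps — writing tables under `results/`.

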