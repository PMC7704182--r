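---
title: "Broad SVM ensembles for MRS metabolite panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Broad SVM ensembles for MRS metabolite panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Neuropsychiatric systemic lupus erythematosus (NPSLE) is hard to diagnose:
about half of affected patients have unremarkable structural MRI, and no
single laboratory marker is reliable. Multivoxel proton MR spectroscopy
(^1^H-MRS) quantifies metabolite concentrations in several brain regions at
once — N-acetylaspartate and its glutamate adduct (neuronal integrity),
choline compounds (membrane turnover), creatine species (energy
metabolism), myo-inositol (glial activation) and Glx (glutamatergic
transmission) — but individual features separate patients from controls
only weakly (single-feature AUCs of at most ~0.78 in the reference
cohort). The hypothesis this package operationalises is that a classifier
over the *joint* feature panel can discriminate where no single metabolite
can, on a cohort of only 39 subjects (23 NPSLE, 16 controls) with
missing-prone measurements.

The feature space is fixed by design: 9 regions (bilateral posterior
cingulate gyrus, dorsal thalamus, lentiform nucleus, paratrigonal white
matter, and the right insula) × 13 measures per region = 117 named
features (`mrs_schema()`).

## The BL-SVM classifier

The core model is a *broad learning system of support vector machines*:
instead of stacking layers that are tuned end-to-end by backpropagation,
it arranges SVM nodes in `L` layers of `m` nodes each, trains them
layer-wise, and widens the input as it goes.

Each node solves the usual max-margin problem: given training pairs
$(x_k, y_k)$ with $y_k \in \{-1, +1\}$, maximise the margin $2 / \lVert
\omega \rVert$ subject to $y_k(\omega^\top x_k + b) \ge 1$. We solve the
standard soft-margin relaxation (cost $C$, default 1, libsvm via
**e1071**), since a 39-subject clinical cohort is not separable in
general; the hard-margin program is recovered as $C \to \infty$. A node's
*confidence* on an input $x$ is

$$ y^{(l,i)}(x) = \tanh(\omega^\top x + b), $$

i.e. the tanh-squashed (kernelised) decision value: signed, strictly
inside $(-1, 1)$, with magnitude growing with distance from the
separating surface. Nodes in layer $l + 1$ receive the base feature
vector concatenated with the confidences of *all* earlier nodes,

$$ x^{(l+1)} = \bigl[x^{(1)},\; y^{(1,1)}, \dots, y^{(1,m)}, \dots,
   y^{(l,1)}, \dots, y^{(l,m)}\bigr]^\top, $$

so node $(l, i)$ consumes an input of dimension $d + (l-1)m$ — an
invariant asserted after every fit (`node_input_dims()`). To diversify
the ensemble, every node trains on its own bootstrap resample (size $K$,
with replacement) of the augmented training set; resamples that come out
single-class are redrawn, at most 100 times. Training is layer-wise and
convex per node — there is no backpropagation, and a fit is a pure
function of the data and the master seed (child seeds are derived per
node by a fixed counter scheme, so results do not depend on training
order).

```{r}
library(blsvm)
cohort <- generate_cohort(cohort_config(seed = 1))
model <- blsvm(cohort$table, cohort$labels, blsvm_config(seed = 1))
pred <- predict(model, cohort$table)
```

### Parameters that matter

* `n_layers = 5` — the published depth of the system.
* `nodes_per_layer = 8` — the source never states the width; 8 is this
  package's default, chosen small because each fold trains on only ~26
  subjects and every extra node adds an input dimension to all later
  layers. It is configurable, and the degenerate `L = 1, m = 1,
  bootstrap = FALSE` model is exactly one preprocessed SVM.
* `kernel = "rbf"` with width $\gamma = 1/(\text{input dim} \times
  \text{input variance})$ — the source invokes kernels without naming
  one; the RBF default follows the common convention of scaling the
  width with dimension, and a linear kernel is available.
* `cost = 1` — soft-margin cost; the published program is hard-margin,
  so no value is prescribed.
* `class_weight = "balanced"` — the per-class penalty is scaled by
  $n/(2 n_c)$. The hard-margin program treats the classes symmetrically;
  an unweighted soft margin on a 23-vs-16 cohort does not, and measurably
  shifts the decision boundary toward the majority class (we observed
  Youden-optimal thresholds consistently above the nominal 0). Balanced
  weighting restores the symmetry; `"none"` gives the plain penalty.
* Preprocessing: per-feature median imputation, then z-scoring, both
  learned from the training portion only and stored in the model — SVMs
  need complete, scale-comparable inputs, and learning these on all data
  would leak the test set.
* Aggregation: a subject's score is the *mean confidence of the final
  layer*, in $[-1, 1]$; the hard label is $+1$ when the score is
  strictly positive (an exact 0 maps to $-1$). The source does not state
  its aggregation rule; the mean is the simplest symmetric choice, and a
  terminal-SVM aggregator trained on the fully augmented input is
  available (`aggregation = "terminal_svm"`).

## Univariate screening

`screen_features()` applies a two-sided Mann-Whitney U test and a
directional ROC AUC per feature, dropping missing values feature-wise
(pairwise deletion preserves per-feature power; the report carries the
missing counts). `U` counts patient-over-control pairs with ties worth
1/2, and `AUC = U/(n_+ n_-)` — values below 0.5 are reported as-is, since
metabolites may move in either direction. The p-value uses the normal
approximation with tie and continuity corrections (exact enumeration
available for small untied samples). Matching the published analysis,
the significance filter is *raw* p < 0.05 with no multiplicity
correction; Benjamini-Hochberg is available behind `adjust = "BH"`.

## Recursive feature elimination

`rfe_rank()` fits a linear soft-margin SVM on standardised features,
scores each feature by the absolute weight of the separator (the only
canonical per-feature importance an SVM offers), removes the `step`
weakest, and repeats down to one feature. Each visited panel size is
scored by repeated stratified cross-validation *with the elimination
re-run inside every training fold*, so the score at a size never sees
its own test subjects — on permuted labels the selected panel scores at
chance, which the test suite checks. The returned panel sits at the
score-maximising size (ties go to the smaller panel), and a fixed size
can be requested instead (`select_panel(curve, size = 26)`), matching
the published pipeline's preset 26-feature panel. Constant features get
zero weight and leave first; importance ties break by schema order, so
the procedure is deterministic.

## The synthetic cohort generator

The study's raw concentration table is withheld, so the package ships a
transcription of the published per-feature group statistics
(`reference_params()`: mean ± dispersion per group, printed p and AUC,
and the 33-significant / 26-selected masks; every transcription
correction is listed in the provenance sidecar installed next to the
CSV) and a generator that emulates the study design from it.
`generate_cohort()` draws each feature independently per subject from a
Gaussian with the published group mean and an SD implied by the
dispersion reading:

* `dispersion_mode = "sem"` (default): the printed ± values are read as
  standard errors, SD = dispersion × √n with the reference group sizes
  (23/16). The source never says which reading is intended; the sem
  reading yields single-feature separations much closer to the printed
  single-feature AUCs than the sd reading, which is why it is the
  default. Both are supported.
* `effect_scale` moves the group means toward/away from their midpoint:
  0 gives an exchangeable null world (used for calibration tests), 1 the
  published separations.
* `missing_rate` applies cell-wise missing-completely-at-random masking
  (`inject_missing()`), never leaving a subject fully missing. The
  source names causes of missingness (motion, partial-volume effects,
  overlapping resonances) but no mechanism; MCAR is the weakest
  assumption and exercises the imputation path.
* Gaussians are not truncated at zero by default (concentrations are
  physical, but the published moments make negative draws rare);
  `clip_at_zero = TRUE` clips.

What the generator does *not* emulate: between-feature correlation (only
marginal moments are published — real regional metabolite panels are
strongly correlated), non-Gaussian tails, systematic (non-random)
missingness, and scanner or session effects. Passing performance bounds
in this surrogate world therefore demonstrates that the pipeline is
correct and well-calibrated, not that the published clinical performance
is reproduced on real data.

A caveat worth stating: several published features are strongly
heteroscedastic (control dispersion several times the patient
dispersion). In the surrogate world this places a tail of control draws
inside the tight patient cluster, and a margin-based classifier at the
fixed 0 threshold pays for it almost entirely in specificity — the
weakest of the three headline metrics in our experiments — even when the
ranking (AUC) is nearly perfect. The Bayes rule with the true moments
separates such cohorts perfectly; margin classifiers trained on 26
subjects do not recover its variance information.

## Evaluation protocol

`repeated_cv()` follows the published protocol: stratified 3-fold
cross-validation (folds balanced per class *and* overall to within one
subject), repeated — 50 times in the published analysis — with fresh
seeded fold draws; two thirds train, one third test. Held-out scores are
pooled within a repeat into one AUC (rank formulation, tie-aware) and
one confusion matrix at threshold 0, then summarised over repeats
(mean, median, quartiles, extremes). Pooling per repeat is this
package's choice — the source does not say pooled vs fold-averaged — and
is the stabler option with 13-subject test folds. Stratification is also
a package choice (the source says only "randomly divided");
`stratify = FALSE` restores the literal reading. The Youden-optimal
threshold is reported per repeat as a secondary statistic.

`run_pipeline()` chains generate → screen → panel → evaluate under one
master seed; `scripts/acceptance.R` uses it in spirit with 10 repeats,
and the shipped experiment sizes (10–20 repeats, 20–50 seeds in the
property tests) are chosen so the whole suite runs in a few minutes on
one CPU while keeping Monte-Carlo error well inside the asserted bands.

## Known limitations

* Synthetic validation only: the clinical table is withheld, so all
  performance statements are about the surrogate Gaussian world.
* Independent features understate the redundancy of real panels; RFE
  panel identities on synthetic cohorts are not comparable to the
  published 26-feature list (which the package ships as data instead).
* Binary classification only; no multiclass, no probability calibration
  beyond the tanh confidence.
* The fixed 0 threshold is a convention, not an optimised operating
  point; users wanting a specific sensitivity/specificity trade-off
  should threshold the returned scores themselves.
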