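---
title: "Uncertainty-aware detection of bilateral pulmonary opacities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-aware detection of bilateral pulmonary opacities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The clinical problem

Acute respiratory distress syndrome (ARDS) is diagnosed in part from a
radiographic criterion: bilateral pulmonary opacities on a chest film.
Bedside ICU radiographs are frequently of poor quality — rotated, underexposed,
crossed by tubes and leads — and readers often cannot commit to a
present/absent call. `opaxr` implements a three-class training scheme for
this setting: *absent*, *present*, and an explicit *equivocal* class for
films that cannot be read with confidence, so that a deployed model can defer
such films to a clinician instead of forcing a low-quality binary guess.

Throughout the package the class order is fixed: `absent` (index 0),
`present` (1), `equivocal` (2). All targets, predictions, and metrics follow
this convention.

## Annotation and adjudication

Each image carries three independent annotator labels from the five-level
vocabulary `bilateral`, `left_lung`, `right_lung`, `absent`, `equivocal`.
`adjudicate()` resolves a panel by three ordered rules:

1. **Majority.** If at least two annotators gave the identical label, it is
   the ground truth, mapped to the three classes as: bilateral → present;
   left/right/absent → absent (a unilateral opacity is not a bilateral one);
   equivocal → equivocal.
2. **Unanimous opacity.** Otherwise, if all three labels assert opacities
   somewhere (`bilateral`/`left_lung`/`right_lung`), the image is present.
3. **Disagreement.** Otherwise the three-way disagreement itself is the
   finding: equivocal.

Rule 1 precedes rule 2; the panel (left, right, bilateral) therefore resolves
through rule 2 to present, while (left, left, bilateral) resolves through
rule 1 to absent. The rules are total over all 125 ordered panels and
permutation-invariant, which the test suite verifies against an independent
rule-by-rule oracle.

## The uncertainty-aware loss

With softmax likelihoods $p_k$ over $K$ classes, training minimises the
generalized cross-entropy

$$H(t, p) = \sum_{k=1}^{K} -t_k \log p_k .$$

Four target schemes are provided (`loss_config()`):

* **`cross_entropy`** — one-hot targets.
* **`smoothed_ce`** — label smoothing $y_s = y(1-\alpha) + \alpha/K$.
* **`focal`** — $\sum_k -t_k (1-p_k)^{\gamma}\log p_k$ with $\gamma = 2$ by
  default; with one-hot targets this is the standard focal loss, and
  $\gamma = 0$ recovers the cross-entropy exactly.
* **`uncertainty_ce`** — the probability-target scheme: absent images get
  $(1,0,0)$, present images $(0,1,0)$, and equivocal images the soft target
  $(0.5, 0.5, 1)$. The equivocal entries encode that a present and an absent
  reading are equally plausible while the equivocal class keeps full weight.

The $(0.5, 0.5, 1)$ target deliberately does not sum to one. We implement it
literally: $H(t, p)$ is well defined for any nonnegative $t$, and over the
probability simplex it is minimised at $p = t/\sum_k t_k$, i.e. at
$(0.25, 0.25, 0.5)$ for equivocal images — the model is *taught* to cap its
confidence at 0.5 on films of this kind. A `normalize_equivocal_target`
switch substitutes $(0.25, 0.25, 0.5)$ directly; both variants share the
same minimiser, so the choice only rescales the equivocal examples' gradient
weight. Likelihoods are clipped at $10^{-12}$ before logs; this is far below
any reportable precision and keeps every loss finite.

## Model and training

The reference architecture, `small_cnn`, is a four-block convolutional
network: 3×3 stride-2 convolutions with 8/16/32/32 channels and ReLU, then a
flattened fully connected head. Convolutions are computed by im2col plus
BLAS matrix multiplication in compiled code, with an independent pure-R
engine kept as a reference implementation; the two are asserted equal in the
tests, and every analytic gradient is checked against central finite
differences. The whole training loop — class-balanced sampling,
augmentation, Adam — runs on one CPU core in seconds at the problem sizes
used here.

Two design points deserve explanation:

* **Flattened head rather than global average pooling.** Bilaterality is a
  *spatial* property — the same local texture on one side versus both sides —
  and global pooling integrates it away. Flattening the final 4×4×32 map
  keeps left/right evidence linearly separable and lets the desk-scale
  network converge within a 10-epoch budget.
* **Learning rate.** `train_config()` defaults to $10^{-4}$, the
  conventional rate for fine-tuning a pretrained backbone. The desk-scale
  recipes in this package train `small_cnn` from random initialization and
  use $10^{-3}$, Adam's canonical from-scratch default.

The full-scale DenseNet-121 configuration used on clinical imagery requires
a GPU tensor backend and externally supplied pretrained weights; this
package does not provide either, and `build_model("densenet121")` says so
rather than silently substituting.

Class imbalance is handled by a weighted random sampler with balanced class
weights $w_c = n/(K\,n_c)$, which simultaneously undersamples the majority
and upsamples the minority class. Splits are at the *patient* level
(`split_patients()`), never the image level, so no patient's films appear on
both sides of a split; a k-fold mode partitions patients into disjoint
folds.

Three schemes mirror common practice: `three_class` trains on all three
labels; `two_class` treats equivocal films as controls (absent);
`two_class_disregard_equivocal` removes them from training *and* testing —
note the latter evaluates on an easier, curated test set and is excluded
from head-to-head comparisons for that reason.

## Preprocessing and augmentation

The deterministic test-time transform is resize (align-corners bilinear) →
per-image histogram equalization (empirical-CDF mapping; a `minmax` rescale
is available as an alternative) → gamma adjustment `out = in^1.5`, which
darkens midtones and stretches the bright end where opacities live. An
`invert_gamma` switch applies `in^(1/γ)` for users who read the convention
the other way.

Training-time augmentation emulates bedside variability: rotation ±15°,
shifts ±10%, scale [0.9, 1.1], brightness/contrast ±20%, horizontal flip
p = 0.5, applied in that order with one seed per image. These ranges suit
full-length training runs; the short stochastic suites in the tests disable
augmentation, because at a 10-epoch budget this much input jitter dominates
the class signal rather than regularizing it.

## Evaluation

All metrics are computed for the *present* class: truth is binarized as
present-vs-rest, the score is the present-class softmax probability, and the
hard call is positive only when present is the argmax class — a predicted
equivocal therefore counts as a negative call. From the 2×2 table:
precision $TP/(TP+FP)$, sensitivity $TP/(TP+FN)$, specificity $TN/(TN+FP)$,
balanced accuracy $(\text{sens}+\text{spec})/2$, and the diagnostic odds
ratio

$$\mathrm{DOR} = \frac{\text{sens}\times\text{spec}}
{(1-\text{sens})(1-\text{spec})},$$

plus the F-score (harmonic mean of precision and sensitivity), AUROC
(Mann–Whitney form, ties counted half), and AUPRC (step-wise average
precision). A metric with a zero denominator is reported as `NA` —
undefined, distinct from zero — with a warning; a DOR with an empty error
cell is `Inf`, and an optional Haldane 0.5 correction is available.
Confidence intervals are percentile bootstrap over images (B = 1000 by
default); resamples on which a metric is undefined are skipped and counted.
Bootstrap resampling is at the image level; patient-level resampling would
also be defensible, and the choice is exposed by simply passing patient-level
aggregates if desired.

## Calibration

Predictions are binned into ten equal-width confidence bins ([l, u), last
bin closed). Confidence is the maximum softmax probability and correctness
is argmax-equals-truth; a `positive_class_only` switch instead bins the
present-class probability against the present event itself, which is the
convention to use when comparing models with different numbers of classes.
The Maximum Calibration Error is the largest |mean confidence − accuracy|
over non-empty bins — a worst-case measure, deliberately conservative for
clinical alerting. Empty bins are excluded rather than treated as 0/0.

## The phantom generator

`generate_phantom()` renders a body ellipse, two darker lung fields, bright
Gaussian opacity blobs strictly confined to the lung masks designated by the
opacity mode, bright line/rectangle occluders standing in for tubes and
devices, additive Gaussian noise, and a degradation control that collapses
contrast and drops a gray band across the film. Degradation at or above a
threshold (0.7) makes the intended truth equivocal. Separate seeded RNG
streams per stage guarantee that phantoms differing only in opacity mode
share their body, occluders and noise, so a bilateral phantom is brighter
inside each lung than its seed-matched opacity-free twin — an invariant the
tests assert.

`generate_dataset()` draws adjudicated classes from a configurable mix
(default 54% present / 23% absent / 23% equivocal, the long-tailed
prevalence of a septic ICU cohort), renders one phantom per image, and
simulates a three-annotator panel per image at a configurable error rate
(default 0.1, uniform over a plausibility-restricted confusion kernel —
e.g. a bilateral film may be misread as unilateral or equivocal, never as
cleanly absent). Because the mix describes *adjudicated* prevalences — that
is what a labeled cohort reports — the panel is drawn conditioned on
adjudicating to the intended class; panels still disagree internally on
roughly a quarter of images at the default error rate. Image quality is a
continuum: readable films draw degradation from [0, 0.6] and equivocal films
from [0.7, 0.8], so borderline films are genuinely ambiguous and equivocal
films keep their opacities partially visible. This matters for calibration:
if equivocal films were rendered as uniformly gray frames they would be
perfectly identifiable, and a model taught the 0.5 probability target would
be systematically *under*-confident on them.

What the phantoms do not emulate: anatomy (ribs, mediastinal structure,
diaphragm), pathology texture, scanner characteristics, or annotator-specific
bias profiles. Passing tests on phantoms therefore demonstrate that the
training, evaluation and calibration machinery behaves as specified — not
that any particular clinical performance level would be reached on real
radiographs.

## Interpretability

`grad_cam()` weights the last convolutional block's post-activation feature
maps by the spatial mean of the target-class score gradient, rectifies the
weighted sum, upsamples it bilinearly to the input size and normalizes by
the maximum (raw values are kept in an attribute). `occlusion_map()` slides
a constant-fill patch (default 16 px, stride 8, fill = image mean) and
records baseline-minus-occluded target-class probability, averaging
overlapping contributions per pixel: positive regions support the class,
negative regions confuse it.

## Radiology-note labeling

The rule-based note labeler mirrors the classic clinical-NLP pipeline:
`sectionize()` splits on colon-terminated headers (INDICATION, COMPARISON,
FINDINGS, IMPRESSION; anything before a header is "other");
`find_mentions()` locates nine screening keywords (ARDS, atelectasis,
consolidation, edema, effusion, opacity, infiltrates, pneumonia,
pneumothorax) with simple morphological variants; `classify_polarity()`
marks a mention negative or uncertain when a cue shares its clause, where
clauses are sentence segments delimited by scope-resetting conjunctions
("but", "however") and negation outranks uncertainty;
`assign_laterality()` takes the nearest descriptor in the sentence
(bilateral/bibasilar/both lungs; right; left). The note-level label for
bilateral opacities is positive when a positive parenchymal mention is
bilateral — or when positive mentions exist on both sides, a combination
rule that can be disabled; strictly unilateral or fully negated evidence is
negative; an uncertain or non-lateralized mention yields uncertain. Only
parenchymal keywords (opacity, infiltrates, consolidation, edema,
pneumonia, ARDS) count toward this label by default, impression-section
evidence outranks findings on conflict, and mentions in the
indication/comparison sections are ignored — they state the clinical
question, not a finding. `generate_note()` emits sectioned synthetic notes
with distractor sentences whose rule-based label provably equals an
intended target, giving the labeler a closed-loop template suite.

## Desk-scale study conditions

The stochastic suites run at sizes chosen to keep the whole suite quick on
ordinary hardware:

* *Parameter recovery*: 600 easy phantoms (64 px; exact annotators, no
  occluders, opacity-free negatives, mild degradation), 10 epochs,
  held-out patient-level AUROC ≥ 0.95 required in at least 4 of 5 seeds.
* *Calibration ordering*: one fixed cohort of 1,200 phantoms with 20%
  equivocal films; the three-class probability-target model and the
  two-class cross-entropy model are trained in five paired seeded runs of
  12 epochs and their max-class MCEs compared. The suite requires the
  probability-target model to win at least 4 of 5 pairings; see the
  limitations below for how this check behaves on phantom data.
* *Properties with closed-form answers* (adjudication, metric formulas,
  loss identities, binning arithmetic) are tested exhaustively or at
  tolerance 1e-9 to 1e-12.

## Known limitations

* **The calibration-ordering advantage of probability targets does not
  transfer to desk scale, and the corresponding check in the test suite is
  expected to fail.** Three effects compound. First, a ~60k-parameter CNN
  trained on a few hundred images is underfit, and an underfit
  cross-entropy model converges toward population-calibrated
  probabilities: the two-class baseline here shows MCEs around 0.1–0.25,
  leaving little miscalibration for soft targets to remove — the
  clinical-scale version of this comparison involves a heavily pretrained,
  overparameterized backbone whose overconfidence is the thing being
  fixed. Second, the equivocal probability target caps confidence at 0.5
  by design, so whenever equivocal films are learnable at better than
  ~50% accuracy the three-class model is genuinely *under*-confident in
  its mid-range bins. Third, MCE is a maximum over bins, and the
  three-class model spreads its confidence over more (hence sparser) bins,
  each of which can contribute a large sampling-noise gap (a 3-image bin
  can single-handedly set the MCE). The comparison machinery is provided
  and the paired check is kept unmodified; `scripts/acceptance.R` reports
  the per-scheme median MCEs and the paired win fraction so the behaviour
  is measured rather than asserted.
* The equivocal probability target's confidence cap is a design property:
  on a dataset whose equivocal films are trivially recognizable, the
  three-class model will look under-confident by max-class calibration.
* MCE, as a maximum over bins, is noisy below a few hundred test images;
  comparisons at smaller sizes should prefer more bins' worth of data, not
  fewer bins.
* The note labeler is a faithful rule-based skeleton (negation, uncertainty,
  laterality, section precedence), not a replica of any full clinical
  phrase inventory; its guarantees are stated over its own template
  language.
* Checkpoints serialize parameters as JSON — portable and diff-able, but
  not space-efficient for large models.
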