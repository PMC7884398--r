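---
title: "Classifying renal tumors on multiparametric MRI with SOM fingerprints and LVQ"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying renal tumors on multiparametric MRI with SOM fingerprints and LVQ}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(somlvq)
```

## The problem and the model

Sarcomatoid differentiation in renal cell carcinoma (sRCC) carries a
markedly worse prognosis than RCC without sarcomatoid components
(nsRCC) and changes management, but renal masses are rarely biopsied
before surgery, so a non-invasive imaging marker is clinically
valuable. `somlvq` implements a voxel-wise approach to this differential
diagnosis on four co-registered MRI sequences — T2-weighted (T2W),
unenhanced fat-saturated T1-weighted (T1W), and arterial- and
venous-phase contrast-enhanced T1-weighted (T1W-CEart, T1W-CEven) — in
three stages:

1. **Intensity calibration and normalization.** Each tumor voxel's T2W
   intensity is divided by the mean T2W intensity of the subject's
   contralateral normal renal cortex; the three T1-family intensities
   are divided by the cortex mean on unenhanced T1W. Because every
   global multiplicative scanner gain cancels in these ratios, voxel
   intensities become comparable across vendors and protocols. The
   calibrated values are then variance-normalized channel-by-channel
   with the mean and population SD of the pooled training + validation
   tumor voxels; the same frozen statistics are applied to test-cohort
   voxels.

2. **Self-organizing map fingerprinting.** A 9×9 Kohonen SOM is trained
   on the pooled 4-channel training voxels, quantizing the continuous
   intensity space into 81 "neurons", each a 4-parameter MRI phenotype.
   (The lattice size reflects the design argument that three intensity
   levels per channel suffice: 3⁴ = 81 phenotype combinations.)
   Counting each tumor voxel's best matching unit (BMU) and
   max-normalizing the counts yields the tumor's 9×9 *activation map* —
   a 2-D fingerprint of its composite MRI phenotype that a radiologist
   can inspect alongside the classifier.

3. **LVQ classification.** The 81-dimensional flattened activation maps
   are classified by a learning vector quantizer (LVQ1): one labeled
   prototype per class, initialized at the class means, moved toward
   same-class examples and away from other-class examples with a
   constant learning rate. Classification is nearest-prototype
   (Voronoi) with sRCC as the positive class.

Model selection follows the training–validation–testing discipline:
leave-six-out cross-validation over the combined training + validation
cohort (C(24,6) = 134,596 splits at full scale), a dual accuracy
threshold on both sides of each split, an optional restriction to
class-balanced splits, and a single finalized model evaluated once on
held-out test subjects.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| SOM lattice | 9 × 9 | neurons | 3 levels × 4 channels = 81 phenotypes |
| SOM neighborhood | bubble | – | all neurons within the radius get the full update |
| SOM learning rate | 0.2 | – | initial value; inverse-time decay |
| SOM radius | 1.0 | lattice units | initial bubble radius (Chebyshev); inverse-time decay |
| SOM iterations | 1,000,000 | draws | sequential updates, sampling voxels with replacement |
| LVQ learning rate | 0.001 | – | constant; the selected operating point |
| LVQ epochs | 1000 | – | with the loss curve recorded per epoch |
| CV holdout | 6 | subjects | leave-six-out over 24 training+validation subjects |
| Selection threshold | 83 | % accuracy | applied to both sides of each split |

Both SOM schedules use inverse-time decay,
`value(t) = value0 / (1 + t/(T/2))`. The neighborhood function and
decay schedule are fixed to the conventional defaults of widely used
minimalist SOM implementations; alternatives (Gaussian neighborhoods,
batch training) are deliberately out of scope.

## Numerical conventions

* **Population SD** (divide by *n*) everywhere in channel statistics,
  so that normalize-refit-normalize is a fixed point.
* **Row-major, 0-based neuron indexing** shared by the codebook,
  activation maps, the CSV on disk, and the LVQ input vectors: neuron
  *n* sits at lattice position `(n %/% 9, n %% 9)`.
* **Ties break low**: BMU lookup returns the smallest index among
  equidistant neurons; LVQ prediction returns the earliest-inserted
  prototype.
* **Max-normalization per map**: normalized hits are
  `raw_hits / max(raw_hits)`, so every valid map has exactly one neuron
  at 1.0 and an all-zero map is undefined (empty voxel tables are
  rejected rather than silently producing one).
* **Differential neurons** are ranked by the difference of per-class
  hit *fractions*, not their ratio, which stays defined on neurons one
  class never visits.
* **Total-cohort denominators** for the reported rates: accuracy, FPR
  and FNR all divide by the cohort size, so
  accuracy + FPR + FNR = 100 exactly. This departs from the usual
  per-class FPR/FNR and is applied consistently; PPV/NPV use their
  standard definitions and are flagged (not thrown) when undefined.
* **Degenerate inputs** fail loudly: non-positive cortex means,
  non-finite tumor intensities (reported with voxel coordinates),
  non-binary or empty masks, grids that disagree in shape or spacing,
  zero-SD channels, and single-class LVQ training are all errors.
* All floating-point model artifacts are serialized with 17 significant
  digits, which round-trips IEEE doubles bit-exactly.

## What the phantom generator emulates — and what it does not

No patient images ship with the package; every pipeline stage is
exercised on synthetic phantom cohorts instead. Each phantom subject
has four co-registered volumes on one grid (default 64×64×32 at 2 mm
isotropic), an ellipsoidal tumor and a disjoint ellipsoidal cortex,
per-subject multiplicative scanner gains (one for T2W, one shared by
the T1 family — mirroring the single unenhanced-T1 cortex reference
that calibrates all three), additive Gaussian noise, and tumor voxels
drawn from class-specific mixtures of phenotype subpopulations defined
on the calibrated scale (cortex ≡ 1):

* **sRCC** is dominated (weight 0.85) by a single tight, poorly
  enhancing subpopulation — hypointense on all three T1-family
  channels — plus a minor T2-bright component. Its activation maps are
  therefore sparse: after long SOM training, most sarcomatoid hits
  concentrate on a handful of neurons.
* **nsRCC** mixes four broader subpopulations that enhance avidly on
  the contrast channels, plus a low-weight, very broad
  necrotic/hemorrhagic component that overlaps the poorly enhancing
  region. Its maps are correspondingly busier.

These choices encode the qualitative contrasts the method exploits
(T1-family hypointensity of sarcomatoid tissue; heterogeneous, avidly
enhancing non-sarcomatoid tissue; busier nsRCC fingerprints) with
magnitudes chosen for testability. The mixture concentration behaviour
is worth noting: with short SOM training, neuron allocation stays
roughly proportional to class mass and both classes light up similar
neuron counts; the sparse-vs-busy asymmetry only emerges at roughly
10⁵ sequential updates and is decisive at the default 10⁶ — one
phantom run showed 6–8 active sarcomatoid neurons against 34–39
non-sarcomatoid ones.

The generator does **not** simulate MRI physics (relaxometry, k-space,
bias fields, partial-volume effects, motion), registration error,
anatomical kidney shapes, or clinically calibrated noise levels — the
pipeline only ever sees masked voxel sets, so tumor shape realism is
irrelevant downstream, but a pass on phantoms demonstrates the
machinery, not clinical performance. Conversely, gains and calibration
interact exactly as in real multi-vendor data, so the end-to-end
gain-invariance of the pipeline is tested faithfully.

Recorded tumor volumes equal the realized mask volume (voxel count ×
voxel volume), so manifests and masks agree exactly by construction.

## Design choices on genuinely open points

* **SOM training cohort.** Published descriptions of this approach
  differ between training the SOM on the base 16-tumor cohort and on an
  augmented 18-tumor cohort. The pipeline trains the SOM (and the LVQ,
  and the channel statistics) on whatever the manifest tags `training`;
  augmentation is expressed as manifest rows rather than special-cased
  flags, and both configurations are therefore available.
* **Codebook initialization** samples data rows (seeded) rather than a
  fixed box: every later update is a convex step toward a data point,
  so trained codebooks provably stay inside the data bounding box.
* **Loss for the LVQ curve** is the training-set misclassification
  ratio after each epoch; validation accuracy is reported separately by
  the evaluation stage, leaving the learning-rate/epoch choice to model
  selection rather than hard-coding it.
* **Subsampled cross-validation.** The exhaustive 134,596-split
  enumeration is supported, but the default is a seeded uniform
  subsample (100 splits) because every split trains an LVQ;
  combinations are materialized by lexicographic unranking, so the
  subsample is deterministic and reproducible without enumerating the
  full stream.
* **Leakage control.** Channel statistics refuse any voxel table tagged
  with the test cohort; the pipeline's provenance log records the exact
  subject sets that entered the statistics pool, SOM training, LVQ
  training and cross-validation, and the test suite asserts test
  subjects appear in none of them. A subject mislabeled in the manifest
  itself is outside what the package can detect — cohort tags are the
  single source of truth.

## Problem sizes used in the test suite

Unit and property tests run on reduced conditions chosen to keep the
suite fast while leaving each property's mechanism intact: phantom
grids of 32³–48×48×24 voxels, cohorts of 2–3 subjects per class per
cohort, SOM runs of 10⁴–2×10⁵ iterations. The end-to-end discrimination
check runs the full default conditions: 8+8 training, 3+3 validation,
5+5 test subjects and the 10⁶-iteration SOM, across three seeds. The
map-sparsity property uses 2×10⁵ iterations, the smallest scale at
which the concentration asymmetry is reliable (see above).

## Known limitations

* Only NIfTI-1 volumes are accepted; DICOM conversion, inter-sequence
  registration, and tumor/cortex segmentation are upstream of this
  package (masks are inputs, assumed on the T2W grid).
* One bubble-neighborhood SOM variant and one LVQ variant (LVQ1);
  no LVQ2/3, generalized LVQ, probabilistic outputs or ROC analysis.
* The permutation-null behaviour of cross-validation is only unbiased
  on class-balanced splits; unbalanced training sides carry a known
  below-chance bias (the noisier minority prototype loses queries to
  the majority), which is a property of small-sample CV design, not of
  this implementation.
* Phantom defaults are calibrated for testability, not fitted to
  clinical data; headline accuracies on phantoms say nothing about
  accuracy on patients.
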