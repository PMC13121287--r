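---
title: "Label-guided self-distillation for coronary calcium scoring: methods and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-guided self-distillation for coronary calcium scoring: methods and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the training procedures, the numerical
design choices, and the limits of the desk-scale experiment shipped with
`cacpipe`. It states assumptions and derivations; it makes no empirical
claims beyond what the test suite and `scripts/acceptance.R` compute.

## Problem and pipeline

Coronary artery calcium (CAC) scoring quantifies calcified plaque in
cardiac CT and maps it to a cardiovascular risk category. `cacpipe`
implements a three-stage pipeline:

1. **Feature extraction** — a Vision Transformer (ViT) backbone pre-trained
   with self-distillation (DINO), optionally *label-guided* (DINO-LG);
2. **Slice classification** — a linear probe on frozen backbone features
   flags slices likely to contain calcification;
3. **Segmentation and scoring** — a U-Net labels calcified pixels per
   artery (RCA, LAD, LCA, LCX) on the flagged slices only, and the Agatston
   score is computed from raw attenuation.

All stages are implemented in base R (matrix algebra over BLAS). The
package ships a synthetic chest-CT phantom generator so the full pipeline
is exercisable end to end on one CPU without any external data.

## Intensity normalization

Raw Hounsfield units (HU) are shifted by the soft-tissue reference
(1024 HU) and min–max normalized per slice,

$$ I_{norm} = \frac{I - I_{min}}{I_{max} - I_{min} + \varepsilon}, \qquad
   I_{final} = 2 I_{norm} - 1, \qquad \varepsilon = 10^{-7}, $$

giving network inputs in $[-1, 1]$. Conventions: a constant slice maps to
all $-1$ (zero numerator; $\varepsilon$ only guards the division), and the
raw HU slice is always retained alongside the normalized values because
**Agatston scoring must read true HU, never normalized intensities**
(`normalize_slice()` enforces this by construction; `score_patient()` takes
the raw volume).

## Self-distillation (DINO) and label guidance

A student and a teacher network share one architecture: ViT trunk plus a
projection head (3-layer MLP, $\ell_2$-normalized bottleneck, prototype
layer of $K$ columns). Per step each slice is expanded into $V$ augmented
views: 2 *global* crops (area ratio 0.4–1.0) and $n$ *local* crops (area
ratio 0.05–0.4). The teacher sees only the global views. With teacher
output distributions $P_t = \mathrm{softmax}((g_t - c)/\tau_t)$ (centered
by $c$, sharpened by $\tau_t$) and student log-softmax $\log Q_s$ at
temperature $\tau_s$, the loss is the cross-entropy averaged over all
(teacher view, student view) pairs with the same-view pair excluded:

$$ \mathcal{L} = \frac{1}{|\mathcal{P}|} \sum_{t \in \{1,2\}}
   \sum_{s \ne t} H(P_t, Q_s). $$

After each optimizer step on the student, the teacher follows by
exponential moving average with cosine-ramped momentum, and the center
follows the teacher's batch-mean logits:
$c \leftarrow m_c\,c + (1 - m_c)\,\bar g$. The two collapse modes this
guards against are the uniform distribution (countered by sharpening,
$\tau_t < \tau_s$) and a one-hot prototype (countered by centering).

**Label guidance (DINO-LG).** For slices with an annotation mask, 4 of the
local crops are *guided*: the crop's anchor pixel is drawn uniformly from
the mask foreground and the square crop is clamped (shifted, never shrunk)
so it always still contains the anchor. Labeled slices therefore produce
2 global + 8 random local + 4 guided local views; unlabeled slices produce
2 + 8. The training log records both bookkeeping definitions of the
effective guided ratio — guided crops among *all* crops and among
*labeled-slice* crops — because the two are genuinely different quantities
and published descriptions have used both.

Augmentations are the medical stack: horizontal/vertical flips (p = 0.5),
3×3 Gaussian blur, ±40 % brightness/contrast jitter, sharpness adjustment
(factor 1.5, p = 0.8), additive Gaussian noise. Solarization and
hue/saturation transforms are deliberately absent: they are RGB-specific
and meaningless for CT.

## Numerical design choices

These choices are implementation decisions of this package, made for
conditioning at small model widths; each is testable and tested.

* **Fixed 2-D sin–cos positional embeddings** (half the channels encode
  rows, half columns) instead of learned embeddings, so global and local
  views of different grid sizes share one embedding function without
  interpolation backprop.
* **Fan-in-scaled initialization** ($\sigma = 1/\sqrt{\text{fan-in}}$) for
  trunk and head. Blanket small-constant initializations leave attention
  uniform and the class token input-independent at the micro widths used
  here.
* **Unit-norm prototype columns**, renormalized after every optimizer step
  and excluded from weight decay — an explicit-renormalization version of
  the weight-normalized prototype layer. Prototype logits then live on a
  cosine scale, so sharpened teacher targets carry signal instead of
  flattening under centering.
* **Desk teacher temperature 0.005** (`desk_profile()` only): the upstream
  default $\tau_t = 0.04$ is tuned for tens of thousands of prototypes at
  full ViT scale; at 128 prototypes and embedding width 48 the logit spread
  is much smaller and 0.04 yields near-uniform teacher targets. Library
  defaults in `dino_config()` keep the reference value.
* **Probe feature standardization**: `train_classifier()` standardizes
  features column-wise with training-set statistics (stored on the head,
  re-applied at prediction). Frozen-backbone embeddings have small,
  backbone-dependent scales; the probe's few optimization steps need
  unit-scale inputs.
* **Argmax ties** in segmentation resolve to the lowest class code, so
  ties over background stay background.
* **AdamW** with decoupled weight decay applied to weight matrices only
  (never biases, gains, or the prototype layer), global gradient-norm
  clipping at 3, cosine learning-rate schedule with linear warmup.

## Agatston scoring

Per slice, candidate pixels carry a non-background segmentation label *and*
raw attenuation ≥ 130 HU. Eight-connected components are formed per artery
class; components under 1 mm² are discarded; each surviving component is a
lesion with area $A_i$ (mm²) and density weight $D_i$ from its peak HU:
1 (130–199), 2 (200–299), 3 (300–399), 4 (≥ 400). The score is

$$ \text{Agatston} = \sum_i A_i \cdot D_i . $$

Note the classic 3 mm slice-thickness normalization factor is deliberately
**not** applied — the implemented formula is exactly the area-times-weight
sum above. Risk categories: low 0–10, moderate 11–100, high 101–400, very
high > 400 (for fractional scores the bin edge is inclusive on the left
category).

One-vs-rest reporting conventions: recall and sensitivity (true positive
rate) are the same quantity and are emitted as equal columns; published
tables that list different values for the two are internally inconsistent
under standard definitions. Metrics with zero denominators are reported as
`NA`, never coerced to 0.

## The phantom: what it emulates, and what it does not

`generate_patient()` builds a chest-like 2-D/3-D scene per slice: air
background, soft-tissue body ellipse, rib-like bone ring with per-patient
phase jitter, z-varying lung fields, a spine block, and a central heart
region in which compact calcified lesions are rasterized with exact pixel
counts, fixed artery quadrants (RCA upper-left, LAD upper-right, LCA
lower-left, LCX lower-right), and HU drawn inside a chosen density bin.
Construction-time ground truth (per-lesion area, peak HU, weight, total
score, risk bin) is kept by **independent bookkeeping that never calls the
scoring module**, so it serves as an oracle: the scorer must reproduce it
exactly. To keep that oracle exact, lesion placement forbids pixels
8-adjacent to previously placed lesions — distinct lesions can never merge
into one connected component (a single lesion splitting across placement
holes is harmless, since all its pixels share one HU bin).

The phantom emulates: class imbalance (≈ 10 % positive slices), per-patient
anatomy variability, density-bin mixtures, cohort-level risk-mix targets
(solved per patient by a greedy lesion-budget search; apportionments use
the largest-remainder method). It does **not** emulate: real calcification
morphology and texture, motion/beam-hardening artifacts, vessel anatomy
(quadrants are a stand-in), non-gated acquisitions, or scanner variation.
Conclusions transferable from the phantom are pipeline-level and
arithmetic-level, not clinical.

## Desk-scale sizing

The desk profile (`desk_profile()`) is sized so the full two-model
experiment runs on one CPU inside a test-suite budget:

| choice | value | default elsewhere | rationale |
|---|---|---|---|
| image size | 64² | 512² clinical | feasible attention length (T = 65) |
| ViT | embed 48, depth 2, heads 2 | ViT-B/8 (`vit_base8_config()`) | R matmul throughput |
| cohort | 24 patients × 20 slices | — | smallest stratified split with non-empty test strata per risk bin |
| pre-training | 6 epochs | 100-epoch regimes | ≈ 1 s/step measured |
| mean lesion area | 12 px | 119 px · (s/512)² | spec-scaled mean (≈ 1.9 px at 64²) is below the sampling limit of 0.05–0.4-area crops resized to 24²; 12 px survives the crop/resize chain |
| blur/noise probability | 0.1 / 0.25 | 0.5 / 0.5 | a 3×3 blur at 64² equals a ≈ 24-px blur at native 512², far stronger than the recipe intends |

`phantom_config()` and `dino_config()` defaults stay at the
reference-scaled values; only `desk_profile()` deviates, for the stated
sampling-theoretic reasons.

## Known limitations

* At desk scale, cross-patient lesion signal is weak in class-token
  features: patient anatomy dominates the embedding, and even a fully
  supervised linear probe on frozen features generalizes poorly across
  patients. The directional comparison between label-guided and standard
  pre-training (`compare_ssl_probes()`) is therefore expected to be noisy
  at this resolution; it tests the *direction* of the effect, not its
  magnitude. This is a resolution/scale limit of the 64² phantom, not a
  property of the method at clinical scale.
* The hand-written networks favor clarity and verifiability (gradients are
  finite-difference-checked in the test suite) over speed; they are not a
  substitute for a GPU framework at clinical resolution.
* The DICOM codec is deliberately minimal: single-frame, uncompressed,
  explicit-VR little-endian only. NIfTI is the primary interchange format.
* Pixel coordinates are 1-based throughout, following R convention.

## Reproducing the desk experiment

```{r desk, eval = FALSE}
library(cacpipe)
res <- reproduce_desk(seed = 1, out_dir = "desk_run")
res$comparison        # probe metrics, label-guided vs standard
res$risk$table        # risk confusion on test patients
```

`scripts/acceptance.R` (run as
`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`)
computes the package's acceptance-target values against the installed
package and writes them as JSON.
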