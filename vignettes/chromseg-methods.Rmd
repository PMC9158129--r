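---
title: "Partitioned IoU losses, confidence correction and mask NMS for overlapping chromosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioned IoU losses, confidence correction and mask NMS for overlapping chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromseg)
```

## The problem

Chromosomes in metaphase-spread images are thin, curved and frequently
overlap. Three standard components of instance-segmentation pipelines
misbehave in exactly this regime:

1. the whole-mask IoU loss `−ln IoU` barely reacts when one arm of a
   chromosome is mis-segmented, because the well-segmented remainder
   dominates the ratio;
2. the classification confidence used to rank detections can be high for
   instances whose box and mask are poor, corrupting both NMS and the
   precision–recall ranking;
3. box-based NMS deletes genuinely distinct instances whose *boxes*
   overlap heavily while their *masks* do not — the signature geometry of
   two crossing chromosomes.

`chromseg` implements one corrective per failure mode, plus the COCO-style
evaluation and a synthetic-scene generator that make the package
self-contained. This vignette documents the model, the tunable parameters,
the numerical choices, and what the synthetic experiments can and cannot
show.

## The partitioned K-IoU loss

For a ground-truth mask `gt` and prediction `pred`, the classic loss is
`L_IoU = −ln IoU(pred, gt)`. The partitioned loss divides the image into
`K = rows × cols` cells and computes

$$L_{K\text{-}IoU} = -\sum_{i=1}^{K} \delta_i \,\ln \mathrm{IoU}_i,
\qquad \delta_i = \frac{|\mathrm{Mask}_i|}{|\mathrm{Mask}|},$$

with `IoUᵢ` the IoU of the two masks restricted to cell *i* and `δᵢ` the
share of ground-truth pixels in that cell. Cells without ground truth
carry `δᵢ = 0` and never contribute. An unweighted variant (`δᵢ = 1` on
every ground-truth-bearing cell) is also provided; it penalizes a
single-cell error at least as hard as the whole-mask loss (the mediant
inequality `((I+C)/(U+C) ≥ I/U` for the untouched remainder `C` makes this
provable for errors confined to one cell), while the δ-weighted form never
exceeds the unweighted one and keeps the penalty proportional to how much
of the chromosome the damaged cell carries.

Design choices that the loss definition leaves open, and how this package
resolves them:

- **Partition frame.** We partition the *tight bounding box* of the
  ground-truth mask into equal cells and extend the boundary cells
  outward so the cells tile the whole image. Predicted false-positive
  pixels outside the ground-truth box therefore land in exactly one cell
  and are penalized; `Σδᵢ = 1` holds by construction. (Partitioning the
  RoI or the full image frame would either move with the proposal or
  make δ depend on image size.)
- **Grid reading.** The canonical setting is the 2 × 2 grid, read as one
  vertical plus one horizontal center split of the bounding box and
  generalized to `rows × cols`.
- **Uneven integer splits.** When the box side is not divisible, cell
  sizes differ by at most one pixel with the larger cells first
  (top/left) — deterministic and documented.
- **Empty∩empty convention.** A cell empty in both masks scores IoU 0,
  not 1. Such cells always have `δᵢ = 0`, so the loss never sees the
  convention; 0 merely avoids spurious perfect scores in per-cell
  reports.
- **Clamping.** Every log is clamped at `eps = 1e-7`. On fine grids some
  cells inevitably have zero IoU, which would otherwise produce an
  infinite loss (and, in a training context, a dead gradient); the clamp
  bounds the per-cell penalty at `−ln eps ≈ 16.1` and keeps every loss
  finite for arbitrary inputs. This is also why very fine grids are not
  useful defaults: K = 4 (2 × 2) is the canonical setting.
- **Soft masks.** All mask losses accept probability-valued masks via the
  soft intersection `Σ p·g` and union `Σ (p + g − p·g)`, which coincide
  with pixel counting on 0/1 input, so the same functions serve as
  differentiable training objectives. Binary masks are the tested
  contract.

## Regression confidence and score correction

The Smooth-L1 regression loss is averaged over the four box offsets
(averaging keeps its scale independent of the offset parameterization;
the quadratic/linear transition sits at 1). It is mapped to a confidence

$$P_{Box} = 1 - \tanh(L_{Reg}) \in (0, 1],$$

a strictly decreasing bijection that is 1 exactly for a perfect
regression. Numerically we evaluate the algebraically identical form
`2 / (1 + exp(2·L_Reg))` and floor it at the smallest positive double:
`1 - tanh(x)` rounds to exactly 0 beyond `x ≈ 19`, which would break the
codomain contract.

The corrected detection score is

$$\mathrm{score} = P_{Cls}\cdot \mathrm{IoU}_{Mask}^{\alpha}\cdot P_{Box}^{\beta},$$

with defaults `α = 2` and `β = 6` — the square on the mask-IoU factor and
a deliberately harsher sixth power on the regression confidence, the
exponent pairing that performed best in the ablation this design follows.
Both exponents are exposed; the correction is monotone non-increasing in
each exponent and non-decreasing in each input, and never exceeds the raw
confidence.

Head-supervision losses are provided for completeness of the per-proposal
ledger `L = L_Box + L_Seg` with `L_Box = L_Cls + L_Reg + L_PBox` and
`L_Seg = L_Mask + L_K-IoU + L_IoUMask`: cross-entropy for the classifier,
cross-entropy of the `P_Box` head against the transform of the realized
regression loss (reading its supervision as target generation through the
transform), mean per-pixel binary cross-entropy for the mask, and — since
no published form exists for the mask-IoU head in this ledger — squared
error to the realized mask IoU, the closest published precedent being
mask-scoring-style IoU regression.

## Mask-based NMS

Both NMS variants run the same greedy traversal: visit detections by
descending score, keep the current best, remove every remaining detection
whose IoU with it *strictly exceeds* the threshold. The only difference
is the overlap criterion (mask IoU vs box IoU). Ties are broken by lower
instance id, which makes the kept set invariant to input permutation.

Two open points are resolved as follows: the traversal is ordered by the
*corrected* score by default (`score_key = "raw"` switches to the raw
classification confidence) since correction happens before screening in
the intended inference path, though the ordering score is not otherwise
pinned down; and no box-level pre-filter runs by default — as many
candidates as possible should reach the mask stage — with an optional
high-threshold (e.g. 0.9) box pre-pass available for throughput.

`omission_fixture()` constructs the canonical failure case: two straight
arms of length 54 px and width 9 px crossing at 30°, centers offset by
6 px, giving box IoU 0.800 and mask IoU 0.200 on the pixel grid. At
threshold 0.5, box-NMS keeps one detection; mask-NMS keeps both.

One spec-level invariant was corrected during development: at threshold 0
greedy NMS does *not* keep exactly one detection per connected overlap
group (a chain A–B–C with A, C disjoint keeps A and C). The true property
— the kept set is a maximal independent set of the overlap graph — is
what the tests assert.

## Evaluation

AP^M follows COCO conventions wholesale: greedy score-ordered matching
with each ground truth consumed at most once, *inclusive* (≥) IoU
comparison at the matching threshold, 101-point interpolation of the
precision envelope, thresholds 0.50–0.95 in steps of 0.05 with AP^M their
mean and AP^M₅₀ / AP^M₇₅ the endpoints of interest. Matching is per
image; ranking pools all images. There is a single category and no
maxDets cap (scene instance counts are small). With no ground truth and
no detections the AP is defined as 0. The implementation is checked
against an independent brute-force scan of the 101 recall points on
random scenes (agreement to 1e-6 and better).

## The synthetic generator

`generate_scene()` emulates the geometry that matters for these methods:
each instance is a smooth random spine (random-walk control points,
cubic-spline interpolation) thickened by a width profile tapering toward
the telomeres, rendered dark on a light background with a sinusoidal
banding pattern along the spine. Defaults (512 × 512 scene, ~20 instances
of length 80–160 px and width 10–18 px, heading-change s.d. 0.35 rad,
overlap level 0.3, minimum tight-box aspect ratio 2) describe a plausible
metaphase-spread-like scene; they are configuration, not claims about any
clinical dataset. `overlap_level = 0` enforces pairwise-disjoint masks and
raises a capacity error when the scene cannot be packed. Each instance is
4-connected by construction (disks stamped along a densely sampled
spine). Every output is a pure function of `(config, seed)`, and
experiment scenes each draw from their own stream derived via
`derive_seed(seed, index)` so any scene can be regenerated alone.

`simulate_detections()` models a detector per ground-truth instance:
morphological erosion/dilation bias plus boundary roughening for the
mask, Gaussian corner jitter for the box, truthful-up-to-noise auxiliary
heads (`p_box` is the transform of the realized regression error of the
jittered box; `iou_mask` is the realized mask IoU), and a raw
classification confidence whose rank correlation with realized mask
quality is steered by `score_informativeness` (0 = confidently blind
detector). Spurious detections are short curve fragments whose truthful
heads are computed against the ground truth they most resemble.

What the generator does **not** model: real Giemsa banding statistics per
chromosome class, stain/illumination artifacts, touching-but-not-
overlapping boundary ambiguity, sub-pixel mask geometry, and full
1,600 × 1,200 clinical frames. Passing tests on these scenes demonstrates
the algebraic and algorithmic properties of the methods — loss
reductions and inequalities, NMS/oracle equivalence, AP correctness,
score-correction benefit under miscalibration — not clinical-grade
segmentation accuracy.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` run at desk scale, chosen so the
whole suite completes in about a minute: 1,000 random 32 × 32 mask pairs
for the loss algebra, 1,000 random 20-detection scenes for the NMS
oracle, 100 random scenes for AP reference agreement, and a 50-scene
confidence experiment on 96 × 96 scenes with 9 instances plus one
spurious detection (~500 detections). The experiment's harsh noise
setting (uninformative raw scores, truthful heads, −1 px erosion bias,
1.5 px boundary roughness on 5–9 px-wide instances) deliberately puts
most realized mask IoUs in the 0.4–0.7 band, where score ordering matters
and the corrected-vs-raw comparison is meaningful; the absolute AP^M
values under this regime are small by design and only the comparisons are
interpreted.

## Known limitations

- The K-IoU loss is implemented as a measurable objective, not wired to
  any autograd framework; gradients are out of scope.
- Binary (chromosome vs background) classification only; no multi-class
  NMS or per-class AP.
- Polygonal/sub-pixel masks and rotated boxes are not supported; all
  geometry is pixel-aligned with 0-based half-open boxes.
- The label-PNG writer refuses overlapping instances in single-map mode
  (a label map cannot represent them) and offers per-instance files
  instead; ids up to 65,535 are encoded across two 8-bit PNG channels.
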