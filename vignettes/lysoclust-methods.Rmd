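---
title: "Measuring lysosomal clustering around the MTOC: models, parameters and validation"
author: "lysoclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring lysosomal clustering around the MTOC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lysoclust)
```

## The measurement model

Lysosomal positioning is read out per cell as an intensity-fraction
statistic. Given a segmented cell, the MTOC located from the γ-tubulin
channel, and a circle of fixed physical diameter centred on the MTOC, the
raw clustering ratio is

$$R \;=\; \frac{\sum_{p \,\in\, \text{circle} \cap \text{cell}} I_{\text{lys}}(p)}
              {\sum_{p \,\in\, \text{cell}} I_{\text{lys}}(p)} \;\in\; [0, 1].$$

$R$ is invariant to positive rescaling of the lysosomal channel, so it does
not depend on exposure or gain, and it is bounded because the numerator
region is the circle *intersected with the cell*. Per well, the ratios of
non-excluded cells are summarized (mean by default, median available) and
divided by the same statistic of the pooled control wells — the *lysosomal
clustering value*. A control population normalized against itself is exactly
1, which anchors the fold-change scale. Hit calling is strict: a compound is
a hit only when its value exceeds the threshold (default 1.1), never at
equality.

The MTOC is found per cell by a three-step chain mirroring classical
interactive image processing, with every parameter explicit: percentile
contrast normalization (monotone clip-and-rescale to $[0,1]$), rolling-ball
background subtraction (grayscale opening with a disc of fixed physical
radius), and a data-driven threshold inside the cell followed by
connected-component analysis. The component with the largest integrated
intensity is taken as the single MTOC; its intensity-weighted centroid is
the circle centre. Cells with no suprathreshold tubulin signal are reported
as undetected and excluded from scoring with a logged reason, as are
border-touching cells (truncated denominators bias $R$) and cells with zero
lysosomal signal.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `circleDiameter` | 7 | µm | the assay's fixed measurement circle at the MTOC |
| `hitFoldThreshold` | 1.1 | fold | strict ">" hit rule on control-normalized values |
| `centralAreaFraction` | 0.70 | — | central region holds 70 % of cell area; the rest is "peripheral" |
| `backgroundRadius` | 5 | µm | rolling-ball radius; larger than the MTOC spot, smaller than a cell |
| `perWellStatistic` | mean | — | legends report mean ± SD; median available for skewed wells |
| `normPercentiles` | 0.001 / 0.9999 | — | spot-preserving contrast stretch (see below) |
| `peripheralIntensityFraction` | 0.5 | — | a cell "has peripheral lysosomes" when > 50 % of its lysosomal intensity is peripheral |
| `minNucleusArea` | 3.2 | µm² | debris rejection in nucleus segmentation |

All geometric parameters are physical; conversion to pixels uses each
field's own pixel size (mandatory input — the circle is a physical object,
so no magnification guessing). Pixel coordinates are 1-based `(row, col)`
indices with pixel `(i, j)` centred at `(i, j)`, the native R raster
convention; geometric centres are real-valued.

The upper normalization percentile deserves a note: an MTOC spot occupies a
few tenths of a percent of a field's pixels, while diffuse cytosolic signal
occupies tens of percent. Clipping at the 99th percentile would flatten the
spot into the cytosolic level and destroy detection; clipping at 0.9999
removes only hot pixels. This is a property of spot statistics, not of any
particular dataset.

## Segmentation choices

Nuclei are segmented by Gaussian smoothing (≈ 0.5 µm), a global data-driven
threshold (Otsu by default) and connected components, with sub-nuclear
debris removed. Cells are grown from nucleus seeds by seeded propagation
over a smoothed tubulin + lysosome composite, restricted to suprathreshold
cytoplasmic support united with the seeds: each nucleus yields exactly one
cell with the same label, every supported pixel belongs to at most one cell,
and each cell contains its seed entirely. The support threshold is computed
on the *log scale* (`log1p`): fluorescence spans decades, and a linear Otsu
threshold on a field with bright organelle clusters lands above the dim
cytosolic fill, collapsing the "cell" to its brightest blob. On the log
scale the background/cytosol separation dominates and bright structures
cannot drag the threshold up. Because the ratio statistic is
intensity-weighted, it is robust to the exact support boundary as long as
bright structures are inside and assigned to the right cell.

The central region of a cell is computed by iterative binary erosion with a
3×3 cross, stopping at the last iterate whose area is at least the target
fraction of the cell's area; this realizes "a fraction of the cell area
toward the cell centre" deterministically, with the achieved area within one
erosion step above the target, and makes central ⊆ cell true by
construction. The peripheral region is the set difference.

## What the synthetic generator emulates

`generateField()` renders the study conditions for validation: cells as
non-overlapping discs on a jittered grid (radius 8 ± 0.4 µm), a nuclear disc
(2.5 µm), one bright MTOC spot offset 1 µm from the nucleus edge, and
`nPuncta = 40` lysosomal puncta per cell, each an isotropic Gaussian of
σ = 0.3 µm. A punctum is placed with probability κ uniformly inside the 7 µm
measurement circle around the MTOC, and otherwise uniformly across the
cytoplasm — including, by chance, inside the circle. Under that placement
the expected raw ratio is

$$\mathbb{E}[R] \;=\; \kappa + (1 - \kappa)\,a,$$

with $a$ the circle's area fraction of the cytoplasmic placement domain
(computed analytically per cell from the disc-intersection geometry and
stored in the ground truth). Two rendering details keep the planted
geometry *exactly* recoverable, which is what makes sharp statistical
validation possible:

* puncta kernels are truncated at 3σ and placed with their full footprint
  inside their compartment (inside the circle for clustered puncta, inside
  the cell for dispersed ones, with a 1-pixel guard for MTOC localization
  error), so at κ = 1 the measured ratio is exactly 1 rather than
  1 − (boundary leakage);
* the tubulin channel carries a dim diffuse cytosolic fill in addition to
  the MTOC spot — as a GFP-tagged tubulin construct genuinely does — which
  gives cell segmentation a whole-cell support so the denominator sees every
  punctum.

Noise is applied last: Poisson on the rendered signal and Gaussian read
noise (sd 2), clamped at zero. The default pixel size is 0.325 µm/px, a
typical 20× high-content configuration making the circle ≈ 21.5 px across.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: irregular cell and nucleus shapes, touching or
overlapping cells, multi-centrosome cells, out-of-focus light and shading
gradients, vesicle substructure, and channel bleed-through. The pipeline's
robustness to those has to be judged on real images; the synthetic suite
validates the *accounting*, i.e. that the implemented measurements compute
what they claim.

## Validation design and problem sizes

The package's own validation (test suite and `scripts/acceptance.R`) runs:

* **Funnel counts.** A 1200-compound table with 63 planted primary hits
  (margin ≥ 0.05 above the 1.1 threshold, noise sd 0.01), a secondary table
  over the 63 with 15 planted passers, 5 flagged autofluorescent: the
  cascade must report 63 → 15 → 10 with exactly the planted identities and
  chained stage counts.
* **Analytic identity.** On constant-intensity cells,
  $R = |{\rm circle} \cap {\rm cell}| / |{\rm cell}|$ to 1e-9.
* **Oracle equivalence.** The clustering ratio, circle mask, hit calling,
  pixels-above-threshold and band ratios each match naive brute-force
  implementations on ≥ 100 random instances.
* **Parameter recovery.** 200 generated cells per κ ∈ {0, 0.25, 0.5, 0.75,
  1}, run end-to-end (segmentation → MTOC detection → ratio); the mean
  measured ratio must lie within 3 standard errors of
  $\kappa + (1-\kappa)a$, cells matched one-to-one to ground truth. These
  runs disable the noise model: the check isolates the geometric accounting,
  for which the generator's own placement examples are defined noise-free;
  noise robustness is covered separately by the localization and separation
  checks below. Being a 3σ criterion on a stochastic quantity, it retains
  an irreducible ≈ 1 % false-alarm probability per κ under resampling.
* **MTOC localization.** Median localization error < 1 px over > 100 cells
  with full noise (spot SNR far above 5).
* **Positive-control separation.** κ = 0.8 wells versus κ = 0.2 controls,
  full noise, 50 seeded replicates: the clustering value must exceed 1.1 in
  ≥ 95 % (the synthetic analogue of a starvation positive control; the
  planted contrast corresponds to a value near 2.2, so this is a robustness
  check, not a borderline one).
* **Flux readouts.** Gating recovers planted dead/RFP-negative counts
  exactly; the median RFP/GFP ratio recovers a planted 2.0× fold change
  within order-statistic error; the HaloTag ratio reproduces
  $100x/(x+y)$ exactly and stays in [0, 100].

## Numerical conventions and degenerate inputs

* Constant images normalize to all zeros; flat images background-subtract
  to zero; an all-zero nuclear image segments to an empty mask (not an
  error).
* A constant positive sample thresholds at half its value, so uniformly
  bright support stays suprathreshold.
* A circle always contains at least the pixel under its centre (diameters
  below the pixel spacing degenerate to that pixel); a centre outside the
  image yields an empty mask with a warning.
* Non-finite fold changes are excluded with a logged reason, never dropped
  silently; zero denominators in flux ratios yield missing values with
  warnings.
* Component ties in MTOC detection break by greater peak intensity, then
  smaller scan-order label; object numbering after filtering is by first
  scan-order encounter. Everything is deterministic for fixed inputs,
  configuration and seed.
* EBImage's grayscale morphology operates on [0, 1]; rasters are rescaled
  by their maximum before opening and back after, which is exact because
  min/max filters commute with positive scaling.

## Open design points, resolved

Several aspects of the published procedure are underdetermined; the package
fixes them as explicit, configurable choices:

* **Circle clipped to the cell** (default on): guarantees $R \le 1$ and
  excludes neighbour-cell bleed-through; the unclipped circle is available
  via `clipCircleToCell = FALSE`.
* **Nucleus in the denominator** (default on): "whole-cell" is read
  literally; `excludeNucleusFromDenominator = TRUE` is provided.
* **Peripheral-lysosome cells**: no quantitative criterion is published;
  the 0.5-intensity-fraction rule is a declared stand-in surfaced as
  configuration.
* **Secondary screen and autofluorescence**: secondary hits are called by
  the same strict 1.1-fold rule on RFP/GFP fold changes, and flagged
  autofluorescent compounds are excluded *afterwards* as an annotation (no
  automatic detection is attempted — none is derivable from fold-change
  tables).
* **One MTOC per cell**: the brightest component is reported;
  multi-centrosome cells are out of scope.
* **Dispersed puncta may fall inside the circle**: the generator places
  non-clustered puncta uniformly over the whole cytoplasm rather than only
  outside the circle, which is both the physically sensible null and the
  placement under which the analytic expectation
  $\kappa + (1-\kappa)a$ holds.

## Known limitations

2-D fields only (no z-stacks), no live-cell tracking or deconvolution, no
plate-effect correction beyond control normalization (no B-score/loess), no
dose–response modelling, no automated flow gating or spectral compensation,
and densitometry starts from band-intensity tables (no gel-image lane
segmentation). The final microscopy confirmation stage of a screening
funnel is inherently manual and is recorded as an annotation, never
computed.
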