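# lysoclust

Quantification of lysosomal positioning for high-content chemical screening.

Lysosomes that cluster around the microtubule-organizing center (MTOC) fuse
more readily with autophagosomes, so compounds that drive lysosomes toward
the MTOC are candidate autophagy inducers — of direct interest for clearing
aggregation-prone proteins such as α-synuclein. `lysoclust` implements the
image-based readout behind that screening idea, for cell biologists and
screening groups working with multi-channel fluorescence plates: a nuclear
stain, a γ-tubulin (MTOC) channel and a lysosomal-marker channel per field,
plus flow-cytometry and densitometry readouts for follow-up flux assays.

## The statistic

For each segmented cell with a detected MTOC, a circle of fixed physical
diameter (default 7 µm) is centred on the MTOC and the **raw clustering
ratio** is

    R = Σ I_lys(circle ∩ cell) / Σ I_lys(cell)          R ∈ [0, 1]

the fraction of the cell's whole lysosomal fluorescence lying inside the
circle. Per well, ratios are summarized (mean by default) and divided by the
pooled control statistic to give the **lysosomal clustering value**; a
compound is a **hit** when its value exceeds the control by *strictly more*
than a 1.1-fold change. A multi-stage cascade (primary call → secondary
RFP/GFP flux call → autofluorescence exclusion → optional annotated
confirmation) is tracked in an auditable ledger whose stage counts chain
exactly.

Supporting metrics: MTOC detection (contrast normalization → rolling-ball
background subtraction → per-cell Otsu spot picking), central/peripheral
cell partitioning by iterative erosion (70 % of cell area toward the
centre), peripheral-lysosome cell percentages, aggregate–lysosome
colocalization, pixels-above-threshold readouts, flow-cytometry RFP/GFP
ratios with live-cell gating, and band-ratio densitometry including the
HaloTag processing ratio `100·x/(x + y)`.

A first-class synthetic-data generator renders multi-channel fields with
known ground truth — cells, nuclei, one MTOC spot each, and lysosomal puncta
whose clustered fraction κ is planted — plus screen tables with planted hits
and flow-event tables with planted gate categories. Every generator is a
pure function of (specification, seed).

## Worked example

```r
library(lysoclust)
res <- runDemo(seed = 7)
```

```
CascadeLedger with 3 stage(s)
  primary hit call                60 ->     5   [fold change > 1.1]
    excluded: C0001, C0002, C0003, C0004, C0005, C0006, C0007, C0008, ... (47 more)
  secondary hit call               5 ->     3   [RFP/GFP fold change > 1.1]
    excluded: C0042, C0039
  autofluorescence exclusion       3 ->     2   [remove flagged autofluorescent compounds]
    excluded: C0031
clustered well clustering value: 2.217 (control = 1)
flow RFP/GFP fold change (planted 2.0): 1.979
final candidates: C0028, C0019
```

The demo plants 5 hits among 60 compounds, recovers all of them at the
1.1-fold rule, passes 3 through a synthetic secondary flux screen, and
removes 1 flagged autofluorescent compound. The two-well image plate shows a
clustered well (κ = 0.8) scoring a clustering value of 2.217 against its
dispersed control (κ = 0.2, value 1 by construction), and the flow branch
recovers a planted 2.0× RFP/GFP fold change as 1.979.

Scoring real images follows the same functions:

```r
field <- readFieldImage("well_A02.tif",
                        c(nuclear = 1, tubulin = 2, lysosome = 3),
                        pixelSize = 0.325, wellId = "A02")
layout <- readPlateLayout("plate.csv")
res <- scorePlate(list(field, ...), layout, analysisConfig())
res$wells          # well_id, n_cells, statistic, clustering_value
callHits(data.frame(compound_id = res$wells$compound_id,
                    fold_change = res$wells$clustering_value), 1.1)
```

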