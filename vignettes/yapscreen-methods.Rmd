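---
title: "Methods: dual-modality YAP/TAZ screen analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-modality YAP/TAZ screen analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yapscreen)
```

## The analysis problem

Nuclear accumulation of the transcriptional co-activators YAP and TAZ marks
an inactive Hippo pathway and drives a TEAD-dependent transcriptional
program implicated in triple-negative breast cancer. An RNAi screen for
Hippo-pathway regulators therefore has two natural, complementary readouts
for each silenced gene: where YAP/TAZ sits in the cell (imaged per well),
and how active the YAP/TAZ-TEAD axis is (a TEAD-driven luciferase
reporter). `yapscreen` implements the full analysis chain for such a paired
screen — image quantification, per-modality hit calling, and multi-level
integration — together with a synthetic-data generator that stands in for
the wet-lab stages so that every statistical step can be verified against
known ground truth.

## Localization modality

**Per-cell quantification.** Nuclei are segmented in the DAPI channel by a
global Otsu threshold followed by a distance-transform watershed
(`segment_nuclei()`); touching nuclei are split, objects under `min_area`
pixels (default 20) are discarded. The cytoplasm of each cell
(`segment_cytoplasm()`) is the FITC-foreground within a ring of
`ring_width` pixels (default 10) around its nucleus, excluding all nuclear
pixels; pixels reachable from several nuclei go to the nearest one, so
cytoplasm territories are disjoint by construction. The commercial software
used on the original instrument does not document its segmentation
algorithm, so these are the standard open building blocks for the same
task; the package makes no attempt to mimic a proprietary pipeline
pixel-for-pixel. Two foreground rules are available for the FITC channel:
the default estimates the background as median + 3 MAD of the non-nuclear
pixels (robust when cytoplasmic brightness varies strongly from cell to
cell, as it does by design in the simulated wells); `fg_method = "otsu"`
applies a bimodal threshold to the same pixels instead.

The **FITC ratio** of a cell is its mean cytoplasmic FITC intensity over
its mean nuclear FITC intensity; low values mean nuclear-enriched YAP/TAZ.
Cells are classed *nuclear* when ratio ≤ 0.4 and *cytoplasmic* when ratio
≥ 0.65. The source thresholds are printed without their comparison
operators, so the package fixes the orientation by the biology (a low
cytoplasm/nucleus ratio is nuclear enrichment) and makes both boundaries
inclusive toward their class; everything between is *intermediate*. Cells
with an empty cytoplasm region or a zero nuclear mean are excluded and
logged, never imputed. The per-well readout is the percentage of
cytoplasmic cells among included cells.

**Hit calling.** Well metrics are divided by the mean of the siCTL
(non-targeting) wells of the same biological replicate. The division-vs-
subtraction choice is deliberately inconsequential: the subsequent Z-score
is location-scale invariant, so hit calls cannot depend on it. Z-scores are
computed per replicate over the library wells of the whole screen (controls
scored against that distribution but excluded from it); the sample SD
(n − 1) is the default. A gene is a cytoplasmic-direction hit when it lies
within the top `ceiling(0.25 · N)` Z-scores of *every* replicate — ties at
the cutoff break lexicographically by gene id so results are deterministic
— and a nuclear-direction hit when z < −1.8 in every replicate. Because
YAP/TAZ is already predominantly nuclear in these cell lines, the nuclear
direction is expected to be nearly empty; under a pure-null simulation its
expected count is `720 · P(Z < −1.8)² ≈ 0.9` genes, which the test suite
checks.

## Reporter modality

Firefly luciferase is normalized to β-galactosidase well by well; both
readings share any plate-level transfection-efficiency factor, which
therefore cancels exactly in the ratio. Normalized values become fold over
the median of the *library* wells of the same plate — controls are excluded
from the median so that control-heavy plates are not biased; the
even-count median is the midpoint of the central pair, making the median
library fold exactly 1 on every plate. Inhibitors are genes with fold
< 0.5 and activators fold > 2, strict inequalities (a fold of exactly 0.5
or 2 is a non-hit). The reporter screen is a single run per cell line; no
replicate intersection is applied.

## Integration

Hit sets intersect first across modalities within a cell line
(cytoplasmic-localization hits × reporter inhibitors, and symmetrically
nuclear hits × reporter activators, even though the latter class is
expected to be nearly empty), then across cell lines. `venn_counts()`
reports exclusive-region and intersection sizes for two or three sets, and
`build_hit_report()` emits one row per gene with Z-scores, fold, all flags
and an evidence string, ordered by evidence tier, then mean Z, then gene
id — a total ordering, so reruns are identical. Genes present in only one
modality's table abort the report with the orphan ids listed, rather than
being silently dropped.

## Follow-up quantifications

`ddct_relative_expression()` implements ΔΔCt with amplification efficiency
fixed at 2: technical replicates are averaged on the Ct scale, ΔCt is
target minus reference (HPRT1 by default) within condition, ΔΔCt subtracts
the calibrator condition (siCTL), and fold = 2^−ΔΔCt. The calibrator fold
is exactly 1 by construction and folds are invariant to any constant Ct
offset. With biological replicates, the SD is taken on the fold scale
across replicates — the uncertainty propagation for these bar-plot style
figures is not standardized, and the fold scale is what the plots show.
`growth_from_counts()` divides condition mean nuclei counts by the control
mean, with the SD of the per-replicate counts mapped onto the same scale.
`categorize_manual()` reproduces manual N>C / N=C / C>N scoring with a
configurable equal band (default ±0.1 around ratio 1) and warns below 30
cells, the conventional minimum for manual quantification.

## The synthetic-data generator

The generator emulates the study design, not optics: a 720-gene kinome
library screened in 384-well plates with 72 siCTL and 16 siMARK4 wells per
run and two biological replicates per cell line, and in 96-well plates with
8 siCTL and 4 siYAP wells on *every* plate (the two schemes differ in kind:
localization controls are totals spread evenly across plates, reporter
controls are per plate, hence the `per_plate` flag of `layout_plates()`).
Control positions are uniform across plates and seed-deterministic; the
combined-control histogram counts (144 siCTL, 32 siMARK4 over two runs)
follow from the per-run scheme, and the counts remain configurable.

Spiked localization effects shift the percent-cytoplasmic well metric by
`loc_effect · effect_sd`; `effect_sd` defaults to the well SD so effects
are in control-SD units, but is an explicit argument so that the noiseless
limit (`well_sd = 0`) can keep finite effects — this is what makes every
downstream statistic recoverable in closed form and is used as the oracle
throughout the test suite. Well noise is additive Gaussian on the percent
metric (default SD 1 percentage point) and multiplicative lognormal on
luminescence (default sdlog 0.2, a ~20 % CV typical of luciferase assays);
plate effects are multiplicative and shared by firefly and β-gal so that
the normalization visibly removes them. Percentages clamp silently to
[0, 100]; values at the bounds are legal. Default effect sizes — 20 dual-
modality inhibitors at +3 SD localization shift and 0.3 reporter fold,
siMARK4 at +6 SD in the MDA-MB231-like line and 0 in the MDA-MB468-like
line, siYAP at 0.2 — are the calibration the screen design is meant to
resolve cleanly, and they stay fixed across the test suite and acceptance
script.

Rendered wells draw each cell as concentric hard-edged disks (DAPI nucleus;
FITC nucleus plus cytoplasmic annulus) over a flat background with optional
per-pixel Gaussian noise, clipped and rounded to 16-bit counts, and record
each cell's constructed ratio as ground truth. This deliberately omits
point-spread blur, illumination gradients, cell crowding and debris; a
passing imaging test therefore certifies the measurement arithmetic and
segmentation logic, not robustness to real microscopy artifacts. With a
zero background the measured ratio of a rendered cell equals the
constructed ratio to within integer quantization (the acceptance checks
use ≤ 1 %); a nonzero background biases ratios toward 1, as it does on a
real microscope without background subtraction.

## Numerical and design choices

* Determinism: every stochastic stage takes a `noise_model()` carrying its
  own seed; `run_full_pipeline()` derives per-stage, per-line seeds from
  the single config seed, and reruns are bit-identical. Ties in ranking
  break by gene id; orderings are total.
* Degenerate inputs fail loudly and name the offender: missing siCTL wells
  name the replicate, zero library SD aborts Z-scoring, a zero plate median
  aborts fold conversion, a missing reference gene names the condition.
* The spike-in recovery contract (checked over 50 simulated screens in the
  test suite; 10 in the faster acceptance script, sizes chosen as a
  comfortable margin for the binomial bounds involved) is ≥ 90 % of spiked
  dual-modality inhibitors recovered with ≤ 8 % of null genes called.
* The control-separation statistic (fraction of siMARK4 Z-scores below the
  siCTL maximum) compares extreme order statistics, so a single screen
  separates completely with probability ≈ 0.96 at a 6 SD effect; the suite
  asserts complete separation for the typical (median) screen rather than
  for every seed, and overlap indistinguishable from null (two-sample KS)
  when the effect is absent.

## Limitations

Spatial plate artifacts (edge effects, gradients) are neither simulated
nor corrected — no B-score/median-polish; the rank-threshold hit rules of
the original design use no p-values, so no FDR machinery is attached; the
4-siRNA pools are treated as single units with no deconvolution; and the
image pipeline targets the synthetic renderer's geometry — applying it to
real micrographs will work mechanically but inherits all the usual caveats
of threshold-based segmentation.
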