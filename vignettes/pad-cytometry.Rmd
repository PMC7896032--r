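---
title: "Chromocenter cytometry and the conserved-heterochromatin scaling model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromocenter cytometry and the conserved-heterochromatin scaling model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(padcyto)
```

## The measurement problem

Pericentromere-associated domains (PADs) are blocks of constitutive
heterochromatin containing one or more centromeres; in interphase nuclei
they appear as DAPI-dense, H3K9me3-positive chromocenters. During early
differentiation commitment these domains reorganize: large perinucleolar
clusters unravel into small, often monocentromeric units. The quantities
that capture this are per-cell counts and sizes of chromocenters, the
nesting of centromere (CENPA) foci inside them, the DNA-content class of
each cell (so that replication is not confounded with fusion–splitting),
the spatial heterogeneity of the active (H3K4me3) chromatin, the
acridine-orange red/green ratio as a DNA-conformation index, and
transcript levels of pericentric satellite lncRNA by qPCR.

`padcyto` implements this battery as one tested pipeline. The original
measurements of this kind were made with interactively drawn contours;
every contour here is instead derived from explicit, configurable
thresholds so that a run is a pure function of (images, configuration,
seed).

## The scaling model and its fits

The central biological model is conservation: a cell holds a total
chromocenter area $A$ (µm²) and redistributes it over $n$ fragments.
Conservation implies mean fragment area $\bar a = A/n$, hence

* $\log n = \log A - \log \bar a$: a log–log regression of count on mean
  area has slope $-1$ (`fitPowerLaw`, log base 10, raw per-cell points);
* $1/n = \bar a / A \propto (\sqrt{\bar a})^2$: over the observed dynamic
  range, $1/n$ rises approximately linearly with the perimeter proxy
  $\sqrt{\bar a}$ (`fitReciprocalSqrt`, ordinary least squares);
* the individual-size spectrum is broad and decreasing; binned counts are
  fitted as $\log(\text{count})$ versus bin centre (`fitExponential`).

Centromere clustering is summarized by both a linear and an exponential
fit of per-chromocenter centromere count on area
(`fitCentromereClustering`), reported side by side because on real data
the two fit comparably well and the comparison itself is informative.

Fitting conventions, chosen where the field leaves them open, are:

* all fits are ordinary least squares; $R^2$ is always reported on the
  fitted (transformed) scale, because that is the scale on which common
  curve-fitting software reports it;
* power-law fits use raw per-cell points and base-10 logs; the
  exponential size-spectrum fit uses equal-width bins up to a cap
  (default 6 µm², covering the bulk of the spectrum) and natural logs, so
  its slope is a rate per µm²;
* non-positive values are excluded before any log (with the exclusion
  count recorded), since zero-count cells carry no information about a
  log-scale relationship;
* no maximum-likelihood power-law estimation is used: the claim being
  checked is regression-based, and an MLE exponent answers a different
  question. Every fit is verified in the test suite against a
  normal-equations oracle at 1e-10.

Degenerate inputs are defined, not crashed on: a constant response yields
slope 0 with $R^2 = 0$; a zero-variance predictor is an error; a
single-bin histogram is an error; an all-equal centromere count makes the
exponential branch return a flagged degenerate result.

## The synthetic-data generator

Because raw microscopy of this experiment is not publicly deposited, the
package ships a generator that emulates the statistical structure the
analysis assumes, with full ground truth, and the entire pipeline is
validated by recovery on it.

Per cell: the DNA-content class is drawn (2C 85 %, S–G2 10 %,
preapoptotic 5 % by default — the proportions a starved, mostly
G0/G1-arrested population shows); the chromocenter count $n$ comes from a
configurable count law (default uniform on 6..16, the range most
interphase cells display); the conserved total area (default 16 µm²) is
split into $n$ fragments by symmetric-Dirichlet stick-breaking
(concentration 5; redrawn, boundedly, so no fragment falls below the
finest resolvable unit). The total is multiplied by a lognormal factor
with `areaCV` (default 0.1) — the cell-to-cell tightness of conservation
is not established anywhere we know of, so 0.1 was fixed once as a
realistic mild scatter and not revisited. Preapoptotic cells override the
count law with 2–4 aggregated chromocenters and render at 0.6× DAPI
intensity (partial DNA loss); S–G2 cells render at 2×.

Rendering: the nucleus is an ellipse; each chromocenter is a
Gaussian-profile disc truncated at its half-maximum contour (soft edge
inside the nominal radius, exactly zero outside — pure Gaussian tails
would bridge neighbouring blobs above threshold and silently merge them).
Placement is rejection sampling with bounded retries; failure is reported,
never silently overlapped. Centromere foci (count
$\max(1, \text{round}(\text{density} \times \text{area}))$, default
density 1.2 µm⁻² — the density of *resolvable* foci, since physically
adjacent centromeres merge optically at this scale) are placed inside
each disc with a minimum separation when feasible; when a chromocenter is
too small to hold its foci separated, they are placed best-effort and the
ground truth records `sep_ok = FALSE`, so exactness guarantees are
conditional on separation, as they are on real images.

All randomness derives from one root seed by a fixed rule (`set.seed`
once, per-cell sub-seeds drawn up front, each cell's draws in its own
stream, then per-field noise streams), which makes ground truth identical
whether or not rasters are rendered and reruns byte-identical.

What the generator does **not** emulate: optics (no PSF, no chromatic
shift, no uneven illumination), 3-D structure (single plane only),
touching or overlapping nuclei, autofluorescent background gradients, and
chromosome-territory geometry. Passing recovery tests therefore
demonstrates the correctness of the measurement code under the stated
model, not robustness to every artefact of real microscopy; the
thresholds exposed in `segmentationConfig()` are the knobs a user would
retune on real data.

## Quantification choices

* **Nucleus segmentation**: Gaussian smoothing (σ = 2 px) then Otsu on
  the DAPI channel, with the cut multiplied by `nucleusThreshFrac`
  (default 0.6). The scaling matters because DNA content varies 0.6–2×
  across classes: a raw Otsu cut sits above the dimmest (preapoptotic)
  nuclei and deletes exactly the class the gating needs. Border-touching
  and sub-minimum objects are dropped and counted in the log; oversized
  objects are kept but flagged as under-segmentation.
* **Connectivity** is 8-neighbour throughout (implemented as 4-connected
  labelling plus a union-find merge of diagonal contacts).
* **DNA gating**: the 2C anchor is the taller peak of a kernel density
  estimate of IFI; the window half-width is 0.25 (no published window
  exists; ±25 % comfortably covers staining and size variation while
  separating 2C from 2× S–G2 content). Gating is IFI-only by default;
  passing per-cell mean chromocenter areas additionally requires
  top-quartile aggregation before calling a low-IFI cell preapoptotic.
* **Chromocenter segmentation**: per nucleus, red threshold =
  median + 0.5 × (peak − median); components below 0.2 µm² (the finest
  unit confocal imaging resolves here) are discarded.
* **Centromere counting**: green components assigned to the chromocenter
  containing their centroid; minimum focus size 1 px (a focus centred on
  a pixel can legitimately occupy a single pixel above threshold).
* **Heterogeneity**: fraction of nucleus pixels deviating *strictly* more
  than 10 % from the mean green intensity — deviations of exactly the
  tolerance do not count, the statistic is scale-invariant by
  construction, and an all-zero field is defined as 0.
* **AO R/G**: measured per nucleus (cells are imaged individually), no
  background subtraction by default (none is documented for the original
  measurement; a constant-offset option exists), normalization by the
  arithmetic mean of the control group so the control mean is exactly 1.
  Whether a 60-min population has split into two subpopulations is
  *reported* by `detectBimodality` (two density modes separated by more
  than twice the pooled within-mode SD) — a reporting rule, not a tested
  claim, because no quantitative split criterion was ever published.

## qPCR and statistics

CT replicates are averaged arithmetically before any difference; the
amplification efficiency is fixed at 2 (the $2^{-\Delta\Delta CT}$
model). Two reference schemes are supported, mirroring the two assay
arms: a single reference gene, or two references combined by arithmetic
mean of CTs — which is exactly geometric-mean normalization on the
quantity scale. The geNorm stability measure is reimplemented from its
published definition: $M_j$ is the mean over other candidates $k$ of the
SD across samples of $\log_2(Q_j/Q_k)$ with $Q = 2^{-CT}$; it is zero for
perfectly covarying references and invariant to per-sample plate offsets.

Group comparisons use the Welch (unequal-variance) two-tailed test —
"t-test" alone underdetermines the variant, and Welch is the safer
default — computable from raw values or directly from published
mean/SD/n summaries. p-values within one experiment form a single
Benjamini–Hochberg family. Degenerate cases are defined: two zero-SD
groups with equal means give p = 1; with different means the p-value is
reported below machine epsilon with a flag rather than as a division
error.

## Problem sizes and numerical conventions

The test suite validates recovery at the sizes a laptop-scale check
needs: 128–420 px fields, cohorts of 6–300 cells, 1000-replicate
simulation loops for the unbiasedness and false-positive-rate properties,
and 300 cells for the conserved-area scaling measurement. Coordinates are
pixel-centred and row-major; areas convert by the square of the pixel
calibration; all comparisons against oracles use 1e-10 (regressions) or
machine-precision (identities) tolerances.

## Known limitations

Segmentation quality on real images depends on the exposed thresholds;
no adaptive/learned segmentation is provided. The heterogeneity statistic
is intensity-based and blind to spatial arrangement (a checkerboard and a
half-split field with the same histogram score identically). The AO
simulation models the per-nucleus ratio distribution, not the
photophysics of the dye. qPCR efficiency correction and cross-plate
calibration are out of scope. The pipeline is 2-D; confocal stacks must
be projected upstream.
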